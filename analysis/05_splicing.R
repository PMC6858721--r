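#!/usr/bin/env Rscript
# Stage 5: type alternative-splicing events between isoforms of each locus,
# census splice-site dinucleotides against the genome, and place every
# splice junction in its genomic context.

suppressPackageStartupMessages(library(isoforge))

data_dir <- "results/data"
genome <- read_fasta(file.path(data_dir, "genome.fa"))
ann <- read_gff3(file.path(data_dir, "annotation.gff3"))
retained <- read_gff3("results/retained.gff3")
retained$gene_id <- NA_character_

loci <- classify_isoforms(build_loci(retained, ann), ann)
events <- detect_locus_as_events(loci, fuzz = 10L)
write.table(events, "results/as_events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
summary <- as_type_percentages(events)
write.table(summary, "results/as_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("AS events by type:\n")
print(as.data.frame(summary))

cen <- splice_site_census(retained, genome)
write.table(cen$per_intron, "results/census.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("splice-site dinucleotide census of retained isoforms:\n")
print(round(100 * cen$fractions, 2))

ctx <- sj_context(introns_of(retained), ann)
write.table(ctx$per_junction, "results/sj_context.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("junction genomic context:\n")
print(ctx$counts)

xc <- exon_count_by_as_status(loci, events)
cat(sprintf("mean exon count: AS genes %.2f (n=%d), non-AS genes %.2f (n=%d)\n",
            mean(xc$as_genes), length(xc$as_genes),
            mean(xc$non_as_genes), length(xc$non_as_genes)))
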