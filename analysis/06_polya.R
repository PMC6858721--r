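#!/usr/bin/env Rscript
# Stage 6: cluster FLNC 3' ends into polyadenylation sites per gene locus
# and summarise alternative polyadenylation.

suppressPackageStartupMessages(library(isoforge))

data_dir <- "results/data"
reads <- read_flnc(file.path(data_dir, "flnc.bed"),
                   file.path(data_dir, "flnc_pid.tsv"))
ann <- read_gff3(file.path(data_dir, "annotation.gff3"))
retained <- read_gff3("results/retained.gff3")
retained$gene_id <- NA_character_

multi <- unique(reads$read_id[duplicated(reads$read_id)])
single <- reads[!reads$read_id %in% multi, ]
loci <- classify_isoforms(build_loci(retained, ann), ann)

sites <- call_polya_sites(single, loci, cluster_radius = 24L,
                          min_support = 2L)
write.table(sites[, setdiff(names(sites), "member_positions")],
            "results/polya_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
apa <- call_apa(sites)
cat(sprintf("%d polyA sites over %d genes; %d genes show APA (>= 2 sites)\n",
            apa$total_sites, apa$genes_with_sites, apa$apa_genes))

truth <- read.table(file.path(data_dir, "truth_polya.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
cat(sprintf("simulated: %d sites with >= 2 supporting reads over %d genes\n",
            sum(truth$n_reads >= 2), length(unique(truth$gene_id))))
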