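#!/usr/bin/env Rscript
# Stage 7: merge the novel isoforms with the reference annotation into the
# unified transcript library and report its structural summary.

suppressPackageStartupMessages(library(isoforge))

ann <- read_gff3("results/data/annotation.gff3")
classified <- read_gff3("results/isoforms_classified.gff3")

# novel = everything not reproducing an annotated structure
loci <- classify_isoforms(build_loci(
  within(classified, gene_id <- NA_character_), ann), ann)
lab <- loci$assignments[!is.na(loci$assignments$label), ]
novel <- classified[classified$tx_id %in%
                      lab$tx_id[lab$label != "known_known"], ]
novel$gene_id <- NA_character_

merged <- merge_library(ann, novel)
write_gff3(merged$library, "results/merged_library.gff3")
s <- merged$summary
jsonlite::write_json(s, "results/library_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat(sprintf("library: %d transcripts (%d reference + %d novel)\n",
            s$n_total, s$n_reference, s$n_novel))
cat(sprintf("median exon size: %s bp; median gene size: %s bp\n",
            format(s$median_exon_size), format(s$median_gene_size)))
cat(sprintf("mean coding exons per gene: %.2f (%d of %d genes lack CDS and fall back to all exons)\n",
            s$mean_coding_exons_per_gene, s$n_genes_cds_fallback, s$n_genes))
cat("transcript length histogram (exonic bp):\n")
print(s$length_histogram)
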