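#!/usr/bin/env Rscript
# Stage 1: generate the study dataset — a toy multi-chromosome genome with
# annotated multi-exon gene models, FLNC read alignments (including novel
# splice variants, intergenic transcripts and chimeric fusion reads), and a
# short-read junction-support set. All downstream stages read these files.

suppressPackageStartupMessages(library(isoforge))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 2026L)
sim <- simulate_genome(cfg)
fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
js <- simulate_junction_support(cfg, fl$reads, sim$annotation)

write_fasta(sim$genome, file.path(out, "genome.fa"))
write_gff3(sim$annotation, file.path(out, "annotation.gff3"))
write_flnc(fl$reads, file.path(out, "flnc.bed"), file.path(out, "flnc_pid.tsv"))
write_junctions(js, file.path(out, "junctions.bed"))

# ground truth, for the comparisons in later stages
write.table(fl$truth$reads, file.path(out, "truth_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fl$truth$polya_sites, file.path(out, "truth_polya.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fl$truth$as_events, file.path(out, "truth_as_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fl$truth$fusions, file.path(out, "truth_fusions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d chromosomes x %d bp\n", cfg$n_chroms,
            cfg$chrom_length))
cat(sprintf("annotation: %d genes\n", nrow(sim$annotation)))
cat(sprintf("reads: %d FLNC (%d segments), labels: %s\n",
            length(unique(fl$reads$read_id)), nrow(fl$reads),
            paste(names(table(fl$truth$reads$label)),
                  table(fl$truth$reads$label), collapse = ", ")))
cat(sprintf("junction support: %d junctions\n", nrow(js)))
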