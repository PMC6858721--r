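#!/usr/bin/env Rscript
# Stage 4: call fusion transcripts from multi-segment alignments under the
# four breakpoint rules and compare with the simulated chimeras.

suppressPackageStartupMessages(library(isoforge))

data_dir <- "results/data"
reads <- read_flnc(file.path(data_dir, "flnc.bed"),
                   file.path(data_dir, "flnc_pid.tsv"))
ann <- read_gff3(file.path(data_dir, "annotation.gff3"))
js <- read_junctions(file.path(data_dir, "junctions.bed"))

calls <- call_fusions(reads, ann, js)
write.table(calls, "results/fusions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cnt <- fusion_type_counts(calls)
cat(sprintf("fusion calls: %d (%d inter-chromosome, %d intra-chromosome)\n",
            cnt$total, cnt$inter, cnt$intra))

truth <- read.table(file.path(data_dir, "truth_fusions.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
cat(sprintf("simulated chimeras: %d; recalled: %d; spurious calls: %d\n",
            nrow(truth), sum(truth$read_id %in% calls$read_id),
            sum(!calls$read_id %in% truth$read_id)))
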