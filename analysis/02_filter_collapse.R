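#!/usr/bin/env Rscript
# Stage 2: collapse redundant FLNC reads into isoform groups and apply the
# retention rules (>= 2 reads, or global identity > 99%, or all junctions
# supported by short reads / annotation).

suppressPackageStartupMessages(library(isoforge))

data_dir <- "results/data"
out <- "results"
reads <- read_flnc(file.path(data_dir, "flnc.bed"),
                   file.path(data_dir, "flnc_pid.tsv"))
ann <- read_gff3(file.path(data_dir, "annotation.gff3"))
js <- read_junctions(file.path(data_dir, "junctions.bed"))

multi <- unique(reads$read_id[duplicated(reads$read_id)])
single <- reads[!reads$read_id %in% multi, ]

# terminal fuzz 24 bp = 3x the simulated 3'-end scatter sd
grouping <- group_identical_structures(single, fuzz = 24L)
retained <- retain_isoforms(grouping, single, js, ann)

write_gff3(retained, file.path(out, "retained.gff3"))
cat(sprintf("%d single-segment reads -> %d structure groups -> %d retained isoforms\n",
            nrow(single), nrow(grouping$groups), nrow(retained)))
cat(sprintf("%d multi-segment reads deferred to fusion calling\n",
            length(multi)))
print(table(retained$retained_by))
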