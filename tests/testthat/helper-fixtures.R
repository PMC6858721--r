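# Shared fixture builders and independent oracles.

mk_tx <- function(id, starts, ends, chrom = "chr1", strand = "+",
                  gene = NA_character_, cds_start = NA_integer_,
                  cds_end = NA_integer_, source = "annotation") {
  transcripts(tx_id = id, chrom = chrom, strand = strand,
              exon_starts = list(as.integer(starts)),
              exon_ends = list(as.integer(ends)), gene_id = gene,
              source = source, cds_start = cds_start, cds_end = cds_end)
}

mk_read <- function(id, starts, ends, chrom = "chr1", strand = "+",
                    gpid = 95, lpid = 97, seg = 1L, read_start = 0L,
                    read_end = NA_integer_) {
  if (is.na(read_end)) read_end <- read_start + sum(ends - starts)
  tibble::tibble(read_id = id, seg_idx = as.integer(seg), chrom = chrom,
                 strand = strand, exon_starts = list(as.integer(starts)),
                 exon_ends = list(as.integer(ends)), global_pid = gpid,
                 local_pid = lpid, read_start = as.integer(read_start),
                 read_end = as.integer(read_end))
}

empty_annotation <- function() {
  transcripts(tx_id = character(0), chrom = character(0),
              strand = character(0), exon_starts = list(),
              exon_ends = list())
}

# Random exon chain within [0, space); returns list(starts, ends).
rand_chain <- function(space = 5000L, max_exons = 4L) {
  n <- sample.int(max_exons, 1L)
  widths <- sample(30:200, n, replace = TRUE)
  gaps <- if (n > 1L) sample(20:300, n - 1L, replace = TRUE) else integer(0)
  need <- sum(widths) + sum(gaps)
  origin <- sample.int(max(1L, space - need), 1L) - 1L
  starts <- integer(n); ends <- integer(n); pos <- origin
  for (i in seq_len(n)) {
    starts[i] <- pos; ends[i] <- pos + widths[i]
    pos <- ends[i] + if (i < n) gaps[i] else 0L
  }
  list(starts = starts, ends = ends)
}

rand_tx_set <- function(n, chroms = c("chr1", "chr2"), space = 5000L) {
  rows <- lapply(seq_len(n), function(i) {
    ch <- rand_chain(space)
    mk_tx(sprintf("t%03d", i), ch$starts, ch$ends,
          chrom = sample(chroms, 1L), strand = sample(c("+", "-"), 1L))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tx_tbl", class(out))
  out
}

# Independent per-base overlap oracle: covered-position set intersection.
pb_overlap <- function(a, b) {
  if (a$chrom[[1L]] != b$chrom[[1L]]) {
    return(list(shared_bp = 0L, frac_a = 0, frac_b = 0,
                max_single_exon_frac = 0))
  }
  cover <- function(s, e) unlist(Map(function(x, y) seq.int(x, y - 1L), s, e))
  pa <- cover(a$exon_starts[[1L]], a$exon_ends[[1L]])
  pb <- cover(b$exon_starts[[1L]], b$exon_ends[[1L]])
  shared <- length(intersect(pa, pb))
  best <- 0
  for (i in seq_along(a$exon_starts[[1L]])) {
    for (j in seq_along(b$exon_starts[[1L]])) {
      ei <- seq.int(a$exon_starts[[1L]][i], a$exon_ends[[1L]][i] - 1L)
      ej <- seq.int(b$exon_starts[[1L]][j], b$exon_ends[[1L]][j] - 1L)
      ov <- length(intersect(ei, ej))
      best <- max(best, ov / min(length(ei), length(ej)))
    }
  }
  list(shared_bp = shared, frac_a = shared / length(pa),
       frac_b = shared / length(pb), max_single_exon_frac = best)
}

# Brute-force locus oracle: pairwise per-base overlap + plain union-find.
oracle_locus_partition <- function(tx, min_frac = 0.20) {
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tx$chrom[i] != tx$chrom[j] || tx$strand[i] != tx$strand[j]) next
      rep_ <- pb_overlap(tx[i, ], tx[j, ])
      if (min(rep_$frac_a, rep_$frac_b) > min_frac &&
          rep_$max_single_exon_frac > min_frac) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(tx$tx_id, roots)
}

canonical_partition <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

# End-to-end simulated run.
run_sim <- function(cfg, group_fuzz = 0L, ...) {
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  js <- simulate_junction_support(cfg, fl$reads, sim$annotation)
  pc <- pipeline_config(genome = sim$genome, annotation = sim$annotation,
                        alignments = fl$reads, junctions = js,
                        group_fuzz = group_fuzz, seed = cfg$seed, ...)
  list(sim = sim, fl = fl, js = js, res = run_pipeline(pc))
}

noise_free_cfg <- function(seed, ...) {
  sim_config(seed = seed, polya_scatter_sd = 0, truncation_5p = c(0L, 0L),
             junction_support_coverage = 1.0, ...)
}

# Fraction of reads whose predicted novelty label matches ground truth
# (fusion reads excluded: they are routed to the fusion caller).
label_agreement <- function(run) {
  mem <- attr(run$res$retained, "members")
  asn <- run$res$loci$assignments
  mem$pred <- asn$label[match(mem$tx_id, asn$tx_id)]
  truth <- run$fl$truth$reads
  mem$true <- truth$label[match(mem$read_id, truth$read_id)]
  mem$true[mem$true == "novel_locus"] <- "novel"
  mem <- mem[mem$true != "fusion", , drop = FALSE]
  mean(mem$pred == mem$true)
}

# Per-gene polyA site-count agreement with simulator truth. Only truth
# sites the generator actually gave >= min_support reads are recoverable,
# so the comparison conditions on that support.
polya_agreement <- function(run, min_support = 2L) {
  truth_sites <- run$fl$truth$polya_sites
  truth_sites <- truth_sites[truth_sites$n_reads >= min_support, ,
                             drop = FALSE]
  truth_reads <- run$fl$truth$reads
  expressed_genes <- unique(truth_reads$gene_id[!is.na(truth_reads$gene_id)])
  gene_map <- match_called_genes(run$res, truth_reads)
  called <- run$res$sites
  called$true_gene <- gene_map[called$gene_id]
  called_count <- table(called$true_gene[!is.na(called$true_gene)])
  true_count <- table(truth_sites$gene_id[truth_sites$gene_id %in%
                                            expressed_genes])
  agree <- vapply(names(true_count), function(g) {
    got <- if (g %in% names(called_count)) called_count[[g]] else 0L
    got == true_count[[g]]
  }, logical(1))
  mean(agree)
}

# AS event agreement: every true injected edit recovered with its exact
# type and coordinates, in the locus of its gene.
as_event_agreement <- function(run) {
  tr <- run$fl$truth$as_events
  ev <- run$res$events
  if (nrow(tr) == 0L) return(if (nrow(ev) == 0L) 1 else 0)
  key <- function(d) paste(d$type, d$chrom, d$start, d$end)
  mean(key(tr) %in% key(ev))
}
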