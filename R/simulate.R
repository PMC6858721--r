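#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the toy-genome simulator. Defaults sketch a small
#' plant-like transcriptome: multi-exon genes with ~120-bp-scale exons, an
#' extended 3'-terminal exon standing in for a 3' UTR, high post-correction
#' read identity, and a short-read junction-support set covering most true
#' introns. The seed fully determines all outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total number of gene models, distributed over chromosomes.
#' @param exons_per_gene integer range `c(lo, hi)` of exons per gene.
#' @param exon_length,intron_length bp ranges for internal exon and intron
#'   sizes (intron minimum must be >= 4 so donor and acceptor dinucleotides
#'   do not collide).
#' @param utr3_extension extra bp added to the 3'-terminal exon, giving room
#'   for alternative polyadenylation sites.
#' @param intergenic_gap bp range between consecutive genes.
#' @param reads_per_isoform integer range of FLNC reads per expressed isoform.
#' @param p_novel_isoform probability a gene carries one novel splice variant
#'   (a single injected edit: skipped exon(s), retained intron(s), or a
#'   shifted exon end).
#' @param p_novel_locus per-gene probability contributing intergenic novel
#'   loci (expected novel loci = `n_genes * p_novel_locus`).
#' @param p_fusion_read probability any individual read is replaced by a
#'   chimeric fusion read joining two genes > 50 kb apart or on different
#'   chromosomes.
#' @param pid_global_mean,pid_global_sd,pid_local_mean,pid_local_sd percent
#'   scale parameters of the simulated whole-read and per-segment alignment
#'   identities.
#' @param truncation_5p bp range of 5' truncation applied to each read.
#' @param polya_sites_per_gene integer range of true polyadenylation sites
#'   per gene.
#' @param polya_site_spacing bp range separating consecutive true sites along
#'   the 3'-terminal exon.
#' @param polya_scatter_sd standard deviation (bp) of read 3'-end scatter
#'   around the true site.
#' @param junction_support_coverage probability a true intron enters the
#'   short-read junction-support set.
#' @param splice_dinucleotides named probability vector over
#'   `c("GT-AG", "GC-AG", "AT-AC")` used to stamp donor/acceptor motifs into
#'   the simulated genome.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_length = 300000L,
                       n_genes = 30L,
                       exons_per_gene = c(3L, 9L),
                       exon_length = c(80L, 300L),
                       intron_length = c(120L, 900L),
                       utr3_extension = 250L,
                       intergenic_gap = c(2000L, 6000L),
                       reads_per_isoform = c(4L, 8L),
                       p_novel_isoform = 0.3,
                       p_novel_locus = 0.15,
                       p_fusion_read = 0.02,
                       pid_global_mean = 95, pid_global_sd = 3,
                       pid_local_mean = 97, pid_local_sd = 2,
                       truncation_5p = c(0L, 0L),
                       polya_sites_per_gene = c(1L, 2L),
                       polya_site_spacing = c(100L, 160L),
                       polya_scatter_sd = 8,
                       junction_support_coverage = 0.9,
                       splice_dinucleotides = c("GT-AG" = 0.95,
                                                "GC-AG" = 0.04,
                                                "AT-AC" = 0.01)) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              utr3_extension = as.integer(utr3_extension),
              intergenic_gap = as.integer(intergenic_gap),
              reads_per_isoform = as.integer(reads_per_isoform),
              p_novel_isoform = p_novel_isoform,
              p_novel_locus = p_novel_locus,
              p_fusion_read = p_fusion_read,
              pid_global_mean = pid_global_mean, pid_global_sd = pid_global_sd,
              pid_local_mean = pid_local_mean, pid_local_sd = pid_local_sd,
              truncation_5p = as.integer(truncation_5p),
              polya_sites_per_gene = as.integer(polya_sites_per_gene),
              polya_site_spacing = as.integer(polya_site_spacing),
              polya_scatter_sd = polya_scatter_sd,
              junction_support_coverage = junction_support_coverage,
              splice_dinucleotides = splice_dinucleotides)
  for (r in c("exons_per_gene", "exon_length", "intron_length",
              "intergenic_gap", "reads_per_isoform", "truncation_5p",
              "polya_sites_per_gene", "polya_site_spacing")) {
    if (length(cfg[[r]]) != 2L || cfg[[r]][1L] > cfg[[r]][2L]) {
      stop("range '", r, "' must be c(lo, hi) with lo <= hi")
    }
  }
  if (cfg$intron_length[1L] < 4L) stop("intron_length minimum must be >= 4")
  if (cfg$exons_per_gene[1L] < 1L) stop("exons_per_gene minimum must be >= 1")
  for (p in c("p_novel_isoform", "p_novel_locus", "p_fusion_read",
              "junction_support_coverage")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("probability '", p, "' not in [0,1]")
  }
  if (is.null(names(cfg$splice_dinucleotides)) ||
      !all(names(cfg$splice_dinucleotides) %in% c("GT-AG", "GC-AG", "AT-AC")) ||
      abs(sum(cfg$splice_dinucleotides) - 1) > 1e-9) {
    stop("splice_dinucleotides must be a named probability vector over ",
         "GT-AG/GC-AG/AT-AC summing to 1")
  }
  if (cfg$polya_scatter_sd < 0) stop("polya_scatter_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Draw one integer uniformly from an inclusive range.
rint <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample(range[1L]:range[2L], 1L)
}

splice_motifs <- list(
  "GT-AG" = c(donor = "GT", acceptor = "AG"),
  "GC-AG" = c(donor = "GC", acceptor = "AG"),
  "AT-AC" = c(donor = "AT", acceptor = "AC")
)

# Overwrite genome sequence at [pos, pos+nchar) 0-based.
stamp <- function(seqs, chrom, pos, bases) {
  substr(seqs[[chrom]], pos + 1L, pos + nchar(bases)) <- bases
  seqs
}

#' Simulate a toy genome and annotation
#'
#' Places non-overlapping multi-exon gene models on both strands of random
#' chromosomes, stamps donor/acceptor dinucleotides into every intron
#' according to `cfg$splice_dinucleotides` (in transcription orientation),
#' and records a CDS span per transcript (terminal-exon halves are left as
#' UTR). The realized dinucleotide class of every intron is attached to the
#' annotation as attribute `"intron_classes"` for ground-truth comparisons.
#'
#' @param cfg a [sim_config()].
#' @return List with `genome` (named character vector) and `annotation`
#'   (transcript table, one transcript per gene).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- stats::setNames(
    vapply(seq_len(cfg$n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1)),
    paste0("chr", seq_len(cfg$n_chroms))
  )

  if (cfg$n_genes == 0L) {
    ann <- transcripts(tx_id = character(0), chrom = character(0),
                       strand = character(0), exon_starts = list(),
                       exon_ends = list())
    attr(ann, "intron_classes") <- tibble::tibble(
      tx_id = character(0), index = integer(0), class = character(0))
    return(list(genome = genome, annotation = ann))
  }

  chrom_of <- rep(names(genome), length.out = cfg$n_genes)
  cursor <- stats::setNames(rep(0L, cfg$n_chroms), names(genome))
  rows <- vector("list", cfg$n_genes)
  classes <- vector("list", cfg$n_genes)

  for (g in seq_len(cfg$n_genes)) {
    chrom <- chrom_of[g]
    n_ex <- rint(cfg$exons_per_gene)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_length),
                     integer(1))
    strand <- sample(c("+", "-"), 1L)
    # extend the 3'-terminal exon to host polyA sites (genomic side by strand)
    if (strand == "+") ex_len[n_ex] <- ex_len[n_ex] + cfg$utr3_extension
    else ex_len[1L] <- ex_len[1L] + cfg$utr3_extension
    in_len <- if (n_ex > 1L) {
      vapply(seq_len(n_ex - 1L), function(i) rint(cfg$intron_length),
             integer(1))
    } else integer(0)
    gap <- rint(cfg$intergenic_gap)
    g_start <- cursor[[chrom]] + gap
    g_len <- sum(ex_len) + sum(in_len)
    if (g_start + g_len > cfg$chrom_length - 10L) {
      stop("capacity: gene ", g, " does not fit on ", chrom,
           " (need ", g_start + g_len, " bp of ", cfg$chrom_length, ")")
    }
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- g_start
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i]
      pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
    }
    cursor[[chrom]] <- ends[n_ex]

    gene_id <- sprintf("G%04d", g)
    tx_id <- paste0(gene_id, ".t1")

    if (n_ex > 1L) {
      cls <- sample(names(cfg$splice_dinucleotides), n_ex - 1L, replace = TRUE,
                    prob = cfg$splice_dinucleotides)
      itr <- chain_introns(starts, ends)
      for (k in seq_len(n_ex - 1L)) {
        m <- splice_motifs[[cls[k]]]
        if (strand == "+") {
          genome <- stamp(genome, chrom, itr$start[k], m[["donor"]])
          genome <- stamp(genome, chrom, itr$end[k] - 2L, m[["acceptor"]])
        } else {
          genome <- stamp(genome, chrom, itr$end[k] - 2L, revcomp(m[["donor"]]))
          genome <- stamp(genome, chrom, itr$start[k], revcomp(m[["acceptor"]]))
        }
      }
      classes[[g]] <- tibble::tibble(tx_id = tx_id, index = seq_len(n_ex - 1L),
                                     class = cls)
    }

    # CDS: inset by half of each terminal exon's pre-extension length
    inset5 <- max(10L, ex_len[1L] %/% 4L)
    inset3 <- max(10L, ex_len[n_ex] %/% 4L)
    if (strand == "+") inset3 <- max(inset3, cfg$utr3_extension + 20L)
    else inset5 <- max(inset5, cfg$utr3_extension + 20L)
    cds_start <- starts[1L] + inset5
    cds_end <- ends[n_ex] - inset3
    if (cds_end <= cds_start) {
      cds_start <- starts[1L]
      cds_end <- ends[n_ex]
    }

    rows[[g]] <- tibble::tibble(
      tx_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
      exon_starts = list(starts), exon_ends = list(ends),
      source = "annotation", cds_start = cds_start, cds_end = cds_end
    )
  }

  ann <- dplyr::bind_rows(rows)
  validate_transcripts(ann)
  class(ann) <- c("tx_tbl", class(ann))
  attr(ann, "intron_classes") <- dplyr::bind_rows(classes)
  list(genome = genome, annotation = ann)
}

# Apply a single AS edit to an exon chain; returns NULL if infeasible.
# Types: "skip" (drop k internal exons), "ir" (merge across k introns),
# "ae" (shift one internal boundary inward by delta).
inject_as_edit <- function(starts, ends, type) {
  n <- length(starts)
  if (type == "skip") {
    if (n < 3L) return(NULL)
    k <- rint(c(1L, min(2L, n - 2L)))
    j <- rint(c(2L, n - k))  # first skipped exon (internal)
    keep <- setdiff(seq_len(n), j:(j + k - 1L))
    list(starts = starts[keep], ends = ends[keep],
         type = if (k == 1L) "SKIP" else "MSKIP",
         start = starts[j], end = ends[j + k - 1L])
  } else if (type == "ir") {
    if (n < 2L) return(NULL)
    k <- rint(c(1L, min(2L, n - 1L)))
    j <- rint(c(1L, n - k))  # first retained intron index
    ns <- starts[-((j + 1L):(j + k))]
    ne <- ends[-(j:(j + k - 1L))]
    list(starts = ns, ends = ne,
         type = if (k == 1L) "IR" else "MIR",
         start = ends[j], end = starts[j + k])
  } else if (type == "ae") {
    if (n < 2L) return(NULL)
    j <- rint(c(1L, n - 1L))  # intron whose boundary shifts
    delta <- rint(c(15L, 45L))
    donor_ok <- (ends[j] - starts[j]) > delta + 20L
    acc_ok <- (ends[j + 1L] - starts[j + 1L]) > delta + 20L
    if (!donor_ok && !acc_ok) return(NULL)
    side <- if (donor_ok && acc_ok) sample(c("donor", "acceptor"), 1L)
            else if (donor_ok) "donor" else "acceptor"
    ns <- starts
    ne <- ends
    if (side == "donor") {
      old <- ends[j]
      ne[j] <- old - delta
      gap <- c(ne[j], old)
    } else {
      old <- starts[j + 1L]
      ns[j + 1L] <- old + delta
      gap <- c(old, ns[j + 1L])
    }
    list(starts = ns, ends = ne, type = "AE", start = gap[1L], end = gap[2L])
  } else {
    stop("unknown edit type: ", type)
  }
}

# Remove t bp of exonic sequence from the 5' end of a chain (strand-aware).
truncate_chain <- function(starts, ends, strand, t) {
  if (t <= 0L) return(list(starts = starts, ends = ends))
  total <- sum(ends - starts)
  t <- min(t, total - 50L)
  if (t <= 0L) return(list(starts = starts, ends = ends))
  if (strand == "+") {
    while (t > 0L) {
      w <- ends[1L] - starts[1L]
      if (t >= w && length(starts) > 1L) {
        starts <- starts[-1L]; ends <- ends[-1L]; t <- t - w
      } else {
        starts[1L] <- starts[1L] + min(t, w - 1L); t <- 0L
      }
    }
  } else {
    while (t > 0L) {
      n <- length(starts)
      w <- ends[n] - starts[n]
      if (t >= w && n > 1L) {
        starts <- starts[-n]; ends <- ends[-n]; t <- t - w
      } else {
        ends[n] <- ends[n] - min(t, w - 1L); t <- 0L
      }
    }
  }
  list(starts = starts, ends = ends)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate FLNC read alignments with ground truth
#'
#' Draws reads from annotated isoforms, injects per-gene novel splice
#' variants (one edit each), places novel-locus transcripts in intergenic
#' space, and replaces a fraction of reads with chimeric fusion reads joining
#' two genes more than 50 kb apart or on different chromosomes. Read 3' ends
#' cycle deterministically through the gene's true polyadenylation sites and
#' are scattered with `cfg$polya_scatter_sd`; 5' ends are truncated per
#' `cfg$truncation_5p`. Per-read global and per-segment local identities are
#' simulated metadata (the pipeline consumes aligner-reported identities).
#'
#' @param cfg a [sim_config()].
#' @param genome,annotation output of [simulate_genome()].
#' @return List with `reads` (tibble, one row per alignment segment) and
#'   `truth` (list: `reads`, `polya_sites`, `as_events`, `fusions`,
#'   `expressed` transcript table).
#' @export
simulate_flnc <- function(cfg, genome, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ann <- annotation

  if (nrow(ann) == 0L && cfg$p_novel_locus == 0) {
    stop("annotation is empty and p_novel_locus = 0: nothing to express")
  }

  expressed <- list()
  as_truth <- list()
  if (nrow(ann) > 0L) {
    for (i in seq_len(nrow(ann))) {
      expressed[[length(expressed) + 1L]] <- dplyr::mutate(
        ann[i, ], label = "known_known", origin = ann$tx_id[i])
    }
    # one novel splice variant per selected gene
    for (i in seq_len(nrow(ann))) {
      if (stats::runif(1) >= cfg$p_novel_isoform) next
      n_ex <- length(ann$exon_starts[[i]])
      feasible <- c(if (n_ex >= 3L) "skip", if (n_ex >= 2L) "ir",
                    if (n_ex >= 2L) "ae")
      if (length(feasible) == 0L) next
      edit <- NULL
      for (try_type in sample(feasible)) {
        edit <- inject_as_edit(ann$exon_starts[[i]], ann$exon_ends[[i]],
                               try_type)
        if (!is.null(edit)) break
      }
      if (is.null(edit)) next
      v_id <- paste0(ann$gene_id[i], ".nv1")
      expressed[[length(expressed) + 1L]] <- tibble::tibble(
        tx_id = v_id, gene_id = ann$gene_id[i], chrom = ann$chrom[i],
        strand = ann$strand[i], exon_starts = list(edit$starts),
        exon_ends = list(edit$ends), source = "flnc",
        cds_start = NA_integer_, cds_end = NA_integer_,
        label = "known_novel", origin = v_id)
      as_truth[[length(as_truth) + 1L]] <- tibble::tibble(
        gene_id = ann$gene_id[i], base_tx = ann$tx_id[i], variant_tx = v_id,
        type = edit$type, chrom = ann$chrom[i], strand = ann$strand[i],
        start = edit$start, end = edit$end)
    }
  }

  # novel loci in intergenic space
  n_novel_loci <- stats::rbinom(1L, cfg$n_genes, cfg$p_novel_locus)
  if (nrow(ann) == 0L && cfg$p_novel_locus > 0) {
    n_novel_loci <- max(n_novel_loci, 1L)
  }
  if (n_novel_loci > 0L) {
    gaps <- intergenic_gaps(ann, genome, margin = 200L)
    for (v in seq_len(n_novel_loci)) {
      n_ex <- rint(c(2L, 4L))
      ex_len <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_length),
                       integer(1))
      in_len <- vapply(seq_len(n_ex - 1L), function(i) rint(cfg$intron_length),
                       integer(1))
      need <- sum(ex_len) + sum(in_len)
      ok <- which(gaps$end - gaps$start >= need)
      if (length(ok) == 0L) break
      gi <- ok[rint(c(1L, length(ok)))]
      offset_max <- gaps$end[gi] - gaps$start[gi] - need
      g_start <- gaps$start[gi] + if (offset_max > 0L) rint(c(0L, offset_max)) else 0L
      starts <- integer(n_ex); ends <- integer(n_ex); pos <- g_start
      for (i in seq_len(n_ex)) {
        starts[i] <- pos; ends[i] <- pos + ex_len[i]
        pos <- ends[i] + if (i < n_ex) in_len[i] else 0L
      }
      # consume the used portion of the gap
      used_end <- ends[n_ex] + 200L
      gaps$start[gi] <- used_end
      gene_id <- sprintf("NG%03d", v)
      expressed[[length(expressed) + 1L]] <- tibble::tibble(
        tx_id = paste0(gene_id, ".t1"), gene_id = gene_id,
        chrom = gaps$chrom[gi], strand = sample(c("+", "-"), 1L),
        exon_starts = list(starts), exon_ends = list(ends), source = "flnc",
        cds_start = NA_integer_, cds_end = NA_integer_,
        label = "novel_locus", origin = paste0(gene_id, ".t1"))
    }
  }

  expressed <- dplyr::bind_rows(expressed)
  if (nrow(expressed) == 0L) {
    stop("no transcripts could be expressed under this configuration")
  }

  # true polyA sites per gene: most 3' base of the gene's primary transcript,
  # plus optional upstream sites along the 3'-terminal exon
  genes <- expressed[!duplicated(expressed$gene_id), ]
  polya <- list()
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
    strand <- genes$strand[i]
    n <- length(s)
    k <- rint(cfg$polya_sites_per_gene)
    if (strand == "+") {
      sites <- e[n] - 1L
      lim <- s[n] + 30L
      while (length(sites) < k) {
        cand <- sites[length(sites)] - rint(cfg$polya_site_spacing)
        if (cand < lim) break
        sites <- c(sites, cand)
      }
    } else {
      sites <- s[1L]
      lim <- e[1L] - 30L
      while (length(sites) < k) {
        cand <- sites[length(sites)] + rint(cfg$polya_site_spacing)
        if (cand > lim) break
        sites <- c(sites, cand)
      }
    }
    polya[[i]] <- tibble::tibble(gene_id = genes$gene_id[i],
                                 chrom = genes$chrom[i], strand = strand,
                                 position = as.integer(sites))
  }
  polya <- dplyr::bind_rows(polya)

  # candidate fusion gene pairs (> 50 kb apart or different chromosomes)
  fusion_pairs <- NULL
  if (cfg$p_fusion_read > 0 && nrow(ann) >= 2L) {
    sp <- transcript_span(ann)
    idx <- utils::combn(nrow(ann), 2L)
    keep <- vapply(seq_len(ncol(idx)), function(j) {
      a <- idx[1L, j]; b <- idx[2L, j]
      ann$chrom[a] != ann$chrom[b] ||
        max(sp$span_start[b] - sp$span_end[a],
            sp$span_start[a] - sp$span_end[b]) > 50000L
    }, logical(1))
    fusion_pairs <- idx[, keep, drop = FALSE]
  }
  if (cfg$p_fusion_read > 0 && (is.null(fusion_pairs) ||
                                ncol(fusion_pairs) == 0L)) {
    stop("p_fusion_read > 0 but no gene pair satisfies the fusion ",
         "distance precondition")
  }

  seg_rows <- list()
  truth_rows <- list()
  fusion_rows <- list()
  counter <- 0L
  # per-gene cycling over true sites, counted over emitted (non-fusion)
  # reads so site support stays balanced even when reads become chimeras
  site_cursor <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  site_hits <- stats::setNames(
    lapply(genes$gene_id, function(g) {
      integer(sum(polya$gene_id == g))
    }), genes$gene_id)

  for (i in seq_len(nrow(expressed))) {
    n_reads <- rint(cfg$reads_per_isoform)
    gid <- expressed$gene_id[i]
    g_sites <- polya$position[polya$gene_id == gid]
    strand <- expressed$strand[i]
    for (r in seq_len(n_reads)) {
      counter <- counter + 1L
      rid <- sprintf("r%06d", counter)
      if (stats::runif(1) < cfg$p_fusion_read) {
        j <- if (ncol(fusion_pairs) == 1L) 1L else rint(c(1L, ncol(fusion_pairs)))
        a <- fusion_pairs[1L, j]; b <- fusion_pairs[2L, j]
        la <- sum(ann$exon_ends[[a]] - ann$exon_starts[[a]])
        lb <- sum(ann$exon_ends[[b]] - ann$exon_starts[[b]])
        gpid <- clamp(stats::rnorm(1, cfg$pid_global_mean, cfg$pid_global_sd),
                      50, 100)
        for (seg in 1:2) {
          k <- if (seg == 1L) a else b
          seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
            read_id = rid, seg_idx = seg, chrom = ann$chrom[k],
            strand = ann$strand[k],
            exon_starts = list(ann$exon_starts[[k]]),
            exon_ends = list(ann$exon_ends[[k]]),
            global_pid = gpid,
            local_pid = clamp(stats::rnorm(1, cfg$pid_local_mean,
                                           cfg$pid_local_sd), 50, 100),
            read_start = if (seg == 1L) 0L else la,
            read_end = if (seg == 1L) la else la + lb)
        }
        ftype <- if (ann$chrom[a] != ann$chrom[b]) "inter_chromosome"
                 else "intra_chromosome"
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          read_id = rid, origin_tx = NA_character_, gene_id = NA_character_,
          label = "fusion", true_polya = NA_integer_)
        fusion_rows[[length(fusion_rows) + 1L]] <- tibble::tibble(
          read_id = rid, gene_a = ann$gene_id[a], gene_b = ann$gene_id[b],
          fusion_type = ftype)
        next
      }
      s <- expressed$exon_starts[[i]]
      e <- expressed$exon_ends[[i]]
      # 3' end: cycle through the gene's true sites, then scatter
      site_idx <- site_cursor[[gid]] %% length(g_sites) + 1L
      site_cursor[[gid]] <- site_cursor[[gid]] + 1L
      site_hits[[gid]][site_idx] <- site_hits[[gid]][site_idx] + 1L
      site <- g_sites[site_idx]
      off <- as.integer(round(stats::rnorm(1, 0, cfg$polya_scatter_sd)))
      n_ex <- length(s)
      if (strand == "+") {
        end3 <- clamp(site + 1L + off, s[n_ex] + 1L,
                      nchar(genome[[expressed$chrom[i]]]))
        e[n_ex] <- end3
      } else {
        start3 <- clamp(site + off, 0L, e[1L] - 1L)
        s[1L] <- start3
      }
      tr <- truncate_chain(s, e, strand, rint(cfg$truncation_5p))
      seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
        read_id = rid, seg_idx = 1L, chrom = expressed$chrom[i],
        strand = strand, exon_starts = list(tr$starts),
        exon_ends = list(tr$ends),
        global_pid = clamp(stats::rnorm(1, cfg$pid_global_mean,
                                        cfg$pid_global_sd), 50, 100),
        local_pid = clamp(stats::rnorm(1, cfg$pid_local_mean,
                                       cfg$pid_local_sd), 50, 100),
        read_start = 0L, read_end = sum(tr$ends - tr$starts))
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        read_id = rid, origin_tx = expressed$origin[i],
        gene_id = expressed$gene_id[i], label = expressed$label[i],
        true_polya = site)
    }
  }

  reads <- dplyr::bind_rows(seg_rows)
  polya$n_reads <- unlist(lapply(genes$gene_id, function(g) site_hits[[g]]))
  truth <- list(
    reads = dplyr::bind_rows(truth_rows),
    polya_sites = polya,
    as_events = if (length(as_truth) > 0) dplyr::bind_rows(as_truth)
                else tibble::tibble(gene_id = character(0),
                                    base_tx = character(0),
                                    variant_tx = character(0),
                                    type = character(0), chrom = character(0),
                                    strand = character(0), start = integer(0),
                                    end = integer(0)),
    fusions = if (length(fusion_rows) > 0) dplyr::bind_rows(fusion_rows)
              else tibble::tibble(read_id = character(0),
                                  gene_a = character(0),
                                  gene_b = character(0),
                                  fusion_type = character(0)),
    expressed = expressed
  )
  list(reads = reads, truth = truth)
}

# Free intervals between gene spans (with a safety margin), per chromosome.
intergenic_gaps <- function(annotation, genome, margin = 200L) {
  out <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    idx <- which(annotation$chrom == chrom)
    if (length(idx) == 0L) {
      out[[chrom]] <- tibble::tibble(chrom = chrom, start = margin,
                                     end = len - margin)
      next
    }
    sp <- transcript_span(annotation[idx, ])
    occ <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, sp$span_start + 1L - margin), pmin(len, sp$span_end + margin)))
    free <- IRanges::gaps(occ, start = 1L, end = len)
    if (length(free) > 0L) {
      out[[chrom]] <- tibble::tibble(chrom = chrom,
                                     start = IRanges::start(free) - 1L,
                                     end = IRanges::end(free))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a short-read junction-support set
#'
#' Every true intron (annotated introns plus introns of all simulated read
#' segments) enters the support set independently with probability
#' `cfg$junction_support_coverage`; each supported junction carries a
#' simulated short-read count of at least 2.
#'
#' @param cfg a [sim_config()].
#' @param reads read table from [simulate_flnc()].
#' @param annotation annotation transcript table.
#' @return Tibble with `chrom`, `strand`, `start`, `end`, `count`.
#' @export
simulate_junction_support <- function(cfg, reads, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  read_tx <- tibble::tibble(tx_id = paste(reads$read_id, reads$seg_idx,
                                          sep = "|"),
                            chrom = reads$chrom, strand = reads$strand,
                            exon_starts = reads$exon_starts,
                            exon_ends = reads$exon_ends)
  all_introns <- dplyr::bind_rows(
    if (nrow(annotation) > 0L) introns_of(annotation),
    if (nrow(read_tx) > 0L) introns_of(read_tx)
  )
  uniq <- dplyr::distinct(all_introns[, c("chrom", "strand", "start", "end")])
  if (nrow(uniq) == 0L) {
    return(tibble::tibble(chrom = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          count = integer(0)))
  }
  uniq <- uniq[order(uniq$chrom, uniq$start, uniq$end, uniq$strand), ]
  keep <- stats::runif(nrow(uniq)) < cfg$junction_support_coverage
  out <- uniq[keep, ]
  out$count <- 2L + stats::rpois(nrow(out), 5)
  out
}

#' Map called gene labels of a pipeline run to simulated gene ids
#'
#' Evaluation utility for synthetic runs: loci inherit their gene label from
#' the annotation when known, and carry their locus id otherwise, so
#' comparing per-gene results (e.g. polyA site counts) against simulator
#' ground truth needs a translation for novel loci. Each locus is mapped to
#' the majority true gene of the reads supporting its isoforms.
#'
#' @param result a [run_pipeline()] result on simulated data.
#' @param truth_reads the `truth$reads` tibble of [simulate_flnc()].
#' @return Named character vector: called gene label (annotated gene id or
#'   locus id) to true simulated gene id.
#' @export
match_called_genes <- function(result, truth_reads) {
  mem <- attr(result$retained, "members")
  asn <- result$loci$assignments
  loci <- result$loci$loci
  mem$locus_id <- asn$locus_id[match(mem$tx_id, asn$tx_id)]
  mem$true_gene <- truth_reads$gene_id[match(mem$read_id,
                                             truth_reads$read_id)]
  mem <- mem[!is.na(mem$true_gene) & !is.na(mem$locus_id), , drop = FALSE]
  if (nrow(mem) == 0L) return(stats::setNames(character(0), character(0)))
  by_locus <- vapply(split(mem$true_gene, mem$locus_id), function(g) {
    names(sort(table(g), decreasing = TRUE))[1L]
  }, character(1))
  called <- ifelse(is.na(loci$known_gene_id), loci$locus_id,
                   loci$known_gene_id)
  out <- unname(by_locus[loci$locus_id])
  names(out) <- called
  out[!is.na(out)]
}
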