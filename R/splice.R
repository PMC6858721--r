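near <- function(x, y, tol) abs(x - y) <= tol

# Events between one ordered pair of exon chains (A = inclusion-side).
# Returns rows of (type, start, end).
pair_as_events <- function(sa, ea, sb, eb, fuzz) {
  ia <- chain_introns(sa, ea)
  ib <- chain_introns(sb, eb)
  rows <- list()
  add <- function(type, start, end) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(type = type,
                                                 start = start, end = end)
  }

  # --- exon skipping: an intron of B spans whole exons of A, flanking
  # junction boundaries matching (exactly -> SKIP/MSKIP, within fuzz ->
  # XSKIP/XMSKIP)
  if (nrow(ia) >= 2L && nrow(ib) >= 1L) {
    for (m in seq_len(nrow(ib))) {
      bs <- ib$start[m]; be <- ib$end[m]
      for (i in seq_len(nrow(ia) - 1L)) {
        if (!near(ia$start[i], bs, fuzz)) next
        for (j in (i + 1L):nrow(ia)) {
          if (!near(ia$end[j], be, fuzz)) next
          k <- j - i  # skipped exons: A exons (i+1) .. j
          exact <- ia$start[i] == bs && ia$end[j] == be
          type <- if (k == 1L) {
            if (exact) "SKIP" else "XSKIP"
          } else {
            if (exact) "MSKIP" else "XMSKIP"
          }
          add(type, sa[i + 1L], ea[j])
        }
      }
    }
  }

  # --- intron retention: an exon of B spans introns of A with boundaries
  # matching A's flanking exon boundaries
  if (nrow(ia) >= 1L) {
    for (m in seq_along(sb)) {
      s <- sb[m]; e <- eb[m]
      inside <- which(ia$start >= s - fuzz & ia$end <= e + fuzz)
      if (length(inside) == 0L) next
      ii <- min(inside); jj <- max(inside)
      if (!all(ii:jj %in% inside)) next
      if (!near(s, sa[ii], fuzz) || !near(e, ea[jj + 1L], fuzz)) next
      k <- jj - ii + 1L
      exact <- s == sa[ii] && e == ea[jj + 1L]
      type <- if (k == 1L) {
        if (exact) "IR" else "XIR"
      } else {
        if (exact) "MIR" else "XMIR"
      }
      add(type, ia$start[ii], ia$end[jj])
    }
  }

  # --- alternative exon ends: introns sharing one boundary, differing at
  # the other, with no whole intron of either isoform inside the gap
  all_introns <- rbind(ia, ib)
  gap_clean <- function(lo, hi) {
    !any(all_introns$start >= lo & all_introns$end <= hi)
  }
  if (nrow(ia) >= 1L && nrow(ib) >= 1L) {
    for (p in seq_len(nrow(ia))) {
      for (q in seq_len(nrow(ib))) {
        as_ <- ia$start[p]; ae_ <- ia$end[p]
        bs_ <- ib$start[q]; be_ <- ib$end[q]
        ds <- abs(as_ - bs_); de <- abs(ae_ - be_)
        if (ds == 0L && de == 0L) next
        if (ds == 0L) {
          # donor boundary shared exactly, acceptor side differs
          lo <- min(ae_, be_); hi <- max(ae_, be_)
          if (gap_clean(lo, hi)) add("AE", lo, hi)
        } else if (de == 0L) {
          lo <- min(as_, bs_); hi <- max(as_, bs_)
          if (gap_clean(lo, hi)) add("AE", lo, hi)
        } else if (ds <= de && ds <= fuzz) {
          # approximately shared donor boundary
          lo <- min(ae_, be_); hi <- max(ae_, be_)
          if (gap_clean(lo, hi)) add("XAE", lo, hi)
        } else if (de < ds && de <= fuzz) {
          lo <- min(as_, bs_); hi <- max(as_, bs_)
          if (gap_clean(lo, hi)) add("XAE", lo, hi)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  dplyr::bind_rows(rows)
}

#' Detect alternative-splicing events between the isoforms of one locus
#'
#' Compares every isoform pair of the locus and types events into the
#' ten-category taxonomy: exon skipping (SKIP, MSKIP for multiple
#' consecutive exons), intron retention (IR, MIR), alternative exon ends
#' (AE), and their approximate X-variants (XSKIP, XMSKIP, XIR, XMIR, XAE)
#' where boundary matching is relaxed to `fuzz` bp instead of exact.
#' Duplicate events (same type and coordinates, found in several pairs) are
#' reported once per locus. Differences confined to transcript start/end
#' sites are not events.
#'
#' @param locus_tx transcript table of the locus's isoforms (>= 2 rows on
#'   one chromosome and strand).
#' @param fuzz approximate-matching tolerance (bp); 0 disables the
#'   X-categories.
#' @return Tibble of events: `type`, `chrom`, `strand`, `start`, `end`,
#'   `iso_a`, `iso_b` (first pair the event was seen in).
#' @export
detect_as_events <- function(locus_tx, fuzz = 10L) {
  empty <- tibble::tibble(type = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), iso_a = character(0),
                          iso_b = character(0))
  n <- nrow(locus_tx)
  if (n < 2L) return(empty)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      for (dir in 1:2) {
        a <- if (dir == 1L) i else j
        b <- if (dir == 1L) j else i
        ev <- pair_as_events(locus_tx$exon_starts[[a]],
                             locus_tx$exon_ends[[a]],
                             locus_tx$exon_starts[[b]],
                             locus_tx$exon_ends[[b]], fuzz)
        if (is.null(ev)) next
        ev$chrom <- locus_tx$chrom[i]
        ev$strand <- locus_tx$strand[i]
        ev$iso_a <- locus_tx$tx_id[a]
        ev$iso_b <- locus_tx$tx_id[b]
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (length(out) == 0L) return(empty)
  ev <- dplyr::bind_rows(out)
  ev <- ev[!duplicated(ev[, c("type", "start", "end")]), ]
  ev[, c("type", "chrom", "strand", "start", "end", "iso_a", "iso_b")]
}

#' Detect AS events across all loci of a locus set
#'
#' Runs [detect_as_events()] on the discovered-isoform members of every
#' locus with at least two of them.
#'
#' @param loci a `locus_set`.
#' @param fuzz tolerance passed to [detect_as_events()].
#' @return Event tibble with a `locus_id` column prepended.
#' @export
detect_locus_as_events <- function(loci, fuzz = 10L) {
  nodes <- loci$transcripts[!loci$transcripts$is_annotation, , drop = FALSE]
  out <- list()
  for (lid in unique(nodes$locus_id)) {
    sub <- nodes[nodes$locus_id == lid, ]
    if (nrow(sub) < 2L) next
    ev <- detect_as_events(sub, fuzz = fuzz)
    if (nrow(ev) == 0L) next
    ev$locus_id <- lid
    out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0L) {
    return(tibble::tibble(locus_id = character(0), type = character(0),
                          chrom = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          iso_a = character(0), iso_b = character(0)))
  }
  ev <- dplyr::bind_rows(out)
  ev[, c("locus_id", "type", "chrom", "strand", "start", "end",
         "iso_a", "iso_b")]
}

#' Summarise AS events by type
#'
#' Reports both counters in use in the field: event counts (fractions sum to
#' 1) and, when the events carry a `locus_id`, the number of distinct gene
#' loci exhibiting each type.
#'
#' @param events event tibble.
#' @return Tibble with `type`, `n_events`, `frac_events` and (when
#'   available) `n_genes`; zero rows for empty input.
#' @export
as_type_percentages <- function(events) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(type = character(0), n_events = integer(0),
                          frac_events = numeric(0), n_genes = integer(0)))
  }
  types <- sort(unique(events$type))
  n <- vapply(types, function(t) sum(events$type == t), integer(1),
              USE.NAMES = FALSE)
  out <- tibble::tibble(type = types, n_events = n,
                        frac_events = n / sum(n))
  if ("locus_id" %in% names(events)) {
    out$n_genes <- vapply(types, function(t) {
      length(unique(events$locus_id[events$type == t]))
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Census of splice-site dinucleotides
#'
#' For every intron of every transcript, reads the donor (first two intron
#' bases) and acceptor (last two) in transcription orientation — reverse
#' complemented on the minus strand — and tallies the canonical GT-AG class
#' against the minor GC-AG and AT-AC (U12-type) classes; everything else,
#' including N-containing sites, is `other`.
#'
#' @param tx transcript table.
#' @param genome named character vector of chromosome sequences.
#' @return List with `counts` (named integer over GT-AG/GC-AG/AT-AC/other),
#'   `fractions` (same keys, summing to 1 when any introns exist), and
#'   `per_intron` (tibble with the observed dinucleotides and class).
#' @export
splice_site_census <- function(tx, genome) {
  itr <- introns_of(tx)
  classes <- c("GT-AG", "GC-AG", "AT-AC", "other")
  if (nrow(itr) == 0L) {
    counts <- stats::setNames(integer(4L), classes)
    return(list(counts = counts, fractions = stats::setNames(rep(NA_real_, 4L),
                                                             classes),
                per_intron = tibble::tibble()))
  }
  donor <- character(nrow(itr))
  acceptor <- character(nrow(itr))
  for (i in seq_len(nrow(itr))) {
    d <- tryCatch(
      genome_subseq(genome, itr$chrom[i], itr$start[i], itr$start[i] + 2L),
      error = function(e) stop("transcript ", itr$tx_id[i], ": ",
                               conditionMessage(e)))
    a <- tryCatch(
      genome_subseq(genome, itr$chrom[i], itr$end[i] - 2L, itr$end[i]),
      error = function(e) stop("transcript ", itr$tx_id[i], ": ",
                               conditionMessage(e)))
    if (itr$strand[i] == "+") {
      donor[i] <- d
      acceptor[i] <- a
    } else {
      donor[i] <- revcomp(a)
      acceptor[i] <- revcomp(d)
    }
  }
  pair <- paste(donor, acceptor, sep = "-")
  cls <- ifelse(pair %in% c("GT-AG", "GC-AG", "AT-AC"), pair, "other")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(cls == cl), integer(1)), classes)
  list(counts = counts, fractions = counts / sum(counts),
       per_intron = tibble::tibble(tx_id = itr$tx_id, chrom = itr$chrom,
                                   strand = itr$strand, start = itr$start,
                                   end = itr$end, donor = donor,
                                   acceptor = acceptor, class = cls))
}

#' Genomic context of splice junctions
#'
#' Assigns every junction, by its donor position (first intron base in
#' transcription orientation), to one of five regions of the annotation with
#' precedence CDS > UTR > intron > intergenic: inside an annotated CDS
#' genomic span; inside an mRNA exon outside the CDS span (5' or 3' UTR by
#' strand and side); inside an annotated transcript span but not in a UTR
#' exon; or intergenic.
#'
#' @param junctions tibble with `chrom`, `strand`, `start`, `end`.
#' @param annotation annotation transcript table with CDS spans.
#' @return List with `counts` (named integer over CDS, 5'UTR, 3'UTR, intron,
#'   intergenic) and `per_junction` tibble.
#' @export
sj_context <- function(junctions, annotation) {
  regions <- c("CDS", "5'UTR", "3'UTR", "intron", "intergenic")
  n <- nrow(junctions)
  out <- character(n)
  span <- transcript_span(annotation)
  for (k in seq_len(n)) {
    p <- if (junctions$strand[k] == "+") junctions$start[k]
         else junctions$end[k] - 1L
    chrom <- junctions$chrom[k]
    cand <- which(annotation$chrom == chrom & span$span_start <= p &
                  span$span_end > p)
    if (length(cand) == 0L) {
      out[k] <- "intergenic"
      next
    }
    assigned <- "intron"
    for (i in cand) {
      cs <- annotation$cds_start[i]
      ce <- annotation$cds_end[i]
      if (!is.na(cs) && p >= cs && p < ce) {
        assigned <- "CDS"
        break
      }
      exonic <- any(annotation$exon_starts[[i]] <= p &
                    annotation$exon_ends[[i]] > p)
      if (exonic && !is.na(cs)) {
        before_cds <- p < cs
        utr <- if (annotation$strand[i] == "+") {
          if (before_cds) "5'UTR" else "3'UTR"
        } else {
          if (before_cds) "3'UTR" else "5'UTR"
        }
        assigned <- utr  # keep scanning: CDS of another mRNA wins
      }
    }
    out[k] <- assigned
  }
  counts <- stats::setNames(
    vapply(regions, function(r) sum(out == r), integer(1)), regions)
  list(counts = counts,
       per_junction = dplyr::mutate(junctions, region = out))
}

#' Exon counts of AS versus non-AS gene loci
#'
#' A locus counts as alternatively spliced when at least one AS event was
#' detected among its isoforms; its exon number is the maximum per-isoform
#' exon count.
#'
#' @param loci a `locus_set`.
#' @param events event tibble with `locus_id` (from
#'   [detect_locus_as_events()]).
#' @return List with `per_locus` (tibble: `locus_id`, `as_gene`,
#'   `max_exons`) and the exon-count vectors `as_genes` and `non_as_genes`.
#' @export
exon_count_by_as_status <- function(loci, events) {
  nodes <- loci$transcripts[!loci$transcripts$is_annotation, , drop = FALSE]
  if (nrow(nodes) == 0L) {
    return(list(per_locus = tibble::tibble(locus_id = character(0),
                                           as_gene = logical(0),
                                           max_exons = integer(0)),
                as_genes = integer(0), non_as_genes = integer(0)))
  }
  n_ex <- vapply(nodes$exon_starts, length, integer(1))
  per <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(locus_id = nodes$locus_id, n_ex = n_ex),
                    locus_id),
    max_exons = max(n_ex), .groups = "drop")
  per$as_gene <- per$locus_id %in% events$locus_id
  list(per_locus = per[, c("locus_id", "as_gene", "max_exons")],
       as_genes = per$max_exons[per$as_gene],
       non_as_genes = per$max_exons[!per$as_gene])
}
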