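#' Build a transcript table
#'
#' The central container of the package: one row per transcript, with the
#' exon chain held in list-columns. All coordinates are 0-based half-open
#' genomic intervals; GFF3/BED I/O converts at the boundary.
#'
#' @param tx_id character vector of transcript ids (unique).
#' @param chrom chromosome name per transcript.
#' @param strand `"+"` or `"-"` per transcript.
#' @param exon_starts,exon_ends lists of integer vectors, one element per
#'   transcript; each pair of vectors must be sorted by start, non-overlapping,
#'   with consecutive exons separated by at least 1 bp (an intron).
#' @param gene_id optional gene id per transcript (`NA` for unassigned).
#' @param source provenance tag, one of `"annotation"`, `"flnc"`, `"merged"`.
#' @param cds_start,cds_end optional genomic CDS span (0-based half-open),
#'   `NA` when absent.
#'
#' @return A tibble with class `tx_tbl`, one row per transcript.
#' @export
transcripts <- function(tx_id, chrom, strand, exon_starts, exon_ends,
                        gene_id = NA_character_, source = "annotation",
                        cds_start = NA_integer_, cds_end = NA_integer_) {
  n <- length(tx_id)
  if (!is.list(exon_starts)) exon_starts <- list(exon_starts)
  if (!is.list(exon_ends)) exon_ends <- list(exon_ends)
  tx <- tibble::tibble(
    tx_id = as.character(tx_id),
    gene_id = rep_len(as.character(gene_id), n),
    chrom = rep_len(as.character(chrom), n),
    strand = rep_len(as.character(strand), n),
    exon_starts = lapply(exon_starts, as.integer),
    exon_ends = lapply(exon_ends, as.integer),
    source = rep_len(as.character(source), n),
    cds_start = rep_len(as.integer(cds_start), n),
    cds_end = rep_len(as.integer(cds_end), n)
  )
  validate_transcripts(tx)
  class(tx) <- c("tx_tbl", class(tx))
  tx
}

#' Validate transcript-table invariants
#'
#' Checks id uniqueness, strand values, and per-transcript exon-chain
#' invariants (sorted, non-overlapping, separated exons; positive exonic
#' length). Called by constructors and readers; exported for use on tables
#' assembled by hand.
#'
#' @param tx a transcript table.
#' @return `tx`, invisibly, if valid; otherwise an error.
#' @export
validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx))
  needed <- c("tx_id", "chrom", "strand", "exon_starts", "exon_ends")
  missing <- setdiff(needed, names(tx))
  if (length(missing) > 0) {
    stop("transcript table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tx$tx_id)) {
    stop("duplicated transcript ids: ",
         paste(unique(tx$tx_id[duplicated(tx$tx_id)]), collapse = ", "))
  }
  if (!all(tx$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  for (i in seq_len(nrow(tx))) {
    s <- tx$exon_starts[[i]]
    e <- tx$exon_ends[[i]]
    id <- tx$tx_id[i]
    if (length(s) == 0L || length(s) != length(e)) {
      stop("transcript ", id, ": exon start/end vectors empty or unequal")
    }
    if (any(e <= s)) stop("transcript ", id, ": exon with end <= start")
    if (length(s) > 1L) {
      if (is.unsorted(s, strictly = TRUE)) {
        stop("transcript ", id, ": exons not sorted by start")
      }
      if (any(s[-1L] <= e[-length(e)])) {
        stop("transcript ", id, ": exons overlap or touch (no intron)")
      }
    }
  }
  invisible(tx)
}

#' Exonic length of each transcript
#'
#' @param tx a transcript table.
#' @return Integer vector: sum of exon widths per transcript.
#' @export
exonic_length <- function(tx) {
  vapply(seq_len(nrow(tx)),
         function(i) sum(tx$exon_ends[[i]] - tx$exon_starts[[i]]),
         integer(1))
}

#' Genomic span of each transcript
#'
#' @param tx a transcript table.
#' @return Tibble with `span_start`, `span_end` (0-based half-open).
#' @export
transcript_span <- function(tx) {
  tibble::tibble(
    span_start = vapply(tx$exon_starts, function(x) x[1L], integer(1)),
    span_end = vapply(tx$exon_ends, function(x) x[length(x)], integer(1))
  )
}

# Introns of one exon chain: n exons -> n-1 half-open intervals.
chain_introns <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  tibble::tibble(start = ends[-n], end = starts[-1L])
}

#' Extract the introns of every transcript
#'
#' Splice junctions are the introns between consecutive exons. A transcript
#' with n exons yields n - 1 introns; single-exon transcripts yield none.
#'
#' @param tx a transcript table.
#' @return Tibble with one row per intron: `tx_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), `index` (1-based position along the
#'   transcript in genomic order).
#' @export
introns_of <- function(tx) {
  out <- lapply(seq_len(nrow(tx)), function(i) {
    itr <- chain_introns(tx$exon_starts[[i]], tx$exon_ends[[i]])
    if (nrow(itr) == 0L) return(NULL)
    tibble::tibble(
      tx_id = tx$tx_id[i], chrom = tx$chrom[i], strand = tx$strand[i],
      start = itr$start, end = itr$end, index = seq_len(nrow(itr))
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(tx_id = character(0), chrom = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), index = integer(0))
  }
  out
}

# Key string for an intron chain ("" for single-exon chains).
intron_chain_key <- function(starts, ends) {
  itr <- chain_introns(starts, ends)
  if (nrow(itr) == 0L) return("")
  paste(paste(itr$start, itr$end, sep = "-"), collapse = ",")
}

#' Exonic overlap between two transcripts
#'
#' Total base-pair intersection of two exon chains, the fraction of each
#' transcript's exonic length it represents, and the strongest single
#' exon-to-exon overlap (relative to the shorter exon of the pair). The last
#' quantity backs the locus rule "at least one exon overlap > 20%".
#' Transcripts on different chromosomes report all zeros; strand is ignored
#' here (callers decide whether strand separates).
#'
#' @param a,b single-row transcript tables (or lists with `chrom`,
#'   `exon_starts`, `exon_ends` fields).
#' @return List with `shared_bp`, `frac_a`, `frac_b`, `max_single_exon_frac`.
#' @export
exonic_overlap <- function(a, b) {
  sa <- if (is.list(a$exon_starts)) a$exon_starts[[1L]] else a$exon_starts
  ea <- if (is.list(a$exon_ends)) a$exon_ends[[1L]] else a$exon_ends
  sb <- if (is.list(b$exon_starts)) b$exon_starts[[1L]] else b$exon_starts
  eb <- if (is.list(b$exon_ends)) b$exon_ends[[1L]] else b$exon_ends
  chrom_a <- a$chrom[[1L]]
  chrom_b <- b$chrom[[1L]]
  len_a <- sum(ea - sa)
  len_b <- sum(eb - sb)
  if (!identical(chrom_a, chrom_b)) {
    return(list(shared_bp = 0L, frac_a = 0, frac_b = 0,
                max_single_exon_frac = 0))
  }
  rep_ <- chain_overlap_report(sa, ea, sb, eb)
  list(shared_bp = rep_$shared_bp,
       frac_a = if (len_a > 0) rep_$shared_bp / len_a else 0,
       frac_b = if (len_b > 0) rep_$shared_bp / len_b else 0,
       max_single_exon_frac = rep_$max_single_exon_frac)
}

# Core overlap arithmetic on raw chains (same chromosome assumed).
chain_overlap_report <- function(sa, ea, sb, eb) {
  ov <- outer(seq_along(sa), seq_along(sb), function(i, j) {
    pmax(0L, pmin(ea[i], eb[j]) - pmax(sa[i], sb[j]))
  })
  shared <- sum(IRanges::width(IRanges::intersect(
    IRanges::IRanges(sa + 1L, ea), IRanges::IRanges(sb + 1L, eb)
  )))
  shorter <- outer(seq_along(sa), seq_along(sb), function(i, j) {
    pmin(ea[i] - sa[i], eb[j] - sb[j])
  })
  msef <- if (length(ov) > 0) max(ov / shorter) else 0
  list(shared_bp = as.integer(shared), max_single_exon_frac = msef)
}

# Reverse complement for plain character DNA (uppercase).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Fetch genome subsequence [start, end) 0-based from a named character genome.
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0L || end > len || start >= end) {
    stop("subsequence [", start, ",", end, ") outside [0,", len,
         ") on ", chrom)
  }
  substr(genome[[chrom]], start + 1L, end)
}
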