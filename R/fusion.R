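#' Call fusion transcripts from multi-segment FLNC alignments
#'
#' A multi-segment read is called a fusion when all four rules hold:
#' \enumerate{
#'   \item its segments hit two or more annotated gene loci, and (in the
#'     default `"read_breakpoint"` mode) consecutive aligned segments overlap
#'     by fewer than `max_locus_overlap` bp in read coordinates — a clean
#'     breakpoint. In `"genomic"` mode the rule is instead read literally:
#'     the hit gene loci overlap each other by fewer than
#'     `max_locus_overlap` bp genomically.
#'   \item every pair of hit loci lies on different chromosomes or more than
#'     `min_distance` bp apart;
#'   \item the read's global identity is at least `min_global_pid` and every
#'     segment's local identity at least `min_local_pid`;
#'   \item every hit locus is supported by at least `min_support_reads`
#'     short reads: summed counts of support junctions matching the introns
#'     of the segments hitting that locus (for intron-less segments,
#'     junctions overlapping the segment span).
#' }
#'
#' Note the permissive `min_global_pid = 10` default: a chimera aligns each
#' half to a different place, so whole-read identity is only a weak sanity
#' floor here and the real identity screening happens per segment; the
#' threshold is exposed for callers who want it strict.
#'
#' @param reads read table (single- and multi-segment; only multi-segment
#'   reads can produce calls).
#' @param annotation annotation transcript table.
#' @param junctions junction-support tibble with `count` column, or `NULL`.
#' @param max_locus_overlap bp, rule 1 threshold (strict `<`).
#' @param min_distance bp, rule 2 threshold (strict `>`).
#' @param min_global_pid,min_local_pid percent, rule 3 thresholds (`>=`).
#' @param min_support_reads rule 4 threshold (`>=`).
#' @param locus_overlap_mode `"read_breakpoint"` (default) or `"genomic"`.
#' @return Tibble of calls: `read_id`, `fusion_type` (`inter_chromosome` /
#'   `intra_chromosome`), `n_segments`, `genes`, `chroms` (comma-separated).
#' @export
call_fusions <- function(reads, annotation, junctions = NULL,
                         max_locus_overlap = 10L, min_distance = 50000L,
                         min_global_pid = 10, min_local_pid = 90,
                         min_support_reads = 2L,
                         locus_overlap_mode = c("read_breakpoint",
                                                "genomic")) {
  locus_overlap_mode <- match.arg(locus_overlap_mode)
  empty <- tibble::tibble(read_id = character(0), fusion_type = character(0),
                          n_segments = integer(0), genes = character(0),
                          chroms = character(0))
  if (nrow(reads) == 0L || nrow(annotation) == 0L) return(empty)

  span <- transcript_span(annotation)
  gene_span <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(gene_id = annotation$gene_id,
                                   chrom = annotation$chrom,
                                   start = span$span_start,
                                   end = span$span_end), gene_id, chrom),
    start = min(start), end = max(end), .groups = "drop")

  jkey <- character(0)
  jcount <- integer(0)
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    jkey <- paste(junctions$chrom, junctions$strand, junctions$start,
                  junctions$end, sep = "|")
    jcount <- junctions$count
  }

  multi <- unique(reads$read_id[duplicated(reads$read_id)])
  calls <- list()
  for (rid in multi) {
    seg <- reads[reads$read_id == rid, ]
    seg <- seg[order(seg$seg_idx), ]
    ns <- nrow(seg)
    seg_span_start <- vapply(seg$exon_starts, function(x) x[1L], integer(1))
    seg_span_end <- vapply(seg$exon_ends, function(x) x[length(x)],
                           integer(1))

    # which genes does each segment hit (span overlap on the same chrom)
    hit_genes <- lapply(seq_len(ns), function(i) {
      g <- gene_span[gene_span$chrom == seg$chrom[i] &
                     gene_span$start < seg_span_end[i] &
                     gene_span$end > seg_span_start[i], ]
      g$gene_id
    })
    genes <- unique(unlist(hit_genes))
    if (length(genes) < 2L) next

    # rule 1
    if (locus_overlap_mode == "read_breakpoint") {
      ok1 <- all(vapply(seq_len(ns - 1L), function(i) {
        max(0L, seg$read_end[i] - seg$read_start[i + 1L]) < max_locus_overlap
      }, logical(1)))
    } else {
      gs <- gene_span[match(genes, gene_span$gene_id), ]
      ok1 <- TRUE
      for (a in seq_len(nrow(gs) - 1L)) {
        for (b in (a + 1L):nrow(gs)) {
          if (gs$chrom[a] == gs$chrom[b]) {
            ov <- max(0L, min(gs$end[a], gs$end[b]) -
                        max(gs$start[a], gs$start[b]))
            if (ov >= max_locus_overlap) ok1 <- FALSE
          }
        }
      }
    }
    if (!ok1) next

    # rule 2: every pair of hit loci far apart or on different chromosomes
    gs <- gene_span[match(genes, gene_span$gene_id), ]
    ok2 <- TRUE
    for (a in seq_len(nrow(gs) - 1L)) {
      for (b in (a + 1L):nrow(gs)) {
        if (gs$chrom[a] != gs$chrom[b]) next
        gap <- max(gs$start[b] - gs$end[a], gs$start[a] - gs$end[b])
        if (gap <= min_distance) ok2 <- FALSE
      }
    }
    if (!ok2) next

    # rule 3
    if (!(seg$global_pid[1L] >= min_global_pid &&
          all(seg$local_pid >= min_local_pid))) next

    # rule 4: short-read support per hit locus
    ok4 <- TRUE
    for (g in genes) {
      segs_g <- which(vapply(hit_genes, function(h) g %in% h, logical(1)))
      support <- 0L
      for (i in segs_g) {
        itr <- chain_introns(seg$exon_starts[[i]], seg$exon_ends[[i]])
        if (nrow(itr) > 0L) {
          keys <- paste(seg$chrom[i], seg$strand[i], itr$start, itr$end,
                        sep = "|")
          support <- support + sum(jcount[match(keys, jkey)], na.rm = TRUE)
        } else if (length(jkey) > 0L && !is.null(junctions)) {
          ov <- junctions$chrom == seg$chrom[i] &
            junctions$start < seg_span_end[i] &
            junctions$end > seg_span_start[i]
          support <- support + sum(junctions$count[ov])
        }
      }
      if (support < min_support_reads) { ok4 <- FALSE; break }
    }
    if (!ok4) next

    calls[[length(calls) + 1L]] <- tibble::tibble(
      read_id = rid,
      fusion_type = if (length(unique(seg$chrom)) >= 2L) "inter_chromosome"
                    else "intra_chromosome",
      n_segments = ns,
      genes = paste(sort(genes), collapse = ","),
      chroms = paste(sort(unique(seg$chrom)), collapse = ","))
  }
  if (length(calls) == 0L) return(empty)
  dplyr::bind_rows(calls)
}

#' Count fusion calls by type
#'
#' @param calls tibble from [call_fusions()].
#' @return List with `inter`, `intra`, `total` (`total = inter + intra`).
#' @export
fusion_type_counts <- function(calls) {
  inter <- sum(calls$fusion_type == "inter_chromosome")
  intra <- sum(calls$fusion_type == "intra_chromosome")
  list(inter = inter, intra = intra, total = inter + intra)
}
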