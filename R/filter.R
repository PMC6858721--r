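#' Group reads with the same splice structure
#'
#' Redundancy collapse before retention: single-segment reads share a group
#' when they lie on the same chromosome and strand, have identical intron
#' chains, and their terminal exon ends agree within `fuzz` bp (single-linkage
#' on both ends). Single-exon reads, which have no intron chain, are grouped
#' positionally with tolerance `single_exon_fuzz`. The group representative
#' is the member with the longest exonic span (ties broken by read id).
#'
#' @param reads read table; must contain single-segment reads only
#'   (multi-segment reads are routed to fusion calling, not collapse).
#' @param fuzz terminal-end tolerance (bp) for multi-exon reads.
#' @param single_exon_fuzz positional tolerance (bp) for single-exon reads.
#' @return List with `groups` (tibble: `group_id`, `chrom`, `strand`,
#'   `n_reads`, `rep_read_id`) and `members` (tibble: `group_id`, `read_id`).
#' @export
group_identical_structures <- function(reads, fuzz = 0L,
                                       single_exon_fuzz = 10L) {
  if (any(duplicated(reads$read_id))) {
    stop("multi-segment reads passed to collapse; route them to fusion ",
         "calling first")
  }
  if (nrow(reads) == 0L) {
    return(list(groups = tibble::tibble(group_id = character(0),
                                        chrom = character(0),
                                        strand = character(0),
                                        n_reads = integer(0),
                                        rep_read_id = character(0)),
                members = tibble::tibble(group_id = character(0),
                                         read_id = character(0))))
  }
  n_ex <- vapply(reads$exon_starts, length, integer(1))
  chain <- vapply(seq_len(nrow(reads)), function(i) {
    intron_chain_key(reads$exon_starts[[i]], reads$exon_ends[[i]])
  }, character(1))
  key <- paste(reads$chrom, reads$strand, chain, sep = "|")

  first5 <- vapply(reads$exon_starts, function(x) x[1L], integer(1))
  last3 <- vapply(reads$exon_ends, function(x) x[length(x)], integer(1))

  grp <- integer(nrow(reads))
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    tol <- if (n_ex[idx[1L]] == 1L) single_exon_fuzz else fuzz
    # single-linkage union-find on terminal ends within tolerance
    parent <- seq_along(idx)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (length(idx) > 1L) {
      ord <- order(first5[idx])
      for (a in seq_along(ord)[-1L]) {
        for (b in seq_len(a - 1L)) {
          i <- ord[a]; j <- ord[b]
          if (abs(first5[idx[i]] - first5[idx[j]]) <= tol &&
              abs(last3[idx[i]] - last3[idx[j]]) <= tol) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      next_id <- next_id + 1L
      grp[idx[roots == r]] <- next_id
    }
  }

  span <- last3 - first5
  exlen <- vapply(seq_len(nrow(reads)), function(i) {
    sum(reads$exon_ends[[i]] - reads$exon_starts[[i]])
  }, integer(1))
  groups <- lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    rep_i <- idx[order(-exlen[idx], reads$read_id[idx])][1L]
    tibble::tibble(group_id = sprintf("grp%05d", g),
                   chrom = reads$chrom[rep_i],
                   strand = reads$strand[rep_i],
                   n_reads = length(idx),
                   rep_read_id = reads$read_id[rep_i])
  })
  members <- tibble::tibble(group_id = sprintf("grp%05d", grp),
                            read_id = reads$read_id)
  list(groups = dplyr::bind_rows(groups),
       members = members[order(members$group_id, members$read_id), ])
}

#' Retain isoform groups
#'
#' A group survives when it is supported by at least `min_reads` FLNC reads,
#' or any member's global percent identity exceeds `min_pid` (strictly), or
#' every intron of its representative is present in the short-read junction
#' support set or among the annotation's introns. Single-exon representatives
#' satisfy the junction clause vacuously. One transcript per retained group
#' is emitted, built from the representative read's exon chain.
#'
#' @param grouping output of [group_identical_structures()].
#' @param reads the read table the grouping was built from.
#' @param junctions junction-support tibble (`chrom`, `strand`, `start`,
#'   `end`, optional `count`), or `NULL` for none.
#' @param annotation annotation transcript table (its introns also count as
#'   support), or `NULL`.
#' @param min_reads minimum FLNC reads per group.
#' @param min_pid global percent-identity threshold (strict `>`).
#' @return Transcript table of retained isoforms, one row per group, with
#'   columns `n_reads`, `rep_read_id` and `retained_by` (comma-separated
#'   clauses that fired) carried along; attribute `"members"` maps retained
#'   transcripts to their supporting read ids.
#' @export
retain_isoforms <- function(grouping, reads, junctions = NULL,
                            annotation = NULL, min_reads = 2L, min_pid = 99) {
  groups <- grouping$groups
  members <- grouping$members
  if (nrow(groups) == 0L) {
    out <- transcripts(tx_id = character(0), chrom = character(0),
                       strand = character(0), exon_starts = list(),
                       exon_ends = list())
    attr(out, "members") <- tibble::tibble(tx_id = character(0),
                                           read_id = character(0))
    return(out)
  }

  support_keys <- character(0)
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    support_keys <- paste(junctions$chrom, junctions$strand,
                          junctions$start, junctions$end, sep = "|")
  }
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    ai <- introns_of(annotation)
    support_keys <- c(support_keys,
                      paste(ai$chrom, ai$strand, ai$start, ai$end, sep = "|"))
  }
  support_keys <- unique(support_keys)

  read_idx <- match(groups$rep_read_id, reads$read_id)
  pid_by_read <- stats::setNames(reads$global_pid, reads$read_id)

  rows <- vector("list", nrow(groups))
  kept_members <- list()
  for (g in seq_len(nrow(groups))) {
    mem <- members$read_id[members$group_id == groups$group_id[g]]
    by <- character(0)
    if (groups$n_reads[g] >= min_reads) by <- c(by, "reads")
    if (any(pid_by_read[mem] > min_pid)) by <- c(by, "pid")
    i <- read_idx[g]
    itr <- chain_introns(reads$exon_starts[[i]], reads$exon_ends[[i]])
    if (nrow(itr) == 0L) {
      by <- c(by, "junctions")
    } else {
      keys <- paste(reads$chrom[i], reads$strand[i], itr$start, itr$end,
                    sep = "|")
      if (all(keys %in% support_keys)) by <- c(by, "junctions")
    }
    if (length(by) == 0L) next
    tx_id <- paste0("ISO.", groups$rep_read_id[g])
    rows[[g]] <- tibble::tibble(
      tx_id = tx_id, gene_id = NA_character_, chrom = reads$chrom[i],
      strand = reads$strand[i], exon_starts = list(reads$exon_starts[[i]]),
      exon_ends = list(reads$exon_ends[[i]]), source = "flnc",
      cds_start = NA_integer_, cds_end = NA_integer_,
      n_reads = groups$n_reads[g], rep_read_id = groups$rep_read_id[g],
      retained_by = paste(by, collapse = ","))
    kept_members[[length(kept_members) + 1L]] <-
      tibble::tibble(tx_id = tx_id, read_id = mem)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- transcripts(tx_id = character(0), chrom = character(0),
                       strand = character(0), exon_starts = list(),
                       exon_ends = list())
    attr(out, "members") <- tibble::tibble(tx_id = character(0),
                                           read_id = character(0))
    return(out)
  }
  validate_transcripts(out)
  class(out) <- c("tx_tbl", class(out))
  attr(out, "members") <- dplyr::bind_rows(kept_members)
  out
}
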