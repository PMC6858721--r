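#' Cluster FLNC 3' ends into polyadenylation sites
#'
#' Each single-segment read's 3' end (last aligned base in transcription
#' orientation: the rightmost base on `+`, the leftmost on `-`) is assigned
#' to the gene locus its exon chain overlaps most, then per-gene ends are
#' single-linkage clustered: consecutive sorted ends more than
#' `cluster_radius` bp apart start a new cluster. Clusters supported by at
#' least `min_support` reads become sites; the representative position is
#' the modal member position, ties resolved to the most downstream position
#' (strand-aware). Reads overlapping no locus are ignored.
#'
#' @param reads read table (multi-segment reads are skipped).
#' @param loci a `locus_set`; gene identity is the locus's known gene id
#'   when present, otherwise the locus id.
#' @param cluster_radius single-linkage distance (bp).
#' @param min_support minimum reads per site.
#' @return Tibble of sites: `gene_id`, `chrom`, `strand`, `position`,
#'   `support`, `member_positions` (list column).
#' @export
call_polya_sites <- function(reads, loci, cluster_radius = 24L,
                             min_support = 2L) {
  empty <- tibble::tibble(gene_id = character(0), chrom = character(0),
                          strand = character(0), position = integer(0),
                          support = integer(0), member_positions = list())
  single <- reads[!reads$read_id %in%
                    unique(reads$read_id[duplicated(reads$read_id)]), ,
                  drop = FALSE]
  if (nrow(single) == 0L || nrow(loci$loci) == 0L) return(empty)

  nodes <- loci$transcripts
  node_span <- transcript_span(nodes)
  gene_of_locus <- ifelse(is.na(loci$loci$known_gene_id), loci$loci$locus_id,
                          loci$loci$known_gene_id)
  names(gene_of_locus) <- loci$loci$locus_id

  # assign each read to the locus with maximal exonic overlap
  assign_rows <- list()
  for (i in seq_len(nrow(single))) {
    s <- single$exon_starts[[i]]
    e <- single$exon_ends[[i]]
    cand <- which(nodes$chrom == single$chrom[i] &
                  nodes$strand == single$strand[i] &
                  node_span$span_start < e[length(e)] &
                  node_span$span_end > s[1L])
    if (length(cand) == 0L) next
    shared <- vapply(cand, function(j) {
      chain_overlap_report(s, e, nodes$exon_starts[[j]],
                           nodes$exon_ends[[j]])$shared_bp
    }, integer(1))
    if (max(shared) == 0L) next
    lid <- nodes$locus_id[cand[which.max(shared)]]
    end3 <- if (single$strand[i] == "+") e[length(e)] - 1L else s[1L]
    assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
      gene_id = unname(gene_of_locus[lid]), chrom = single$chrom[i],
      strand = single$strand[i], end3 = end3)
  }
  if (length(assign_rows) == 0L) return(empty)
  ends <- dplyr::bind_rows(assign_rows)

  site_rows <- list()
  for (g in unique(ends$gene_id)) {
    sub <- ends[ends$gene_id == g, ]
    pos <- sort(sub$end3)
    breaks <- which(diff(pos) > cluster_radius)
    cluster_id <- cumsum(c(1L, seq_along(pos)[-1L] %in% (breaks + 1L)))
    for (cl in unique(cluster_id)) {
      members <- pos[cluster_id == cl]
      if (length(members) < min_support) next
      tab <- table(members)
      modal <- as.integer(names(tab)[tab == max(tab)])
      rep_pos <- if (sub$strand[1L] == "+") max(modal) else min(modal)
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        gene_id = g, chrom = sub$chrom[1L], strand = sub$strand[1L],
        position = rep_pos, support = length(members),
        member_positions = list(members))
    }
  }
  if (length(site_rows) == 0L) return(empty)
  out <- dplyr::bind_rows(site_rows)
  out[order(out$gene_id, out$position), ]
}

#' Summarise alternative polyadenylation
#'
#' A gene shows alternative polyadenylation (APA) when it carries two or
#' more called polyA sites.
#'
#' @param sites site tibble from [call_polya_sites()].
#' @return List with `genes_with_sites`, `total_sites`, `apa_genes`
#'   (`apa_genes <= genes_with_sites <= total_sites`).
#' @export
call_apa <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(genes_with_sites = 0L, total_sites = 0L, apa_genes = 0L))
  }
  per_gene <- table(sites$gene_id)
  list(genes_with_sites = length(per_gene),
       total_sites = nrow(sites),
       apa_genes = sum(per_gene >= 2L))
}
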