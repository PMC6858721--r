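#' Merge novel isoforms with the reference annotation
#'
#' Builds the unified transcript library: the union of all reference
#' transcripts and the discovered novel isoforms (labels `known_novel` or
#' `novel`), each row tagged with a `provenance` attribute (`reference` /
#' `flnc`). Novel transcripts never replace or deduplicate against reference
#' entries; isoforms that reproduce annotated structures (`known_known`) are
#' expected to be excluded upstream.
#'
#' @param annotation reference transcript table.
#' @param novel_isoforms transcript table of discovered novel isoforms; if a
#'   `label` column is present it must only contain `known_novel` / `novel`.
#' @param ... passed to [summarize_structure()].
#' @return List with `library` (merged transcript table, `provenance`
#'   column) and `summary` (see [summarize_structure()]).
#' @export
merge_library <- function(annotation, novel_isoforms, ...) {
  if ("label" %in% names(novel_isoforms) && nrow(novel_isoforms) > 0L) {
    bad <- setdiff(unique(novel_isoforms$label), c("known_novel", "novel"))
    if (length(bad) > 0L) {
      stop("novel isoform table contains non-novel labels: ",
           paste(bad, collapse = ", "))
    }
  }
  clash <- intersect(annotation$tx_id, novel_isoforms$tx_id)
  if (length(clash) > 0L) {
    stop("transcript id collision between annotation and novel set: ",
         paste(clash, collapse = ", "))
  }
  keep <- c("tx_id", "gene_id", "chrom", "strand", "exon_starts",
            "exon_ends", "source", "cds_start", "cds_end")
  fill_cols <- function(x) {
    for (col in setdiff(keep, names(x))) {
      x[[col]] <- if (col %in% c("cds_start", "cds_end")) NA_integer_
                  else NA_character_
    }
    x[, keep]
  }
  ref <- fill_cols(annotation)
  nov <- fill_cols(novel_isoforms)
  ref$provenance <- rep("reference", nrow(ref))
  nov$provenance <- rep("flnc", nrow(nov))
  lib <- dplyr::bind_rows(ref, nov)
  summary <- summarize_structure(lib)
  summary$n_reference <- nrow(ref)
  summary$n_novel <- nrow(nov)
  list(library = lib, summary = summary)
}

#' Structural summary statistics of a transcript library
#'
#' Computes the headline structure numbers of a transcript set: the median
#' exon size over all exons, the median gene size (genomic span of each
#' gene, the union of its transcripts; transcripts without a gene id count
#' as their own gene), the mean number of coding exons per gene (exons
#' overlapping the CDS span, maximised over the gene's transcripts; genes
#' without any CDS fall back to all exons and are counted separately in
#' `n_genes_cds_fallback`), and a transcript-length histogram over exonic
#' lengths.
#'
#' @param tx transcript table.
#' @param hist_breaks right-closed bin edges (bp) for the length histogram;
#'   a final open-ended bin is added.
#' @return List with `n_total`, `median_exon_size`, `median_gene_size`,
#'   `mean_coding_exons_per_gene`, `n_genes`, `n_genes_cds_fallback`,
#'   `length_histogram` (named integer vector).
#' @export
summarize_structure <- function(tx, hist_breaks = c(500, 1000, 1500, 2000,
                                                    2500, 3000, 4000,
                                                    5000)) {
  exon_sizes <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    tx$exon_ends[[i]] - tx$exon_starts[[i]]
  }))
  gene_id <- if ("gene_id" %in% names(tx)) tx$gene_id else
    rep(NA_character_, nrow(tx))
  gene_id <- ifelse(is.na(gene_id), tx$tx_id, gene_id)
  span <- transcript_span(tx)
  gene_start <- tapply(span$span_start, gene_id, min)
  gene_end <- tapply(span$span_end, gene_id, max)
  gene_size <- as.integer(gene_end - gene_start)

  coding_exons <- function(i) {
    s <- tx$exon_starts[[i]]
    e <- tx$exon_ends[[i]]
    cs <- if ("cds_start" %in% names(tx)) tx$cds_start[i] else NA_integer_
    ce <- if ("cds_end" %in% names(tx)) tx$cds_end[i] else NA_integer_
    if (is.na(cs)) return(c(n = length(s), fallback = 1L))
    c(n = sum(e > cs & s < ce), fallback = 0L)
  }
  per_tx <- vapply(seq_len(nrow(tx)), coding_exons, c(n = 0L, fallback = 0L))
  # per gene: prefer CDS-bearing transcripts; max coding-exon count
  per_gene <- vapply(split(seq_len(nrow(tx)), gene_id), function(idx) {
    has_cds <- per_tx["fallback", idx] == 0L
    use <- if (any(has_cds)) idx[has_cds] else idx
    c(max(per_tx["n", use]), as.integer(!any(has_cds)))
  }, integer(2))

  exlen <- exonic_length(tx)
  breaks <- c(0, hist_breaks, Inf)
  labels <- paste0(
    c(0, hist_breaks), "-",
    c(hist_breaks, "Inf"))
  histo <- stats::setNames(
    as.integer(table(cut(exlen, breaks = breaks, labels = labels,
                         right = TRUE))), labels)

  list(n_total = nrow(tx),
       median_exon_size = stats::median(exon_sizes),
       median_gene_size = stats::median(gene_size),
       mean_coding_exons_per_gene = mean(per_gene[1L, ]),
       n_genes = ncol(per_gene),
       n_genes_cds_fallback = sum(per_gene[2L, ]),
       length_histogram = histo)
}
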