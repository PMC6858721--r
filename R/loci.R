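#' Group isoforms and annotation transcripts into gene loci
#'
#' Transcripts are nodes of an overlap graph; two transcripts are connected
#' when they share chromosome and strand, their mutual exonic overlap
#' exceeds `min_frac` of both exonic lengths, and at least one exon-to-exon
#' overlap exceeds `min_frac` of the shorter exon. Loci are the connected
#' components. A locus containing annotation transcripts inherits the
#' annotated gene id; components mixing several annotated genes are kept but
#' flagged in the `warnings` element.
#'
#' Because loci are strand-specific, an isoform overlapping a known gene on
#' the opposite strand lands in its own locus and is therefore novel.
#'
#' @param isoforms transcript table of discovered isoforms.
#' @param annotation annotation transcript table (participates in the graph;
#'   never emitted as a discovery).
#' @param min_frac overlap fraction threshold (strict `>`).
#' @return An object of class `locus_set`: list with `assignments` (tibble:
#'   `locus_id`, `tx_id`, `is_annotation`, `gene_id`), `loci` (tibble:
#'   `locus_id`, `chrom`, `strand`, `known_gene_id`, `n_isoforms`,
#'   `n_annotation`), `transcripts` (all node transcripts with `locus_id`),
#'   and `warnings`.
#' @export
build_loci <- function(isoforms, annotation, min_frac = 0.20) {
  iso <- isoforms
  ann <- annotation
  nodes <- dplyr::bind_rows(
    if (nrow(iso) > 0L) dplyr::mutate(iso[, c("tx_id", "gene_id", "chrom",
                                              "strand", "exon_starts",
                                              "exon_ends")],
                                      is_annotation = FALSE),
    if (nrow(ann) > 0L) dplyr::mutate(ann[, c("tx_id", "gene_id", "chrom",
                                              "strand", "exon_starts",
                                              "exon_ends")],
                                      is_annotation = TRUE)
  )
  if (is.null(nodes) || nrow(nodes) == 0L) {
    return(structure(list(
      assignments = tibble::tibble(locus_id = character(0),
                                   tx_id = character(0),
                                   is_annotation = logical(0),
                                   gene_id = character(0)),
      loci = tibble::tibble(locus_id = character(0), chrom = character(0),
                            strand = character(0),
                            known_gene_id = character(0),
                            n_isoforms = integer(0),
                            n_annotation = integer(0)),
      transcripts = nodes, warnings = character(0)), class = "locus_set"))
  }

  edges <- overlap_edges(nodes, min_frac)
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = data.frame(name = nodes$tx_id, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[nodes$tx_id]

  span <- transcript_span(nodes)
  # deterministic locus ids: order components by (chrom, min span start)
  comp_min <- tapply(span$span_start, comp, min)
  comp_chrom <- tapply(nodes$chrom, comp, function(x) x[1L])
  comp_order <- order(comp_chrom, comp_min)
  locus_of_comp <- stats::setNames(
    sprintf("LOC%05d", seq_along(comp_order)),
    names(comp_min)[comp_order])
  locus_id <- locus_of_comp[as.character(comp)]

  assignments <- tibble::tibble(locus_id = unname(locus_id),
                                tx_id = nodes$tx_id,
                                is_annotation = nodes$is_annotation,
                                gene_id = nodes$gene_id)
  warnings <- character(0)
  loci_rows <- lapply(split(seq_len(nrow(nodes)), locus_id), function(idx) {
    genes <- unique(nodes$gene_id[idx][nodes$is_annotation[idx]])
    lid <- locus_id[idx[1L]]
    if (length(genes) > 1L) {
      warnings <<- c(warnings, paste0(
        "locus ", lid, " merges annotated genes: ",
        paste(sort(genes), collapse = ", ")))
    }
    tibble::tibble(
      locus_id = lid, chrom = nodes$chrom[idx[1L]],
      strand = nodes$strand[idx[1L]],
      known_gene_id = if (length(genes) >= 1L) sort(genes)[1L]
                      else NA_character_,
      n_isoforms = sum(!nodes$is_annotation[idx]),
      n_annotation = sum(nodes$is_annotation[idx]))
  })
  loci <- dplyr::bind_rows(loci_rows)
  loci <- loci[order(loci$locus_id), ]
  nodes$locus_id <- unname(locus_id)

  structure(list(assignments = assignments, loci = loci,
                 transcripts = nodes, warnings = warnings),
            class = "locus_set")
}

# Candidate pairs via span overlap, refined by the exact exonic criterion.
overlap_edges <- function(nodes, min_frac) {
  span <- transcript_span(nodes)
  gr <- GenomicRanges::GRanges(
    nodes$chrom, IRanges::IRanges(span$span_start + 1L, span$span_end),
    strand = nodes$strand)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  from <- S4Vectors::queryHits(hits)
  to <- S4Vectors::subjectHits(hits)
  exlen <- exonic_length(nodes)
  keep <- vapply(seq_along(from), function(k) {
    i <- from[k]; j <- to[k]
    rep_ <- chain_overlap_report(nodes$exon_starts[[i]], nodes$exon_ends[[i]],
                                 nodes$exon_starts[[j]], nodes$exon_ends[[j]])
    fa <- rep_$shared_bp / exlen[i]
    fb <- rep_$shared_bp / exlen[j]
    min(fa, fb) > min_frac && rep_$max_single_exon_frac > min_frac
  }, logical(1))
  data.frame(from = nodes$tx_id[from[keep]], to = nodes$tx_id[to[keep]],
             stringsAsFactors = FALSE)
}

#' Assign novelty labels to discovered isoforms
#'
#' Labels every non-annotation member of each locus:
#' \describe{
#'   \item{`novel`}{the locus contains no annotated transcript (covers both
#'     the sub-threshold-overlap and the opposite-strand cases, since loci
#'     are strand-specific).}
#'   \item{`known_novel`}{the locus is a known gene but the isoform's splice
#'     structure is not among the gene's annotated transcripts.}
#'   \item{`known_known`}{the isoform reproduces an annotated structure.}
#' }
#'
#' What counts as a novel structure is controlled by `new_site_mode`:
#' \describe{
#'   \item{`"chain"` (default)}{known only when the intron chain exactly
#'     matches an annotated transcript of the gene; a single-exon isoform is
#'     known only when the gene has a single-exon annotated transcript. This
#'     catches skipped exons, retained introns and shifted splice sites
#'     alike.}
#'   \item{`"boundary"`}{novel when any intron boundary is absent from the
#'     gene's annotated splice-site set (plus the single-/multi-exon
#'     mismatch rule).}
#'   \item{`"intron"`}{novel when any whole intron is absent from the gene's
#'     annotated intron set (plus the single-/multi-exon mismatch rule).}
#' }
#'
#' @param loci a `locus_set` from [build_loci()].
#' @param annotation annotation transcript table.
#' @param new_site_mode one of `"chain"`, `"boundary"`, `"intron"`.
#' @return The `locus_set` with a `label` column added to `assignments` and
#'   `transcripts` (NA for annotation members).
#' @export
classify_isoforms <- function(loci, annotation,
                              new_site_mode = c("chain", "boundary",
                                                "intron")) {
  new_site_mode <- match.arg(new_site_mode)
  asn <- loci$assignments
  nodes <- loci$transcripts
  ann_by_gene <- split(seq_len(nrow(annotation)), annotation$gene_id)
  ann_introns <- introns_of(annotation)

  label <- rep(NA_character_, nrow(asn))
  known_gene <- stats::setNames(loci$loci$known_gene_id, loci$loci$locus_id)

  for (i in seq_len(nrow(asn))) {
    if (asn$is_annotation[i]) next
    gene <- known_gene[[asn$locus_id[i]]]
    if (is.na(gene)) {
      label[i] <- "novel"
      next
    }
    ni <- match(asn$tx_id[i], nodes$tx_id)
    s <- nodes$exon_starts[[ni]]
    e <- nodes$exon_ends[[ni]]
    gi <- ann_by_gene[[gene]]
    g_single <- any(vapply(annotation$exon_starts[gi], length,
                           integer(1)) == 1L)
    iso_single <- length(s) == 1L
    gj <- ann_introns[ann_introns$tx_id %in% annotation$tx_id[gi], ]

    novel <- if (new_site_mode == "chain") {
      if (iso_single) {
        !g_single
      } else {
        key <- intron_chain_key(s, e)
        ann_keys <- vapply(gi, function(k) {
          intron_chain_key(annotation$exon_starts[[k]],
                           annotation$exon_ends[[k]])
        }, character(1))
        !(key %in% ann_keys)
      }
    } else if (new_site_mode == "boundary") {
      itr <- chain_introns(s, e)
      bounds <- unique(c(gj$start, gj$end))
      new_site <- nrow(itr) > 0L &&
        !all(c(itr$start, itr$end) %in% bounds)
      # single/multi mismatch: exactly one side single-exon
      mismatch <- (iso_single && !g_single) || (!iso_single && g_single &&
                  all(vapply(annotation$exon_starts[gi], length,
                             integer(1)) == 1L))
      new_site || mismatch
    } else {
      itr <- chain_introns(s, e)
      keys <- paste(itr$start, itr$end, sep = "-")
      ann_keys <- paste(gj$start, gj$end, sep = "-")
      new_intron <- nrow(itr) > 0L && !all(keys %in% ann_keys)
      mismatch <- (iso_single && !g_single) || (!iso_single && g_single &&
                  all(vapply(annotation$exon_starts[gi], length,
                             integer(1)) == 1L))
      new_intron || mismatch
    }
    label[i] <- if (novel) "known_novel" else "known_known"
  }
  loci$assignments$label <- label
  loci$transcripts$label <- label[match(loci$transcripts$tx_id, asn$tx_id)]
  loci
}

#' Tabulate the locus/isoform novelty partition
#'
#' Reproduces the three-way summary table: known genes with known isoforms,
#' known genes with novel isoforms, and novel genes, with loci and isoform
#' counts per row plus a total row. Isoform counts always partition exactly.
#' Locus counting is controlled by `mode`: `"disjoint"` (default) counts each
#' locus once under its most novel member (novel > known_novel >
#' known_known), so locus rows also sum to the total; `"overlapping"` counts
#' a locus under every row it has a member of.
#'
#' @param assignments tibble with `locus_id`, `tx_id`, `label` (isoform rows
#'   only; annotation rows with `NA` label are dropped), e.g. the
#'   `assignments` element of a classified `locus_set`.
#' @param mode `"disjoint"` or `"overlapping"`.
#' @return Tibble with `category`, `n_loci`, `n_isoforms`; categories
#'   `known_known`, `known_novel`, `novel`, `total`.
#' @export
partition_counts <- function(assignments, mode = c("disjoint",
                                                   "overlapping")) {
  mode <- match.arg(mode)
  asn <- assignments[!is.na(assignments$label), , drop = FALSE]
  cats <- c("known_known", "known_novel", "novel")
  n_iso <- vapply(cats, function(cl) sum(asn$label == cl), integer(1))
  if (mode == "disjoint") {
    rank <- c(known_known = 1L, known_novel = 2L, novel = 3L)
    best <- tapply(rank[asn$label], asn$locus_id, max)
    n_loc <- vapply(cats, function(cl) sum(best == rank[[cl]]), integer(1))
  } else {
    n_loc <- vapply(cats, function(cl) {
      length(unique(asn$locus_id[asn$label == cl]))
    }, integer(1))
  }
  tibble::tibble(
    category = c(cats, "total"),
    n_loci = unname(c(n_loc, if (mode == "disjoint") sum(n_loc)
                      else length(unique(asn$locus_id)))),
    n_isoforms = unname(c(n_iso, sum(n_iso))))
}
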