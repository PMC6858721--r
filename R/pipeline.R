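#' Assemble a pipeline configuration
#'
#' Inputs may be given as file paths (FASTA/GFF3/BED12+TSV/BED) or as the
#' in-memory objects the rest of the package uses; thresholds default to the
#' package-wide defaults of each stage. Unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param genome named character vector or FASTA path.
#' @param annotation transcript table or GFF3 path.
#' @param alignments read table, or `c(bed, tsv)` paths for
#'   [read_flnc()].
#' @param junctions junction tibble or BED path; `NULL` for none.
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param min_reads,min_pid retention thresholds (see [retain_isoforms()]).
#' @param group_fuzz,single_exon_fuzz collapse tolerances (see
#'   [group_identical_structures()]).
#' @param min_frac locus overlap threshold (see [build_loci()]).
#' @param new_site_mode novelty test mode (see [classify_isoforms()]).
#' @param partition_mode locus counting mode (see [partition_counts()]).
#' @param max_locus_overlap,min_distance,min_global_pid,min_local_pid,min_support_reads
#'   fusion thresholds (see [call_fusions()]).
#' @param as_fuzz AS-event tolerance (see [detect_as_events()]).
#' @param cluster_radius,min_support polyA thresholds (see
#'   [call_polya_sites()]).
#' @param seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, alignments,
                            junctions = NULL, out_dir = NULL,
                            min_reads = 2L, min_pid = 99,
                            group_fuzz = 0L, single_exon_fuzz = 10L,
                            min_frac = 0.20,
                            new_site_mode = "chain",
                            partition_mode = "disjoint",
                            max_locus_overlap = 10L, min_distance = 50000L,
                            min_global_pid = 10, min_local_pid = 90,
                            min_support_reads = 2L,
                            as_fuzz = 10L,
                            cluster_radius = 24L, min_support = 2L,
                            seed = NA_integer_) {
  cfg <- as.list(environment())
  stopifnot(min_reads >= 1L, min_pid >= 0, min_pid <= 100,
            min_frac >= 0, min_frac < 1, group_fuzz >= 0L,
            single_exon_fuzz >= 0L, as_fuzz >= 0L,
            cluster_radius >= 0L, min_support >= 1L,
            max_locus_overlap >= 0L, min_distance >= 0L,
            min_support_reads >= 0L)
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_input <- function(x, reader, what) {
  if (is.character(x) && is.null(names(x)) && length(x) <= 2L) {
    for (p in x) if (!file.exists(p)) stop("missing ", what, " file: ", p)
    if (length(x) == 2L) reader(x[1L], x[2L]) else reader(x)
  } else x
}

#' Run the full annotation pipeline
#'
#' Stages run in order: collapse and retention of single-segment reads;
#' locus construction and novelty classification against the annotation;
#' fusion calling on multi-segment reads; AS-event detection and typing;
#' splice-site census and junction-context assignment; polyA-site
#' clustering and APA summary; merge of novel isoforms with the reference
#' into the unified library. The run is deterministic: identical inputs and
#' configuration reproduce identical outputs byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @return The run manifest (list): configuration echo, package version,
#'   per-stage record counts, all stage results, and (when `out_dir` is set)
#'   the paths written. Conservation identities (isoform partition sums,
#'   fusion `inter + intra = total`, library `reference + novel = total`)
#'   hold on every manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  genome <- resolve_input(cfg$genome, read_fasta, "genome")
  annotation <- resolve_input(cfg$annotation, read_gff3, "annotation")
  reads <- resolve_input(cfg$alignments, read_flnc, "alignments")
  junctions <- if (is.null(cfg$junctions)) NULL
               else resolve_input(cfg$junctions, read_junctions, "junctions")

  multi_ids <- unique(reads$read_id[duplicated(reads$read_id)])
  single <- reads[!reads$read_id %in% multi_ids, , drop = FALSE]

  grouping <- group_identical_structures(single, fuzz = cfg$group_fuzz,
                                         single_exon_fuzz =
                                           cfg$single_exon_fuzz)
  retained <- retain_isoforms(grouping, single, junctions, annotation,
                              min_reads = cfg$min_reads,
                              min_pid = cfg$min_pid)

  loci <- build_loci(retained, annotation, min_frac = cfg$min_frac)
  loci <- classify_isoforms(loci, annotation,
                            new_site_mode = cfg$new_site_mode)
  partition <- partition_counts(loci$assignments, mode = cfg$partition_mode)

  fusions <- call_fusions(reads, annotation, junctions,
                          max_locus_overlap = cfg$max_locus_overlap,
                          min_distance = cfg$min_distance,
                          min_global_pid = cfg$min_global_pid,
                          min_local_pid = cfg$min_local_pid,
                          min_support_reads = cfg$min_support_reads)
  fusion_counts <- fusion_type_counts(fusions)

  events <- detect_locus_as_events(loci, fuzz = cfg$as_fuzz)
  as_summary <- as_type_percentages(events)
  census <- splice_site_census(retained, genome)
  all_junc <- introns_of(retained)
  context <- sj_context(all_junc, annotation)
  exon_as <- exon_count_by_as_status(loci, events)

  sites <- call_polya_sites(single, loci,
                            cluster_radius = cfg$cluster_radius,
                            min_support = cfg$min_support)
  apa <- call_apa(sites)

  labels <- loci$assignments[!is.na(loci$assignments$label), ]
  novel_ids <- labels$tx_id[labels$label %in% c("known_novel", "novel")]
  iso_out <- retained
  iso_out$label <- labels$label[match(iso_out$tx_id, labels$tx_id)]
  iso_out$locus_id <- labels$locus_id[match(iso_out$tx_id, labels$tx_id)]
  novel <- iso_out[iso_out$tx_id %in% novel_ids, , drop = FALSE]
  merged <- merge_library(annotation, novel)

  manifest <- list(
    config = cfg[setdiff(names(cfg), c("genome", "annotation", "alignments",
                                       "junctions", "out_dir"))],
    version = as.character(utils::packageVersion("isoforge")),
    counts = list(
      reads_in = length(unique(reads$read_id)),
      reads_single_segment = nrow(single),
      reads_multi_segment = length(multi_ids),
      groups = nrow(grouping$groups),
      retained_isoforms = nrow(retained),
      loci_with_isoforms = sum(loci$loci$n_isoforms > 0L),
      fusion_calls = nrow(fusions),
      as_events = nrow(events),
      polya_sites = nrow(sites)),
    partition = partition,
    fusion_counts = fusion_counts,
    as_summary = as_summary,
    census = list(counts = census$counts, fractions = census$fractions),
    sj_context = context$counts,
    exon_count_as = list(as_genes = exon_as$as_genes,
                         non_as_genes = exon_as$non_as_genes),
    apa = apa,
    library_summary = merged$summary,
    locus_warnings = loci$warnings)

  results <- list(manifest = manifest, retained = retained, loci = loci,
                  fusions = fusions, events = events, census = census,
                  context = context, sites = sites, merged = merged)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    write_gff3(iso_out, out("isoforms.gff3"))
    utils::write.table(partition, out("partition.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(fusions, out("fusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(events, out("as_events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(census$per_intron, out("census.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(context$per_junction, out("sj_context.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sites_flat <- sites[, setdiff(names(sites), "member_positions")]
    utils::write.table(sites_flat, out("polya_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gff3(merged$library, out("merged_library.gff3"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$outputs <- vapply(
      c("isoforms.gff3", "partition.tsv", "fusions.tsv", "as_events.tsv",
        "census.tsv", "sj_context.tsv", "polya_sites.tsv",
        "merged_library.gff3", "manifest.json"), out, character(1))
    results$manifest <- manifest
  }
  results
}
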