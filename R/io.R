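#' Read a FASTA genome
#'
#' Sequence ids are taken from the header up to the first whitespace and
#' sequences are upper-cased, so masked (lowercase) genomes behave like their
#' unmasked counterparts.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per record, order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (any(nchar(out) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(names(out)[nchar(out) == 0L], collapse = ", "))
  }
  out
}

#' Write a FASTA genome
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Expects the conventional gene/mRNA/exon hierarchy with optional CDS
#' features. GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention. Exons without a parent mRNA, or
#' mRNAs without a parent gene, are parse errors.
#'
#' @param path GFF3 file.
#' @return A transcript table (see [transcripts()]) with `gene_id` filled and
#'   CDS spans where annotated.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exon <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(mrna) == 0L) stop("no mRNA/transcript features in ", path)
  if (any(is.na(mrna$Parent))) {
    stop("mRNA with no parent gene: ",
         paste(mrna$ID[is.na(mrna$Parent)], collapse = ", "))
  }
  if (any(is.na(exon$Parent))) stop("exon with no parent mRNA in ", path)
  orphan <- setdiff(unique(exon$Parent), mrna$ID)
  if (length(orphan) > 0L) {
    stop("exon parent(s) not an mRNA: ", paste(orphan, collapse = ", "))
  }

  ord <- order(match(exon$Parent, mrna$ID), exon$start)
  exon <- exon[ord, , drop = FALSE]
  starts <- split(as.integer(exon$start - 1L), exon$Parent)
  ends <- split(as.integer(exon$end), exon$Parent)
  no_exon <- setdiff(mrna$ID, names(starts))
  if (length(no_exon) > 0L) {
    stop("mRNA with no exon children: ", paste(no_exon, collapse = ", "))
  }

  cds_start <- rep(NA_integer_, nrow(mrna))
  cds_end <- rep(NA_integer_, nrow(mrna))
  if (nrow(cds) > 0L) {
    cs <- vapply(split(as.integer(cds$start - 1L), cds$Parent), min, integer(1))
    ce <- vapply(split(as.integer(cds$end), cds$Parent), max, integer(1))
    idx <- match(names(cs), mrna$ID)
    keep <- !is.na(idx)
    cds_start[idx[keep]] <- cs[keep]
    cds_end[idx[keep]] <- ce[keep]
  }

  src <- if ("source_tag" %in% names(mrna)) mrna$source_tag else "annotation"
  transcripts(
    tx_id = mrna$ID,
    gene_id = mrna$Parent,
    chrom = as.character(mrna$seqnames),
    strand = as.character(mrna$strand),
    exon_starts = lapply(unname(starts[mrna$ID]), unname),
    exon_ends = lapply(unname(ends[mrna$ID]), unname),
    source = "annotation",
    cds_start = cds_start,
    cds_end = cds_end
  )
}

#' Write a transcript table as GFF3
#'
#' Emits gene, mRNA, exon and (when present) CDS features with ID/Parent
#' attributes, converting internal 0-based half-open coordinates back to
#' GFF3's 1-based inclusive convention. Optional `label`, `locus_id` and
#' `provenance` columns of the table are carried as mRNA attributes, so the
#' file round-trips through [read_gff3()] with coordinates intact.
#'
#' @param tx a transcript table; rows with `NA` gene id are written under a
#'   gene feature named after the transcript.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(tx, path, source = "isoforge") {
  validate_transcripts(tx)
  gene_id <- if ("gene_id" %in% names(tx)) tx$gene_id else rep(NA, nrow(tx))
  gene_id <- ifelse(is.na(gene_id), paste0(tx$tx_id, ".gene"), gene_id)
  span <- transcript_span(tx)

  lines <- character(0)
  push <- function(...) lines[[length(lines) + 1L]] <<- paste(..., sep = "\t")
  push("##gff-version 3")
  lines <- lines[-1L]
  header <- "##gff-version 3"

  for (g in unique(gene_id)) {
    rows <- which(gene_id == g)
    g_start <- min(span$span_start[rows])
    g_end <- max(span$span_end[rows])
    chrom <- tx$chrom[rows[1L]]
    strand <- tx$strand[rows[1L]]
    push(chrom, source, "gene", g_start + 1L, g_end, ".", strand, ".",
         paste0("ID=", g))
    for (i in rows) {
      attrs <- paste0("ID=", tx$tx_id[i], ";Parent=", g)
      for (extra in c("label", "locus_id", "provenance")) {
        if (extra %in% names(tx) && !is.na(tx[[extra]][i])) {
          attrs <- paste0(attrs, ";", extra, "=", tx[[extra]][i])
        }
      }
      push(chrom, source, "mRNA", span$span_start[i] + 1L, span$span_end[i],
           ".", strand, ".", attrs)
      s <- tx$exon_starts[[i]]
      e <- tx$exon_ends[[i]]
      for (k in seq_along(s)) {
        push(chrom, source, "exon", s[k] + 1L, e[k], ".", strand, ".",
             paste0("ID=", tx$tx_id[i], ".exon", k, ";Parent=", tx$tx_id[i]))
      }
      if ("cds_start" %in% names(tx) && !is.na(tx$cds_start[i])) {
        cs <- tx$cds_start[i]
        ce <- tx$cds_end[i]
        keep <- which(e > cs & s < ce)
        for (k in keep) {
          push(chrom, source, "CDS", max(s[k], cs) + 1L, min(e[k], ce), ".",
               strand, "0",
               paste0("ID=", tx$tx_id[i], ".cds", k, ";Parent=", tx$tx_id[i]))
        }
      }
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write FLNC alignments as BED12 plus a sidecar identity table
#'
#' Each alignment segment becomes one BED12 record named
#' `read_id|segment_index`; per-read global identity and per-segment local
#' identity and read coordinates go to a tab-separated sidecar, since BED
#' has no slot for them.
#'
#' @param reads read table (one row per segment; see [simulate_flnc()]).
#' @param bed_path,tsv_path output files.
#' @return `bed_path`, invisibly.
#' @export
write_flnc <- function(reads, bed_path, tsv_path) {
  grl <- GenomicRanges::GRangesList(lapply(seq_len(nrow(reads)), function(i) {
    GenomicRanges::GRanges(
      reads$chrom[i],
      IRanges::IRanges(reads$exon_starts[[i]] + 1L, reads$exon_ends[[i]]),
      strand = reads$strand[i]
    )
  }))
  names(grl) <- paste(reads$read_id, reads$seg_idx, sep = "|")
  rtracklayer::export(grl, bed_path, format = "bed")
  side <- reads[, c("read_id", "seg_idx", "global_pid", "local_pid",
                    "read_start", "read_end")]
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed_path)
}

#' Read FLNC alignments from BED12 plus the sidecar identity table
#'
#' @param bed_path BED12 of alignment segments, names `read_id|segment_index`.
#' @param tsv_path sidecar with `read_id`, `seg_idx`, `global_pid`,
#'   `local_pid`, `read_start`, `read_end`.
#' @return Read table, one row per segment.
#' @export
read_flnc <- function(bed_path, tsv_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  blk <- rtracklayer::blocks(gr)
  ids <- strsplit(gr$name, "|", fixed = TRUE)
  side <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  out <- tibble::tibble(
    read_id = vapply(ids, `[`, character(1), 1L),
    seg_idx = as.integer(vapply(ids, `[`, character(1), 2L)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_starts = lapply(unname(blk),
                         function(b) as.integer(GenomicRanges::start(b) - 1L)),
    exon_ends = lapply(unname(blk),
                       function(b) as.integer(GenomicRanges::end(b)))
  )
  out <- dplyr::left_join(out, side, by = c("read_id", "seg_idx"))
  out[order(out$read_id, out$seg_idx), ]
}

#' Write a junction-support set as BED
#'
#' Introns are written as 0-based half-open BED intervals with the supporting
#' short-read count in the score column.
#'
#' @param junctions tibble with `chrom`, `strand`, `start`, `end`, `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  df <- data.frame(junctions$chrom, junctions$start, junctions$end,
                   ".", junctions$count, junctions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a junction-support BED
#'
#' @param path BED file written by [write_junctions()] (or any BED6 whose
#'   score column holds supporting read counts).
#' @return Tibble with `chrom`, `strand`, `start`, `end`, `count`.
#' @export
read_junctions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  tibble::tibble(chrom = as.character(df[[1L]]), strand = as.character(df[[6L]]),
                 start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                 count = as.integer(df[[5L]]))
}
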