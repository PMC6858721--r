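small_cfg <- function(seed = 1L, n_genes = 10L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 120000L,
             n_genes = n_genes, ...)
}

test_that("the seed fully determines genome, reads and ground truth", {
  cfg <- small_cfg(seed = 5L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)
  fa <- simulate_flnc(cfg, a$genome, a$annotation)
  fb <- simulate_flnc(cfg, b$genome, b$annotation)
  expect_identical(fa, fb)
  ja <- simulate_junction_support(cfg, fa$reads, a$annotation)
  jb <- simulate_junction_support(cfg, fb$reads, b$annotation)
  expect_identical(ja, jb)
  # and written files are byte-identical
  d1 <- withr::local_tempfile(fileext = ".fa")
  d2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$genome, d1)
  write_fasta(b$genome, d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("a gene-free configuration yields an empty annotation", {
  sim <- simulate_genome(small_cfg(n_genes = 0L))
  expect_identical(nrow(sim$annotation), 0L)
  expect_length(sim$genome, 2L)
})

test_that("infeasible gene load raises a capacity error", {
  cfg <- sim_config(seed = 1L, n_chroms = 1L, chrom_length = 20000L,
                    n_genes = 30L)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("all introns are canonical when the config says so", {
  cfg <- small_cfg(splice_dinucleotides = c("GT-AG" = 1.0))
  sim <- simulate_genome(cfg)
  cen <- splice_site_census(sim$annotation, sim$genome)
  expect_identical(unname(cen$counts[c("GC-AG", "AT-AC", "other")]),
                   c(0L, 0L, 0L))
  expect_gt(cen$counts[["GT-AG"]], 0L)
})

test_that("probability switches drive the ground-truth labels", {
  cfg0 <- small_cfg(p_novel_isoform = 0, p_novel_locus = 0, p_fusion_read = 0)
  sim <- simulate_genome(cfg0)
  fl <- simulate_flnc(cfg0, sim$genome, sim$annotation)
  expect_identical(unique(fl$truth$reads$label), "known_known")

  cfg1 <- small_cfg(p_fusion_read = 1)
  sim1 <- simulate_genome(cfg1)
  fl1 <- simulate_flnc(cfg1, sim1$genome, sim1$annotation)
  expect_identical(unique(fl1$truth$reads$label), "fusion")
  expect_identical(nrow(fl1$truth$fusions),
                   length(unique(fl1$reads$read_id)))
})

test_that("zero scatter puts every read 3' end exactly on its true site", {
  cfg <- small_cfg(polya_scatter_sd = 0, p_fusion_read = 0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  e3 <- ifelse(fl$reads$strand == "+",
               vapply(fl$reads$exon_ends, function(x) x[length(x)],
                      integer(1)) - 1L,
               vapply(fl$reads$exon_starts, function(x) x[1L], integer(1)))
  expect_identical(e3, fl$truth$reads$true_polya)
})

test_that("every simulated segment stays within genome bounds", {
  cfg <- small_cfg(seed = 9L, p_fusion_read = 0.1)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  for (i in seq_len(nrow(fl$reads))) {
    len <- nchar(sim$genome[[fl$reads$chrom[i]]])
    expect_gte(fl$reads$exon_starts[[i]][1L], 0L)
    expect_lte(fl$reads$exon_ends[[i]][length(fl$reads$exon_ends[[i]])], len)
  }
})

test_that("fusion reads join genes satisfying the distance precondition", {
  cfg <- small_cfg(seed = 3L, p_fusion_read = 0.3)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  expect_gt(nrow(fl$truth$fusions), 0L)
  span <- transcript_span(sim$annotation)
  for (k in seq_len(nrow(fl$truth$fusions))) {
    a <- match(fl$truth$fusions$gene_a[k], sim$annotation$gene_id)
    b <- match(fl$truth$fusions$gene_b[k], sim$annotation$gene_id)
    if (sim$annotation$chrom[a] == sim$annotation$chrom[b]) {
      gap <- max(span$span_start[b] - span$span_end[a],
                 span$span_start[a] - span$span_end[b])
      expect_gt(gap, 50000L)
    } else {
      succeed()
    }
  }
})

test_that("junction support respects its coverage probability", {
  cfg <- small_cfg(junction_support_coverage = 1.0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  js1 <- simulate_junction_support(cfg, fl$reads, sim$annotation)
  truth_introns <- dplyr::distinct(dplyr::bind_rows(
    introns_of(sim$annotation),
    introns_of(tibble::tibble(tx_id = paste0(fl$reads$read_id, "|",
                                             fl$reads$seg_idx),
                              chrom = fl$reads$chrom,
                              strand = fl$reads$strand,
                              exon_starts = fl$reads$exon_starts,
                              exon_ends = fl$reads$exon_ends))
  )[, c("chrom", "strand", "start", "end")])
  expect_identical(nrow(js1), nrow(truth_introns))
  expect_true(all(js1$count >= 2L))

  cfg0 <- small_cfg(junction_support_coverage = 0)
  js0 <- simulate_junction_support(cfg0, fl$reads, sim$annotation)
  expect_identical(nrow(js0), 0L)

  # half coverage stays inside the binomial 99% interval
  cfg5 <- sim_config(seed = 2L, n_chroms = 2L, chrom_length = 500000L,
                     n_genes = 40L, exons_per_gene = c(6L, 10L),
                     junction_support_coverage = 0.5)
  sim5 <- simulate_genome(cfg5)
  fl5 <- simulate_flnc(cfg5, sim5$genome, sim5$annotation)
  js5 <- simulate_junction_support(cfg5, fl5$reads, sim5$annotation)
  n_true <- nrow(dplyr::distinct(dplyr::bind_rows(
    introns_of(sim5$annotation),
    introns_of(tibble::tibble(tx_id = paste0(fl5$reads$read_id, "|",
                                             fl5$reads$seg_idx),
                              chrom = fl5$reads$chrom,
                              strand = fl5$reads$strand,
                              exon_starts = fl5$reads$exon_starts,
                              exon_ends = fl5$reads$exon_ends))
  )[, c("chrom", "strand", "start", "end")]))
  bound <- stats::qbinom(c(0.005, 0.995), n_true, 0.5)
  expect_gte(nrow(js5), bound[1L])
  expect_lte(nrow(js5), bound[2L])
})

test_that("expressing nothing is an explicit error", {
  cfg <- small_cfg(n_genes = 0L, p_novel_locus = 0)
  sim <- simulate_genome(cfg)
  expect_error(simulate_flnc(cfg, sim$genome, sim$annotation),
               "nothing to express")
})
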