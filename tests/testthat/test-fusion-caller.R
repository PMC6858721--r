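fusion_world <- function() {
  # gA on chr1; gB on chr2; gC/gD on chr3, 60 kb apart; gE/gF on chr4, 40 kb
  dplyr::bind_rows(
    mk_tx("gA.t1", c(1000L, 1400L), c(1200L, 1600L), gene = "gA"),
    mk_tx("gB.t1", c(2000L, 2400L), c(2200L, 2600L), chrom = "chr2",
          gene = "gB"),
    mk_tx("gC.t1", c(1000L, 1400L), c(1200L, 1600L), chrom = "chr3",
          gene = "gC"),
    mk_tx("gD.t1", c(62000L, 62400L), c(62200L, 62600L), chrom = "chr3",
          gene = "gD"),
    mk_tx("gE.t1", c(1000L, 1400L), c(1200L, 1600L), chrom = "chr4",
          gene = "gE"),
    mk_tx("gF.t1", c(42000L, 42400L), c(42200L, 42600L), chrom = "chr4",
          gene = "gF"))
}

support_for <- function(ann, genes, count = 3L) {
  itr <- introns_of(ann[ann$gene_id %in% genes, ])
  tibble::tibble(chrom = itr$chrom, strand = itr$strand, start = itr$start,
                 end = itr$end, count = count)
}

fusion_read <- function(id, ann, gene1, gene2, gpid = 95, lpid1 = 95,
                        lpid2 = 95, break_overlap = 0L) {
  i <- match(paste0(gene1, ".t1"), ann$tx_id)
  j <- match(paste0(gene2, ".t1"), ann$tx_id)
  l1 <- sum(ann$exon_ends[[i]] - ann$exon_starts[[i]])
  l2 <- sum(ann$exon_ends[[j]] - ann$exon_starts[[j]])
  dplyr::bind_rows(
    mk_read(id, ann$exon_starts[[i]], ann$exon_ends[[i]],
            chrom = ann$chrom[i], gpid = gpid, lpid = lpid1, seg = 1L,
            read_start = 0L, read_end = l1),
    mk_read(id, ann$exon_starts[[j]], ann$exon_ends[[j]],
            chrom = ann$chrom[j], gpid = gpid, lpid = lpid2, seg = 2L,
            read_start = l1 - break_overlap,
            read_end = l1 - break_overlap + l2))
}

test_that("a clean two-segment chimera passes all four rules", {
  ann <- fusion_world()
  js <- support_for(ann, c("gA", "gB"))
  r <- fusion_read("f1", ann, "gA", "gB")
  calls <- call_fusions(r, ann, js)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$fusion_type, "inter_chromosome")
  expect_identical(calls$genes, "gA,gB")
})

test_that("the genomic distance rule separates 40 kb from 60 kb", {
  ann <- fusion_world()
  far <- fusion_read("f1", ann, "gC", "gD")
  near <- fusion_read("f2", ann, "gE", "gF")
  js <- support_for(ann, c("gC", "gD", "gE", "gF"))
  calls <- call_fusions(dplyr::bind_rows(far, near), ann, js)
  expect_identical(calls$read_id, "f1")
  expect_identical(calls$fusion_type, "intra_chromosome")
})

test_that("identity and support thresholds veto calls", {
  ann <- fusion_world()
  js <- support_for(ann, c("gA", "gB"))
  low_local <- fusion_read("f1", ann, "gA", "gB", lpid2 = 89)
  expect_identical(nrow(call_fusions(low_local, ann, js)), 0L)
  low_global <- fusion_read("f2", ann, "gA", "gB", gpid = 5)
  expect_identical(nrow(call_fusions(low_global, ann, js)), 0L)
  ok <- fusion_read("f3", ann, "gA", "gB")
  js1 <- support_for(ann, c("gA", "gB"), count = 1L)
  expect_identical(nrow(call_fusions(ok, ann, js1)), 0L)
  no_js <- call_fusions(ok, ann, NULL)
  expect_identical(nrow(no_js), 0L)
})

test_that("a blunt breakpoint (segments overlapping on the read) vetoes rule 1", {
  ann <- fusion_world()
  js <- support_for(ann, c("gA", "gB"))
  blunt <- fusion_read("f1", ann, "gA", "gB", break_overlap = 15L)
  expect_identical(nrow(call_fusions(blunt, ann, js)), 0L)
  grazing <- fusion_read("f2", ann, "gA", "gB", break_overlap = 9L)
  expect_identical(nrow(call_fusions(grazing, ann, js)), 1L)
})

test_that("single-segment reads never produce fusion calls", {
  ann <- fusion_world()
  r <- mk_read("r1", c(1000L, 1400L), c(1200L, 1600L))
  expect_identical(nrow(call_fusions(r, ann, support_for(ann, "gA"))), 0L)
})

test_that("fusion counts always reconcile", {
  ann <- fusion_world()
  js <- support_for(ann, unique(ann$gene_id))
  r <- dplyr::bind_rows(
    fusion_read("f1", ann, "gA", "gB"),
    fusion_read("f2", ann, "gB", "gC"),
    fusion_read("f3", ann, "gC", "gD"))
  calls <- call_fusions(r, ann, js)
  cnt <- fusion_type_counts(calls)
  expect_identical(cnt$total, cnt$inter + cnt$intra)
  expect_identical(cnt$inter, 2L)
  expect_identical(cnt$intra, 1L)
})

test_that("tightening each threshold never enlarges the call set", {
  cfg <- sim_config(seed = 17L, n_chroms = 3L, chrom_length = 200000L,
                    n_genes = 18L, p_fusion_read = 0.2,
                    junction_support_coverage = 1.0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  js <- simulate_junction_support(cfg, fl$reads, sim$annotation)
  base <- call_fusions(fl$reads, sim$annotation, js)
  expect_gt(nrow(base), 0L)
  tighter <- list(
    call_fusions(fl$reads, sim$annotation, js, max_locus_overlap = 1L),
    call_fusions(fl$reads, sim$annotation, js, min_distance = 200000L),
    call_fusions(fl$reads, sim$annotation, js, min_global_pid = 99.9),
    call_fusions(fl$reads, sim$annotation, js, min_local_pid = 99.9),
    call_fusions(fl$reads, sim$annotation, js, min_support_reads = 10000L))
  for (t in tighter) expect_true(all(t$read_id %in% base$read_id))
})

test_that("simulated fusions are recovered perfectly under full support", {
  cfg <- sim_config(seed = 23L, n_chroms = 3L, chrom_length = 200000L,
                    n_genes = 18L, p_fusion_read = 0.15,
                    junction_support_coverage = 1.0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(cfg, sim$genome, sim$annotation)
  js <- simulate_junction_support(cfg, fl$reads, sim$annotation)
  calls <- call_fusions(fl$reads, sim$annotation, js)
  expect_setequal(calls$read_id, fl$truth$fusions$read_id)
  got_type <- calls$fusion_type[match(fl$truth$fusions$read_id,
                                      calls$read_id)]
  expect_identical(got_type, fl$truth$fusions$fusion_type)
  # and a fusion-free world yields no calls at all
  cfg0 <- sim_config(seed = 23L, n_chroms = 3L, chrom_length = 200000L,
                     n_genes = 18L, p_fusion_read = 0,
                     junction_support_coverage = 1.0)
  sim0 <- simulate_genome(cfg0)
  fl0 <- simulate_flnc(cfg0, sim0$genome, sim0$annotation)
  js0 <- simulate_junction_support(cfg0, fl0$reads, sim0$annotation)
  expect_identical(nrow(call_fusions(fl0$reads, sim0$annotation, js0)), 0L)
})
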