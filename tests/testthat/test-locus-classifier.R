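toy_annotation <- function() {
  dplyr::bind_rows(
    mk_tx("gA.t1", c(0L, 200L, 400L), c(100L, 300L, 500L), gene = "gA"),
    mk_tx("gB.t1", c(2000L, 2200L), c(2100L, 2300L), gene = "gB",
          strand = "-"),
    mk_tx("gC.t1", 5000L, 5400L, gene = "gC"))
}

test_that("isoforms join the locus of the gene they reproduce", {
  ann <- toy_annotation()
  iso <- mk_tx("i1", c(0L, 200L, 400L), c(100L, 300L, 500L),
               source = "flnc")
  loci <- build_loci(iso, ann)
  asn <- loci$assignments
  expect_identical(asn$locus_id[asn$tx_id == "i1"],
                   asn$locus_id[asn$tx_id == "gA.t1"])
  expect_identical(
    loci$loci$known_gene_id[loci$loci$locus_id ==
                              asn$locus_id[asn$tx_id == "i1"]], "gA")
})

test_that("non-overlapping and opposite-strand isoforms found novel loci", {
  ann <- toy_annotation()
  off <- mk_tx("i1", c(9000L, 9200L), c(9100L, 9300L), source = "flnc")
  anti <- mk_tx("i2", c(0L, 200L, 400L), c(100L, 300L, 500L), strand = "-",
                source = "flnc")
  loci <- classify_isoforms(build_loci(dplyr::bind_rows(off, anti), ann), ann)
  lab <- loci$assignments
  expect_identical(lab$label[lab$tx_id == "i1"], "novel")
  expect_identical(lab$label[lab$tx_id == "i2"], "novel")
})

test_that("mutually overlapping novel isoforms share one novel locus", {
  ann <- toy_annotation()
  a <- mk_tx("i1", 9000L, 9200L, source = "flnc")
  b <- mk_tx("i2", 9100L, 9300L, source = "flnc")  # 50% overlap with a
  loci <- build_loci(dplyr::bind_rows(a, b), ann)
  asn <- loci$assignments
  expect_identical(asn$locus_id[asn$tx_id == "i1"],
                   asn$locus_id[asn$tx_id == "i2"])
  expect_identical(
    sum(loci$loci$n_isoforms == 2L & is.na(loci$loci$known_gene_id)), 1L)
})

test_that("below-threshold overlap separates loci", {
  ann <- empty_annotation()
  a <- mk_tx("i1", 0L, 100L, source = "flnc")
  b <- mk_tx("i2", 85L, 185L, source = "flnc")  # 15% < 20%
  c_ <- mk_tx("i3", 70L, 170L, source = "flnc") # 30% > 20%
  expect_identical(nrow(build_loci(dplyr::bind_rows(a, b), ann)$loci), 2L)
  expect_identical(nrow(build_loci(dplyr::bind_rows(a, c_), ann)$loci), 1L)
})

test_that("novelty labels follow the splice-structure rules", {
  ann <- toy_annotation()
  exact <- mk_tx("i1", c(0L, 200L, 400L), c(100L, 300L, 500L),
                 source = "flnc")
  skip <- mk_tx("i2", c(0L, 400L), c(100L, 500L), source = "flnc")
  mono_in_multi <- mk_tx("i3", 0L, 500L, source = "flnc")
  mono_in_mono <- mk_tx("i4", 5050L, 5350L, source = "flnc")
  multi_in_mono <- mk_tx("i5", c(5000L, 5300L), c(5100L, 5400L),
                         source = "flnc")
  iso <- dplyr::bind_rows(exact, skip, mono_in_multi, mono_in_mono,
                          multi_in_mono)
  lab <- classify_isoforms(build_loci(iso, ann), ann)$assignments
  get <- function(id) lab$label[lab$tx_id == id]
  expect_identical(get("i1"), "known_known")
  expect_identical(get("i2"), "known_novel")   # skipped exon
  expect_identical(get("i3"), "known_novel")   # single-exon in multi-exon gene
  expect_identical(get("i4"), "known_known")   # single-exon in single-exon gene
  expect_identical(get("i5"), "known_novel")   # spliced in single-exon gene
  # annotation transcripts are never labelled
  expect_true(all(is.na(lab$label[lab$is_annotation])))
})

test_that("novelty modes agree on shifted ends but differ on intron retention", {
  ann <- toy_annotation()
  ir <- mk_tx("i1", c(0L, 400L), c(300L, 500L), source = "flnc")
  ae <- mk_tx("i2", c(0L, 200L, 400L), c(80L, 300L, 500L), source = "flnc")
  iso <- dplyr::bind_rows(ir, ae)
  for (mode in c("chain", "intron", "boundary")) {
    lab <- classify_isoforms(build_loci(iso, ann), ann,
                             new_site_mode = mode)$assignments
    expect_identical(lab$label[lab$tx_id == "i2"], "known_novel")
  }
  # only chain comparison catches intron retention: the retained variant
  # carries no unannotated intron or boundary
  for (mode in c("chain", "intron", "boundary")) {
    lab <- classify_isoforms(build_loci(iso, ann), ann,
                             new_site_mode = mode)$assignments
    expect_identical(lab$label[lab$tx_id == "i1"],
                     if (mode == "chain") "known_novel" else "known_known")
  }
})

test_that("a toy world with one skipped-exon isoform partitions as expected", {
  ann <- toy_annotation()
  iso <- dplyr::bind_rows(
    mk_tx("i1", c(0L, 200L, 400L), c(100L, 300L, 500L), source = "flnc"),
    mk_tx("i2", c(0L, 400L), c(100L, 500L), source = "flnc"),
    mk_tx("i3", c(2000L, 2200L), c(2100L, 2300L), strand = "-",
          source = "flnc"))
  loci <- classify_isoforms(build_loci(iso, ann), ann)
  tab <- partition_counts(loci$assignments)
  expect_identical(tab$n_isoforms[tab$category == "known_novel"], 1L)
  expect_identical(tab$n_loci[tab$category == "known_novel"], 1L)
  expect_identical(tab$n_isoforms[tab$category == "total"], 3L)
  # disjoint mode: the skip gene counts once, under its most novel member
  expect_identical(tab$n_loci[tab$category == "total"], 2L)
  over <- partition_counts(loci$assignments, mode = "overlapping")
  expect_identical(over$n_loci[over$category == "known_known"], 2L)
})

test_that("locus construction matches the brute-force union-find oracle", {
  set.seed(77)
  for (i in 1:12) {
    tx <- rand_tx_set(25L, space = 3000L)
    got <- build_loci(tx, empty_annotation())
    got_part <- canonical_partition(split(got$assignments$tx_id,
                                          got$assignments$locus_id))
    want_part <- canonical_partition(oracle_locus_partition(tx))
    expect_identical(got_part, want_part)
  }
})

test_that("raising the overlap threshold never merges loci", {
  set.seed(13)
  for (i in 1:6) {
    tx <- rand_tx_set(30L, space = 4000L)
    n_loose <- nrow(build_loci(tx, empty_annotation(), min_frac = 0.1)$loci)
    n_mid <- nrow(build_loci(tx, empty_annotation(), min_frac = 0.3)$loci)
    n_tight <- nrow(build_loci(tx, empty_annotation(), min_frac = 0.6)$loci)
    expect_lte(n_loose, n_mid)
    expect_lte(n_mid, n_tight)
  }
})

test_that("components merging several annotated genes are flagged", {
  ann <- dplyr::bind_rows(
    mk_tx("g1.t1", 0L, 500L, gene = "g1"),
    mk_tx("g2.t1", 1000L, 1500L, gene = "g2"))
  bridge <- mk_tx("i1", c(0L, 1000L), c(500L, 1500L), source = "flnc")
  loci <- build_loci(bridge, ann)
  expect_match(loci$warnings, "merges annotated genes")
  expect_identical(nrow(loci$loci), 1L)
})
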