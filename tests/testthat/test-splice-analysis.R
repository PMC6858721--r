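# A three-exon base isoform and edits of it, all on chr1 +.
base_iso <- function(id = "base") {
  mk_tx(id, c(0L, 200L, 400L), c(100L, 300L, 500L), source = "flnc")
}

test_that("canonical skipping, retention and alternative ends are typed", {
  b <- base_iso()
  skip <- mk_tx("skip", c(0L, 400L), c(100L, 500L), source = "flnc")
  ev <- detect_as_events(dplyr::bind_rows(b, skip), fuzz = 0L)
  expect_identical(ev$type, "SKIP")
  expect_identical(ev$start, 200L)
  expect_identical(ev$end, 300L)

  ir <- mk_tx("ir", c(0L, 400L), c(300L, 500L), source = "flnc")
  ev <- detect_as_events(dplyr::bind_rows(b, ir), fuzz = 0L)
  expect_identical(ev$type, "IR")
  expect_identical(ev$start, 100L)
  expect_identical(ev$end, 200L)

  ae <- mk_tx("ae", c(0L, 200L, 400L), c(70L, 300L, 500L), source = "flnc")
  ev <- detect_as_events(dplyr::bind_rows(b, ae), fuzz = 0L)
  expect_identical(ev$type, "AE")
  expect_identical(ev$start, 70L)
  expect_identical(ev$end, 100L)
})

test_that("multi-exon skipping and multi-intron retention get M types", {
  four <- mk_tx("four", c(0L, 200L, 400L, 600L), c(100L, 300L, 500L, 700L),
                source = "flnc")
  mskip <- mk_tx("mskip", c(0L, 600L), c(100L, 700L), source = "flnc")
  ev <- detect_as_events(dplyr::bind_rows(four, mskip), fuzz = 0L)
  expect_identical(ev$type, "MSKIP")
  expect_identical(c(ev$start, ev$end), c(200L, 500L))

  mir <- mk_tx("mir", c(0L, 600L), c(500L, 700L), source = "flnc")
  ev <- detect_as_events(dplyr::bind_rows(four, mir), fuzz = 0L)
  expect_identical(ev$type, "MIR")
  expect_identical(c(ev$start, ev$end), c(100L, 400L))
})

test_that("near-matching boundaries fall into the X categories by fuzz", {
  b <- base_iso()
  xskip <- mk_tx("xskip", c(0L, 400L), c(95L, 500L), source = "flnc")
  at10 <- detect_as_events(dplyr::bind_rows(b, xskip), fuzz = 10L)
  expect_identical(at10$type, "XSKIP")
  at0 <- detect_as_events(dplyr::bind_rows(b, xskip), fuzz = 0L)
  expect_false("XSKIP" %in% at0$type)
  at4 <- detect_as_events(dplyr::bind_rows(b, xskip), fuzz = 4L)
  expect_false("XSKIP" %in% at4$type)
})

test_that("events are symmetric in isoform order and deduplicated", {
  b <- base_iso()
  skip <- mk_tx("skip", c(0L, 400L), c(100L, 500L), source = "flnc")
  fwd <- detect_as_events(dplyr::bind_rows(b, skip), fuzz = 0L)
  rev <- detect_as_events(dplyr::bind_rows(skip, b), fuzz = 0L)
  expect_identical(fwd[, c("type", "start", "end")],
                   rev[, c("type", "start", "end")])
  # a third identical-structure isoform adds no duplicate events
  skip2 <- mk_tx("skip2", c(0L, 400L), c(100L, 500L), source = "flnc")
  tri <- detect_as_events(dplyr::bind_rows(b, skip, skip2), fuzz = 0L)
  expect_identical(nrow(tri), 1L)
})

test_that("growing fuzz never loses events", {
  set.seed(19)
  for (i in 1:8) {
    rows <- lapply(1:4, function(k) {
      ch <- rand_chain(3000L)
      mk_tx(paste0("t", k), ch$starts, ch$ends, source = "flnc")
    })
    tx <- dplyr::bind_rows(rows)
    counts <- vapply(c(0L, 5L, 10L, 25L, 60L), function(fz) {
      nrow(detect_as_events(tx, fuzz = fz))
    }, integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("AS type fractions sum to one and count genes separately", {
  ev <- tibble::tibble(
    locus_id = c("L1", "L1", "L2", "L3"),
    type = c("SKIP", "SKIP", "IR", "AE"),
    chrom = "chr1", strand = "+",
    start = c(1L, 50L, 100L, 150L), end = c(10L, 60L, 110L, 160L),
    iso_a = "a", iso_b = "b")
  s <- as_type_percentages(ev)
  expect_equal(sum(s$frac_events), 1)
  expect_equal(s$frac_events[s$type == "SKIP"], 0.5)
  expect_equal(s$frac_events[s$type == "IR"], 0.25)
  expect_identical(s$n_genes[s$type == "SKIP"], 1L)
  expect_identical(nrow(as_type_percentages(ev[0, ])), 0L)
})

test_that("splice-site census reads dinucleotides strand-aware", {
  #            0123456789012345678901234
  genome <- c(chr1 = "AAAAAGTCCCCCCCCCCCAGAAAAA",
              chr2 = "AAAAACTCCCCCCCCCCCACAAAAA")
  plus <- mk_tx("p", c(0L, 20L), c(5L, 25L))           # intron GT..AG
  minus <- mk_tx("m", c(0L, 20L), c(5L, 25L), chrom = "chr2", strand = "-")
  cen <- splice_site_census(dplyr::bind_rows(plus, minus), genome)
  # minus-strand genomic CT..AC reverse-complements to GT..AG
  expect_identical(cen$counts[["GT-AG"]], 2L)
  expect_equal(sum(cen$fractions), 1)
  # order invariance
  cen2 <- splice_site_census(dplyr::bind_rows(minus, plus), genome)
  expect_identical(cen$counts, cen2$counts)
  # out-of-bounds introns name the transcript
  bad <- mk_tx("bad", c(0L, 40L), c(5L, 45L))
  expect_error(splice_site_census(bad, genome), "bad")
})

test_that("census matches the simulator's intron-class construction exactly", {
  cfg <- sim_config(seed = 41L, n_chroms = 2L, chrom_length = 200000L,
                    n_genes = 16L,
                    splice_dinucleotides = c("GT-AG" = 0.9, "GC-AG" = 0.1))
  sim <- simulate_genome(cfg)
  cen <- splice_site_census(sim$annotation, sim$genome)
  built <- table(attr(sim$annotation, "intron_classes")$class)
  expect_identical(cen$counts[["GT-AG"]], unname(built[["GT-AG"]]))
  expect_identical(cen$counts[["GC-AG"]], unname(built[["GC-AG"]]))
  expect_identical(cen$counts[["other"]], 0L)
})

test_that("junction context follows CDS > UTR > intron > intergenic", {
  # one + gene: exons (0,100),(200,300),(400,500); CDS 50..450
  ann <- mk_tx("m1", c(0L, 200L, 400L), c(100L, 300L, 500L), gene = "g1",
               cds_start = 50L, cds_end = 450L)
  # one - gene further away: exons (1000,1100),(1200,1300); CDS 1050..1250
  ann2 <- mk_tx("m2", c(1000L, 1200L), c(1100L, 1300L), gene = "g2",
                strand = "-", cds_start = 1050L, cds_end = 1250L)
  ann <- dplyr::bind_rows(ann, ann2)
  j <- tibble::tibble(
    chrom = "chr1", strand = c("+", "+", "+", "-", "+"),
    start = c(100L,   # donor at 100: inside CDS span
              20L,    # donor at 20: exonic, before CDS on + -> 5'UTR
              10000L, # intergenic
              1000L,  # - strand junction, donor = end-1 = 1039
              460L),  # exonic after CDS on + -> 3'UTR
    end = c(200L, 60L, 10100L, 1040L, 490L))
  ctx <- sj_context(j, ann)
  expect_identical(unname(ctx$per_junction$region),
                   c("CDS", "5'UTR", "intergenic", "3'UTR", "3'UTR"))
  expect_identical(sum(ctx$counts), nrow(j))
})

test_that("genes with AS events have the exon counts the simulator gave them", {
  ann <- dplyr::bind_rows(
    mk_tx("g1.t1", c(0L, 200L, 400L, 600L), c(100L, 300L, 500L, 700L),
          gene = "g1"),
    mk_tx("g2.t1", c(5000L, 5200L), c(5100L, 5300L), gene = "g2"))
  iso <- dplyr::bind_rows(
    mk_tx("i1", c(0L, 200L, 400L, 600L), c(100L, 300L, 500L, 700L),
          source = "flnc"),
    mk_tx("i2", c(0L, 400L, 600L), c(100L, 500L, 700L), source = "flnc"),
    mk_tx("i3", c(5000L, 5200L), c(5100L, 5300L), source = "flnc"))
  loci <- classify_isoforms(build_loci(iso, ann), ann)
  ev <- detect_locus_as_events(loci, fuzz = 0L)
  xc <- exon_count_by_as_status(loci, ev)
  expect_identical(xc$as_genes, 4L)
  expect_identical(xc$non_as_genes, 2L)
  expect_gt(mean(xc$as_genes), mean(xc$non_as_genes))
})
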