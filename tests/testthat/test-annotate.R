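gene_fixture <- function() {
  set.seed(90)
  seq <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
               collapse = "")
  manual_genome(
    c(chr1 = seq),
    tracks = list(
      genes = tibble::tibble(chrom = "chr1", start = 10000L, end = 20000L,
                             strand = "+", gene_id = "G1"),
      exons = tibble::tibble(chrom = "chr1", start = c(10000L, 15000L),
                             end = c(12000L, 20000L), strand = "+",
                             gene_id = "G1"),
      five_utr = tibble::tibble(chrom = "chr1", start = 10000L, end = 10200L,
                                strand = "+", gene_id = "G1"),
      three_utr = tibble::tibble(chrom = "chr1", start = 19700L, end = 20000L,
                                 strand = "+", gene_id = "G1"),
      cpg_islands = tibble::tibble(chrom = "chr1", start = 30000L,
                                   end = 31000L),
      repeats = tibble::tibble(chrom = "chr1", start = 40000L, end = 41000L,
                               class = "LINE"),
      enhancers = tibble::tibble(chrom = "chr1", start = 45000L, end = 46000L)
    )
  )
}

test_that("promoter and downstream tracks derive 2 kb strand-aware flanks", {
  g <- gene_fixture()
  ann <- derive_tracks(g)
  expect_equal(as.data.frame(ann$promoter_2kb),
               data.frame(chrom = "chr1", start = 8000, end = 10000))
  expect_equal(as.data.frame(ann$downstream_2kb),
               data.frame(chrom = "chr1", start = 20000, end = 22000))

  g_minus <- g
  g_minus$tracks$genes$strand <- "-"
  ann_minus <- derive_tracks(g_minus)
  expect_equal(as.data.frame(ann_minus$promoter_2kb),
               data.frame(chrom = "chr1", start = 20000, end = 22000))
})

test_that("junction loci receive every containing class, multi-label", {
  g <- gene_fixture()
  ann <- derive_tracks(g)
  # a circle starting in the promoter (locus 9,500) and ending in the intron
  calls <- tibble::tibble(chrom = "chr1", start = 9500L, end = 13001L)
  lab <- classify_junction(calls, ann)
  start_classes <- lab$class[lab$pos == 9500L]
  end_classes <- lab$class[lab$pos == 13000L]
  expect_true("promoter_2kb" %in% start_classes)
  expect_true("intron" %in% end_classes)
})

test_that("loci on annotation-free territory fall in distal_intergenic", {
  g <- gene_fixture()
  ann <- derive_tracks(g)
  calls <- tibble::tibble(chrom = "chr1", start = 50000L, end = 55001L)
  lab <- classify_junction(calls, ann)
  expect_true(all(lab$class %in% c("distal_intergenic")))
  expect_identical(nrow(lab), 2L)
})

test_that("classification equals the point-in-interval oracle", {
  g <- tiny_genome(seed = 91, n_chrom = 2, len = 50000)
  ann <- derive_tracks(g)
  set.seed(91)
  n <- 150
  calls <- tibble::tibble(
    chrom = sample(g$chroms$chrom, n, replace = TRUE),
    start = sample.int(49000, n)
  )
  calls$end <- calls$start + 1L # single locus per breakpoint pair
  lab <- classify_junction(calls, ann, loci = "start")
  plain_ann <- lapply(unclass(ann), as.data.frame)
  for (i in sample(n, 40)) {
    want <- sort(oracle_classify_point(calls$chrom[i], calls$start[i],
                                       plain_ann))
    got <- sort(lab$class[lab$locus_id == i])
    expect_identical(got, want, info = paste("locus", i))
  }
})

test_that("enrichment normalization fixed points hold exactly", {
  g <- gene_fixture()
  whole <- list(
    everything = tibble::tibble(chrom = "chr1", start = 0L, end = 60000L),
    one_percent = tibble::tibble(chrom = "chr1", start = 0L, end = 600L)
  )
  class(whole) <- c("ecc_annotation", "list")
  set.seed(92)
  calls <- tibble::tibble(chrom = "chr1",
                          start = c(sample(0:599, 5), sample(10000:50000, 45)))
  calls$end <- calls$start + 200L
  enr <- element_enrichment(calls, whole, g, loci = "start")
  expect_equal(enr$normalized_score[enr$class == "everything"], 1)
  # 5 of 50 start loci in a 1%-coverage class -> (5/50)/(0.01) = 10
  expect_equal(enr$normalized_score[enr$class == "one_percent"], 10)
})

test_that("zero-coverage classes are excluded with a warning", {
  g <- gene_fixture()
  ann <- list(
    empty = tibble::tibble(chrom = character(), start = integer(),
                           end = integer()),
    full = tibble::tibble(chrom = "chr1", start = 0L, end = 60000L)
  )
  class(ann) <- c("ecc_annotation", "list")
  calls <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L)
  expect_warning(enr <- element_enrichment(calls, ann, g), "zero coverage")
  expect_identical(enr$class, "full")
})

test_that("bin distribution counts starts and normalizes to one", {
  g <- coords_genome(c(2500000, 1500000))
  calls <- tibble::tibble(chrom = "chr1",
                          start = c(10L, 20L, 999999L), end = c(500L, 520L, 1000300L))
  bins <- bin_distribution(calls, g)
  expect_identical(sum(bins$count), 3L)
  expect_equal(sum(bins$fraction), 1)
  expect_equal(bins$fraction[bins$chrom == "chr1" & bins$bin_start == 0], 1)
  expect_error(bin_distribution(calls[0, ], g), "empty")
  # trailing partial bins are kept
  expect_equal(max(bins$bin_end[bins$chrom == "chr2"]), 1500000)
})

test_that("uniform calls fill bins evenly", {
  g <- coords_genome(10000000)
  set.seed(93)
  calls <- tibble::tibble(chrom = "chr1",
                          start = sample.int(10000000, 10000) - 1L)
  calls$end <- calls$start + 300L
  bins <- bin_distribution(calls, g)
  expect_identical(nrow(bins), 10L)
  expect_true(all(abs(bins$fraction - 0.1) < 0.01))
})

test_that("KS on bin distributions honours the degenerate limits", {
  g <- coords_genome(3000000)
  a <- tibble::tibble(chrom = "chr1", start = rep(10L, 50), end = rep(400L, 50))
  b <- tibble::tibble(chrom = "chr1", start = rep(1000010L, 50),
                      end = rep(1000400L, 50))
  ba <- bin_distribution(a, g)
  bb <- bin_distribution(b, g)
  expect_equal(compare_bin_distributions(ba, ba)$value, 0)
  expect_equal(compare_bin_distributions(ba, bb)$value, 1)
  mismatched <- bin_distribution(a, coords_genome(2000000))
  expect_error(compare_bin_distributions(ba, mismatched), "tilings")
})

test_that("random regions conserve lengths, are seeded, and spread by size", {
  g <- coords_genome(c(1000000, 3000000))
  template <- tibble::tibble(chrom = "chr1", start = 0L,
                             end = rep(1000L, 4000))
  r1 <- random_regions(template, g, seed = 7)
  r2 <- random_regions(template, g, seed = 7)
  r3 <- random_regions(template, g, seed = 8)
  expect_identical(r1, r2)
  expect_false(identical(r1$start, r3$start))
  expect_identical(sort(r1$end - r1$start), sort(template$end - template$start))
  expect_true(all(r1$end <= g$chroms$length[match(r1$chrom, g$chroms$chrom)]))
  frac_chr1 <- mean(r1$chrom == "chr1")
  expect_lt(abs(frac_chr1 - 0.25), 0.02)
  too_long <- tibble::tibble(chrom = "chr1", start = 0L, end = 4000000L)
  expect_error(random_regions(too_long, g, seed = 1), "longer")
})
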