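test_that("a singleton call set has a trivial profile", {
  calls <- tibble::tibble(chrom = "chr1", start = 0L, end = 337L)
  prof <- size_profile(calls)
  expect_identical(prof$median, 337L)
  expect_identical(prof$peaks$size, 337L)
  expect_error(size_profile(calls[0, ]), "empty")
})

test_that("the cumulative boundary follows the strictly-shorter convention", {
  calls <- tibble::tibble(chrom = "chr1", start = 0L,
                          end = as.integer(seq(100, 1000, by = 100)))
  prof <- size_profile(calls)
  expect_identical(size_quantile_boundary(prof, 0.9), 1000L)
  expect_identical(size_quantile_boundary(prof, 0.5), 600L)
  expect_identical(prof$median, 550)
})

test_that("quantiles and median are invariant to call ordering", {
  set.seed(7)
  sizes <- sample(100:2000, 500, replace = TRUE)
  calls <- tibble::tibble(chrom = "chr1", start = 0L, end = sizes)
  shuffled <- calls[sample(nrow(calls)), ]
  p1 <- size_profile(calls)
  p2 <- size_profile(shuffled)
  expect_identical(p1$median, p2$median)
  expect_identical(p1$peaks, p2$peaks)
  expect_identical(size_quantile_boundary(p1, 0.9),
                   size_quantile_boundary(p2, 0.9))
})

test_that("find_direct_repeat equals the LCP oracle on random breakpoints", {
  g <- tiny_genome(seed = 50, n_chrom = 2, len = 50000)
  set.seed(50)
  n <- 300
  calls <- tibble::tibble(
    chrom = sample(g$chroms$chrom, n, replace = TRUE),
    start = sample.int(40000, n),
    end = NA_integer_
  )
  calls$end <- calls$start + sample(100:5000, n, replace = TRUE)
  got <- find_direct_repeat(calls, g)
  want <- vapply(seq_len(n), function(i) {
    oracle_lcp(g, calls$chrom[i], calls$start[i], calls$end[i])
  }, 1)
  expect_identical(got, as.integer(want))
})

test_that("planted repeat lengths 0..20 are recovered exactly", {
  for (k in c(0L, 1L, 2L, 4L, 11L, 20L)) {
    set.seed(60 + k)
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    s <- 300L; e <- 900L
    if (k > 0) substr(seq, e + 1, e + k) <- substr(seq, s + 1, s + k)
    # pin the window at exactly k
    bad <- substr(seq, s + k + 1, s + k + 1)
    repl <- setdiff(c("A", "C", "G", "T"), bad)[1]
    substr(seq, e + k + 1, e + k + 1) <- repl
    g <- manual_genome(c(chr1 = seq))
    call <- tibble::tibble(chrom = "chr1", start = s, end = e)
    expect_identical(find_direct_repeat(call, g), k)
  }
})

test_that("a 2-bp repeat counts toward the 2-bp class but not the 4-bp class", {
  set.seed(70)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  s <- 100L; e <- 400L
  substr(seq, e + 1, e + 2) <- substr(seq, s + 1, s + 2)
  bad <- substr(seq, s + 3, s + 3)
  substr(seq, e + 3, e + 3) <- setdiff(c("A", "C", "G", "T"), bad)[1]
  g <- manual_genome(c(chr1 = seq))
  prof <- repeat_fraction_by_size(tibble::tibble(chrom = "chr1", start = s,
                                                 end = e), g, min_n = 1)
  expect_identical(prof$fraction_ge2, 1)
  expect_identical(prof$fraction_ge4, 0)
})

test_that("repeat fractions saturate when every call has a planted repeat", {
  ds <- sim_dataset(seed = 51, n_single = 12, depth = 20, repeat_lens = 3L)
  res <- call_dataset(ds)
  prof <- repeat_fraction_by_size(res$calls, ds$genome, min_n = 1)
  expect_identical(prof$fraction_ge2, 1)
  ok_bins <- prof$by_size_bin[prof$by_size_bin$n > 0, ]
  expect_true(all(ok_bins$fraction_ge2 == 1))
})

test_that("repeat-free circles show only the random background", {
  g <- tiny_genome(seed = 52, n_chrom = 1, len = 50000)
  set.seed(52)
  n <- 1500
  calls <- tibble::tibble(
    chrom = "chr1", start = sample.int(30000, n)
  )
  calls$end <- calls$start + sample(200:2000, n, replace = TRUE)
  prof <- repeat_fraction_by_size(calls, g)
  background <- vapply(seq_len(n), function(i) {
    oracle_lcp(g, "chr1", calls$start[i], calls$end[i])
  }, 1)
  expect_identical(prof$fraction_ge2, mean(background >= 2))
  # binomial sanity: the >=2 background on a uniform genome is ~ 1/16
  expect_lt(abs(prof$fraction_ge2 - 1 / 16), 3 * sqrt(1 / 16 * 15 / 16 / n))
})

test_that("fraction_ge monotonicity in max_len cannot be violated", {
  ds <- sim_dataset(seed = 53, n_single = 10, depth = 15)
  res <- call_dataset(ds)
  wide <- repeat_fraction_by_size(res$calls, ds$genome, max_len = 20)
  narrow <- repeat_fraction_by_size(res$calls, ds$genome, max_len = 2)
  expect_gte(wide$fraction_ge2, narrow$fraction_ge2)
})

test_that("end-nucleotide fractions sum to one and honour construction", {
  set.seed(80)
  seq <- paste(sample(c("A", "C", "G"), 5000, replace = TRUE), collapse = "")
  # make every circle end base (position end-1, 0-based) a T
  ends <- seq(500L, 4500L, by = 100L)
  for (e in ends) substr(seq, e, e) <- "T" # 1-based position e = 0-based e-1
  g <- manual_genome(c(chr1 = seq))
  calls <- tibble::tibble(chrom = "chr1", start = ends - 400L, end = ends)
  comp <- end_nucleotide_composition(calls, g)
  expect_equal(comp$T, rep(1, nrow(comp)))
  expect_equal(comp$A + comp$C + comp$G + comp$T + comp$N,
               rep(1, nrow(comp)), tolerance = 1e-9)
})

test_that("default size classes split at 2 and 3 kb", {
  g <- tiny_genome(seed = 54, n_chrom = 1, len = 50000)
  calls <- tibble::tibble(chrom = "chr1",
                          start = c(1000L, 2000L, 3000L),
                          end = c(1000L + 1500L, 2000L + 2500L, 3000L + 4000L))
  comp <- end_nucleotide_composition(calls, g)
  expect_identical(nrow(comp), 3L)
  expect_identical(comp$n, c(1L, 1L, 1L))
})

test_that("base fractions on a uniform genome approach 1/4", {
  g <- tiny_genome(seed = 55, n_chrom = 1, len = 60000)
  set.seed(55)
  n <- 4000
  calls <- tibble::tibble(chrom = "chr1", start = sample.int(50000, n, TRUE))
  calls$end <- calls$start + 300L
  comp <- end_nucleotide_composition(calls, g, size_classes = c(10000))
  fr <- unlist(comp[1, c("A", "C", "G", "T")])
  expect_true(all(abs(fr - 0.25) < 0.02))
})
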