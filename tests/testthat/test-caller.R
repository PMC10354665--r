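test_that("no evidence gives an empty call set", {
  calls <- call_single_fragment(
    eccprofiler:::empty_evidence(), tiny_genome()
  )
  expect_identical(nrow(calls), 0L)
})

test_that("planted single-fragment circles are called at exact breakpoints", {
  ds <- shared_sim()
  res <- call_dataset(ds)
  truth1 <- ds$truth[ds$truth$n_fragments == 1, c("chrom", "start", "end")]
  called <- as.data.frame(res$calls[, c("chrom", "start", "end")])
  expect_setequal(
    do.call(paste, called),
    do.call(paste, as.data.frame(truth1))
  )
  expect_true(all(res$calls$n_split_support >= 1))
  expect_true(all(res$calls$n_split_support <= res$calls$n_evidence_reads))
})

test_that("recovered direct-repeat lengths match the planted lengths", {
  ds <- shared_sim()
  res <- call_dataset(ds)
  merged <- merge(as.data.frame(res$calls),
                  as.data.frame(ds$truth[ds$truth$n_fragments == 1, ]),
                  by = c("chrom", "start", "end"))
  expect_identical(merged$direct_repeat_len, merged$repeat_len)
})

test_that("calls are invariant under alignment input order", {
  ds <- sim_dataset(seed = 40, n_single = 8, depth = 20)
  res1 <- call_dataset(ds)
  ds_shuffled <- ds
  set.seed(1)
  ds_shuffled$alignments <- ds$alignments[sample(nrow(ds$alignments)), ]
  res2 <- call_dataset(ds_shuffled)
  expect_equal(as.data.frame(res1$calls), as.data.frame(res2$calls))
})

test_that("min_support filters weakly supported junctions", {
  ds <- shared_sim()
  ev <- correct_junction_for_direct_repeat(
    extract_junction_evidence(ds$alignments), ds$genome
  )
  strict <- call_single_fragment(ev, ds$genome, min_support = 10^6)
  expect_identical(nrow(strict), 0L)
})

test_that("calls render with gene-anchored report names", {
  genes <- tibble::tibble(chrom = "chr22", start = 50440000L,
                          end = 50450000L, strand = "+", gene_id = "SBF1")
  calls <- tibble::tibble(chrom = "chr22", start = 50447496L, end = 50447834L)
  expect_identical(
    format_call_names(calls, genes),
    "SBF1^circle 50,447,497–50,447,834"
  )
})

test_that("the caller equals the brute-force oracle on a random instance", {
  ds <- sim_dataset(seed = 41, n_chrom = 2, len = 50000, n_single = 8,
                    depth = 12)
  res <- call_dataset(ds)
  oracle <- oracle_call_set(ds$alignments, ds$genome)
  got <- as.data.frame(res$calls[, c("chrom", "start", "end",
                                     "n_split_support")])
  rownames(oracle) <- NULL
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("cross-chromosomal evidence is excluded from single-fragment calls", {
  ds <- sim_dataset(seed = 42, n_chrom = 3, len = 80000, n_single = 2,
                    n_multi2 = 3, depth = 20)
  res <- call_dataset(ds)
  truth_multi <- ds$truth[ds$truth$n_fragments > 1, ]
  called_keys <- paste(res$calls$chrom, res$calls$start, res$calls$end)
  multi_keys <- paste(truth_multi$chrom, truth_multi$start, truth_multi$end)
  expect_length(intersect(called_keys, multi_keys), 0)
})

test_that("confident regions require cross-chromosomal support at both ends", {
  ds <- sim_dataset(seed = 43, n_chrom = 2, len = 80000, n_single = 5,
                    n_multi2 = 0, depth = 20)
  ev <- correct_junction_for_direct_repeat(
    extract_junction_evidence(ds$alignments), ds$genome
  )
  regions <- extract_confident_regions(ev, ds$alignments, ds$genome)
  expect_identical(nrow(regions), 0L)
})

test_that("two-fragment circles produce reciprocal confident regions", {
  ds <- sim_dataset(seed = 44, n_chrom = 2, len = 80000, n_single = 0,
                    n_multi2 = 1, depth = 30)
  ev <- correct_junction_for_direct_repeat(
    extract_junction_evidence(ds$alignments), ds$genome
  )
  regions <- extract_confident_regions(ev, ds$alignments, ds$genome)
  truth <- ds$truth
  expect_identical(nrow(regions), 2L)
  expect_setequal(paste(regions$chrom, regions$start, regions$end),
                  paste(truth$chrom, truth$start, truth$end))
  expect_true(all(regions$left_partner_chrom != regions$chrom))
  expect_true(all(regions$right_partner_chrom != regions$chrom))
})

test_that("a coverage gap disqualifies a confident region", {
  ds <- sim_dataset(seed = 45, n_chrom = 2, len = 80000, n_single = 0,
                    n_multi2 = 1, depth = 30)
  ev <- correct_junction_for_direct_repeat(
    extract_junction_evidence(ds$alignments), ds$genome
  )
  frag1 <- ds$truth[1, ]
  gap <- c(frag1$start + 100L, frag1$start + 150L)
  al <- ds$alignments
  keep <- !(al$chrom == frag1$chrom & al$start < gap[2] & al$end > gap[1])
  regions <- extract_confident_regions(ev, al[keep, ], ds$genome)
  expect_false(any(regions$chrom == frag1$chrom &
                     regions$start == frag1$start))
})

test_that("assembly recovers planted multi-fragment circles exactly", {
  ds <- sim_dataset(seed = 46, n_chrom = 4, len = 120000, n_single = 0,
                    n_multi2 = 4, n_multi3 = 2, depth = 30)
  ev <- correct_junction_for_direct_repeat(
    extract_junction_evidence(ds$alignments), ds$genome
  )
  regions <- extract_confident_regions(ev, ds$alignments, ds$genome)
  cycles <- assemble_multifragment(regions, ev)
  truth_sets <- split(
    paste(ds$truth$chrom, ds$truth$start, ds$truth$end),
    ds$truth$circle_id
  )
  truth_sets <- lapply(truth_sets, sort)
  cycle_sets <- split(
    paste(cycles$chrom, cycles$start, cycles$end), cycles$cycle_id
  )
  cycle_sets <- lapply(cycle_sets, sort)
  matched <- sum(vapply(truth_sets, function(ts) {
    any(vapply(cycle_sets, identical, TRUE, y = ts))
  }, TRUE))
  expect_identical(matched, length(truth_sets))
  # no chimeric cycle mixes fragments of different truth circles
  for (cs in cycle_sets) {
    owners <- unique(unlist(lapply(cs, function(key) {
      names(truth_sets)[vapply(truth_sets, function(ts) key %in% ts, TRUE)]
    })))
    expect_length(owners, 1)
  }
})

test_that("a directed open chain assembles no cycle", {
  regions <- tibble::tibble(
    chrom = c("chr1", "chr2", "chr3"),
    start = c(100L, 200L, 300L), end = c(400L, 500L, 600L),
    left_partner_chrom = "chrX", left_partner_pos = 0L,
    right_partner_chrom = "chrX", right_partner_pos = 0L,
    left_support = 1L, right_support = 1L, covered_fraction = 1
  )
  # chain chr1 -> chr2 -> chr3 with no closing edge
  ev <- rbind(
    chain_evidence("chr1", 400L, "chr2", 200L),
    chain_evidence("chr2", 500L, "chr3", 300L)
  )
  cycles <- assemble_multifragment(regions, ev)
  expect_identical(nrow(cycles), 0L)
})
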