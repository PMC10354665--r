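genes_fixture <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L),
    end = c(2000L, 8000L, 4000L),
    strand = "+",
    gene_id = c("G1", "G2", "G3")
  )
}

test_that("gene abundance handles empty overlap and the plain arithmetic case", {
  genes <- genes_fixture()
  calls <- tibble::tibble(chrom = "chr2", start = 2500L, end = 3000L,
                          n_split_support = 50L, sample_id = "S1")
  ab <- gene_abundance(calls, genes, c(S1 = 1e6))
  expect_equal(ab$raw$S1[ab$raw$gene_id == "G3"], 50)
  expect_equal(ab$normalized$S1[ab$normalized$gene_id == "G3"], 50)
  expect_equal(ab$raw$S1[ab$raw$gene_id == "G1"], 0)
  expect_error(gene_abundance(calls, genes, c(S1 = 0)), "> 0")
})

test_that("a call overlapping several genes contributes to each of them", {
  genes <- tibble::tibble(chrom = "chr1", start = c(100L, 400L),
                          end = c(500L, 900L), strand = "+",
                          gene_id = c("A", "B"))
  calls <- tibble::tibble(chrom = "chr1", start = 350L, end = 450L,
                          n_split_support = 7L, sample_id = "S1")
  ab <- gene_abundance(calls, genes, c(S1 = 1000))
  expect_equal(ab$raw$S1, c(7, 7))
})

test_that("gene abundance equals the overlap-and-sum oracle", {
  set.seed(120)
  for (rep in 1:8) {
    n_genes <- sample(5:15, 1)
    genes <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      start = sample.int(50000, n_genes)
    )
    genes$end <- genes$start + sample(500:5000, n_genes, replace = TRUE)
    genes$gene_id <- paste0("g", seq_len(n_genes))
    n_calls <- sample(10:40, 1)
    calls <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_calls, replace = TRUE),
      start = sample.int(50000, n_calls),
      sample_id = "S1"
    )
    calls$end <- calls$start + sample(100:2000, n_calls, replace = TRUE)
    calls$n_split_support <- sample(1:20, n_calls, replace = TRUE)
    ab <- gene_abundance(calls, genes, c(S1 = 1e6))
    want <- oracle_gene_counts(calls, genes)
    expect_equal(stats::setNames(ab$raw$S1, ab$raw$gene_id), want,
                 info = paste("instance", rep))
  }
})

test_that("normalized counts are scale invariant", {
  genes <- genes_fixture()
  calls <- tibble::tibble(chrom = "chr1", start = 1200L, end = 1500L,
                          n_split_support = 10L, sample_id = "S1")
  calls2 <- calls
  calls2$n_split_support <- 30L
  ab1 <- gene_abundance(calls, genes, c(S1 = 1e4))
  ab2 <- gene_abundance(calls2, genes, c(S1 = 3e4))
  expect_equal(ab1$normalized$S1, ab2$normalized$S1)
})

test_that("single-sample groups produce no recurrent circles", {
  calls <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L,
                          sample_id = "S1")
  rec <- recurrent_eccdna(calls, c(S1 = "grp"))
  expect_identical(nrow(rec), 0L)
})

test_that("a circle in two of three samples is the sole recurrent member", {
  calls <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 900L, 5000L),
    end = c(400L, 400L, 1200L, 5400L),
    sample_id = c("S1", "S3", "S2", "S2")
  )
  rec <- recurrent_eccdna(calls, c(S1 = "g", S2 = "g", S3 = "g"))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$start, 100L)
  expect_identical(rec$n_samples, 2L)
  expect_identical(rec$samples[[1]], c("S1", "S3"))
})

test_that("recurrence with zero tolerance equals a hash-join oracle", {
  set.seed(121)
  calls <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
    start = sample.int(200, 300, replace = TRUE), # few keys force recurrence
    sample_id = sample(paste0("S", 1:4), 300, replace = TRUE)
  )
  calls$end <- calls$start + 300L
  rec <- recurrent_eccdna(calls, stats::setNames(rep("g", 4), paste0("S", 1:4)))
  key <- paste(calls$chrom, calls$start, calls$end)
  oracle_n <- tapply(calls$sample_id, key, function(x) length(unique(x)))
  oracle_keys <- sort(names(oracle_n)[oracle_n >= 2])
  expect_identical(sort(paste(rec$chrom, rec$start, rec$end)), oracle_keys)
})

test_that("breakpoint tolerance merges near-identical circles", {
  calls <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 103L),
    end = c(400L, 402L),
    sample_id = c("S1", "S2")
  )
  strict <- recurrent_eccdna(calls, c(S1 = "g", S2 = "g"))
  expect_identical(nrow(strict), 0L)
  loose <- recurrent_eccdna(calls, c(S1 = "g", S2 = "g"), tolerance_bp = 5)
  expect_identical(nrow(loose), 1L)
  expect_false(loose$wide_cluster)
})

test_that("biomarker intersection is set arithmetic, commutative, monotone", {
  expect_identical(
    intersect_biomarkers(c("A", "B", "C"), c("B", "C", "D"))$genes[[1]],
    c("B", "C")
  )
  suppressWarnings({
    empty <- intersect_biomarkers(c("A"), c("B"))
  })
  expect_identical(empty$n, 0L)
  ab <- intersect_biomarkers(c("A", "B", "C"), c("B", "C", "D"))
  ba <- intersect_biomarkers(c("B", "C", "D"), c("A", "B", "C"))
  expect_identical(ab$genes[[1]], ba$genes[[1]])
  bigger <- intersect_biomarkers(c("A", "B", "C", "D"), c("B", "C", "D"))
  expect_true(all(ab$genes[[1]] %in% bigger$genes[[1]]))
  expect_warning(intersect_biomarkers(c("A"), c("B")), "namespace")
})

test_that("flank export writes exact 150-bp sequences and drops edge cases", {
  g <- tiny_genome(seed = 122, n_chrom = 1, len = 50000)
  calls <- tibble::tibble(chrom = "chr1", start = c(1000L, 30L),
                          end = c(2000L, 500L))
  fa <- withr::local_tempfile(fileext = ".fa")
  expect_message(res <- export_flank_fasta(calls, g, fa), "dropped 1")
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(res$n_written, 3L)
  expect_true(all(Biostrings::width(seqs) == 150))
  # start flank of circle [1000, 2000) spans [900, 1050)
  start_flank <- as.character(seqs[[grep("start_flank", names(seqs))[1]]])
  expect_identical(start_flank, genome_subseq(g, "chr1", 900L, 1050L))
  # round trip: every exported record re-extracts identically
  for (nm in names(seqs)) {
    loc <- sub("/.*$", "", nm)
    expect_identical(nchar(as.character(seqs[[nm]])), 150L)
  }
})

test_that("differential input export writes integer counts plus design", {
  genes <- genes_fixture()
  calls <- tibble::tibble(chrom = "chr1", start = 1200L, end = 1500L,
                          n_split_support = 10L, sample_id = "S1")
  ab <- gene_abundance(calls, genes, c(S1 = 1e4, S2 = 2e4))
  dir <- withr::local_tempdir()
  paths <- export_differential_inputs(ab, c(S1 = "case", S2 = "ctrl"), dir)
  counts <- readr::read_tsv(paths["counts"], show_col_types = FALSE)
  expect_identical(names(counts), c("gene_id", "S1", "S2"))
  expect_true(all(counts$S1 == floor(counts$S1)))
  design <- readr::read_tsv(paths["design"], show_col_types = FALSE)
  expect_identical(design$group, c("case", "ctrl"))
})
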