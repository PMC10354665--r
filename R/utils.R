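# Shared validation and small helpers.

`%||%` <- rlang::`%||%`

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# Deterministic child seed derived from a user seed and a stage label.
# Keeps every stage's RNG stream independent while remaining a pure function
# of (seed, label); result stays inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  h <- (sum(bytes * seq_along(bytes)) * 2654435761) %% 2147480000
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480000) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 1-based inclusive rendering of a 0-based half-open interval, with the
# thousands separator used in reports, e.g. "50,447,497-50,447,834".
format_locus_1based <- function(start0, end0) {
  paste0(
    format(start0 + 1L, big.mark = ",", scientific = FALSE, trim = TRUE),
    "-",
    format(end0, big.mark = ",", scientific = FALSE, trim = TRUE)
  )
}

# GRanges from a 0-based half-open tibble; used behind interval operations.
as_granges0 <- function(df, genome = NULL) {
  seqlen <- NULL
  if (!is.null(genome)) {
    seqlen <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*",
    seqlengths = seqlen
  )
}

granges_to_tibble0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Total merged base pairs covered by a 0-based interval tibble.
merged_coverage_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  gr <- GenomicRanges::reduce(as_granges0(df))
  sum(as.numeric(GenomicRanges::width(gr)))
}
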