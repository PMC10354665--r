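# Size, direct-repeat and end-nucleotide characterization of call sets.

#' Size profile of a call set
#'
#' Builds the 1-bp-resolution size histogram, finds modal sizes as local
#' maxima of the moving-average-smoothed histogram (ranked by smoothed
#' height), and exposes the empirical cumulative size distribution.
#'
#' @param calls An `ecc_calls` tibble (or any tibble with `start`/`end` or a
#'   `size` column).
#' @param smooth_window Moving-average window in bp (default 5).
#' @param min_peak_separation Minimum distance between reported modal sizes
#'   in bp (default 50); nearby shoulder maxima are suppressed in favour of
#'   the higher peak.
#' @return A list of class `ecc_size_profile`: `sizes`, `median`, `peaks`
#'   (tibble `size`, `height`, `rank`), `histogram`, and `quantile_fn`
#'   (size -> cumulative fraction, the "<= size" empirical convention).
#' @export
size_profile <- function(calls, smooth_window = 5L,
                         min_peak_separation = 50L) {
  sizes <- call_sizes(calls)
  assert_that(length(sizes) > 0, "size_profile: empty call set")
  rng <- range(sizes)
  breaks <- seq(rng[1], rng[2])
  counts <- tabulate(sizes - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  k <- max(1L, min(as.integer(smooth_window), length(counts)))
  smooth <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2))
  smooth[is.na(smooth)] <- 0
  if (length(smooth) >= 3) {
    pk <- pracma::findpeaks(smooth, minpeakdistance = min_peak_separation,
                            sortstr = TRUE)
  } else {
    pk <- NULL
  }
  peaks <- if (is.null(pk)) {
    tibble(size = breaks[which.max(smooth)], height = max(smooth), rank = 1L)
  } else {
    tibble(size = breaks[pk[, 2]], height = pk[, 1]) |>
      arrange(desc(.data$height), .data$size) |>
      mutate(rank = row_number())
  }
  ecdf_fn <- stats::ecdf(sizes)
  structure(
    list(
      sizes = sizes,
      median = stats::median(sizes),
      peaks = peaks,
      histogram = tibble(size = breaks, count = counts, smoothed = smooth),
      quantile_fn = ecdf_fn
    ),
    class = "ecc_size_profile"
  )
}

#' Size below which a given fraction of circles falls
#'
#' Returns the smallest observed size `x` such that at least a fraction `q`
#' of circles are strictly shorter than `x` (the "q of molecules were shorter
#' than x" convention used for cumulative size reporting).
#'
#' @param profile An `ecc_size_profile`.
#' @param q Fraction in (0, 1].
#' @return Size in bp.
#' @export
size_quantile_boundary <- function(profile, q) {
  sz <- sort(unique(profile$sizes))
  n <- length(profile$sizes)
  below <- vapply(sz, function(x) sum(profile$sizes < x), numeric(1)) / n
  hit <- sz[below >= q]
  if (length(hit) == 0) max(profile$sizes) + 1L else hit[1]
}

call_sizes <- function(calls) {
  if ("size" %in% names(calls)) calls$size else calls$end - calls$start
}

#' @export
print.ecc_size_profile <- function(x, ...) {
  cat("<ecc_size_profile> n =", length(x$sizes), " median =", x$median, "bp\n")
  cat("top peaks:", paste(utils::head(x$peaks$size, 3), collapse = ", "), "bp\n")
  invisible(x)
}

#' Find the flanking direct repeat of a circle
#'
#' A direct repeat is a short sequence at the start of the circle whose
#' genomic copy flanks the end of the circle: the repeat length is the
#' largest `k <= max_len` with `genome[start, start+k) == genome[end, end+k)`
#' (0 when the first bases already differ). The search is truncated at the
#' chromosome edge. Exact matches only.
#'
#' @param calls An `ecc_calls` tibble (vectorized over rows).
#' @param genome The reference `ecc_genome`.
#' @param max_len Longest repeat searched for (default 20 bp).
#' @return Integer vector of repeat lengths, one per call.
#' @export
find_direct_repeat <- function(calls, genome, max_len = 20L) {
  n <- nrow(calls)
  out <- integer(n)
  for (i in seq_len(n)) {
    cc <- calls$chrom[i]
    w <- min(max_len, chrom_length(genome, cc) - calls$end[i],
             chrom_length(genome, cc) - calls$start[i])
    out[i] <- if (w <= 0) 0L else {
      lcp_len(
        genome_subseq(genome, cc, calls$start[i], calls$start[i] + w),
        genome_subseq(genome, cc, calls$end[i], calls$end[i] + w)
      )
    }
  }
  out
}

#' Direct-repeat fractions, overall and by size stratum
#'
#' Rescans each call's canonical coordinates for its flanking direct repeat
#' and reports the fraction of calls with repeats of at least 2 bp and at
#' least 4 bp, overall and per size stratum.
#'
#' @param calls An `ecc_calls` tibble.
#' @param genome The reference `ecc_genome`.
#' @param size_bins Stratum boundaries in bp (right-open; -Inf/Inf added).
#' @param max_len Longest repeat searched (default 20).
#' @param min_n Strata with fewer calls are flagged low-confidence.
#' @return A list of class `ecc_repeat_profile`: `repeat_len` (per call),
#'   `fraction_ge2`, `fraction_ge4`, and `by_size_bin` (tibble with `bin`,
#'   `n`, `fraction_ge2`, `fraction_ge4`, `low_confidence`).
#' @export
repeat_fraction_by_size <- function(calls, genome,
                                    size_bins = c(200, 400, 1000),
                                    max_len = 20L, min_n = 10L) {
  assert_that(nrow(calls) > 0, "repeat_fraction_by_size: empty call set")
  rl <- find_direct_repeat(calls, genome, max_len = max_len)
  sizes <- call_sizes(calls)
  bin <- cut(sizes, breaks = c(-Inf, size_bins, Inf), right = FALSE)
  by_bin <- tibble(bin = bin, repeat_len = rl) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(
      n = n(),
      fraction_ge2 = if (n() > 0) mean(.data$repeat_len >= 2) else NA_real_,
      fraction_ge4 = if (n() > 0) mean(.data$repeat_len >= 4) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(low_confidence = .data$n < min_n)
  structure(
    list(
      repeat_len = rl,
      fraction_ge2 = mean(rl >= 2),
      fraction_ge4 = mean(rl >= 4),
      by_size_bin = by_bin
    ),
    class = "ecc_repeat_profile"
  )
}

#' End-nucleotide composition by size class
#'
#' For each size class, the fraction of A/C/G/T (N in a separate bucket) at
#' the circle's terminal reference base, read from the forward strand. The
#' terminal base is the last base inside the circle (1-based position `end`);
#' set `which_end = "start"` for the first base instead.
#'
#' @param calls An `ecc_calls` tibble.
#' @param genome The reference `ecc_genome`.
#' @param size_classes Class boundaries in bp; the defaults reproduce the
#'   < 2,000 / 2,000-3,000 / > 3,000 bp classes.
#' @param which_end `"end"` (default) or `"start"`.
#' @return Tibble: `size_class`, `n`, and fraction columns `A`, `C`, `G`,
#'   `T`, `N` summing to 1 per class.
#' @export
end_nucleotide_composition <- function(calls, genome,
                                       size_classes = c(2000, 3000),
                                       which_end = c("end", "start")) {
  assert_that(nrow(calls) > 0, "end_nucleotide_composition: empty call set")
  which_end <- match.arg(which_end)
  pos0 <- if (which_end == "end") calls$end - 1L else calls$start
  base <- toupper(genome_subseq(genome, calls$chrom, pos0, pos0 + 1L))
  base[!base %in% c("A", "C", "G", "T")] <- "N"
  sizes <- call_sizes(calls)
  cls <- cut(sizes, breaks = c(-Inf, size_classes, Inf), right = TRUE)
  tibble(size_class = cls, base = factor(base, c("A", "C", "G", "T", "N"))) |>
    count(.data$size_class, .data$base, .drop = FALSE) |>
    group_by(.data$size_class) |>
    mutate(total = sum(.data$n)) |>
    ungroup() |>
    filter(.data$total > 0) |>
    mutate(fraction = .data$n / .data$total) |>
    select(-"n") |>
    pivot_wider(names_from = "base", values_from = "fraction") |>
    rename(n = "total")
}
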