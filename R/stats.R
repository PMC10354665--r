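# Exact small-sample nonparametric tests. For n <= 25 the exact null
# distributions are computed with the distribution-counting (shift)
# recurrence over doubled mid-ranks, which enumerates the 2^n sign
# assignments / C(n, k) group assignments implicitly and handles ties on the
# observed tie structure; larger n falls back to the normal approximation
# with tie correction and continuity correction.

EXACT_N_MAX <- 25L

test_result <- function(statistic, value, p_value, sided, exact, n,
                        degenerate = FALSE) {
  out <- tibble(
    statistic = statistic, value = value,
    p_value = max(min(p_value, 1), .Machine$double.xmin),
    sided = sided, exact = exact, n = n, degenerate = degenerate
  )
  structure(out, class = c("ecc_test", class(out)))
}

# Counts of subset sums of integer weights w (each in/out): vector c with
# c[s+1] = number of subsets summing to s.
subset_sum_counts <- function(w) {
  total <- sum(w)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (wi in w) {
    if (wi == 0) { cnt <- cnt * 2; next }
    shifted <- c(numeric(wi), cnt[seq_len(total + 1 - wi)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Exact Wilcoxon signed-rank test
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are removed first; ties among the absolute differences are
#' handled with mid-ranks. For n <= 25 nonzero differences the p-value is
#' exact (full enumeration of the 2^n sign assignments on the observed tie
#' structure); beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param differences Numeric vector of paired differences.
#' @param sided `"two"`, `"greater"` (positive shift) or `"less"`.
#' @return A one-row `ecc_test` tibble: `statistic` ("V" = rank sum of the
#'   positive differences), `value`, `p_value`, `sided`, `exact`, `n`,
#'   `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(2, 1, 3, 5, 4), sided = "greater") # p = 1/32
#' @export
wilcoxon_signed_rank <- function(differences,
                                 sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result("V", 0, 1, sided, TRUE, 0L, degenerate = TRUE))
  }
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled mid-ranks (integers)
  v2 <- sum(r2[d > 0])
  if (n <= EXACT_N_MAX) {
    cnt <- subset_sum_counts(r2)
    tot <- 2^n
    p_ge <- sum(cnt[seq(v2 + 1, length(cnt))]) / tot
    p_le <- sum(cnt[seq_len(v2 + 1)]) / tot
    exact <- TRUE
  } else {
    mu <- sum(r2) / 2
    sig2 <- sum(r2^2) / 4
    z_ge <- (v2 - mu - 1) / sqrt(sig2) # continuity correction (doubled scale)
    z_le <- (v2 - mu + 1) / sqrt(sig2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    exact <- FALSE
  }
  p <- switch(sided,
    greater = p_ge,
    less = p_le,
    two = min(1, 2 * min(p_ge, p_le))
  )
  test_result("V", v2 / 2, p, sided, exact, n)
}

# Counts over (subset size, doubled-rank sum): matrix M with
# M[k+1, s+1] = number of k-subsets of w summing to s.
subset_size_sum_counts <- function(w, k_max) {
  total <- sum(w)
  m <- matrix(0, nrow = k_max + 1, ncol = total + 1)
  m[1, 1] <- 1
  for (wi in w) {
    for (k in seq(min(k_max, 1e9), 1)) {
      src <- m[k, ]
      if (wi > 0) src <- c(numeric(wi), src[seq_len(total + 1 - wi)])
      m[k + 1, ] <- m[k + 1, ] + src
    }
  }
  m
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test with mid-ranks for ties. Exact by
#' enumeration of all C(nA+nB, nA) group assignments (on the observed tie
#' structure) when nA+nB <= 25; normal approximation with tie and continuity
#' corrections otherwise.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param sided `"two"`, `"greater"` (a tends larger) or `"less"`.
#' @return A one-row `ecc_test` tibble with statistic `"W"` (rank sum of
#'   group a).
#' @examples
#' wilcoxon_rank_sum(1:4, 5:8, sided = "less") # p = 1/70
#' @export
wilcoxon_rank_sum <- function(a, b, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  assert_that(length(a) > 0 && length(b) > 0, "both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  r2 <- as.integer(round(2 * rank(c(a, b))))
  w2 <- sum(r2[seq_len(na)])
  if (length(unique(c(a, b))) == 1) {
    return(test_result("W", w2 / 2, 1, sided, TRUE, n, degenerate = TRUE))
  }
  if (n <= EXACT_N_MAX) {
    m <- subset_size_sum_counts(r2, na)
    row <- m[na + 1, ]
    tot <- sum(row) # == choose(n, na)
    p_ge <- sum(row[seq(w2 + 1, length(row))]) / tot
    p_le <- sum(row[seq_len(w2 + 1)]) / tot
    exact <- TRUE
  } else {
    mu <- na * (n + 1) # mean of the doubled-rank sum
    tie_sizes <- tabulate(match(r2, unique(r2)))
    tie_term <- sum(tie_sizes^3 - tie_sizes)
    # standard rank-sum variance with tie correction, on the doubled scale
    sig2 <- 4 * na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z_ge <- (w2 - mu - 1) / sqrt(sig2)
    z_le <- (w2 - mu + 1) / sqrt(sig2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    exact <- FALSE
  }
  p <- switch(sided,
    greater = p_ge,
    less = p_le,
    two = min(1, 2 * min(p_ge, p_le))
  )
  test_result("W", w2 / 2, p, sided, exact, n)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the common result layout:
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' asymptotic (ties make it approximate, as usual).
#'
#' @param a,b Numeric samples (both nonempty).
#' @return A one-row `ecc_test` tibble with statistic `"D"`.
#' @export
ks_two_sample <- function(a, b) {
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  test_result("D", unname(kt$statistic), unname(kt$p.value), "two", FALSE,
              length(a) + length(b))
}
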