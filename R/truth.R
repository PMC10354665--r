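# Ground-truth circle sets: sizes, placement, direct-repeat planting.

#' Simulation parameters for synthetic circle-sequencing data
#'
#' Bundles the knobs of the synthetic data generator. Defaults reflect a
#' nucleosome-ladder circle population (bimodal sizes with modes near 201 and
#' 348 bp), 150-bp paired-end reads and 200-300 bp library fragments.
#'
#' @param seed Integer seed; together with the genome it fully determines the
#'   truth set and the simulated alignments.
#' @param n_single Number of single-fragment circles.
#' @param n_multi2,n_multi3 Numbers of two- and three-fragment circles (each
#'   fragment on a distinct chromosome).
#' @param size_mixture Tibble or data frame with columns `mode_bp`, `sd_bp`,
#'   `weight` describing the Gaussian size mixture; weights must sum to 1.
#' @param read_len Read length in bp.
#' @param frag_mean,frag_sd Library fragment size mean / sd in bp.
#' @param depth Mean junction-spanning read pairs per circle.
#' @param error_rate Substitution rate per base (default 0; the pipeline under
#'   test operates post-alignment, so errors are off by default).
#' @param repeat_lens Integer vector; each circle's planted flanking
#'   direct-repeat length is drawn uniformly from it (0 = no repeat; max 20).
#' @param chemistry `"rca"` (rolling-circle tandem concatemers, the tissue
#'   library chemistry) or `"tagmentation"` (plasma-style, no amplification).
#' @param rca_mean_copies Mean concatemer copy count for RCA (geometric).
#' @param duplicate_fraction Fraction of read pairs flagged as PCR/optical
#'   duplicates.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_single = 50L, n_multi2 = 0L, n_multi3 = 0L,
                       size_mixture = data.frame(
                         mode_bp = c(201, 348), sd_bp = c(15, 20),
                         weight = c(0.5, 0.5)
                       ),
                       read_len = 150L, frag_mean = 250L, frag_sd = 25L,
                       depth = 30, error_rate = 0, repeat_lens = 0:10,
                       chemistry = c("rca", "tagmentation"),
                       rca_mean_copies = 5, duplicate_fraction = 0) {
  chemistry <- match.arg(chemistry)
  size_mixture <- as_tibble(size_mixture)
  assert_that(abs(sum(size_mixture$weight) - 1) < 1e-9,
              "size_mixture weights must sum to 1")
  assert_that(read_len <= frag_mean, "read_len must not exceed frag_mean")
  assert_that(all(repeat_lens >= 0 & repeat_lens <= 20),
              "repeat lengths must lie in [0, 20]")
  structure(
    list(seed = as.integer(seed), n_single = n_single, n_multi2 = n_multi2,
         n_multi3 = n_multi3, size_mixture = size_mixture,
         read_len = as.integer(read_len), frag_mean = frag_mean,
         frag_sd = frag_sd, depth = depth, error_rate = error_rate,
         repeat_lens = as.integer(repeat_lens), chemistry = chemistry,
         rca_mean_copies = rca_mean_copies,
         duplicate_fraction = duplicate_fraction),
    class = "sim_params"
  )
}

draw_sizes <- function(n, size_mixture, min_len = 50L) {
  comp <- sample.int(nrow(size_mixture), n, replace = TRUE,
                     prob = size_mixture$weight)
  sz <- round(stats::rnorm(n, size_mixture$mode_bp[comp],
                           size_mixture$sd_bp[comp]))
  pmax(as.integer(sz), min_len)
}

#' Generate ground-truth eccDNA circles and plant their direct repeats
#'
#' Places single- and multi-fragment circles on the genome without overlap
#' (multi-fragment circles put each fragment on a distinct chromosome) and,
#' for circles with a planted direct repeat of length k > 0, edits the genome
#' so the k bases at each fragment's downstream flank equal the k bases at the
#' start of the next fragment in the cycle — for a single-fragment circle
#' `[s, e)` this makes `genome[s, s+k) == genome[e, e+k)`.
#'
#' @param genome An `ecc_genome` (will be edited to plant repeats).
#' @param params A [sim_params()] object.
#' @return List with `genome` (edited) and `truth`, a tibble of class
#'   `ecc_truth` with one row per fragment: `circle_id`, `frag_index`,
#'   `n_fragments`, `chrom`, `start`, `end`, `strand`, `size`,
#'   `circle_size`, `repeat_len`, `chemistry`, `copy_number`.
#' @export
make_truth_circles <- function(genome, params) {
  margin <- 30L # keeps planted-repeat edits and flank scans clear of neighbours
  with_seed(derive_seed(params$seed, "truth"), {
    occupied <- stats::setNames(
      vector("list", nrow(genome$chroms)), genome$chroms$chrom
    )
    place_fragment <- function(len, exclude_chroms = character(0)) {
      ok <- genome$chroms |>
        filter(!.data$chrom %in% exclude_chroms, .data$length > len + 2L * margin)
      assert_that(nrow(ok) > 0, "no chromosome can hold a fragment this long")
      for (attempt in seq_len(300)) {
        cc <- sample(ok$chrom, 1, prob = ok$length)
        s <- sample.int(chrom_length(genome, cc) - len - 2L * margin, 1L) + margin
        iv <- c(s - margin, s + len + margin)
        hits <- occupied[[cc]]
        clash <- !is.null(hits) &&
          any(hits[, 1] < iv[2] & iv[1] < hits[, 2])
        if (!clash) {
          occupied[[cc]] <<- rbind(hits, iv)
          return(list(chrom = cc, start = s, end = s + len))
        }
      }
      rlang::abort("fragment placement failed after 300 attempts; genome too crowded")
    }

    n_circ <- params$n_single + params$n_multi2 + params$n_multi3
    n_frag_per <- c(rep(1L, params$n_single), rep(2L, params$n_multi2),
                    rep(3L, params$n_multi3))
    rows <- vector("list", n_circ)
    for (ci in seq_len(n_circ)) {
      k_frag <- n_frag_per[ci]
      sizes <- draw_sizes(k_frag, params$size_mixture)
      rep_len <- if (length(params$repeat_lens) == 1) params$repeat_lens else
        sample(params$repeat_lens, 1)
      placed <- list()
      used_chroms <- character(0)
      for (fi in seq_len(k_frag)) {
        excl <- if (k_frag > 1) used_chroms else character(0)
        p <- place_fragment(sizes[fi], exclude_chroms = excl)
        used_chroms <- c(used_chroms, p$chrom)
        placed[[fi]] <- p
      }
      rows[[ci]] <- tibble(
        circle_id = sprintf("circ%04d", ci),
        frag_index = seq_len(k_frag),
        n_fragments = k_frag,
        chrom = purrr::map_chr(placed, "chrom"),
        start = purrr::map_int(placed, ~ as.integer(.x$start)),
        end = purrr::map_int(placed, ~ as.integer(.x$end)),
        strand = "+",
        size = sizes,
        circle_size = sum(sizes),
        repeat_len = as.integer(rep_len),
        chemistry = params$chemistry,
        copy_number = 1L
      )
    }
    truth <- purrr::list_rbind(rows)

    # Plant direct repeats: junction i joins fragment i's end to fragment
    # (i mod m)+1's start; copy the k start bases onto the downstream flank.
    # The flanking homology is then pinned to exactly k bases (mismatches
    # forced just outside the window) so the truth coordinates are the
    # canonical leftmost junction representation.
    other_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
    for (cid in unique(truth$circle_id)) {
      circ <- truth |> filter(.data$circle_id == cid)
      k <- circ$repeat_len[1]
      m <- nrow(circ)
      for (i in seq_len(m)) {
        nxt <- circ[if (i == m) 1L else i + 1L, ]
        if (k > 0) {
          donor <- genome_subseq(genome, nxt$chrom, nxt$start, nxt$start + k)
          genome <- genome_replace(genome, circ$chrom[i], circ$end[i], donor)
        }
        # cap the homology window on the right: base k after each breakpoint
        after_end <- genome_subseq(genome, circ$chrom[i], circ$end[i] + k,
                                   circ$end[i] + k + 1L)
        after_start <- genome_subseq(genome, nxt$chrom, nxt$start + k,
                                     nxt$start + k + 1L)
        if (after_end == after_start) {
          genome <- genome_replace(genome, circ$chrom[i], circ$end[i] + k,
                                   other_base(after_end))
        }
        # and on the left: base before each breakpoint (edit the upstream
        # flank of the next fragment, which lies outside every circle)
        before_end <- genome_subseq(genome, circ$chrom[i], circ$end[i] - 1L,
                                    circ$end[i])
        before_start <- genome_subseq(genome, nxt$chrom, nxt$start - 1L,
                                      nxt$start)
        if (before_end == before_start) {
          genome <- genome_replace(genome, nxt$chrom, nxt$start - 1L,
                                   other_base(before_start))
        }
      }
    }
    list(genome = genome, truth = structure(truth, class = c("ecc_truth", class(truth))))
  })
}

#' Write a truth circle set as BED
#'
#' One line per fragment: chrom, start, end, circle id, circle size, strand.
#' Coordinates are 0-based half-open.
#'
#' @param truth An `ecc_truth` tibble from [make_truth_circles()].
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  readr::write_tsv(
    tibble(chrom = truth$chrom, start = truth$start, end = truth$end,
           name = paste0(truth$circle_id, "/", truth$frag_index, "of",
                         truth$n_fragments),
           score = truth$circle_size, strand = truth$strand),
    path, col_names = FALSE
  )
  invisible(path)
}
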