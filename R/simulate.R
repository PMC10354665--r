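# Circle-sequencing read simulator: rolling-circle concatemer or tagmentation
# templates, bwa-mem-style split-read representation (primary + supplementary
# with soft clips and an SA descriptor), written as already-aligned records.

# Split one read's template interval [a, b) into alignment segments.
# `cum0` holds the circle-coordinate start of each fragment (first element 0);
# junctions therefore sit at circle positions cum0 (mod L). When the circle
# carries a k-bp planted direct repeat the split boundary is placed uniformly
# among the k+1 legal offsets, mimicking aligner ambiguity.
segment_read <- function(a, b, L, cum0, frag_chrom, frag_start, k_repeat,
                         min_seg = 20L) {
  # junction template positions strictly inside (a, b)
  jt <- numeric(0)
  for (j0 in cum0) {
    kmin <- ceiling((a - j0 + 1) / L)
    kmax <- floor((b - j0 - 1) / L)
    if (kmax >= kmin) jt <- c(jt, j0 + L * (kmin:kmax))
  }
  jt <- sort(jt)
  # shift each boundary by a uniform offset within the legal repeat window
  if (k_repeat > 0 && length(jt) > 0) {
    bounds <- c(jt, b)
    for (i in seq_along(jt)) {
      dmax <- min(k_repeat, bounds[i + 1] - jt[i] - 1)
      if (dmax > 0) jt[i] <- jt[i] + sample.int(dmax + 1L, 1L) - 1L
    }
    jt <- jt[jt > a & jt < b]
  }
  starts <- c(a, jt)
  ends <- c(jt, b)
  keep <- (ends - starts) >= min_seg
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(NULL)
  if (length(starts) > 2) { # read wraps more than once: keep the first wrap
    starts <- starts[1:2]; ends <- ends[1:2]
  }
  cp <- starts %% L
  fi <- findInterval(cp, cum0)
  list(
    u = starts, v = ends,
    chrom = frag_chrom[fi],
    gstart = frag_start[fi] + (cp - cum0[fi])
  )
}

cigar_smc <- function(leftS, M, rightS) {
  paste0(
    ifelse(leftS > 0, paste0(leftS, "S"), ""),
    M, "M",
    ifelse(rightS > 0, paste0(rightS, "S"), "")
  )
}

#' Simulate aligned circle-sequencing reads for a truth set
#'
#' Emulates the two library chemistries: for `"rca"` the template is a tandem
#' concatemer of the circle sequence (geometric copy count), for
#' `"tagmentation"` a two-copy template so fragments can wrap the junction
#' once. Library fragments of length Normal(`frag_mean`, `frag_sd`) are drawn
#' uniformly from the template; each yields one 150-bp-style read pair (read 1
#' forward, read 2 reverse). A read spanning a circle junction is emitted as a
#' primary alignment with a soft-clipped end plus a supplementary alignment of
#' the clipped part, each carrying the partner placement in its SA descriptor.
#' Records are stored in forward-genome orientation (SAM convention). Reads
#' wrapping the junction more than once keep only the first wrap (later wraps
#' are soft-clipped without a supplementary). Split segments shorter than
#' 20 bp are soft-clipped rather than emitted, as a practical aligner would.
#'
#' @param genome The (repeat-planted) `ecc_genome` returned by
#'   [make_truth_circles()].
#' @param truth The `ecc_truth` tibble.
#' @param params The same [sim_params()] used to build the truth set.
#' @return A tibble of class `ecc_alignments`, one row per alignment record
#'   (0-based half-open coordinates), with SA-descriptor columns
#'   (`sa_chrom`, `sa_start`, `sa_strand`, `sa_cigar`) linking split mates.
#' @export
simulate_alignments <- function(genome, truth, params) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  emit <- function(...) acc$rows[[length(acc$rows) + 1L]] <- list(...)

  with_seed(derive_seed(params$seed, "reads"), {
    for (cid in unique(truth$circle_id)) {
      circ <- truth[truth$circle_id == cid, ]
      simulate_circle_reads(genome, circ, params, emit)
    }
  })

  if (length(acc$rows) == 0) {
    return(empty_alignments())
  }
  rows <- acc$rows
  col <- function(field, proto) vapply(rows, `[[`, proto, field)
  df <- tibble(
    read_id = col("read_id", character(1)),
    in_pair = col("in_pair", integer(1)),
    chrom = col("chrom", character(1)),
    start = col("start", integer(1)),
    end = col("end", integer(1)),
    strand = col("strand", character(1)),
    cigar = col("cigar", character(1)),
    mapq = col("mapq", integer(1)),
    is_supplementary = col("is_supplementary", logical(1)),
    is_secondary = col("is_secondary", logical(1)),
    is_duplicate = col("is_duplicate", logical(1)),
    mate_chrom = col("mate_chrom", character(1)),
    mate_start = col("mate_start", integer(1)),
    seq = col("seq", character(1)),
    sa_chrom = col("sa_chrom", character(1)),
    sa_start = col("sa_start", integer(1)),
    sa_strand = col("sa_strand", character(1)),
    sa_cigar = col("sa_cigar", character(1)),
    circle_id = col("circle_id", character(1))
  )
  structure(df, class = c("ecc_alignments", class(df)))
}

empty_alignments <- function() {
  structure(
    tibble(
      read_id = character(), in_pair = integer(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      cigar = character(), mapq = integer(), is_supplementary = logical(),
      is_secondary = logical(), is_duplicate = logical(),
      mate_chrom = character(), mate_start = integer(), seq = character(),
      sa_chrom = character(), sa_start = integer(), sa_strand = character(),
      sa_cigar = character(), circle_id = character()
    ),
    class = c("ecc_alignments", class(tibble()))
  )
}

simulate_circle_reads <- function(genome, circ, params, emit) {
  m <- nrow(circ)
  lens <- circ$end - circ$start
  L <- sum(lens)
  cum0 <- cumsum(c(0L, lens))[seq_len(m)]
  R <- params$read_len
  circle_seq <- paste0(
    genome_subseq(genome, circ$chrom, circ$start, circ$end), collapse = ""
  )

  copies <- if (params$chemistry == "rca") {
    stats::rgeom(1, 1 / params$rca_mean_copies) + 1L
  } else {
    2L
  }
  copies <- max(copies, ceiling((params$frag_mean + 4 * params$frag_sd) / L) + 1L)
  template <- strrep(circle_seq, copies)
  t_len <- nchar(template)

  # Calibrate the number of library fragments so the expected number of
  # junction-spanning split reads per junction is `depth`. A read crossing a
  # junction yields a split record only when both segments reach min_seg
  # (20 bp), so the effective spanning window is R - 2*min_seg + 1; the
  # template has copies*m - 1 interior junctions and t_len - frag_mean + 1
  # legal fragment starts, each fragment contributing two reads.
  w_eff <- R - 2L * 20L + 1L
  n_junc <- copies * m - 1L
  n_starts <- max(1L, t_len - params$frag_mean + 1L)
  n_frag <- max(1L, ceiling(params$depth * m * n_starts / (2 * n_junc * w_eff)))
  if (params$depth == 0) n_frag <- 0L
  k_rep <- circ$repeat_len[1]

  for (fr in seq_len(n_frag)) {
    fl <- max(R, round(stats::rnorm(1, params$frag_mean, params$frag_sd)))
    fl <- min(fl, t_len)
    f <- sample.int(t_len - fl + 1L, 1L) - 1L
    is_dup <- params$duplicate_fraction > 0 &&
      stats::runif(1) < params$duplicate_fraction
    rid <- paste0(circ$circle_id[1], ":", fr)
    intervals <- list(c(f, f + R), c(f + fl - R, f + fl))
    segs <- purrr::map(intervals, function(iv) {
      segment_read(iv[1], iv[2], L, cum0, circ$chrom, circ$start, k_rep)
    })
    if (any(purrr::map_lgl(segs, is.null))) next
    for (w in 1:2) {
      emit_read(emit, genome, template, rid, w, intervals[[w]], segs[[w]],
                segs[[3 - w]], is_dup, circ$circle_id[1], params)
    }
  }
  invisible(NULL)
}

emit_read <- function(emit, genome, template, rid, in_pair, iv, seg, mate_seg,
                      is_dup, circle_id, params) {
  a <- iv[1]; b <- iv[2]
  R <- b - a
  seq <- substring(template, a + 1, b)
  if (params$error_rate > 0) {
    n_err <- stats::rbinom(1, R, params$error_rate)
    if (n_err > 0) {
      pos <- sample.int(R, n_err)
      for (p in pos) {
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(seq, p, p)), 1)
      }
    }
  }
  strand <- if (in_pair == 1L) "+" else "-"
  n_seg <- length(seg$u)
  primary_idx <- which.max(seg$v - seg$u)
  mate_primary <- which.max(mate_seg$v - mate_seg$u)
  mate_chrom <- mate_seg$chrom[mate_primary]
  mate_start <- mate_seg$gstart[mate_primary]
  for (si in seq_len(n_seg)) {
    other <- if (n_seg == 2) 3L - si else NA_integer_
    seg_len <- seg$v[si] - seg$u[si]
    emit(
      read_id = rid, in_pair = in_pair,
      chrom = seg$chrom[si],
      start = as.integer(seg$gstart[si]),
      end = as.integer(seg$gstart[si] + seg_len),
      strand = strand,
      cigar = cigar_smc(seg$u[si] - a, seg_len, b - seg$v[si]),
      mapq = 60L,
      is_supplementary = si != primary_idx,
      is_secondary = FALSE,
      is_duplicate = is_dup,
      mate_chrom = mate_chrom,
      mate_start = as.integer(mate_start),
      seq = seq,
      sa_chrom = if (is.na(other)) NA_character_ else seg$chrom[other],
      sa_start = if (is.na(other)) NA_integer_ else as.integer(seg$gstart[other]),
      sa_strand = if (is.na(other)) NA_character_ else strand,
      sa_cigar = if (is.na(other)) NA_character_ else
        cigar_smc(seg$u[other] - a, seg$v[other] - seg$u[other], b - seg$v[other]),
      circle_id = circle_id
    )
  }
}

#' Export simulated reads as FASTQ
#'
#' Writes the original read sequences (reverse-complemented back for
#' reverse-strand records) as a read-1/read-2 FASTQ pair, for integration
#' tests against a real aligner.
#'
#' @param alignments An `ecc_alignments` tibble.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @export
export_fastq <- function(alignments, prefix) {
  prim <- alignments |> filter(!.data$is_supplementary)
  paths <- character(2)
  for (w in 1:2) {
    rr <- prim |> filter(.data$in_pair == w)
    sq <- Biostrings::DNAStringSet(rr$seq)
    rev <- rr$strand == "-"
    sq[rev] <- Biostrings::reverseComplement(sq[rev])
    names(sq) <- rr$read_id
    paths[w] <- paste0(prefix, "_", w, ".fastq")
    Biostrings::writeXStringSet(sq, paths[w], format = "fastq")
  }
  invisible(paths)
}
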