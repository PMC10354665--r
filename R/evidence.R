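# Junction evidence: pairing split reads with their contiguously mapped mates,
# and base-pair correction of junction shifts caused by flanking direct repeats.

parse_smc <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  left <- purrr::map2_int(ops, lens, function(o, l) {
    i <- which(!o %in% c("S", "H"))[1]
    if (is.na(i) || i == 1L) 0L else sum(l[seq_len(i - 1L)])
  })
  tibble(
    left_clip = left,
    ref_width = GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  )
}

contiguous_cigar <- function(cigar, max_clip = 5L) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  purrr::map2_lgl(ops, lens, function(o, l) {
    core <- o[!o %in% c("S", "H")]
    identical(core, "M") && sum(l[o %in% c("S", "H")]) < max_clip
  })
}

#' Extract split-read junction evidence from alignments
#'
#' Collects read pairs where one read is uniquely and contiguously mapped (a
#' single match block, soft/hard clips under 5 bp, mapping quality at least
#' `min_mapq`) and the other read is a split read whose two segments (primary
#' plus the supplementary placement in its SA descriptor) map discordantly.
#' Secondary alignments are always discarded; duplicate-flagged reads are kept
#' by default so every junction can be discovered.
#'
#' @param alignments An `ecc_alignments` tibble ([read_alignments()] or
#'   [simulate_alignments()]).
#' @param min_mapq Uniqueness threshold for the mate anchor (default 20).
#' @param keep_duplicates Keep duplicate-flagged pairs (default `TRUE`).
#' @return A tibble of class `ecc_evidence`, one row per split read: placement
#'   A (the read-first segment, `a_*`), placement B (`b_*`), the mate anchor
#'   interval, and `repeat_shift_window` (`NA` until
#'   [correct_junction_for_direct_repeat()] is applied).
#' @export
extract_junction_evidence <- function(alignments, min_mapq = 20,
                                      keep_duplicates = TRUE,
                                      sample_id = "sample") {
  al <- alignments |> filter(!.data$is_secondary)
  if (nrow(al) == 0) return(empty_evidence())

  supp <- al |> filter(.data$is_supplementary)
  prim <- al |> filter(!.data$is_supplementary)
  orphan <- supp |>
    anti_join(prim, by = c("read_id", "in_pair"))
  if (nrow(orphan) > 0) {
    rlang::inform(paste0("skipped ", nrow(orphan),
                         " supplementary record(s) without a reachable primary"))
  }

  split_prim <- prim |> filter(!is.na(.data$sa_chrom))
  if (!keep_duplicates) split_prim <- split_prim |> filter(!.data$is_duplicate)
  if (nrow(split_prim) == 0) return(empty_evidence())

  mates <- prim |>
    filter(is.na(.data$sa_chrom), .data$mapq >= min_mapq,
           contiguous_cigar(.data$cigar)) |>
    transmute(.data$read_id, mate_pair = .data$in_pair,
              mate_chrom = .data$chrom, mate_start = .data$start,
              mate_end = .data$end, mate_mapq = .data$mapq)

  pc <- parse_smc(split_prim$cigar)
  sc <- parse_smc(split_prim$sa_cigar)
  ev <- split_prim |>
    mutate(
      p_left = pc$left_clip, p_end = .data$start + pc$ref_width,
      s_left = sc$left_clip, s_end = .data$sa_start + sc$ref_width
    )
  a_first <- ev$p_left <= ev$s_left # primary segment comes first in the read
  ev <- tibble(
    read_id = ev$read_id,
    sample_id = sample_id,
    is_duplicate = ev$is_duplicate,
    a_chrom = ifelse(a_first, ev$chrom, ev$sa_chrom),
    a_start = ifelse(a_first, ev$start, ev$sa_start),
    a_end = ifelse(a_first, ev$p_end, ev$s_end),
    a_strand = ifelse(a_first, ev$strand, ev$sa_strand),
    b_chrom = ifelse(a_first, ev$sa_chrom, ev$chrom),
    b_start = ifelse(a_first, ev$sa_start, ev$start),
    b_end = ifelse(a_first, ev$s_end, ev$p_end),
    b_strand = ifelse(a_first, ev$sa_strand, ev$strand),
    split_pair = ev$in_pair,
    circle_id = if ("circle_id" %in% names(ev)) ev$circle_id else NA_character_
  ) |>
    inner_join(mates, by = "read_id", relationship = "many-to-many") |>
    filter(.data$mate_pair != .data$split_pair) |>
    select(-"mate_pair") |>
    mutate(repeat_shift_window = NA_integer_)
  structure(ev, class = c("ecc_evidence", class(ev)))
}

empty_evidence <- function() {
  structure(
    tibble(
      read_id = character(), sample_id = character(), is_duplicate = logical(),
      a_chrom = character(), a_start = integer(), a_end = integer(),
      a_strand = character(), b_chrom = character(), b_start = integer(),
      b_end = integer(), b_strand = character(), split_pair = integer(),
      circle_id = character(), mate_chrom = character(),
      mate_start = integer(), mate_end = integer(), mate_mapq = integer(),
      repeat_shift_window = integer()
    ),
    class = c("ecc_evidence", class(tibble()))
  )
}

# Longest common prefix of two strings (byte-wise, exact match only).
lcp_len <- function(x, y) {
  rx <- charToRaw(x); ry <- charToRaw(y)
  n <- min(length(rx), length(ry))
  if (n == 0) return(0L)
  neq <- which(rx[seq_len(n)] != ry[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Correct junction placement for flanking direct repeats
#'
#' A direct repeat flanking a circle junction makes the exact split position
#' ambiguous: the aligner may place the boundary at any of `k + 1` equivalent
#' offsets. This operation computes, for each evidence row, the maximal window
#' of equivalent junction offsets by extending exact sequence matches across
#' both placements, then shifts both breakpoints to the canonical leftmost
#' offset. It is idempotent, and all legal offsets of the same junction
#' canonicalize to identical coordinates.
#'
#' @param evidence An `ecc_evidence` tibble.
#' @param genome The reference `ecc_genome`.
#' @param max_shift Safety cap on the repeat search (default 50 bp).
#' @return The evidence with canonicalized `a_end` / `b_start` and
#'   `repeat_shift_window` filled in: the number of equivalent junction
#'   offsets beyond the canonical one, i.e. the flanking direct-repeat
#'   length; 0 means no flanking homology.
#' @export
correct_junction_for_direct_repeat <- function(evidence, genome,
                                               max_shift = 50L) {
  if (nrow(evidence) == 0) return(evidence)
  n <- nrow(evidence)
  l_ext <- integer(n); r_ext <- integer(n)
  for (i in seq_len(n)) {
    ae <- evidence$a_end[i]; bs <- evidence$b_start[i]
    ac <- evidence$a_chrom[i]; bc <- evidence$b_chrom[i]
    # leftward: common suffix of the sequences ending at a_end and b_start
    wl <- min(max_shift, ae, bs)
    l_ext[i] <- if (wl > 0) {
      lcp_len(str_rev(genome_subseq(genome, ac, ae - wl, ae)),
              str_rev(genome_subseq(genome, bc, bs - wl, bs)))
    } else 0L
    # rightward: common prefix of the sequences starting at a_end and b_start
    wr <- min(max_shift, chrom_length(genome, ac) - ae,
              chrom_length(genome, bc) - bs)
    r_ext[i] <- if (wr > 0) {
      lcp_len(genome_subseq(genome, ac, ae, ae + wr),
              genome_subseq(genome, bc, bs, bs + wr))
    } else 0L
  }
  evidence |>
    mutate(
      a_end = .data$a_end - l_ext,
      b_start = .data$b_start - l_ext,
      repeat_shift_window = as.integer(l_ext + r_ext)
    )
}
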