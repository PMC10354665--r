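# Shared fixture builders. Everything is generated in code at test time.

# Small two/three-chromosome genome (50 kb chromosomes keep tests fast).
tiny_genome <- function(seed = 1, n_chrom = 2, len = 50000) {
  make_genome(seed, n_chrom, len)
}

# Genome stub with chromosome table only (for operations that never touch
# sequence, e.g. binning and random region placement).
coords_genome <- function(lengths) {
  structure(
    list(
      chroms = tibble::tibble(
        chrom = paste0("chr", seq_along(lengths)),
        length = as.integer(lengths)
      ),
      seq = NULL, tracks = NULL
    ),
    class = "ecc_genome"
  )
}

# Genome with hand-specified sequence and tracks (annotation unit tests).
manual_genome <- function(seqs, tracks = list()) {
  defaults <- list(
    genes = tibble::tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           gene_id = character()),
    exons = tibble::tibble(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           gene_id = character()),
    five_utr = tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              gene_id = character()),
    three_utr = tibble::tibble(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               gene_id = character()),
    cpg_islands = tibble::tibble(chrom = character(), start = integer(),
                                 end = integer()),
    repeats = tibble::tibble(chrom = character(), start = integer(),
                             end = integer(), class = character()),
    enhancers = tibble::tibble(chrom = character(), start = integer(),
                               end = integer())
  )
  defaults[names(tracks)] <- tracks
  structure(
    list(
      chroms = tibble::tibble(chrom = names(seqs),
                              length = nchar(unname(seqs))),
      seq = seqs,
      tracks = defaults
    ),
    class = "ecc_genome"
  )
}

# One simulated dataset: genome + truth + alignments, defaulting to a small
# mixed single/multi circle population at calling depth.
sim_dataset <- function(seed = 1, n_chrom = 3, len = 120000, n_single = 10,
                        n_multi2 = 0, n_multi3 = 0, depth = 30,
                        repeat_lens = 0:10, ...) {
  g <- make_genome(seed, n_chrom, len)
  p <- sim_params(seed = seed, n_single = n_single, n_multi2 = n_multi2,
                  n_multi3 = n_multi3, depth = depth,
                  repeat_lens = repeat_lens, ...)
  planted <- make_truth_circles(g, p)
  al <- simulate_alignments(planted$genome, planted$truth, p)
  list(genome = planted$genome, truth = planted$truth, alignments = al,
       params = p)
}

# Evidence -> corrected -> calls in one step.
call_dataset <- function(ds, min_support = 1, keep_duplicates = TRUE) {
  ev <- extract_junction_evidence(ds$alignments,
                                  keep_duplicates = keep_duplicates)
  ev <- correct_junction_for_direct_repeat(ev, ds$genome)
  list(evidence = ev,
       calls = call_single_fragment(ev, ds$genome, min_support = min_support))
}

# Hand-built alignment rows (for constructed SAM-level cases).
align_row <- function(read_id, in_pair, chrom, start, cigar, strand = "+",
                      mapq = 60L, supplementary = FALSE, duplicate = FALSE,
                      mate_chrom = chrom, mate_start = 0L, seq = NULL,
                      sa_chrom = NA_character_, sa_start = NA_integer_,
                      sa_strand = NA_character_, sa_cigar = NA_character_) {
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  read_w <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  tibble::tibble(
    read_id = read_id, in_pair = as.integer(in_pair), chrom = chrom,
    start = as.integer(start), end = as.integer(start + ref_w),
    strand = strand, cigar = cigar, mapq = as.integer(mapq),
    is_supplementary = supplementary, is_secondary = FALSE,
    is_duplicate = duplicate, mate_chrom = mate_chrom,
    mate_start = as.integer(mate_start),
    seq = seq %||% strrep("A", read_w),
    sa_chrom = sa_chrom, sa_start = as.integer(sa_start),
    sa_strand = sa_strand, sa_cigar = sa_cigar,
    circle_id = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal CIGAR reader used by simulator-facing tests (independent of the
# package's own CIGAR handling).
parse_cigar_for_test <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  left <- if (ops[1] == "S") lens[1] else 0L
  list(left = left, ops = ops, lens = lens)
}

empty_al <- function() {
  align_row("x", 1, "chr1", 0, "10M")[0, ]
}

# split read: first 75 bp at chr1:1000 (cigar 75M75S), rest at chr1:500
# (75S75M); mate read 2 contiguous 150M at chr1:700 (inside [500, 1075)).
hand_built_split_pair <- function() {
  rbind(
    align_row("r1", 1, "chr1", 1000, "75M75S",
              sa_chrom = "chr1", sa_start = 500L, sa_strand = "+",
              sa_cigar = "75S75M"),
    align_row("r1", 1, "chr1", 500, "75S75M", supplementary = TRUE,
              sa_chrom = "chr1", sa_start = 1000L, sa_strand = "+",
              sa_cigar = "75M75S"),
    align_row("r1", 2, "chr1", 700, "150M", strand = "-")
  )
}

# A constructed circle whose junction carries an exact k-bp direct repeat,
# with mismatching bases pinning the homology window.
repeat_junction_genome <- function(k, circle_start = 200L, circle_end = 500L) {
  set.seed(99 + k)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  if (k > 0) {
    donor <- substr(seq, circle_start + 1, circle_start + k)
    substr(seq, circle_end + 1, circle_end + k) <- donor
  }
  pin <- function(s, pos, avoid) {
    cand <- setdiff(c("A", "C", "G", "T"), avoid)
    substr(s, pos + 1, pos + 1) <- cand[1]
    s
  }
  # pin both edges so the homology window is exactly k
  seq <- pin(seq, circle_end + k, substr(seq, circle_start + k + 1,
                                         circle_start + k + 1))
  seq <- pin(seq, circle_start - 1, substr(seq, circle_end, circle_end))
  list(genome = manual_genome(c(chr1 = seq)), circle_start = circle_start,
       circle_end = circle_end, k = as.integer(k))
}

junction_evidence_at_offset <- function(g, offset) {
  ev_row(
    a_chrom = "chr1", a_start = g$circle_end - 75L + offset,
    a_end = g$circle_end + offset,
    b_chrom = "chr1", b_start = g$circle_start + offset,
    b_end = g$circle_start + 75L + offset
  )
}

ev_row <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  tibble::tibble(
    read_id = "r", sample_id = "s", is_duplicate = FALSE,
    a_chrom = a_chrom, a_start = as.integer(a_start),
    a_end = as.integer(a_end), a_strand = "+",
    b_chrom = b_chrom, b_start = as.integer(b_start),
    b_end = as.integer(b_end), b_strand = "+", split_pair = 1L,
    circle_id = NA_character_, mate_chrom = a_chrom,
    mate_start = as.integer(b_start), mate_end = as.integer(b_start + 150L),
    mate_mapq = 60L, repeat_shift_window = NA_integer_
  )
}

chain_evidence <- function(a_chrom, a_end, b_chrom, b_start) {
  tibble::tibble(
    read_id = paste0(a_chrom, b_chrom), sample_id = "s",
    is_duplicate = FALSE, a_chrom = a_chrom, a_start = a_end - 75L,
    a_end = a_end, a_strand = "+", b_chrom = b_chrom, b_start = b_start,
    b_end = b_start + 75L, b_strand = "+", split_pair = 1L,
    circle_id = NA_character_, mate_chrom = a_chrom, mate_start = a_end - 100L,
    mate_end = a_end, mate_mapq = 60L, repeat_shift_window = 0L
  )
}

# Memoized mixed dataset reused across test files (simulation is the
# expensive step; the fixture is deterministic, so sharing is safe).
.shared_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared_cache$ds)) {
    .shared_cache$ds <- sim_dataset(
      seed = 5, n_chrom = 3, len = 150000, n_single = 20, n_multi2 = 4,
      n_multi3 = 2, depth = 30
    )
  }
  .shared_cache$ds
}
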