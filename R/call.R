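# Circle calling: single-fragment calls from same-chromosome junctions,
# confident regions and multi-fragment cycles from cross-chromosomal junctions.

#' Call single-fragment eccDNA from corrected junction evidence
#'
#' Groups canonicalized evidence by exact (chrom, start, end). A group is a
#' candidate circle when both split-read segments lie on one chromosome and
#' strand in head-to-tail circular orientation (the read-first segment maps
#' downstream of the read-second segment: the start of the second mapping is
#' the circle start, the end of the first mapping is the circle end) and the
#' mate anchor overlaps the circle interval. Groups with at least
#' `min_support` distinct supporting reads become calls. Evidence on two
#' chromosomes is left for [extract_confident_regions()]; strand-inconsistent
#' (inverted) junctions are returned in the `"inverted"` attribute, not
#' called.
#'
#' @param evidence An `ecc_evidence` tibble, canonicalized by
#'   [correct_junction_for_direct_repeat()].
#' @param genome The reference `ecc_genome` (bounds checking).
#' @param min_support Minimum split-read support per call (default 1).
#' @return A tibble of class `ecc_calls`, sorted by (chrom, start, end):
#'   `chrom`, `start`, `end`, `size`, `n_split_support`, `n_evidence_reads`,
#'   `direct_repeat_len`, `sample_id`.
#' @export
call_single_fragment <- function(evidence, genome, min_support = 1) {
  same <- evidence |>
    filter(.data$a_chrom == .data$b_chrom)
  inverted <- same |> filter(.data$a_strand != .data$b_strand)
  circ <- same |>
    filter(
      .data$a_strand == .data$b_strand,
      .data$b_start < .data$a_start,        # discordant, circular orientation
      .data$b_start < .data$a_end,
      .data$mate_chrom == .data$a_chrom,    # mate anchor overlaps the circle
      .data$mate_start < .data$a_end,
      .data$mate_end > .data$b_start
    )
  calls <- circ |>
    group_by(chrom = .data$a_chrom, start = .data$b_start, end = .data$a_end,
             sample_id = .data$sample_id) |>
    summarise(
      n_split_support = n_distinct(.data$read_id),
      n_evidence_reads = n(),
      direct_repeat_len = max(.data$repeat_shift_window, 0L),
      .groups = "drop"
    ) |>
    filter(.data$n_split_support >= min_support,
           .data$start >= 0, .data$end <= chrom_length(genome, .data$chrom)) |>
    mutate(size = .data$end - .data$start, .after = "end") |>
    arrange(match(.data$chrom, genome$chroms$chrom), .data$start, .data$end) |>
    select("chrom", "start", "end", "size", "n_split_support",
           "n_evidence_reads", "direct_repeat_len", "sample_id")
  out <- structure(calls, class = c("ecc_calls", class(calls)))
  attr(out, "inverted") <- inverted
  out
}

#' Render report names for calls overlapping genes
#'
#' Formats each call the way loci are printed in reports:
#' `"<gene>^circle <start>-<end>"` with 1-based inclusive coordinates and
#' thousands separators (e.g. `"SBF1^circle 50,447,497-50,447,834"`); calls
#' not overlapping a gene use their chromosome instead of a gene symbol.
#'
#' @param calls An `ecc_calls` tibble.
#' @param genes Gene intervals (`chrom`, `start`, `end`, `gene_id`).
#' @return Character vector of display names, en-dash separated.
#' @export
format_call_names <- function(calls, genes) {
  hits <- GenomicRanges::findOverlaps(as_granges0(calls), as_granges0(genes))
  label <- calls$chrom
  first <- !duplicated(S4Vectors::queryHits(hits))
  label[S4Vectors::queryHits(hits)[first]] <-
    genes$gene_id[S4Vectors::subjectHits(hits)[first]]
  paste0(
    label, "^circle ",
    format(calls$start + 1L, big.mark = ",", scientific = FALSE, trim = TRUE),
    "–",
    format(calls$end, big.mark = ",", scientific = FALSE, trim = TRUE)
  )
}

#' Extract confident regions bounded by cross-chromosomal junctions
#'
#' A confident region is a genomic interval whose every base has read coverage
#' of at least one and whose start and end each coincide (after direct-repeat
#' correction) with a split-read breakpoint joined to a different chromosome.
#' Candidate boundaries are taken from the cross-chromosomal evidence; each
#' start breakpoint is paired with the nearest downstream end breakpoint.
#'
#' @param evidence Corrected `ecc_evidence` (cross-chromosomal rows are used).
#' @param alignments The full alignment tibble, for the coverage mask.
#' @param genome The reference `ecc_genome`.
#' @param max_region_len Regions longer than this are rejected (default 100 kb).
#' @return Tibble of class `ecc_regions`: `chrom`, `start`, `end`,
#'   `left_partner_chrom`, `left_partner_pos`, `right_partner_chrom`,
#'   `right_partner_pos`, `left_support`, `right_support`,
#'   `covered_fraction` (always 1 for emitted regions).
#' @export
extract_confident_regions <- function(evidence, alignments, genome,
                                      max_region_len = 100000) {
  cross <- evidence |> filter(.data$a_chrom != .data$b_chrom)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    left_partner_chrom = character(), left_partner_pos = integer(),
    right_partner_chrom = character(), right_partner_pos = integer(),
    left_support = integer(), right_support = integer(),
    covered_fraction = numeric()
  )
  if (nrow(cross) == 0) {
    return(structure(empty, class = c("ecc_regions", class(empty))))
  }

  # breakpoints: b_start opens a region (joined from a_chrom), a_end closes
  # one (joined to b_chrom)
  opens <- cross |>
    count(chrom = .data$b_chrom, pos = .data$b_start,
          partner_chrom = .data$a_chrom, partner_pos = .data$a_end) |>
    group_by(.data$chrom, .data$pos) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup()
  # direct-repeat window at each opening breakpoint: the first w bases of the
  # region are sequence-identical to the partner's downstream flank, so the
  # aligner may place junction reads on either copy; the coverage requirement
  # starts after the window
  open_win <- cross |>
    group_by(chrom = .data$b_chrom, pos = .data$b_start) |>
    summarise(win = max(coalesce(.data$repeat_shift_window, 0L)),
              .groups = "drop")
  opens <- opens |> left_join(open_win, by = c("chrom", "pos")) |>
    mutate(win = coalesce(.data$win, 0L))
  closes <- cross |>
    count(chrom = .data$a_chrom, pos = .data$a_end,
          partner_chrom = .data$b_chrom, partner_pos = .data$b_start) |>
    group_by(.data$chrom, .data$pos) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup()

  cov <- alignment_coverage(alignments, genome)
  rows <- list()
  for (cc in unique(opens$chrom)) {
    op <- opens |> filter(.data$chrom == cc) |> arrange(.data$pos)
    cl <- closes |> filter(.data$chrom == cc) |> arrange(.data$pos)
    if (nrow(cl) == 0) next
    for (i in seq_len(nrow(op))) {
      j <- which(cl$pos > op$pos[i])[1]
      if (is.na(j)) next
      s <- op$pos[i]; e <- cl$pos[j]
      if (e - s > max_region_len) {
        rlang::inform(paste0("rejected candidate region ", cc, ":", s, "-", e,
                             " (exceeds max_region_len)"))
        next
      }
      covered <- region_fully_covered(cov, cc, min(s + op$win[i], e - 1L), e)
      if (!covered) next
      rows[[length(rows) + 1L]] <- tibble(
        chrom = cc, start = s, end = e,
        left_partner_chrom = op$partner_chrom[i],
        left_partner_pos = op$partner_pos[i],
        right_partner_chrom = cl$partner_chrom[j],
        right_partner_pos = cl$partner_pos[j],
        left_support = op$n[i], right_support = cl$n[j],
        covered_fraction = 1
      )
    }
  }
  out <- if (length(rows)) purrr::list_rbind(rows) else empty
  out <- out |> arrange(match(.data$chrom, genome$chroms$chrom), .data$start)
  structure(out, class = c("ecc_regions", class(out)))
}

alignment_coverage <- function(alignments, genome) {
  al <- alignments |> filter(!.data$is_secondary)
  gr <- as_granges0(al[, c("chrom", "start", "end")], genome)
  GenomicRanges::coverage(gr)
}

region_fully_covered <- function(cov, chrom, start, end) {
  if (!chrom %in% names(cov)) return(FALSE)
  v <- cov[[chrom]]
  if (end > length(v)) return(FALSE)
  min(S4Vectors::runValue(IRanges::Views(v, start + 1L, end))[[1]]) >= 1
}

#' Assemble multi-chromosomal-fragment circles from confident regions
#'
#' Builds a directed graph whose nodes are confident regions and whose edges
#' are cross-chromosomal junctions (evidence joining one region's end to
#' another region's start), then reports simple cycles of length 2 and 3 that
#' visit pairwise distinct chromosomes. Cycles are reported once, rotated so
#' the lexicographically smallest fragment comes first; regions shared by
#' several cycles are all reported and flagged.
#'
#' @param regions `ecc_regions` from [extract_confident_regions()].
#' @param evidence Corrected `ecc_evidence`.
#' @return Tibble of class `ecc_cycles`, one row per fragment: `cycle_id`,
#'   `n_fragments`, `frag_index`, `chrom`, `start`, `end`,
#'   `junction_support` (reads supporting the junction leaving this
#'   fragment), `shared_region`.
#' @export
assemble_multifragment <- function(regions, evidence) {
  empty <- tibble(
    cycle_id = character(), n_fragments = integer(), frag_index = integer(),
    chrom = character(), start = integer(), end = integer(),
    junction_support = integer(), shared_region = logical()
  )
  if (nrow(regions) == 0) {
    return(structure(empty, class = c("ecc_cycles", class(empty))))
  }
  cross <- evidence |> filter(.data$a_chrom != .data$b_chrom)
  reg <- regions |> mutate(node = row_number())
  # edge i -> j: a junction from region i's end into region j's start
  edges <- cross |>
    inner_join(reg |> select(from = "node", a_chrom = "chrom", a_end = "end"),
               by = c("a_chrom", "a_end")) |>
    inner_join(reg |> select(to = "node", b_chrom = "chrom", b_start = "start"),
               by = c("b_chrom", "b_start")) |>
    count(.data$from, .data$to, name = "support")

  cycles <- list()
  add_cycle <- function(nodes, supports) {
    key <- order(reg$chrom[nodes], reg$start[nodes])[1]
    rot <- c(seq_along(nodes), seq_along(nodes))[key:(key + length(nodes) - 1)]
    cycles[[length(cycles) + 1L]] <<-
      list(nodes = nodes[rot], supports = supports[rot])
  }
  e2 <- edges |>
    inner_join(edges, by = c("from" = "to", "to" = "from"),
               suffix = c("", ".back")) |>
    filter(.data$from < .data$to,
           reg$chrom[.data$from] != reg$chrom[.data$to])
  for (i in seq_len(nrow(e2))) {
    add_cycle(c(e2$from[i], e2$to[i]), c(e2$support[i], e2$support.back[i]))
  }
  e3 <- edges |>
    rename(n1 = "from", n2 = "to", s1 = "support") |>
    inner_join(edges |> rename(n2 = "from", n3 = "to", s2 = "support"),
               by = "n2") |>
    inner_join(edges |> rename(n3 = "from", n1_back = "to", s3 = "support"),
               by = "n3") |>
    filter(.data$n1_back == .data$n1,
           .data$n1 < .data$n2, .data$n1 < .data$n3, .data$n2 != .data$n3) |>
    filter(reg$chrom[.data$n1] != reg$chrom[.data$n2],
           reg$chrom[.data$n1] != reg$chrom[.data$n3],
           reg$chrom[.data$n2] != reg$chrom[.data$n3])
  for (i in seq_len(nrow(e3))) {
    add_cycle(c(e3$n1[i], e3$n2[i], e3$n3[i]),
              c(e3$s1[i], e3$s2[i], e3$s3[i]))
  }
  if (length(cycles) == 0) {
    return(structure(empty, class = c("ecc_cycles", class(empty))))
  }
  node_use <- table(unlist(purrr::map(cycles, "nodes")))
  out <- purrr::list_rbind(purrr::map(seq_along(cycles), function(k) {
    cy <- cycles[[k]]
    tibble(
      cycle_id = sprintf("cycle%03d", k),
      n_fragments = length(cy$nodes),
      frag_index = seq_along(cy$nodes),
      chrom = reg$chrom[cy$nodes],
      start = reg$start[cy$nodes],
      end = reg$end[cy$nodes],
      junction_support = as.integer(cy$supports),
      shared_region = as.vector(node_use[as.character(cy$nodes)] > 1)
    )
  }))
  structure(out, class = c("ecc_cycles", class(out)))
}
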