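# Genomic annotation of junction loci: derived tracks, 1-Mb bin
# distributions, multi-label classification and double-normalized enrichment.

#' Derive the full annotation class set from genome tracks
#'
#' Expands the raw tracks into the class vocabulary used for junction
#' annotation: gene structure (5'UTR, exon, intron, 3'UTR), promoter regions
#' (2 kb upstream of genes, strand-aware), immediate downstream regions (2 kb
#' downstream), CpG islands with their 2-kb upstream/downstream flanks,
#' distal intergenic regions (the genome minus all genic and aforementioned
#' regions), every repeat class present, and enhancers. All intervals are
#' clipped to chromosome bounds.
#'
#' @param genome An `ecc_genome` (or a list with the same `tracks` layout).
#' @param flank_bp Promoter/downstream and CpG flank width (default 2000).
#' @return Named list of interval tibbles (`chrom`, `start`, `end`), class
#'   `ecc_annotation`.
#' @export
derive_tracks <- function(genome, flank_bp = 2000L) {
  tr <- genome$tracks
  clip <- function(df) {
    df |>
      mutate(
        start = pmax(.data$start, 0L),
        end = pmin(.data$end, chrom_length(genome, .data$chrom))
      ) |>
      filter(.data$end > .data$start)
  }
  genes <- tr$genes
  plus <- genes$strand == "+"
  promoter <- tibble(
    chrom = genes$chrom,
    start = ifelse(plus, genes$start - flank_bp, genes$end),
    end = ifelse(plus, genes$start, genes$end + flank_bp)
  )
  downstream <- tibble(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, genes$start - flank_bp),
    end = ifelse(plus, genes$end + flank_bp, genes$start)
  )
  cpg <- tr$cpg_islands
  cpg_up <- tibble(chrom = cpg$chrom, start = cpg$start - flank_bp, end = cpg$start)
  cpg_down <- tibble(chrom = cpg$chrom, start = cpg$end, end = cpg$end + flank_bp)

  introns <- {
    g <- GenomicRanges::reduce(as_granges0(genes))
    e <- GenomicRanges::reduce(as_granges0(tr$exons))
    granges_to_tibble0(GenomicRanges::setdiff(g, e))
  }

  ann <- list(
    five_utr = tr$five_utr |> select("chrom", "start", "end"),
    exon = tr$exons |> select("chrom", "start", "end"),
    intron = introns,
    three_utr = tr$three_utr |> select("chrom", "start", "end"),
    promoter_2kb = promoter,
    downstream_2kb = downstream,
    CpG_island = cpg,
    CpG_up2kb = cpg_up,
    CpG_down2kb = cpg_down
  )
  ann <- purrr::map(ann, clip)

  # distal intergenic: whatever the genic/CpG/derived classes do not cover
  covered <- GenomicRanges::reduce(as_granges0(purrr::list_rbind(ann)))
  whole <- as_granges0(
    tibble(chrom = genome$chroms$chrom, start = 0L, end = genome$chroms$length)
  )
  ann$distal_intergenic <- granges_to_tibble0(
    GenomicRanges::setdiff(whole, covered)
  )

  for (cl in sort(unique(tr$repeats$class))) {
    ann[[cl]] <- tr$repeats |>
      filter(.data$class == cl) |>
      select("chrom", "start", "end")
  }
  ann$enhancer <- tr$enhancers |> select("chrom", "start", "end")
  structure(ann, class = c("ecc_annotation", "list"))
}

# Junction loci of a call set as point positions (0-based base coordinates):
# the start breakpoint, plus (mode "both") the end breakpoint's final base.
junction_loci <- function(calls, loci = c("both", "start")) {
  loci <- match.arg(loci)
  out <- tibble(chrom = calls$chrom, pos = calls$start)
  if (loci == "both") {
    out <- bind_rows(out, tibble(chrom = calls$chrom, pos = calls$end - 1L))
  }
  out |> mutate(locus_id = row_number(), .before = 1)
}

#' Classify junction loci against the annotation set
#'
#' Multi-label: each junction locus (the start breakpoint plus, by default,
#' the end breakpoint as a second locus) receives every class whose intervals
#' contain it; a locus in none of the genic/CpG/derived classes falls in
#' `distal_intergenic` by construction of that track.
#'
#' @param calls An `ecc_calls` tibble.
#' @param annotation From [derive_tracks()].
#' @param loci `"both"` breakpoints (default) or `"start"` only.
#' @return Long tibble: `locus_id`, `chrom`, `pos`, `class`.
#' @export
classify_junction <- function(calls, annotation, loci = c("both", "start")) {
  pts <- junction_loci(calls, loci)
  gr_pts <- GenomicRanges::GRanges(
    pts$chrom, IRanges::IRanges(pts$pos + 1L, width = 1L)
  )
  purrr::list_rbind(purrr::imap(unclass(annotation), function(df, cl) {
    if (nrow(df) == 0) return(NULL)
    hits <- GenomicRanges::findOverlaps(gr_pts, as_granges0(df))
    idx <- unique(S4Vectors::queryHits(hits))
    if (length(idx) == 0) return(NULL)
    pts[idx, ] |> mutate(class = cl)
  }))
}

#' Element enrichment with double normalization
#'
#' For each annotation class, the junction count is normalized by the total
#' junction count and by the class's merged coverage of the genome:
#' `score = (junction_count / total_junctions) / (class_bp / genome_bp)`.
#' Under uniform junction placement the expected score is 1 for every class.
#'
#' @param calls An `ecc_calls` tibble.
#' @param annotation From [derive_tracks()].
#' @param genome The reference `ecc_genome`.
#' @param loci `"both"` breakpoints (default) or `"start"` only.
#' @return Tibble of class `ecc_enrichment`: `class`, `junction_count`,
#'   `total_junctions`, `class_coverage_bp`, `genome_bp`, `normalized_score`.
#' @export
element_enrichment <- function(calls, annotation, genome,
                               loci = c("both", "start")) {
  pts <- junction_loci(calls, loci)
  labels <- classify_junction(calls, annotation, loci)
  genome_bp <- genome_length(genome)
  cov <- purrr::map_dbl(unclass(annotation), merged_coverage_bp)
  zero <- names(cov)[cov == 0]
  if (length(zero) > 0) {
    rlang::warn(paste("classes with zero coverage excluded:",
                      paste(zero, collapse = ", ")))
  }
  counts <- labels |> count(.data$class, name = "junction_count")
  out <- tibble(class = names(cov)[cov > 0],
                class_coverage_bp = unname(cov[cov > 0])) |>
    left_join(counts, by = "class") |>
    mutate(
      junction_count = coalesce(.data$junction_count, 0L),
      total_junctions = nrow(pts),
      genome_bp = genome_bp,
      normalized_score = (.data$junction_count / .data$total_junctions) /
        (.data$class_coverage_bp / .data$genome_bp)
    ) |>
    select("class", "junction_count", "total_junctions", "class_coverage_bp",
           "genome_bp", "normalized_score")
  structure(out, class = c("ecc_enrichment", class(out)))
}

#' Genome-wide bin distribution of calls
#'
#' Tiles every chromosome with non-overlapping bins (default 1 Mb, trailing
#' partial bins kept), assigns each call to the bin containing its start
#' breakpoint, and normalizes counts by the total.
#'
#' @param calls An `ecc_calls` tibble (must be nonempty).
#' @param genome The reference `ecc_genome`.
#' @param bin_width Bin width in bp (default 1e6).
#' @return Tibble of class `ecc_bins`: `chrom`, `bin_start`, `bin_end`,
#'   `count`, `fraction`; `bin_width` stored as an attribute.
#' @export
bin_distribution <- function(calls, genome, bin_width = 1e6) {
  assert_that(nrow(calls) > 0, "bin_distribution: empty call set")
  bins <- genome$chroms |>
    rowwise() |>
    reframe(
      chrom = .data$chrom,
      bin_start = seq(0L, .data$length - 1L, by = bin_width)
    ) |>
    mutate(bin_end = pmin(.data$bin_start + bin_width,
                          chrom_length(genome, .data$chrom)))
  counted <- calls |>
    mutate(bin_start = (.data$start %/% bin_width) * bin_width) |>
    count(.data$chrom, .data$bin_start)
  out <- bins |>
    left_join(counted, by = c("chrom", "bin_start")) |>
    mutate(count = coalesce(.data$n, 0L), fraction = .data$count / sum(.data$count)) |>
    select("chrom", "bin_start", "bin_end", "count", "fraction")
  attr(out, "bin_width") <- bin_width
  structure(out, class = c("ecc_bins", class(out)))
}

#' Compare two bin distributions with a two-sample KS test
#'
#' Treats each distribution as an empirical sample over the ordered genome
#' bins (every call contributes its bin's index once) and applies the
#' two-sample Kolmogorov-Smirnov test, so two distributions concentrated in
#' different single bins give D = 1 and identical distributions give D = 0.
#' Requires identical bin tilings.
#'
#' @param a,b `ecc_bins` tibbles over the same genome and bin width.
#' @return An `ecc_test` tibble (see [ks_two_sample()]).
#' @export
compare_bin_distributions <- function(a, b) {
  assert_that(
    identical(a[, c("chrom", "bin_start", "bin_end")],
              b[, c("chrom", "bin_start", "bin_end")]),
    "bin tilings differ; recompute both on the same genome and bin width"
  )
  idx <- seq_len(nrow(a))
  ks_two_sample(rep(idx, a$count), rep(idx, b$count))
}
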