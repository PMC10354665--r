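# Gene-level eccDNA abundance from supportive split reads, recurrence-based
# highly-abundant sets, biomarker intersection, and exports for external
# differential-abundance / motif tools.

#' Total split reads per sample
#'
#' Convenience count of distinct split reads per sample from a junction
#' evidence table; the denominator of the per-million normalization.
#'
#' @param evidence An `ecc_evidence` tibble (may combine samples).
#' @return Named numeric vector, one total per `sample_id`.
#' @export
count_split_reads <- function(evidence) {
  tot <- evidence |>
    group_by(.data$sample_id) |>
    summarise(n = n_distinct(.data$read_id), .groups = "drop")
  stats::setNames(as.numeric(tot$n), tot$sample_id)
}

#' Gene-level eccDNA abundance matrix from supportive split reads
#'
#' A gene accrues the split-read support of every call whose interval
#' overlaps the gene body (a call overlapping k genes contributes to all k).
#' Normalized counts are counts per million total split reads of the sample.
#'
#' @param calls An `ecc_calls` tibble covering one or more samples
#'   (`sample_id`, `n_split_support`).
#' @param genes Gene intervals (`chrom`, `start`, `end`, `gene_id`).
#' @param total_split_reads Named vector of per-sample totals (> 0), e.g.
#'   from [count_split_reads()].
#' @param extend_bp Optional symmetric gene-body extension in bp (default 0).
#' @return List of class `ecc_gene_abundance`: `raw` and `normalized`
#'   (tibbles, `gene_id` x one column per sample) and `totals`.
#' @export
gene_abundance <- function(calls, genes, total_split_reads, extend_bp = 0L) {
  assert_that(all(total_split_reads > 0), "total_split_reads must be > 0")
  samples <- names(total_split_reads)
  assert_that(all(calls$sample_id %in% samples),
              "every call's sample_id needs a total in total_split_reads")
  g <- genes |>
    mutate(start = pmax(0L, .data$start - extend_bp),
           end = .data$end + extend_bp)
  long <- if (nrow(calls) == 0) {
    tibble(gene_id = character(), sample_id = character(), raw = numeric())
  } else {
    hits <- GenomicRanges::findOverlaps(as_granges0(calls), as_granges0(g))
    tibble(
      gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
      sample_id = calls$sample_id[S4Vectors::queryHits(hits)],
      support = calls$n_split_support[S4Vectors::queryHits(hits)]
    ) |>
      group_by(.data$gene_id, .data$sample_id) |>
      summarise(raw = sum(.data$support), .groups = "drop")
  }
  wide <- function(values) {
    long |>
      mutate(value = values(.data$raw, .data$sample_id)) |>
      select("gene_id", "sample_id", "value") |>
      pivot_wider(names_from = "sample_id", values_from = "value",
                  values_fill = 0) |>
      complete(gene_id = genes$gene_id) |>
      arrange(match(.data$gene_id, genes$gene_id))
  }
  raw <- wide(function(r, s) r)
  norm <- wide(function(r, s) r / total_split_reads[s] * 1e6)
  for (s in setdiff(samples, names(raw))) {
    raw[[s]] <- 0
    norm[[s]] <- 0
  }
  raw <- raw |> mutate(across(-"gene_id", ~ coalesce(.x, 0)))
  norm <- norm |> mutate(across(-"gene_id", ~ coalesce(.x, 0)))
  structure(
    list(raw = raw, normalized = norm, totals = total_split_reads),
    class = "ecc_gene_abundance"
  )
}

#' Recurrent ("highly abundant") eccDNA per group
#'
#' Identifies unique eccDNA molecules present in at least `min_samples`
#' distinct samples of each group. Identity is the exact (chrom, start, end)
#' triple when `tolerance_bp = 0`; with a positive tolerance, single-linkage
#' clustering merges circles whose start and end breakpoints both lie within
#' the tolerance, and clusters whose breakpoints span more than twice the
#' tolerance are flagged.
#'
#' @param calls An `ecc_calls` tibble with `sample_id`.
#' @param groups Tibble (`sample_id`, `group`) or named vector mapping
#'   samples to groups.
#' @param min_samples Minimum distinct samples (default 2).
#' @param tolerance_bp Breakpoint matching tolerance (default 0).
#' @param genes Optional gene intervals; when given, each group's associated
#'   gene set (gene-body overlap) is attached as attribute `gene_sets`.
#' @return Tibble of class `ecc_recurrent`: `group`, `chrom`, `start`,
#'   `end`, `n_samples`, `samples` (list column), `wide_cluster`.
#' @export
recurrent_eccdna <- function(calls, groups, min_samples = 2, tolerance_bp = 0,
                             genes = NULL) {
  if (!is.data.frame(groups)) {
    groups <- tibble(sample_id = names(groups), group = unname(groups))
  }
  dat <- calls |> inner_join(groups, by = "sample_id")
  out <- dat |>
    group_by(.data$group) |>
    group_modify(function(gd, key) {
      recur_one_group(gd, min_samples, tolerance_bp)
    }) |>
    ungroup()
  out <- structure(out, class = c("ecc_recurrent", class(out)))
  if (!is.null(genes) && nrow(out) > 0) {
    sets <- purrr::map(split(out, out$group), function(gg) {
      hits <- GenomicRanges::findOverlaps(as_granges0(gg), as_granges0(genes))
      sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)]))
    })
    attr(out, "gene_sets") <- sets
  }
  out
}

recur_one_group <- function(gd, min_samples, tolerance_bp) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_samples = integer(), samples = list(),
                  wide_cluster = logical())
  if (nrow(gd) == 0) return(empty)
  if (tolerance_bp == 0) {
    res <- gd |>
      distinct(.data$chrom, .data$start, .data$end, .data$sample_id) |>
      group_by(.data$chrom, .data$start, .data$end) |>
      summarise(n_samples = n_distinct(.data$sample_id),
                samples = list(sort(unique(.data$sample_id))),
                .groups = "drop") |>
      mutate(wide_cluster = FALSE)
  } else {
    d <- gd |>
      distinct(.data$chrom, .data$start, .data$end, .data$sample_id) |>
      arrange(.data$chrom, .data$start, .data$end)
    cl <- integer(nrow(d)); cur <- 0L
    for (i in seq_len(nrow(d))) {
      linked <- i > 1 && d$chrom[i] == d$chrom[i - 1] &&
        d$start[i] - d$start[i - 1] <= tolerance_bp &&
        abs(d$end[i] - d$end[i - 1]) <= tolerance_bp
      if (!linked) cur <- cur + 1L
      cl[i] <- cur
    }
    res <- d |>
      mutate(cluster = cl) |>
      group_by(.data$cluster) |>
      summarise(
        chrom = .data$chrom[1],
        span_start = diff(range(.data$start)),
        span_end = diff(range(.data$end)),
        start = min(.data$start), end = min(.data$end),
        n_samples = n_distinct(.data$sample_id),
        samples = list(sort(unique(.data$sample_id))),
        .groups = "drop"
      ) |>
      mutate(wide_cluster = .data$span_start > 2 * tolerance_bp |
               .data$span_end > 2 * tolerance_bp) |>
      select("chrom", "start", "end", "n_samples", "samples", "wide_cluster")
  }
  res |> filter(.data$n_samples >= min_samples)
}

#' Intersect recurrent plasma gene sets with placental differential gene sets
#'
#' Per pair of input sets, reports the intersection (candidate biomarker
#' genes). Inputs may be character vectors or named lists of character
#' vectors; empty intersections are valid results. Raises a diagnostic if no
#' identifier is shared across all inputs (namespace mismatch).
#'
#' @param group_recurrent_genes Named list (or single character vector) of
#'   per-group recurrent eccDNA-associated genes (e.g. plasma).
#' @param differential_genes Named list (or vector) of differentially
#'   abundant eccDNA-associated genes (e.g. placenta, per direction).
#' @return Tibble: `recurrent_set`, `differential_set`, `n`, `genes`
#'   (list column). Commutative in its two arguments up to column naming.
#' @export
intersect_biomarkers <- function(group_recurrent_genes, differential_genes) {
  as_sets <- function(x, default) {
    if (!is.list(x)) x <- stats::setNames(list(x), default)
    if (is.null(names(x))) names(x) <- paste0(default, seq_along(x))
    x
  }
  a <- as_sets(group_recurrent_genes, "recurrent")
  b <- as_sets(differential_genes, "differential")
  if (length(intersect(unique(unlist(a)), unique(unlist(b)))) == 0 &&
      length(unlist(a)) > 0 && length(unlist(b)) > 0) {
    rlang::warn("no gene identifier shared across inputs; check namespaces")
  }
  tidyr::expand_grid(recurrent_set = names(a), differential_set = names(b)) |>
    mutate(
      genes = purrr::map2(.data$recurrent_set, .data$differential_set,
                          function(i, j) sort(intersect(a[[i]], b[[j]]))),
      n = purrr::map_int(.data$genes, length)
    ) |>
    select("recurrent_set", "differential_set", "n", "genes")
}

#' Export inputs for external differential-abundance tools
#'
#' Writes the integer raw count matrix and a design file; the external tool
#' (e.g. a negative-binomial count model) performs its own normalization.
#'
#' @param abundance An `ecc_gene_abundance` object.
#' @param design Tibble (`sample_id`, `group`) or named vector.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_differential_inputs <- function(abundance, design, dir) {
  if (!is.data.frame(design)) {
    design <- tibble(sample_id = names(design), group = unname(design))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, "gene_counts.tsv")
  design_path <- file.path(dir, "design.tsv")
  raw <- abundance$raw |>
    mutate(across(-"gene_id", ~ as.integer(round(.x))))
  readr::write_tsv(raw, counts_path)
  readr::write_tsv(design, design_path)
  invisible(c(counts = counts_path, design = design_path))
}

#' Export 150-bp breakpoint-flanking sequences as FASTA
#'
#' For each call and each breakpoint, writes the 150-bp flank formed by 50 bp
#' inside the circle and 100 bp outside: the start flank spans
#' `[start-100, start+50)` and the end flank `[end-50, end+100)`. Flanks that
#' would cross a chromosome edge are dropped and counted, never silently
#' clipped.
#'
#' @param calls An `ecc_calls` tibble.
#' @param genome The reference `ecc_genome`.
#' @param path Output FASTA path.
#' @param inside_bp,outside_bp Flank composition (defaults 50/100).
#' @return Invisibly, a list with `path`, `n_written`, `n_dropped`.
#' @export
export_flank_fasta <- function(calls, genome, path, inside_bp = 50L,
                               outside_bp = 100L) {
  flanks <- bind_rows(
    tibble(chrom = calls$chrom, start = calls$start - outside_bp,
           end = calls$start + inside_bp,
           name = paste0(calls$chrom, ":", calls$start + 1L, "-", calls$end,
                         "/start_flank")),
    tibble(chrom = calls$chrom, start = calls$end - inside_bp,
           end = calls$end + outside_bp,
           name = paste0(calls$chrom, ":", calls$start + 1L, "-", calls$end,
                         "/end_flank"))
  )
  ok <- flanks$start >= 0 & flanks$end <= chrom_length(genome, flanks$chrom)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    rlang::inform(paste0("dropped ", n_dropped,
                         " flank(s) crossing a chromosome edge"))
  }
  keep <- flanks[ok, ]
  seqs <- Biostrings::DNAStringSet(
    genome_subseq(genome, keep$chrom, keep$start, keep$end)
  )
  names(seqs) <- keep$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(list(path = path, n_written = nrow(keep), n_dropped = n_dropped))
}
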