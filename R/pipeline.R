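# End-to-end synthetic pipeline: simulate -> call -> features -> annotate ->
# enhancer test -> differential prep -> recurrence -> biomarkers. All stages
# are pure functions of the config; a rerun with an identical config writes
# byte-identical outputs.

#' Default pipeline configuration
#'
#' @param seed Master seed; every random stage derives its own stream from it.
#' @param n_samples Number of synthetic samples.
#' @param ... Overrides for any top-level field (see the returned list).
#' @return Named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_samples = 4L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    genome = list(n_chrom = 3L, chrom_length = 300000L),
    sim = list(n_single = 40L, n_multi2 = 6L, n_multi3 = 2L, depth = 30,
               chemistry = "rca", duplicate_fraction = 0,
               circle_retain_prob = 0.7),
    caller = list(min_mapq = 20, min_support = 1, keep_duplicates = TRUE),
    features = list(smooth_window = 5L),
    enrichment = list(bin_width = 100000, n_draws = 5L),
    recurrent = list(min_samples = 2L)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full synthetic eccDNA pipeline
#'
#' Generates a genome and a master truth-circle pool, gives each sample a
#' random subset of the pool (so circles recur across samples), simulates
#' alignments, writes SAM + truth BED per sample, then runs calling,
#' breakpoint features, annotation enrichment, the enhancer-overlap test,
#' gene abundance export, recurrence and biomarker intersection. Every output
#' is written under `out_dir`; a deterministic log records parameters, input
#' hashes and row counts.
#'
#' @param config A config list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    assert_that(file.exists(config), paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(default_config(), config)
  for (field in c("seed", "n_samples", "genome", "sim", "caller")) {
    assert_that(!is.null(config[[field]]),
                paste0("config is missing required field '", field, "'"))
  }
  assert_that(isTRUE(config$genome$n_chrom >= 1),
              "config field 'genome$n_chrom' must be >= 1")
  assert_that(isTRUE(config$genome$chrom_length >= 50000),
              "config field 'genome$chrom_length' must be >= 50000")
  assert_that(isTRUE(config$n_samples >= 1),
              "config field 'n_samples' must be >= 1")
  assert_that(isTRUE(config$sim$depth >= 0),
              "config field 'sim$depth' must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("eccprofiler pipeline log",
                 paste0("config: ", yaml::as.yaml(config)))
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))

  # ---- simulate -------------------------------------------------------------
  genome <- make_genome(config$seed, config$genome$n_chrom,
                        config$genome$chrom_length)
  pool_params <- sim_params(
    seed = config$seed,
    n_single = config$sim$n_single, n_multi2 = config$sim$n_multi2,
    n_multi3 = config$sim$n_multi3, depth = config$sim$depth,
    chemistry = config$sim$chemistry,
    duplicate_fraction = config$sim$duplicate_fraction
  )
  planted <- make_truth_circles(genome, pool_params)
  genome <- planted$genome
  pool <- planted$truth
  write_genome(genome, file.path(out_dir, "genome"))
  write_truth_bed(pool, file.path(out_dir, "truth_pool.bed"))

  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  per_sample <- purrr::map(seq_along(sample_ids), function(i) {
    sid <- sample_ids[i]
    keep <- with_seed(derive_seed(config$seed, paste0("subset/", sid)), {
      ids <- unique(pool$circle_id)
      ids[stats::runif(length(ids)) < config$sim$circle_retain_prob]
    })
    truth_s <- pool |> filter(.data$circle_id %in% keep)
    params_s <- pool_params
    params_s$seed <- derive_seed(config$seed, paste0("reads/", sid))
    al <- simulate_alignments(genome, truth_s, params_s)
    sam <- file.path(out_dir, paste0(sid, ".sam"))
    write_sam(al, genome, sam, sample_id = sid)
    list(sid = sid, truth = truth_s, alignments = al, sam = sam)
  })
  for (ps in per_sample) {
    log_add("simulate ", ps$sid, ": ", nrow(ps$alignments), " records, sha ",
            unname(tools::md5sum(ps$sam)))
  }

  # ---- call -----------------------------------------------------------------
  called <- purrr::map(per_sample, function(ps) {
    ev <- extract_junction_evidence(
      ps$alignments, min_mapq = config$caller$min_mapq,
      keep_duplicates = config$caller$keep_duplicates, sample_id = ps$sid
    ) |>
      correct_junction_for_direct_repeat(genome)
    calls <- call_single_fragment(ev, genome,
                                  min_support = config$caller$min_support)
    regions <- extract_confident_regions(ev, ps$alignments, genome)
    cycles <- assemble_multifragment(regions, ev)
    list(sid = ps$sid, evidence = ev, calls = calls, regions = regions,
         cycles = cycles)
  })
  calls_all <- purrr::list_rbind(purrr::map(called, "calls"))
  regions_all <- purrr::list_rbind(purrr::map(called, function(x) {
    x$regions |> mutate(sample_id = x$sid)
  }))
  readr::write_tsv(calls_all, file.path(out_dir, "single_fragment_calls.tsv"))
  readr::write_tsv(
    purrr::list_rbind(purrr::map(called, function(x) {
      x$cycles |> mutate(sample_id = x$sid)
    })),
    file.path(out_dir, "multi_fragment_calls.tsv")
  )
  log_add("call: ", nrow(calls_all), " single-fragment calls, ",
          nrow(regions_all), " confident regions")

  # ---- features -------------------------------------------------------------
  prof <- size_profile(calls_all, config$features$smooth_window)
  readr::write_tsv(prof$histogram, file.path(out_dir, "size_histogram.tsv"))
  rep_prof <- repeat_fraction_by_size(calls_all, genome)
  readr::write_tsv(rep_prof$by_size_bin |> mutate(bin = as.character(.data$bin)),
                   file.path(out_dir, "repeat_fractions.tsv"))
  endcomp <- end_nucleotide_composition(calls_all, genome)
  readr::write_tsv(endcomp |> mutate(size_class = as.character(.data$size_class)),
                   file.path(out_dir, "end_nucleotides.tsv"))
  log_add("features: median size ", prof$median, ", top peak ",
          prof$peaks$size[1])

  # ---- annotate -------------------------------------------------------------
  annotation <- derive_tracks(genome)
  enr <- element_enrichment(calls_all, annotation, genome)
  readr::write_tsv(enr, file.path(out_dir, "element_enrichment.tsv"))
  bins <- bin_distribution(calls_all, genome, config$enrichment$bin_width)
  readr::write_tsv(bins, file.path(out_dir, "bin_distribution.tsv"))
  log_add("annotate: ", nrow(enr), " classes scored")

  # ---- enhancer test --------------------------------------------------------
  enh <- NULL
  if (nrow(regions_all) > 0) {
    enh <- enhancer_enrichment_test(
      regions_all, genome$tracks$enhancers, genome,
      n_draws = config$enrichment$n_draws,
      seed = derive_seed(config$seed, "enhancer")
    )
    readr::write_tsv(enh$scores, file.path(out_dir, "enhancer_scores.tsv"))
    log_add("enhancer test: p = ", format(enh$p_value))
  }

  # ---- differential prep, recurrence, biomarkers ----------------------------
  ev_all <- purrr::list_rbind(purrr::map(called, "evidence"))
  totals <- count_split_reads(ev_all)
  abund <- gene_abundance(calls_all, genome$tracks$genes, totals)
  groups <- tibble(
    sample_id = sample_ids,
    group = rep(c("groupA", "groupB"), length.out = length(sample_ids))
  )
  export_differential_inputs(abund, groups, out_dir)
  export_flank_fasta(calls_all, genome, file.path(out_dir, "flanks.fa"))
  recur <- recurrent_eccdna(calls_all, groups,
                            min_samples = config$recurrent$min_samples,
                            genes = genome$tracks$genes)
  readr::write_tsv(
    recur |> mutate(samples = purrr::map_chr(.data$samples, paste, collapse = ",")),
    file.path(out_dir, "recurrent_eccdna.tsv")
  )
  gene_sets <- attr(recur, "gene_sets") %||% list()
  biom <- if (length(gene_sets) >= 2) {
    intersect_biomarkers(gene_sets[1], gene_sets[2])
  } else {
    NULL
  }
  if (!is.null(biom)) {
    readr::write_tsv(
      biom |> mutate(genes = purrr::map_chr(.data$genes, paste, collapse = ",")),
      file.path(out_dir, "biomarkers.tsv")
    )
  }
  log_add("differential: ", nrow(abund$raw), " genes x ", length(totals),
          " samples; ", nrow(recur), " recurrent circles")

  readr::write_lines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(
    genome = genome, truth_pool = pool, samples = per_sample, called = called,
    calls = calls_all, regions = regions_all, size_profile = prof,
    enrichment = enr, bins = bins, enhancer_test = enh, abundance = abund,
    recurrent = recur, biomarkers = biom
  ))
}
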