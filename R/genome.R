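# Synthetic reference genome with internally consistent annotation tracks.

random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

#' Generate a synthetic reference genome with annotation tracks
#'
#' Builds a toy multi-chromosome genome (uniform random A/C/G/T) together with
#' internally consistent annotation tracks: genes with exon/intron/UTR
#' structure on both strands, CpG islands, repeat elements labelled with
#' common repeat classes, and enhancer intervals. All coordinates are 0-based
#' half-open. The same seed yields a byte-identical genome and tracks.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_chrom Number of chromosomes (>= 1).
#' @param lengths Integer vector of chromosome lengths in bp (each >= 50000);
#'   recycled to `n_chrom`.
#' @param gene_density,repeat_density,cpg_density,enhancer_density Expected
#'   features per bp; defaults give gene-dense toy chromosomes.
#' @return An object of class `ecc_genome`: a list with `chroms` (tibble of
#'   `chrom`, `length`), `seq` (named character vector of sequences) and
#'   `tracks` (named list of interval tibbles: `genes`, `exons`, `five_utr`,
#'   `three_utr`, `cpg_islands`, `repeats`, `enhancers`).
#' @examples
#' g <- make_genome(seed = 1, n_chrom = 2, lengths = 60000)
#' g$chroms
#' @export
make_genome <- function(seed, n_chrom = 3, lengths = 100000,
                        gene_density = 1 / 20000, repeat_density = 1 / 10000,
                        cpg_density = 1 / 50000, enhancer_density = 1 / 30000) {
  assert_that(n_chrom >= 1, "n_chrom must be >= 1")
  lengths <- as.integer(rep_len(lengths, n_chrom))
  assert_that(all(lengths >= 50000), "every chromosome length must be >= 50 kb")
  chroms <- tibble(chrom = paste0("chr", seq_len(n_chrom)), length = lengths)

  with_seed(derive_seed(seed, "genome"), {
    seqs <- stats::setNames(
      vapply(lengths, random_dna, character(1)),
      chroms$chrom
    )
    tracks <- make_tracks(chroms, gene_density, repeat_density,
                          cpg_density, enhancer_density)
  })

  structure(
    list(chroms = chroms, seq = seqs, tracks = tracks),
    class = "ecc_genome"
  )
}

#' @export
print.ecc_genome <- function(x, ...) {
  cat("<ecc_genome> ", nrow(x$chroms), " chromosome(s), ",
      format(sum(x$chroms$length), big.mark = ","), " bp\n", sep = "")
  cat("tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  invisible(x)
}

genome_length <- function(genome) sum(as.numeric(genome$chroms$length))

chrom_length <- function(genome, chrom) {
  genome$chroms$length[match(chrom, genome$chroms$chrom)]
}

# Extract sequence on 0-based half-open coordinates (vectorized).
genome_subseq <- function(genome, chrom, start, end) {
  out <- character(length(chrom))
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    out[i] <- substring(genome$seq[[cc]], start[i] + 1L, end[i])
  }
  out
}

# Overwrite genome sequence at a 0-based offset (used to plant direct repeats).
genome_replace <- function(genome, chrom, start, replacement) {
  s <- genome$seq[[chrom]]
  substr(s, start + 1L, start + nchar(replacement)) <- replacement
  genome$seq[[chrom]] <- s
  genome
}

# ---- annotation track generation -------------------------------------------

# Non-overlapping random intervals on one chromosome; greedy left-to-right
# walk with exponential gaps so density is approximately `per_bp`.
scatter_intervals <- function(chrom_len, per_bp, min_len, max_len) {
  n_target <- max(1L, stats::rpois(1, chrom_len * per_bp))
  gap_mean <- max(1, chrom_len / n_target - (min_len + max_len) / 2)
  pos <- 0
  starts <- integer(0)
  ends <- integer(0)
  repeat {
    pos <- pos + stats::rgeom(1, 1 / gap_mean) + 1L
    len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
    if (pos + len > chrom_len) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + len)
    pos <- pos + len
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

make_tracks <- function(chroms, gene_density, repeat_density,
                        cpg_density, enhancer_density) {
  repeat_classes <- c("LINE", "SINE/Alu", "SINE/MIR", "LTR/ERVL",
                      "simple_repeat", "low_complexity", "srpRNA")
  per_chrom <- purrr::map(seq_len(nrow(chroms)), function(i) {
    cc <- chroms$chrom[i]
    len <- chroms$length[i]
    genes <- scatter_intervals(len, gene_density, 2000L, 15000L) |>
      mutate(chrom = cc, strand = sample(c("+", "-"), n(), replace = TRUE))
    cpg <- scatter_intervals(len, cpg_density, 300L, 2000L) |> mutate(chrom = cc)
    reps <- scatter_intervals(len, repeat_density, 150L, 6000L) |>
      mutate(chrom = cc,
             class = sample(repeat_classes, n(), replace = TRUE,
                            prob = c(0.3, 0.3, 0.1, 0.1, 0.1, 0.08, 0.02)))
    enh <- scatter_intervals(len, enhancer_density, 200L, 2000L) |> mutate(chrom = cc)
    list(genes = genes, cpg = cpg, reps = reps, enh = enh)
  })

  genes <- purrr::list_rbind(purrr::map(per_chrom, "genes")) |>
    mutate(gene_id = paste0("GENE", sprintf("%04d", row_number()))) |>
    select("chrom", "start", "end", "strand", "gene_id")
  empty_exonic <- tibble(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         gene_id = character(), type = character())
  exonic <- bind_rows(
    empty_exonic,
    purrr::list_rbind(purrr::map(seq_len(nrow(genes)), function(i) {
      gene_exons(genes[i, ])
    }))
  )
  list(
    genes = genes,
    exons = exonic |> filter(.data$type == "exon") |> select(-"type"),
    five_utr = exonic |> filter(.data$type == "five_utr") |> select(-"type"),
    three_utr = exonic |> filter(.data$type == "three_utr") |> select(-"type"),
    cpg_islands = purrr::list_rbind(purrr::map(per_chrom, "cpg")) |>
      select("chrom", "start", "end"),
    repeats = purrr::list_rbind(purrr::map(per_chrom, "reps")) |>
      select("chrom", "start", "end", "class"),
    enhancers = purrr::list_rbind(purrr::map(per_chrom, "enh")) |>
      select("chrom", "start", "end")
  )
}

# Exon/UTR structure for one gene: 2-6 exons, UTRs at the transcript ends
# (strand-aware: the 5' UTR sits at the gene start on + genes).
gene_exons <- function(gene) {
  glen <- gene$end - gene$start
  n_exon <- sample(2:6, 1)
  cuts <- sort(sample.int(glen - 2L, 2L * n_exon - 2L)) # alternating exon/intron
  bounds <- c(0L, cuts, glen)
  starts <- gene$start + bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- gene$start + bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  exons <- tibble(chrom = gene$chrom, start = starts, end = ends,
                  strand = gene$strand, gene_id = gene$gene_id, type = "exon")
  utr5_len <- min(200L, ends[1] - starts[1])
  utr3_len <- min(300L, ends[length(ends)] - starts[length(starts)])
  if (gene$strand == "+") {
    utr5 <- tibble(chrom = gene$chrom, start = starts[1],
                   end = starts[1] + utr5_len)
    utr3 <- tibble(chrom = gene$chrom, start = ends[length(ends)] - utr3_len,
                   end = ends[length(ends)])
  } else {
    utr5 <- tibble(chrom = gene$chrom, start = ends[length(ends)] - utr5_len,
                   end = ends[length(ends)])
    utr3 <- tibble(chrom = gene$chrom, start = starts[1],
                   end = starts[1] + utr3_len)
  }
  bind_rows(
    exons,
    utr5 |> mutate(strand = gene$strand, gene_id = gene$gene_id, type = "five_utr"),
    utr3 |> mutate(strand = gene$strand, gene_id = gene$gene_id, type = "three_utr")
  )
}

# ---- serialization ----------------------------------------------------------

#' Write a synthetic genome and its annotation tracks to disk
#'
#' Writes the genome FASTA (via Biostrings), gene models as GTF and the other
#' tracks as BED6 (via rtracklayer-compatible plain BED written with readr).
#' Output is byte-identical for identical genomes.
#'
#' @param genome An `ecc_genome`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, fa)

  files <- c(fasta = fa)
  bed_tracks <- c("cpg_islands", "repeats", "enhancers")
  for (tr in bed_tracks) {
    df <- genome$tracks[[tr]]
    path <- file.path(dir, paste0(tr, ".bed"))
    name_col <- if (tr == "repeats") df$class else tr
    readr::write_tsv(
      tibble(chrom = df$chrom, start = df$start, end = df$end,
             name = name_col, score = 0L, strand = "."),
      path, col_names = FALSE
    )
    files[tr] <- path
  }

  gtf <- file.path(dir, "genes.gtf")
  gtf_rows <- bind_rows(
    genome$tracks$genes |> mutate(type = "gene"),
    genome$tracks$exons |> mutate(type = "exon"),
    genome$tracks$five_utr |> mutate(type = "five_prime_utr"),
    genome$tracks$three_utr |> mutate(type = "three_prime_utr")
  ) |>
    arrange(.data$chrom, .data$start, .data$type)
  readr::write_tsv(
    tibble(
      seqname = gtf_rows$chrom, source = "eccprofiler", feature = gtf_rows$type,
      start = gtf_rows$start + 1L, end = gtf_rows$end, score = ".",
      strand = gtf_rows$strand, frame = ".",
      attribute = paste0("gene_id \"", gtf_rows$gene_id, "\";")
    ),
    gtf, col_names = FALSE, escape = "none"
  )
  files["gtf"] <- gtf
  invisible(files)
}

#' Read annotation tracks from BED files
#'
#' Reads BED6 interval tracks (as written by [write_genome()] or supplied by
#' the user) into 0-based half-open tibbles.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  out <- tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                end = as.integer(df[[3]]))
  out$name <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  out$strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "."
  out
}
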