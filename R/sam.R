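# SAM input/output. Records are held internally as 0-based half-open tibbles;
# SAM's 1-based POS convention is converted at this boundary only.

FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L; FLAG_READ1 <- 0x40L; FLAG_READ2 <- 0x80L
FLAG_SECONDARY <- 0x100L; FLAG_DUP <- 0x400L; FLAG_SUPP <- 0x800L

#' Write alignment records as a coordinate-sorted SAM file
#'
#' @param alignments An `ecc_alignments` tibble (e.g. from
#'   [simulate_alignments()]).
#' @param genome The `ecc_genome` providing the sequence dictionary.
#' @param path Output SAM path.
#' @param sample_id Read-group sample name recorded in the header.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, genome, path, sample_id = "sample") {
  al <- alignments |>
    mutate(.chrord = match(.data$chrom, genome$chroms$chrom)) |>
    arrange(.data$.chrord, .data$start, .data$read_id, .data$in_pair) |>
    select(-".chrord")
  flag <- FLAG_PAIRED + FLAG_PROPER +
    ifelse(al$strand == "-", FLAG_REVERSE, 0L) +
    ifelse(al$in_pair == 1L, FLAG_MREVERSE + FLAG_READ1, FLAG_READ2) +
    ifelse(al$is_duplicate, FLAG_DUP, 0L) +
    ifelse(al$is_supplementary, FLAG_SUPP, 0L)
  sa <- ifelse(
    is.na(al$sa_chrom), "",
    paste0("\tSA:Z:", al$sa_chrom, ",", al$sa_start + 1L, ",", al$sa_strand,
           ",", al$sa_cigar, ",", al$mapq, ",0;")
  )
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", genome$chroms$chrom, "\tLN:", genome$chroms$length),
    paste0("@RG\tID:", sample_id, "\tSM:", sample_id)
  )
  body <- if (nrow(al) == 0) character(0) else paste0(
    al$read_id, "\t", flag, "\t", al$chrom, "\t", al$start + 1L, "\t",
    al$mapq, "\t", al$cigar, "\t",
    ifelse(al$mate_chrom == al$chrom, "=", al$mate_chrom), "\t",
    al$mate_start + 1L, "\t0\t", al$seq, "\t",
    strrep("I", nchar(al$seq)), "\tNM:i:0\tRG:Z:", sample_id, sa
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

parse_sa_first <- function(sa) {
  first <- sub(";.*$", "", sa)
  parts <- strsplit(first, ",", fixed = TRUE)
  tibble(
    sa_chrom = purrr::map_chr(parts, 1, .default = NA_character_),
    sa_start = suppressWarnings(
      as.integer(purrr::map_chr(parts, 2, .default = NA_character_))
    ) - 1L,
    sa_strand = purrr::map_chr(parts, 3, .default = NA_character_),
    sa_cigar = purrr::map_chr(parts, 4, .default = NA_character_)
  )
}

#' Read a SAM/BAM file into an alignment tibble
#'
#' Reads through Rsamtools (SAM files are converted to BAM on the fly) and
#' returns the same tibble layout the simulator produces: one row per record,
#' 0-based half-open coordinates, SA descriptor split into columns. Unmapped
#' records are dropped.
#'
#' @param path SAM or BAM file.
#' @return An `ecc_alignments` tibble.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "seq"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(res$qname) == 0) return(empty_alignments())
  flag <- res$flag
  bit <- function(mask) bitwAnd(flag, mask) != 0L
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  sa_raw <- res$tag$SA %||% rep(NA_character_, length(flag))
  sa <- parse_sa_first(ifelse(is.na(sa_raw), NA_character_, sa_raw))
  df <- tibble(
    read_id = res$qname,
    in_pair = ifelse(bit(FLAG_READ1), 1L, 2L),
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + ref_width,
    strand = ifelse(bit(FLAG_REVERSE), "-", "+"),
    cigar = res$cigar,
    mapq = res$mapq,
    is_supplementary = bit(FLAG_SUPP),
    is_secondary = bit(FLAG_SECONDARY),
    is_duplicate = bit(FLAG_DUP),
    mate_chrom = as.character(res$mrnm),
    mate_start = res$mpos - 1L,
    seq = as.character(res$seq),
    circle_id = sub(":.*$", "", res$qname)
  )
  df <- bind_cols(df[, 1:14], sa, df[, "circle_id", drop = FALSE])
  structure(df, class = c("ecc_alignments", class(df)))
}
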