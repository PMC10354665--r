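# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: plain loops, regex CIGAR parsing, per-base character
# comparisons, and full enumeration for the exact tests.

oracle_char <- function(genome, chrom, pos0) {
  substr(genome$seq[[chrom]], pos0 + 1, pos0 + 1)
}

# Longest k with genome[s, s+k) == genome[e, e+k), scanned base by base.
oracle_lcp <- function(genome, chrom, s, e, max_len = 20) {
  k <- 0
  limit <- nchar(genome$seq[[chrom]])
  while (k < max_len && s + k < limit && e + k < limit &&
         oracle_char(genome, chrom, s + k) == oracle_char(genome, chrom, e + k)) {
    k <- k + 1
  }
  k
}

oracle_parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  list(ops = ops, lens = lens)
}

oracle_left_clip <- function(cigar) {
  p <- oracle_parse_cigar(cigar)
  i <- 1
  clip <- 0
  while (i <= length(p$ops) && p$ops[i] %in% c("S", "H")) {
    clip <- clip + p$lens[i]
    i <- i + 1
  }
  clip
}

oracle_ref_width <- function(cigar) {
  p <- oracle_parse_cigar(cigar)
  sum(p$lens[p$ops %in% c("M", "D", "N", "=", "X")])
}

oracle_is_contiguous <- function(cigar, max_clip = 5) {
  p <- oracle_parse_cigar(cigar)
  core <- p$ops[!p$ops %in% c("S", "H")]
  identical(core, "M") && sum(p$lens[p$ops %in% c("S", "H")]) < max_clip
}

# Full single-fragment caller oracle: enumerate every (split read, mate)
# pair, test the calling criteria on the records directly, and canonicalize
# each junction by exhaustive downward shift search over per-base matches.
oracle_call_set <- function(alignments, genome, min_mapq = 20,
                            min_support = 1) {
  al <- alignments[!alignments$is_secondary, ]
  prim <- al[!al$is_supplementary, ]
  found <- list()
  for (i in seq_len(nrow(prim))) {
    r <- prim[i, ]
    if (is.na(r$sa_chrom)) next
    # two placements of the split read, ordered by position in the read
    seg <- data.frame(
      chrom = c(r$chrom, r$sa_chrom),
      start = c(r$start, r$sa_start),
      end = c(r$start + oracle_ref_width(r$cigar),
              r$sa_start + oracle_ref_width(r$sa_cigar)),
      strand = c(r$strand, r$sa_strand),
      clip = c(oracle_left_clip(r$cigar), oracle_left_clip(r$sa_cigar))
    )
    seg <- seg[order(seg$clip), ]
    if (seg$chrom[1] != seg$chrom[2]) next
    if (seg$strand[1] != seg$strand[2]) next
    a <- seg[1, ]; b <- seg[2, ]
    if (!(b$start < a$start)) next
    # mate: the other read of the pair, uniquely and contiguously mapped
    mates <- prim[prim$read_id == r$read_id & prim$in_pair != r$in_pair, ]
    for (j in seq_len(nrow(mates))) {
      mt <- mates[j, ]
      if (!is.na(mt$sa_chrom)) next
      if (mt$mapq < min_mapq) next
      if (!oracle_is_contiguous(mt$cigar)) next
      # exhaustive leftmost shift: slide the junction down while the bases
      # entering from both sides keep matching
      sh <- 0
      while (sh < 50 && a$end - sh - 1 >= 0 && b$start - sh - 1 >= 0 &&
             oracle_char(genome, a$chrom, a$end - sh - 1) ==
             oracle_char(genome, b$chrom, b$start - sh - 1)) {
        sh <- sh + 1
      }
      start <- b$start - sh
      end <- a$end - sh
      if (!(mt$chrom == a$chrom && mt$start < end && mt$end > start)) next
      key <- paste(a$chrom, start, end, sep = ":")
      found[[key]] <- c(found[[key]], r$read_id)
      break
    }
  }
  if (length(found) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_split_support = integer()))
  }
  parts <- strsplit(names(found), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3)),
    n_split_support = vapply(found, function(x) length(unique(x)), 1L)
  )
  out <- out[out$n_split_support >= min_support, ]
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# Exact signed-rank p by explicit enumeration of all 2^n sign assignments.
oracle_signed_rank <- function(d, sided = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  switch(sided, greater = p_ge, less = p_le,
         two = min(1, 2 * min(p_ge, p_le)))
}

# Exact rank-sum p by explicit enumeration of all C(n, nA) assignments.
oracle_rank_sum <- function(a, b, sided = "greater") {
  r <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(sided, greater = p_ge, less = p_le,
         two = min(1, 2 * min(p_ge, p_le)))
}

# Overlap-and-sum oracle for gene abundance.
oracle_gene_counts <- function(calls, genes) {
  out <- setNames(numeric(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(genes))) {
      if (calls$chrom[i] == genes$chrom[j] &&
          calls$start[i] < genes$end[j] && genes$start[j] < calls$end[i]) {
        out[j] <- out[j] + calls$n_split_support[i]
      }
    }
  }
  out
}

# Point-in-interval scan for junction classification.
oracle_classify_point <- function(chrom, pos, annotation) {
  hits <- character(0)
  for (cl in names(annotation)) {
    df <- annotation[[cl]]
    for (j in seq_len(nrow(df))) {
      if (df$chrom[j] == chrom && df$start[j] <= pos && pos < df$end[j]) {
        hits <- c(hits, cl)
        break
      }
    }
  }
  hits
}
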