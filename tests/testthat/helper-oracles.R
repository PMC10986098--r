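# Independent brute-force oracles and small fixture builders.
# Oracles deliberately avoid the package's own algorithms: plain loops and
# complete enumeration, feasible only at test scale.

frag_tbl <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 length = end - start)
}

toy_genome <- function(lengths = c(chr1 = 10000, chr2 = 5000), seqs = NULL) {
  gi <- tibble::tibble(chrom = names(lengths), length = unname(lengths))
  if (!is.null(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- names(lengths)
    return(genome_index(gi, sequence = ss))
  }
  genome_index(gi)
}

# O(n^2) pair enumeration over expanded dyads, one chromosome
brute_phaseogram_counts <- function(pos, n, max_distance) {
  dyads <- rep(pos, n)
  counts <- numeric(max_distance)
  m <- length(dyads)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- abs(dyads[j] - dyads[i])
      if (d >= 1 && d <= max_distance) counts[d] <- counts[d] + 1
    }
  }
  counts
}

# vectorised but still all-pairs (outer), for larger random tracks
brute_phaseogram_counts_fast <- function(pos, n, max_distance) {
  dyads <- rep(pos, n)
  d <- abs(outer(dyads, dyads, "-"))
  d <- d[upper.tri(d)]
  d <- d[d >= 1 & d <= max_distance]
  tabulate(d, nbins = max_distance)
}

# all-pairs fraction-overlap matching without any interval index
brute_has_match <- function(query, subject, f, reciprocal = FALSE) {
  vapply(seq_len(nrow(query)), function(i) {
    qs <- query$start[i]; qe <- query$end[i]; qc <- query$chrom[i]
    ql <- qe - qs
    for (j in seq_len(nrow(subject))) {
      if (subject$chrom[j] != qc) next
      ov <- min(qe, subject$end[j]) - max(qs, subject$start[j])
      if (ov <= 0) next
      if (ov >= f * ql &&
          (!reciprocal || ov >= f * (subject$end[j] - subject$start[j]))) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

brute_any_overlap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          pmin(query$end[i], subject$end) -
          pmax(query$start[i], subject$start) > 0)
  }, logical(1))
}

# two-sided Fisher exact p by direct hypergeometric enumeration
brute_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# clipped (fragment x feature) overlap mass with the flank window
brute_profile_mass <- function(fragments, features, flank) {
  total <- 0
  for (i in seq_len(nrow(fragments))) {
    for (j in seq_len(nrow(features))) {
      if (fragments$chrom[i] != features$chrom[j]) next
      c0 <- features$start[j] +
        floor((features$end[j] - features$start[j]) / 2)
      lo <- max(fragments$start[i], c0 - flank)
      hi <- min(fragments$end[i] - 1, c0 + flank)
      if (hi >= lo) total <- total + (hi - lo + 1)
    }
  }
  total
}

# memoised synthetic cohorts shared across test files
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 101, with_sequence = FALSE) {
  key <- paste0("c", seed, "_", with_sequence)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      synthetic_config(seed = seed, with_sequence = with_sequence))
  }
  .cohort_cache[[key]]
}

sample_frags <- function(cohort, patient, condition) {
  f <- cohort$fragments
  f[f$patient == patient & f$condition == condition, ]
}
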