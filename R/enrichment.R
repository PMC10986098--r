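#' Length-preserving random interval placement
#'
#' Re-places each query interval uniformly at random on its own chromosome
#' (preserving its length), the chance model for interval enrichment.
#' Placements overlapping `excluded` regions are rejection-sampled, up to
#' `max_attempts` rounds. An interval exactly as long as its chromosome is
#' forced to position 0.
#'
#' @param query Region tibble.
#' @param genome A [genome_index()].
#' @param seed Integer seed (placement must be reproducible).
#' @param excluded Optional region tibble that shuffled intervals must not
#'   touch.
#' @param max_attempts Rejection-sampling rounds before aborting.
#' @return A region tibble of shuffled intervals (same lengths, same
#'   chromosomes, original order).
#' @export
shuffle_intervals <- function(query, genome, seed, excluded = NULL,
                              max_attempts = 1000) {
  stopifnot(!missing(seed))
  len <- query$end - query$start
  lim <- genome$chroms$length[.chrom_rank(query$chrom, genome)]
  if (anyNA(lim)) rlang::abort("query interval on a chromosome absent from the genome")
  if (any(len > lim)) rlang::abort("query interval longer than its chromosome")
  set.seed(seed)
  n <- nrow(query)
  start <- numeric(n)
  todo <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    u <- stats::runif(length(todo))
    start[todo] <- floor(u * (lim[todo] - len[todo] + 1))
    if (is.null(excluded)) {
      todo <- integer(0)
    } else {
      st <- start[todo]
      placed <- tibble::tibble(chrom = query$chrom[todo],
                               start = st, end = st + len[todo])
      bad <- count_overlap_flags(placed, excluded)
      todo <- todo[bad]
    }
    if (length(todo) == 0) break
  }
  if (length(todo) > 0) {
    rlang::abort("shuffle_intervals: rejection sampling exhausted (excluded regions too dense)")
  }
  tibble::tibble(chrom = query$chrom, start = start, end = start + len)
}

# logical: does each query interval overlap any reference interval?
count_overlap_flags <- function(query, reference) {
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(reference) == 0) return(hit)
  for (ch in intersect(unique(query$chrom), unique(reference$chrom))) {
    qi <- which(query$chrom == ch)
    ri <- which(reference$chrom == ch)
    hit[qi] <- IRanges::overlapsAny(.as_iranges(query[qi, ]),
                                    .as_iranges(reference[ri, ]))
  }
  hit
}

#' Count query intervals overlapping a reference set
#'
#' @param query,reference Region tibbles.
#' @return The number of query intervals with at least 1 bp of overlap with
#'   any reference interval (half-open abutment does not count).
#' @export
count_overlapping <- function(query, reference) {
  sum(count_overlap_flags(query, reference))
}

#' Interval enrichment with an exact test
#'
#' Measures how many query intervals overlap a reference annotation versus
#' the number expected by chance, where chance is estimated by
#' length-preserving same-chromosome shuffling pooled over `n_shuffles`
#' rounds. Fold enrichment is the observed overlap rate over the pooled
#' random rate; the p-value is the two-sided Fisher exact test on the
#' pooled 2x2 table `[[a, b], [R, n*|query| - R]]` with `a` observed
#' overlapping, `b` observed non-overlapping and `R` the summed random
#' overlap count.
#'
#' @param query Non-empty region tibble (e.g. gained nucleosomes).
#' @param reference Annotation region tibble (e.g. CpG islands).
#' @param genome A [genome_index()].
#' @param seed Integer seed for the shuffles.
#' @param n_shuffles Number of random placements pooled (default 10).
#' @param excluded Optional regions the shuffles must avoid.
#' @return An object of class `enrichment_result` with the 2x2 counts,
#'   `fold` (`Inf` when no random interval overlaps), `p_value`, `seed`,
#'   `n_shuffles`.
#' @export
fisher_enrichment <- function(query, reference, genome, seed,
                              n_shuffles = 10, excluded = NULL) {
  stopifnot(!missing(seed), nrow(query) > 0, n_shuffles >= 1)
  nq <- nrow(query)
  a <- count_overlapping(query, reference)
  b <- nq - a
  # canonical order so the statistics are invariant to query permutation
  query_sorted <- dplyr::arrange(query, .data$chrom, .data$start, .data$end)
  rand_total <- 0
  for (i in seq_len(n_shuffles)) {
    shuf <- shuffle_intervals(query_sorted, genome, seed = seed + i - 1,
                              excluded = excluded)
    rand_total <- rand_total + count_overlapping(shuf, reference)
  }
  d <- nq * n_shuffles - rand_total
  fold <- if (rand_total == 0) Inf else (a / nq) / (rand_total / (nq * n_shuffles))
  tab <- matrix(c(a, b, rand_total, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  structure(list(n_query = nq, n_overlapping = a,
                 n_random = nq * n_shuffles, n_random_overlapping = rand_total,
                 mean_random_overlapping = rand_total / n_shuffles,
                 fold = fold, p_value = p, seed = seed,
                 n_shuffles = n_shuffles),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$n_overlapping, "/", x$n_query,
      " query vs ", x$n_random_overlapping, "/", x$n_random,
      " random overlapping; fold = ", format(x$fold, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(n_query = x$n_query, n_overlapping = x$n_overlapping,
                 n_random = x$n_random,
                 n_random_overlapping = x$n_random_overlapping,
                 fold = x$fold, p_value = x$p_value,
                 n_shuffles = x$n_shuffles, seed = x$seed)
}
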