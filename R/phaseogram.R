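#' Phaseogram / NRL estimation configuration
#'
#' Bundles every tunable of the NRL estimator. Defaults follow the
#' paired-end dyad-distance protocol: distances to 2,000 bp at single-bp
#' resolution, stacked-position cutoff 50 dyads/bp, 40 million reads per
#' chromosome, and automatic peak detection on the smoothed genome-averaged
#' curve followed by linear regression of peak position on peak order.
#'
#' @param max_distance Largest dyad-dyad distance D considered (bp).
#' @param stack_cutoff Positions with more than this many dyads are dropped.
#' @param max_reads Per-chromosome fragment cap before pair counting.
#' @param min_pairs Minimum weighted pair count for a chromosome to enter
#'   the genome average.
#' @param smooth_halfwidth Half-width of the centred moving average applied
#'   before peak detection (window `2*h + 1` bp).
#' @param min_separation Minimum distance between detected peaks (bp).
#' @param search_range Length-2 numeric: distances searched for peaks.
#' @param max_peaks Peaks retained for the regression (leftmost first).
#' @param min_rel_prominence Peaks whose prominence on the smoothed curve is
#'   below this fraction of the largest peak prominence are discarded; this
#'   suppresses sampling ripple in the unphased tail of the curve.
#' @param size_band Fragment-length analysis band `[low, high)` applied
#'   before dyad extraction.
#' @param seed Integer seed for the read-cap subsample.
#' @return A list of class `phaseogram_config`.
#' @export
phaseogram_config <- function(max_distance = 2000,
                              stack_cutoff = 50,
                              max_reads = 4e7,
                              min_pairs = 10000,
                              smooth_halfwidth = 10,
                              min_separation = 100,
                              search_range = c(100, max_distance),
                              max_peaks = 10,
                              min_rel_prominence = 0.15,
                              size_band = c(120, 180),
                              seed = 1L) {
  stopifnot(max_distance >= 2, stack_cutoff >= 1,
            smooth_halfwidth >= 0, smooth_halfwidth < min_separation,
            length(search_range) == 2, search_range[1] < search_range[2],
            max_peaks >= 3, length(size_band) == 2,
            size_band[1] < size_band[2])
  structure(list(max_distance = max_distance, stack_cutoff = stack_cutoff,
                 max_reads = max_reads, min_pairs = min_pairs,
                 smooth_halfwidth = smooth_halfwidth,
                 min_separation = min_separation,
                 search_range = search_range, max_peaks = max_peaks,
                 min_rel_prominence = min_rel_prominence,
                 size_band = size_band, seed = as.integer(seed)),
            class = "phaseogram_config")
}

# weighted pair counts at distances 1..D for one chromosome;
# pos sorted unique positions, cnt their multiplicities
.pair_counts <- function(pos, cnt, max_distance, chunk_pairs = 5e6) {
  m <- length(pos)
  counts <- numeric(max_distance)
  if (m < 2) return(counts)
  hi <- findInterval(pos + max_distance, pos)
  n_nb <- hi - seq_len(m)
  if (sum(n_nb) == 0) return(counts)
  # chunk the pair expansion to bound memory
  lo <- 1L
  while (lo <= m) {
    cum <- cumsum(n_nb[lo:m])
    take <- max(1L, min(findInterval(chunk_pairs, cum) + 1L, m - lo + 1L))
    idx <- lo:(lo + take - 1L)
    nn <- n_nb[idx]
    if (sum(nn) > 0) {
      ii <- rep.int(idx, nn)
      jj <- ii + sequence(nn)
      d <- pos[jj] - pos[ii]
      w <- cnt[ii] * cnt[jj]
      agg <- rowsum(w, group = d, reorder = FALSE)
      dd <- as.numeric(rownames(agg))
      counts[dd] <- counts[dd] + agg[, 1]
    }
    lo <- lo + take
  }
  counts
}

#' Compute a dyad-distance phaseogram
#'
#' For each chromosome, counts all ordered dyad pairs at distances
#' `1..max_distance` bp (weighted by per-position multiplicities), plus
#' co-located pairs at distance 0, which are stored but excluded from
#' normalisation. Each chromosome curve is normalised to unit mass and
#' chromosomes with fewer than `min_pairs` weighted pairs are excluded;
#' the genome curve is the unweighted mean of the included chromosomes.
#'
#' @param track Dyad track ([build_dyad_track()]), with stacking and read
#'   caps already applied.
#' @param config A [phaseogram_config()].
#' @return An object of class `phaseogram`: list with `distance` (1..D),
#'   `frequency` (genome-averaged), `per_chrom` (tibble chrom x distance
#'   long format with raw counts and frequencies), `chroms_used`,
#'   `pairs_same_position`.
#' @export
compute_phaseogram <- function(track, config = phaseogram_config()) {
  D <- config$max_distance
  chroms <- unique(track$chrom)
  per <- list()
  zero_pairs <- 0
  for (ch in chroms) {
    sub <- track[track$chrom == ch, ]
    ord <- order(sub$pos)
    cnt_d <- .pair_counts(sub$pos[ord], sub$n[ord], D)
    zero_pairs <- zero_pairs + sum(sub$n * (sub$n - 1) / 2)
    tot <- sum(cnt_d)
    if (tot >= config$min_pairs) {
      per[[ch]] <- cnt_d
    }
  }
  if (length(per) == 0) {
    rlang::abort("insufficient data: no chromosome reaches the minimum pair count")
  }
  freq_mat <- vapply(per, function(x) x / sum(x), numeric(D))
  avg <- rowMeans(freq_mat)
  per_chrom <- purrr::imap(per, function(cnts, ch) {
    tibble::tibble(chrom = ch, distance = seq_len(D), count = cnts,
                   frequency = cnts / sum(cnts))
  }) |> dplyr::bind_rows()
  structure(list(distance = seq_len(D), frequency = avg,
                 per_chrom = per_chrom, chroms_used = names(per),
                 pairs_same_position = zero_pairs, config = config),
            class = "phaseogram")
}

#' @export
print.phaseogram <- function(x, ...) {
  cat("<phaseogram> distances 1..", max(x$distance), " bp, ",
      length(x$chroms_used), " chromosome(s) averaged\n", sep = "")
  invisible(x)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::tidy
tidy.phaseogram <- function(x, ...) {
  tibble::tibble(distance = x$distance, frequency = x$frequency)
}

# centred moving average, partial windows at the edges
.smooth_ma <- function(v, halfwidth) {
  if (halfwidth == 0) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - halfwidth, 1)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# prominence of peak at index i on curve v (indices within search window)
.prominence <- function(v, peaks) {
  vapply(peaks, function(i) {
    left <- right <- v[i]
    j <- i
    lmin <- v[i]
    while (j > 1 && v[j - 1] <= v[i]) {
      j <- j - 1
      if (v[j] < lmin) lmin <- v[j]
    }
    if (j == 1 && v[1] <= v[i]) lmin <- min(lmin, v[1])
    j <- i
    rmin <- v[i]
    n <- length(v)
    while (j < n && v[j + 1] <= v[i]) {
      j <- j + 1
      if (v[j] < rmin) rmin <- v[j]
    }
    v[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect phaseogram peaks
#'
#' Smooths the genome-averaged curve with a centred moving average, finds
#' local maxima inside the search range, enforces the minimum peak
#' separation (on conflict the higher peak wins; exact ties go to the
#' leftmost), discards low-prominence ripple, and returns the leftmost
#' `max_peaks` peaks indexed `k = 1..K`.
#'
#' @param phaseogram A `phaseogram`, or any numeric curve indexed from
#'   distance 1.
#' @param config A [phaseogram_config()].
#' @return A tibble with columns `k` and `position` (bp), strictly
#'   increasing in `position`. Errors with "too few peaks" when `K < 3`.
#' @export
detect_peaks <- function(phaseogram, config = phaseogram_config()) {
  v <- if (inherits(phaseogram, "phaseogram")) phaseogram$frequency else as.numeric(phaseogram)
  sm <- .smooth_ma(v, config$smooth_halfwidth)
  r1 <- max(1, ceiling(config$search_range[1]))
  r2 <- min(length(sm), floor(config$search_range[2]))
  w <- sm[r1:r2]
  n <- length(w)
  if (n < 3) rlang::abort("too few peaks: empty search range")
  # local maxima, leftmost point of plateaus
  cand <- which(w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] >= w[3:n]) + 1L
  if (length(cand) == 0) rlang::abort("too few peaks: no local maxima detected")
  # greedy selection by height (ties leftmost), enforcing min separation
  ord <- cand[order(-w[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) >= config$min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  prom <- .prominence(w, kept)
  kept <- kept[prom >= config$min_rel_prominence * max(prom)]
  kept <- utils::head(kept, config$max_peaks)
  if (length(kept) < 3) {
    rlang::abort("too few peaks: fewer than 3 peaks detected")
  }
  tibble::tibble(k = seq_along(kept), position = kept + r1 - 1)
}

#' Fit the NRL from detected peaks
#'
#' Ordinary least squares of peak position on peak order with a free
#' intercept; the slope is the nucleosome repeat length in bp. The free
#' intercept absorbs any constant offset of the first peak, so linker
#' asymmetry does not bias the slope.
#'
#' @param peaks Tibble with columns `k` and `position` (at least 3 rows).
#' @return An object of class `nrl_estimate` with elements `nrl` (slope,
#'   bp), `intercept`, `r_squared`, `n_peaks` and the `peaks` table.
#' @export
fit_nrl <- function(peaks) {
  if (nrow(peaks) < 3) rlang::abort("at least 3 peaks are required to fit an NRL")
  stopifnot(all(diff(peaks$position) > 0))
  fit <- stats::lm(position ~ k, data = peaks)
  structure(list(nrl = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_peaks = nrow(peaks), peaks = peaks,
                 provenance = NULL),
            class = "nrl_estimate")
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat("<nrl_estimate> NRL = ", format(x$nrl, digits = 5), " bp (",
      x$n_peaks, " peaks, R² = ", format(x$r_squared, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy methods for NRL objects
#'
#' `tidy()` returns the per-peak (or per-distance) table; `glance()` a
#' one-row model summary.
#'
#' @param x A `nrl_estimate` or `phaseogram`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.nrl_estimate <- function(x, ...) {
  dplyr::mutate(x$peaks,
                fitted = x$intercept + x$nrl * .data$k,
                residual = .data$position - .data$fitted)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::glance
glance.nrl_estimate <- function(x, ...) {
  tibble::tibble(nrl = x$nrl, intercept = x$intercept,
                 r_squared = x$r_squared, n_peaks = x$n_peaks,
                 n_fragments = if (is.null(x$provenance)) NA_real_ else x$provenance$n_after_cap)
}
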