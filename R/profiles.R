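#' Profile configuration
#'
#' @param flank Half-window around feature centres in bp (default 2,000).
#' @param smooth Moving-average smoothing window in bp (default 10;
#'   expanded to the next odd width so the window is centred).
#' @param per_million Normalise to fragments per million in the sample.
#' @param strand_aware Mirror the window for `-`-strand features.
#' @param per_feature_average Divide by the number of features, turning the
#'   summed profile into a per-feature mean.
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(flank = 2000, smooth = 10, per_million = TRUE,
                           strand_aware = TRUE, per_feature_average = FALSE) {
  stopifnot(flank > 0, smooth >= 1)
  structure(list(flank = flank, smooth = smooth, per_million = per_million,
                 strand_aware = strand_aware,
                 per_feature_average = per_feature_average),
            class = "profile_config")
}

# feature centres with the same floor-midpoint rule as fragment dyads
.feature_centres <- function(features) {
  if ("centre" %in% names(features)) return(features$centre)
  features$start + floor((features$end - features$start) / 2)
}

.feature_strands <- function(features, strand_aware) {
  if (strand_aware && "strand" %in% names(features)) {
    ifelse(features$strand == "-", "-", "+")
  } else {
    rep("+", nrow(features))
  }
}

#' Aggregate occupancy profile around features
#'
#' Accumulates per-bp fragment coverage over `[centre - flank,
#' centre + flank]` across all features (summed, not averaged, unless
#' `per_feature_average`), reverses minus-strand windows when
#' strand-aware, optionally normalises to fragments-per-million using the
#' full sample size, and smooths with a centred moving average.
#'
#' @param fragments Fragment tibble.
#' @param features Region tibble with defined centres (interval midpoint,
#'   or a `centre` column).
#' @param config A [profile_config()].
#' @param n_fragments Sample depth used for per-million normalisation;
#'   defaults to `nrow(fragments)` (i.e. depth before any restriction).
#' @return An object of class `occupancy_profile`: list with `offset`
#'   (-flank..flank), `value`, `n_features`, `n_fragments`.
#' @export
aggregate_occupancy <- function(fragments, features,
                                config = profile_config(),
                                n_fragments = nrow(fragments)) {
  if (nrow(features) == 0) rlang::abort("empty feature set")
  flank <- config$flank
  width <- 2 * flank + 1
  acc <- numeric(width + 1)  # difference array, one slot longer
  centres <- .feature_centres(features)
  strands <- .feature_strands(features, config$strand_aware)
  for (ch in intersect(unique(features$chrom), unique(fragments$chrom))) {
    fi <- which(features$chrom == ch)
    gi <- which(fragments$chrom == ch)
    win <- IRanges::IRanges(start = centres[fi] - flank + 1,
                            end = centres[fi] + flank + 1)
    frg <- IRanges::IRanges(start = fragments$start[gi] + 1,
                            end = fragments$end[gi])
    hits <- IRanges::findOverlaps(frg, win)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    c0 <- centres[fi][sh]
    lo <- pmax(fragments$start[gi][qh], c0 - flank) - c0  # offsets
    hi <- pmin(fragments$end[gi][qh] - 1, c0 + flank) - c0
    minus <- strands[fi][sh] == "-"
    lo2 <- ifelse(minus, -hi, lo)
    hi2 <- ifelse(minus, -lo, hi)
    i1 <- lo2 + flank + 1
    i2 <- hi2 + flank + 2
    acc_add <- tabulate(i1, nbins = width + 1) - tabulate(i2, nbins = width + 1)
    acc <- acc + acc_add
  }
  value <- cumsum(acc[seq_len(width)])
  if (config$per_million) value <- value / (n_fragments / 1e6)
  if (config$per_feature_average) value <- value / nrow(features)
  w <- config$smooth
  if (w %% 2 == 0) w <- w + 1
  if (w > 1) value <- .smooth_ma(value, (w - 1) / 2)
  structure(list(offset = seq(-flank, flank), value = value,
                 n_features = nrow(features), n_fragments = n_fragments,
                 config = config),
            class = "occupancy_profile")
}

#' Average profiles across samples
#'
#' Pointwise arithmetic mean of profiles on identical offset axes. Masked
#' (`NA`) offsets propagate by available-case averaging.
#'
#' @param profiles A list of `occupancy_profile` objects.
#' @return An `occupancy_profile`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]$offset
  for (p in profiles) {
    if (!identical(p$offset, ref)) rlang::abort("profiles have different offset axes")
  }
  vals <- vapply(profiles, function(p) p$value, numeric(length(ref)))
  structure(list(offset = ref,
                 value = rowMeans(as.matrix(vals), na.rm = TRUE),
                 n_features = profiles[[1]]$n_features,
                 n_fragments = NA_real_, config = profiles[[1]]$config),
            class = "occupancy_profile")
}

#' Input-normalise a ChIP profile
#'
#' Pointwise ratio of a ChIP occupancy profile to its sequencing input.
#' Offsets where the input signal is below `min_input` are masked (`NA`),
#' not zeroed.
#'
#' @param chip,input `occupancy_profile` objects on the same axis.
#' @param min_input Mask threshold for the input signal (default `1e-8`).
#' @return An `occupancy_profile` of ratios.
#' @export
normalize_by_input <- function(chip, input, min_input = 1e-8) {
  if (!identical(chip$offset, input$offset)) {
    rlang::abort("profiles have different offset axes")
  }
  ratio <- chip$value / input$value
  ratio[input$value < min_input] <- NA_real_
  structure(list(offset = chip$offset, value = ratio,
                 n_features = chip$n_features, n_fragments = chip$n_fragments,
                 config = chip$config),
            class = "occupancy_profile")
}

#' Aggregate DNA methylation profile around features
#'
#' Sums CpG methylation beta values at each offset from feature centres
#' over all (CpG, feature) pairs within the flank; a CpG in range of two
#' features contributes to both. No normalisation is applied — the profile
#' is in arbitrary units, exactly the summed betas.
#'
#' @param records Methylation tibble ([read_methylation()]).
#' @param features Region tibble with centres.
#' @param config A [profile_config()] (only `flank` and `strand_aware` are
#'   used).
#' @return An object of class `methylation_profile`: `offset`, `value`
#'   (summed beta), `n_features`.
#' @export
aggregate_methylation <- function(records, features,
                                  config = profile_config()) {
  flank <- config$flank
  width <- 2 * flank + 1
  value <- numeric(width)
  centres <- .feature_centres(features)
  strands <- .feature_strands(features, config$strand_aware)
  if (nrow(records) > 0 && nrow(features) > 0) {
    for (ch in intersect(unique(features$chrom), unique(records$chrom))) {
      fi <- which(features$chrom == ch)
      mi <- which(records$chrom == ch)
      win <- IRanges::IRanges(start = centres[fi] - flank + 1,
                              end = centres[fi] + flank + 1)
      pts <- IRanges::IRanges(start = records$position[mi] + 1, width = 1)
      hits <- IRanges::findOverlaps(pts, win)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      off <- records$position[mi][qh] - centres[fi][sh]
      off <- ifelse(strands[fi][sh] == "-", -off, off)
      agg <- rowsum(records$beta[mi][qh], group = off, reorder = FALSE)
      idx <- as.numeric(rownames(agg)) + flank + 1
      value[idx] <- value[idx] + agg[, 1]
    }
  }
  structure(list(offset = seq(-flank, flank), value = value,
                 n_features = nrow(features), config = config),
            class = "methylation_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("<occupancy_profile> offsets ", min(x$offset), "..", max(x$offset),
      " bp over ", x$n_features, " feature(s)\n", sep = "")
  invisible(x)
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat("<methylation_profile> offsets ", min(x$offset), "..", max(x$offset),
      " bp over ", x$n_features, " feature(s), total beta mass ",
      format(sum(x$value), digits = 5), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::tidy
tidy.occupancy_profile <- function(x, ...) {
  tibble::tibble(offset = x$offset, value = x$value)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::tidy
tidy.methylation_profile <- function(x, ...) {
  tibble::tibble(offset = x$offset, beta_sum = x$value)
}
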