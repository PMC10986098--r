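#' Default MNase fragment-size bins
#'
#' The five canonical 20-bp fractionation bins spanning 100-200 bp. Bins are
#' lower-inclusive, upper-exclusive, so adjacent bins are disjoint and
#' partition `[100, 200)`.
#'
#' @return A tibble with columns `low`, `high` (bp) and a `label` such as
#'   `"100-120"`.
#' @export
fragment_size_bins <- function() {
  tibble::tibble(low = c(100, 120, 140, 160, 180),
                 high = c(120, 140, 160, 180, 200),
                 label = c("100-120", "120-140", "140-160",
                           "160-180", "180-200"))
}

#' Filter fragments by size
#'
#' Keeps exactly the fragments with `low <= length < high`; input order is
#' preserved. The default band `[120, 180)` is the mono-nucleosome analysis
#' band used throughout the NRL and classification pipelines.
#'
#' @param fragments Fragment tibble with a `length` column (see
#'   [read_fragments()]).
#' @param low,high Bin bounds in bp, lower-inclusive, upper-exclusive.
#' @return The filtered fragment tibble.
#' @export
filter_by_size <- function(fragments, low = 120, high = 180) {
  stopifnot(low < high)
  fragments[fragments$length >= low & fragments$length < high, ]
}

#' Assign each fragment to a size bin
#'
#' @param fragments Fragment tibble.
#' @param bins A bin tibble as returned by [fragment_size_bins()].
#' @return `fragments` with an added `size_bin` column (`NA` outside all
#'   bins).
#' @export
bin_by_size <- function(fragments, bins = fragment_size_bins()) {
  stopifnot(all(bins$low < bins$high))
  idx <- rep(NA_integer_, nrow(fragments))
  for (i in seq_len(nrow(bins))) {
    hit <- fragments$length >= bins$low[i] & fragments$length < bins$high[i]
    idx[hit] <- i
  }
  fragments$size_bin <- bins$label[idx]
  fragments
}

#' Compute fragment dyads
#'
#' The dyad (nucleosome centre) of a fragment is `start + floor(length / 2)`.
#' The floor convention on even lengths is fixed so that downstream
#' phaseograms are exactly reproducible.
#'
#' @param fragments Fragment tibble.
#' @return `fragments` with an added `dyad` column.
#' @export
compute_dyad <- function(fragments) {
  fragments$dyad <- fragments$start + floor(fragments$length / 2)
  fragments
}

#' Build a dyad track
#'
#' Tallies fragment dyads per base pair: the substrate of the phaseogram.
#'
#' @param fragments Fragment tibble (a `dyad` column is added via
#'   [compute_dyad()] when absent).
#' @return A tibble with columns `chrom`, `pos`, `n` (`n >= 1`), sorted by
#'   chromosome and position; the column sum of `n` equals the number of
#'   contributing fragments.
#' @export
build_dyad_track <- function(fragments) {
  if (nrow(fragments) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(), n = numeric()))
  }
  if (!"dyad" %in% names(fragments)) fragments <- compute_dyad(fragments)
  fragments |>
    dplyr::count(.data$chrom, pos = .data$dyad, name = "n") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Drop hyper-stacked dyad positions
#'
#' Removes entirely every position carrying more than `max_per_bp` dyads:
#' such pileups reflect amplification or mapping artefacts rather than
#' nucleosome spacing. The boundary is kept (`> max_per_bp` is strict), and
#' the operation is idempotent.
#'
#' @param track Dyad track from [build_dyad_track()].
#' @param max_per_bp Stacking cutoff (default 50 dyads per bp).
#' @return The filtered track.
#' @export
drop_stacked_positions <- function(track, max_per_bp = 50) {
  stopifnot(max_per_bp >= 1)
  track[track$n <= max_per_bp, ]
}

#' Cap the number of fragments per chromosome
#'
#' Chromosomes holding at most `max_reads` fragments are returned intact;
#' larger ones are downsampled to exactly `max_reads` fragments, uniformly
#' without replacement, reproducibly under `seed`.
#'
#' @param fragments Fragment tibble.
#' @param max_reads Per-chromosome cap (default 4e7).
#' @param seed Integer seed (required: subsampling must be reproducible).
#' @return The capped fragment tibble.
#' @export
cap_reads_per_chromosome <- function(fragments, max_reads = 4e7, seed) {
  stopifnot(!missing(seed), max_reads >= 1)
  counts <- table(fragments$chrom)
  if (all(counts <= max_reads)) return(fragments)
  keep <- logical(nrow(fragments))
  set.seed(seed)
  for (ch in names(counts)) {
    idx <- which(fragments$chrom == ch)
    if (length(idx) <= max_reads) {
      keep[idx] <- TRUE
    } else {
      keep[sort(sample(idx, max_reads))] <- TRUE
    }
  }
  fragments[keep, ]
}

#' Classify genome windows by GC content
#'
#' Tiles each chromosome into non-overlapping windows (the final partial
#' tile is kept when at least half a window long), computes the GC fraction
#' over non-N bases, and labels windows `low-GC` (`GC < threshold`) or
#' `high-GC`. All-N windows get label `NA`.
#'
#' @param genome A [genome_index()] with sequence.
#' @param window Window size in bp (default 10,000).
#' @param threshold GC fraction separating the two classes (default 0.40).
#' @return A tibble with `chrom`, `start`, `end`, `gc`, `label`.
#' @export
gc_windows <- function(genome, window = 10000, threshold = 0.40) {
  stopifnot(inherits(genome, "genome_index"), window >= 2)
  if (is.null(genome$sequence)) rlang::abort("genome has no sequence")
  res <- purrr::map(seq_len(nrow(genome$chroms)), function(i) {
    ch <- genome$chroms$chrom[i]
    len <- genome$chroms$length[i]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    keep <- (ends - starts) >= window / 2
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) return(NULL)
    v <- Biostrings::Views(genome$sequence[[ch]], start = starts + 1, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
    gc_n <- as.numeric(freq[, "G"] + freq[, "C"])
    tot <- as.numeric(gc_n + freq[, "A"] + freq[, "T"])
    gc <- ifelse(tot > 0, gc_n / tot, NA_real_)
    tibble::tibble(chrom = ch, start = starts, end = ends, gc = gc)
  })
  out <- dplyr::bind_rows(res)
  out$label <- dplyr::case_when(is.na(out$gc) ~ NA_character_,
                                out$gc < threshold ~ "low-GC",
                                TRUE ~ "high-GC")
  out
}

#' Mean fragment GC content by fragment length
#'
#' For every observed fragment length, the arithmetic mean GC fraction of
#' the fragment sequences of that length. N bases are excluded from both
#' numerator and denominator; fragments that are entirely N are skipped.
#'
#' @param fragments Fragment tibble.
#' @param genome A [genome_index()] with sequence.
#' @return A tibble with `length`, `mean_gc`, `n_fragments`, sorted by
#'   length.
#' @export
fragment_gc_by_length <- function(fragments, genome) {
  stopifnot(inherits(genome, "genome_index"))
  if (is.null(genome$sequence)) rlang::abort("genome has no sequence")
  if (nrow(fragments) == 0) {
    return(tibble::tibble(length = numeric(), mean_gc = numeric(),
                          n_fragments = integer()))
  }
  gcs <- purrr::map(split(seq_len(nrow(fragments)), fragments$chrom),
    function(idx) {
      ch <- fragments$chrom[idx[1]]
      v <- Biostrings::Views(genome$sequence[[ch]],
                             start = fragments$start[idx] + 1,
                             end = fragments$end[idx])
      freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
      gc_n <- as.numeric(freq[, "G"] + freq[, "C"])
      tot <- as.numeric(gc_n + freq[, "A"] + freq[, "T"])
      tibble::tibble(idx = idx, gc = ifelse(tot > 0, gc_n / tot, NA_real_))
    }) |> dplyr::bind_rows()
  gcs <- gcs[order(gcs$idx), ]
  tibble::tibble(length = fragments$length, gc = gcs$gc) |>
    dplyr::filter(!is.na(.data$gc)) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(mean_gc = mean(.data$gc), n_fragments = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$length)
}

#' Fragment density per region
#'
#' Counts fragments whose dyad falls inside each region and normalises by
#' region length in kb: the per-gene nucleosome-density statistic used to
#' rank genes by protected-fragment enrichment.
#'
#' @param fragments Fragment tibble.
#' @param regions Region tibble (`chrom`, `start`, `end`, optional `name`).
#' @return `regions` with added `n_fragments` and `density` (fragments per
#'   kb) columns.
#' @export
region_fragment_density <- function(fragments, regions) {
  stopifnot(all(regions$end > regions$start))
  if (!"dyad" %in% names(fragments)) fragments <- compute_dyad(fragments)
  n <- numeric(nrow(regions))
  if (nrow(fragments) > 0 && nrow(regions) > 0) {
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      d <- fragments$dyad[fragments$chrom == ch]
      if (length(d) == 0) next
      # dyad in [start, end): count via sorted cumulative positions
      ds <- sort(d)
      n[ri] <- findInterval(regions$end[ri] - 1, ds) -
        findInterval(regions$start[ri] - 1, ds)
    }
  }
  regions$n_fragments <- n
  regions$density <- n / ((regions$end - regions$start) / 1000)
  regions
}

#' Top or bottom regions by a score
#'
#' @param regions Region tibble with the score column present.
#' @param score Name of the score column (default `"density"`).
#' @param k Number of regions to keep (default 3,000).
#' @param direction `"top"` (largest scores) or `"bottom"`.
#' @return The selected rows of `regions`. Ties are broken by original
#'   order; `k` larger than `nrow(regions)` returns everything.
#' @export
rank_regions <- function(regions, score = "density", k = 3000,
                         direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  stopifnot(score %in% names(regions))
  s <- regions[[score]]
  ord <- if (direction == "top") order(-s) else order(s)
  regions[sort(utils::head(ord, k)), ]
}
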