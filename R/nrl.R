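#' Restrict fragments to regions by dyad membership
#'
#' Keeps the fragments whose dyad lies inside some region. Used before
#' phaseogram construction so that pair distances reflect intra-region
#' nucleosome spacing.
#'
#' @param fragments Fragment tibble.
#' @param regions Region tibble.
#' @return The filtered fragment tibble (with a `dyad` column).
#' @export
restrict_to_regions <- function(fragments, regions) {
  if (!"dyad" %in% names(fragments)) fragments <- compute_dyad(fragments)
  if (nrow(fragments) == 0 || nrow(regions) == 0) return(fragments[0, ])
  keep <- logical(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == ch)
    rr <- regions[regions$chrom == ch, ]
    if (nrow(rr) == 0) next
    q <- IRanges::IRanges(start = fragments$dyad[fi] + 1, width = 1)
    s <- IRanges::IRanges(start = rr$start + 1, end = rr$end)
    keep[fi] <- IRanges::overlapsAny(q, s)
  }
  fragments[keep, ]
}

#' Estimate the nucleosome repeat length of a sample
#'
#' Full estimator pipeline: fragment-size band filter, optional region
#' restriction (by dyad membership), per-chromosome read cap, dyad track,
#' stacked-position drop, phaseogram, peak detection and peak-order
#' regression. Filter attrition is recorded in the returned object's
#' `provenance`.
#'
#' @param fragments Fragment tibble ([read_fragments()]).
#' @param config A [phaseogram_config()].
#' @param regions Optional region tibble restricting the analysis.
#' @return An `nrl_estimate` (see [fit_nrl()]) whose `provenance` lists the
#'   fragment counts retained at each stage, the phaseogram, and the
#'   configuration.
#' @export
estimate_nrl <- function(fragments, config = phaseogram_config(),
                         regions = NULL) {
  n_in <- nrow(fragments)
  frags <- filter_by_size(fragments, config$size_band[1], config$size_band[2])
  n_band <- nrow(frags)
  if (!is.null(regions)) frags <- restrict_to_regions(frags, regions)
  n_region <- nrow(frags)
  frags <- cap_reads_per_chromosome(frags, config$max_reads, seed = config$seed)
  n_cap <- nrow(frags)
  track <- build_dyad_track(frags)
  track <- drop_stacked_positions(track, config$stack_cutoff)
  if (nrow(track) == 0) rlang::abort("insufficient data: no dyads after filtering")
  phas <- compute_phaseogram(track, config)
  peaks <- detect_peaks(phas, config)
  est <- fit_nrl(peaks)
  est$provenance <- list(n_input = n_in, n_in_band = n_band,
                         n_in_regions = n_region, n_after_cap = n_cap,
                         n_dyads_kept = sum(track$n),
                         chroms_used = phas$chroms_used, config = config)
  est$phaseogram <- phas
  est
}

#' Promoter-centred windows around TSSs
#'
#' Builds the `[-flank, +flank)` windows around annotated transcription
#' start sites. For `+`-strand genes the TSS is `start`; for `-`-strand
#' genes it is `end - 1`. Windows are clipped at chromosome ends when a
#' genome is given.
#'
#' @param genes Region tibble with a `strand` column (`+`/`-`).
#' @param flank Half-window in bp (default 5,000).
#' @param genome Optional [genome_index()] for clipping.
#' @return A region tibble of TSS windows.
#' @export
tss_windows <- function(genes, flank = 5000, genome = NULL) {
  if (!"strand" %in% names(genes) || any(!genes$strand %in% c("+", "-"))) {
    rlang::abort("tss_windows requires a strand column with '+'/'-' entries")
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  out <- tibble::tibble(chrom = genes$chrom,
                        start = tss - flank, end = tss + flank,
                        strand = genes$strand)
  if ("name" %in% names(genes)) out$name <- genes$name
  .clip_regions(out, genome)
}

#' Filter gene bodies by length
#'
#' Keeps genes with `min_length < length < max_length` (both strict), the
#' criterion used to select protein-coding gene bodies for intragenic NRL
#' estimation.
#'
#' @param genes Region tibble.
#' @param min_length,max_length Strict bounds in bp (defaults 1 kb and
#'   200 kb).
#' @return The filtered tibble.
#' @export
filter_gene_bodies <- function(genes, min_length = 1000, max_length = 200000) {
  len <- genes$end - genes$start
  genes[len > min_length & len < max_length, ]
}

#' Symmetrically pad regions
#'
#' Extends every region by `pad` bp on both sides, clipping at chromosome
#' boundaries (at 0 when no genome is given).
#'
#' @param regions Region tibble.
#' @param pad Padding in bp (default 1,000).
#' @param genome Optional [genome_index()] for right-end clipping.
#' @return The padded tibble.
#' @export
pad_regions <- function(regions, pad = 1000, genome = NULL) {
  regions$start <- regions$start - pad
  regions$end <- regions$end + pad
  .clip_regions(regions, genome)
}

.clip_regions <- function(regions, genome) {
  regions$start <- pmax(regions$start, 0)
  if (!is.null(genome)) {
    lim <- genome$chroms$length[.chrom_rank(regions$chrom, genome)]
    if (anyNA(lim)) rlang::abort("region on a chromosome absent from the genome index")
    regions$end <- pmin(regions$end, lim)
  }
  regions[regions$end > regions$start, ]
}

#' Compare paired NRL estimates between two conditions
#'
#' Takes a long table of per-sample NRL values, pairs them by patient (and
#' any further grouping columns, e.g. assay), computes per-pair differences
#' `condition_a - condition_b`, and tests the mean difference with a paired
#' two-sided t test. With zero variance of the differences the comparison
#' is reported as degenerate and no p-value is emitted.
#'
#' @param table Tibble with columns `patient`, `condition`, `nrl` (extra
#'   grouping columns are allowed and used in the pairing key).
#' @param condition_a,condition_b The two condition labels to compare
#'   (difference = a - b).
#' @return An object of class `nrl_comparison` with the pair table, mean
#'   difference (bp), `t`, `df`, two-sided `p_value` and `degenerate` flag.
#' @export
compare_paired_nrl <- function(table, condition_a = "normal",
                               condition_b = "tumour") {
  stopifnot(all(c("patient", "condition", "nrl") %in% names(table)))
  keys <- setdiff(names(table), c("condition", "nrl"))
  wide <- table |>
    dplyr::filter(.data$condition %in% c(condition_a, condition_b)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "condition", values_from = "nrl") |>
    dplyr::filter(!is.na(.data[[condition_a]]), !is.na(.data[[condition_b]]))
  if (nrow(wide) < 2) {
    rlang::abort("at least 2 complete pairs are required for a paired t test")
  }
  a <- wide[[condition_a]]
  b <- wide[[condition_b]]
  d <- a - b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, parameter = length(d) - 1,
               p.value = NA_real_)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
  }
  structure(list(pairs = dplyr::mutate(wide, difference = d),
                 condition_a = condition_a, condition_b = condition_b,
                 mean_difference = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = degenerate,
                 n_pairs = length(d)),
            class = "nrl_comparison")
}

#' @export
print.nrl_comparison <- function(x, ...) {
  cat("<nrl_comparison> ", x$condition_a, " - ", x$condition_b, ": mean ",
      format(x$mean_difference, digits = 4), " bp over ", x$n_pairs,
      " pairs", sep = "")
  if (x$degenerate) {
    cat(" (degenerate: zero variance of differences)\n")
  } else {
    cat(", t = ", format(x$t, digits = 4), ", p = ",
        format(x$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::tidy
tidy.nrl_comparison <- function(x, ...) x$pairs

#' @rdname tidy.nrl_estimate
#' @exportS3Method generics::glance
glance.nrl_comparison <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference, t = x$t, df = x$df,
                 p_value = x$p_value, n_pairs = x$n_pairs,
                 degenerate = x$degenerate)
}
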