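#' Run the full analysis on a synthetic cohort
#'
#' End-to-end driver mirroring the study design: generate (or accept) a
#' paired-condition cohort, estimate the NRL of every sample, compare the
#' paired NRLs between conditions, classify nucleosome repositioning per
#' patient against the planted truth, profile methylation around common
#' and shifted nucleosomes, and measure enrichment of the gained set in
#' the planted gained loci's neighbourhoods. All statistics are returned
#' in one report object; with `out_dir`, report tables are written as TSV.
#'
#' @param config A [synthetic_config()].
#' @param cohort Optionally a pre-generated `synthetic_cohort` (overrides
#'   `config`).
#' @param phaseo_config A [phaseogram_config()] for the NRL stage.
#' @param class_config A [classification_config()].
#' @param out_dir Optional output directory for report tables.
#' @return An object of class `pipeline_report`: list with `nrl_table`
#'   (per-sample estimates), `comparison` (`nrl_comparison`),
#'   `classification` (per patient), `class_recovery` (recall/precision
#'   vs planted events), `methylation_profiles`, `enrichment` and the
#'   resolved configurations.
#' @export
run_end_to_end <- function(config = synthetic_config(),
                           cohort = NULL,
                           phaseo_config = phaseogram_config(seed = config$seed),
                           class_config = classification_config(),
                           out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  config <- cohort$config
  frags <- cohort$fragments
  samples <- dplyr::distinct(frags, .data$patient, .data$condition)
  # per-sample NRL
  nrl_rows <- purrr::pmap(samples, function(patient, condition) {
    sub <- frags[frags$patient == patient & frags$condition == condition, ]
    est <- estimate_nrl(sub, phaseo_config)
    tibble::tibble(patient = patient, condition = condition,
                   nrl = est$nrl, r_squared = est$r_squared,
                   n_peaks = est$n_peaks, n_fragments = nrow(sub))
  })
  nrl_table <- dplyr::bind_rows(nrl_rows)
  comparison <- compare_paired_nrl(
    nrl_table[, c("patient", "condition", "nrl")],
    condition_a = "normal", condition_b = "tumour")
  # per-patient classification and recovery against the planted truth
  patients <- unique(frags$patient)
  classification <- list()
  recovery <- list()
  for (pt in patients) {
    get <- function(p, cond) frags[frags$patient == p &
                                     frags$condition == cond, ]
    cls <- classify_pair(get(pt, "normal"), get(pt, "tumour"),
                         lapply(setdiff(patients, pt), get, cond = "normal"),
                         lapply(setdiff(patients, pt), get, cond = "tumour"),
                         class_config)
    classification[[pt]] <- cls
    recovery[[pt]] <- dplyr::mutate(
      event_recovery(cls, cohort$truth), patient = pt, .before = 1)
  }
  class_recovery <- dplyr::bind_rows(recovery)
  # methylation around common vs shifted nucleosomes of the first patient
  meth_profiles <- NULL
  if (nrow(cohort$methylation) > 0) {
    cls1 <- classification[[patients[1]]]
    pc <- profile_config(flank = 1000, strand_aware = FALSE)
    meth_profiles <- list(
      common = aggregate_methylation(cohort$methylation, cls1$common, pc),
      shifted = aggregate_methylation(cohort$methylation, cls1$shifted, pc))
  }
  # enrichment of called gained fragments in the planted gained loci
  enrichment <- NULL
  gained_true <- cohort$truth$loci[cohort$truth$loci$event == "gained", ]
  cls1 <- classification[[patients[1]]]
  if (nrow(gained_true) > 0 && nrow(cls1$gained_b) > 0) {
    ref <- tibble::tibble(chrom = gained_true$chrom,
                          start = gained_true$dyad_tumour - 100,
                          end = gained_true$dyad_tumour + 100)
    enrichment <- fisher_enrichment(cls1$gained_b, ref, cohort$genome,
                                    seed = config$seed, n_shuffles = 10)
  }
  report <- structure(list(nrl_table = nrl_table, comparison = comparison,
                           classification = classification,
                           class_recovery = class_recovery,
                           methylation_profiles = meth_profiles,
                           enrichment = enrichment,
                           truth_nrl = cohort$truth$nrl,
                           config = config, phaseo_config = phaseo_config,
                           class_config = class_config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(nrl_table, file.path(out_dir, "nrl_per_sample.tsv"),
                     progress = FALSE)
    readr::write_tsv(glance(comparison),
                     file.path(out_dir, "nrl_comparison.tsv"),
                     progress = FALSE)
    readr::write_tsv(class_recovery,
                     file.path(out_dir, "event_recovery.tsv"),
                     progress = FALSE)
    counts <- purrr::imap(classification,
                          \(cls, pt) dplyr::mutate(cls$counts, patient = pt,
                                                   .before = 1)) |>
      dplyr::bind_rows()
    readr::write_tsv(counts, file.path(out_dir, "class_counts.tsv"),
                     progress = FALSE)
  }
  report
}

#' Recall and precision of planted repositioning events
#'
#' Scores a classification against the generator truth: a planted event is
#' recovered when at least one called fragment of the matching class has
#' its dyad within 74 bp (half a core particle) of the event's dyad.
#' Precision is the fraction of called fragments lying within 74 bp of
#' some matching planted event.
#'
#' @param class_set A `nucleosome_class_set` from [classify_pair()].
#' @param truth A `synthetic_truth`.
#' @return A tibble with one row per event class (`gained`, `lost`,
#'   `shifted`): planted and recovered counts, `recall`, `precision`.
#' @export
event_recovery <- function(class_set, truth) {
  loci <- truth$loci
  spec <- list(
    gained = list(events = loci[loci$event == "gained", ],
                  dyad_col = "dyad_tumour", called = class_set$gained_b),
    lost = list(events = loci[loci$event == "lost", ],
                dyad_col = "dyad_normal", called = class_set$lost_b),
    shifted = list(events = loci[loci$event == "shifted", ],
                   dyad_col = "dyad_normal", called = class_set$shifted))
  purrr::imap(spec, function(s, cls) {
    ev <- s$events
    called <- compute_dyad(s$called)
    recovered <- 0L
    n_near <- 0L
    for (ch in unique(ev$chrom)) {
      ev_d <- ev[[s$dyad_col]][ev$chrom == ch]
      ca_d <- called$dyad[called$chrom == ch]
      recovered <- recovered + sum(.nearest_distance(ev_d, ca_d) <= 74)
      n_near <- n_near + sum(.nearest_distance(ca_d, ev_d) <= 74)
    }
    hit_frac <- if (nrow(called) > 0 && nrow(ev) > 0) {
      n_near / nrow(called)
    } else {
      NA_real_
    }
    tibble::tibble(class = cls, n_planted = nrow(ev),
                   n_recovered = recovered,
                   recall = if (nrow(ev) > 0) recovered / nrow(ev) else NA_real_,
                   n_called = nrow(called), precision = hit_frac)
  }) |> dplyr::bind_rows()
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n\nPer-sample NRL estimates:\n")
  print(as.data.frame(x$nrl_table), row.names = FALSE)
  cat("\nPaired comparison: ")
  print(x$comparison)
  cat("\nPlanted-event recovery:\n")
  print(as.data.frame(x$class_recovery), row.names = FALSE)
  if (!is.null(x$enrichment)) {
    cat("\nGained-set enrichment at planted gained loci: ")
    print(x$enrichment)
  }
  invisible(x)
}
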