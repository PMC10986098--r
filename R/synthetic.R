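#' Synthetic cohort configuration
#'
#' Parameters of the synthetic paired-condition MNase cohort generator.
#' The generator emulates the data structure the analysis assumes: phased
#' nucleosome arrays with condition-specific repeat length (tumour a few bp
#' shorter), a mono/di-nucleosome fragment-length mixture, per-patient
#' reproducible positions, planted gained/lost/shifted repositioning
#' events, and CpG methylation higher at retained than at shifted
#' nucleosomes. Everything is a pure function of this configuration,
#' including its `seed`.
#'
#' @param seed Integer master seed; all stages derive substreams from it.
#' @param chromosomes Tibble with `chrom`, `length` (bp), `gc` (per-base GC
#'   probability of the i.i.d. synthetic sequence).
#' @param array_span Distance in bp spanned by the dyads of one phased
#'   array; with the default repeat lengths this yields arrays of ~6
#'   nucleosomes.
#' @param gap_mean Mean inter-array gap; each gap is drawn uniformly from
#'   `[0.5, 1.5] * gap_mean`.
#' @param nrl_normal True repeat length of the normal condition (bp).
#' @param nrl_delta Tumour shortening: `nrl_tumour = nrl_normal - nrl_delta`.
#' @param jitter_sd Per-nucleosome positional jitter sd (bp), shared
#'   between the conditions of a locus.
#' @param coverage Mean fragments per nucleosome per sample (Poisson).
#' @param frag_mixture Fragment-length mixture: tibble `component`, `mean`,
#'   `sd`, `weight` (weights sum to 1). The default has subnucleosomal,
#'   core, chromatosome and (20%) dinucleosome components.
#' @param frag_jitter_sd Per-fragment centre jitter sd (bp) for
#'   mono-nucleosome components.
#' @param min_frag_length Fragment lengths are clipped below this (bp).
#' @param frac_gained,frac_lost,frac_shifted Event fractions per locus.
#' @param shift_min,shift_max Shift displacement range as a fraction of the
#'   147-bp core (minimum 0.25 guarantees a reciprocal-overlap failure at
#'   the 80% threshold).
#' @param n_patients Patients per cohort (paired samples each).
#' @param reproducibility Probability that a patient reproduces a base
#'   locus position exactly; otherwise it is jittered by up to
#'   `patient_jitter_max` bp.
#' @param patient_jitter_max Maximum per-patient positional deviation (bp).
#' @param beta_mean_high,beta_mean_low,beta_sd Methylation beta parameters
#'   for CpGs near retained (high) and shifted (low) dyads.
#' @param cpg_rate CpG density per bp, used only when the genome carries no
#'   sequence (with sequence, CpGs are the actual CG dinucleotides).
#' @param with_sequence Generate genome sequence (needed for GC and
#'   methylation work; spacing analyses run without it).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             chromosomes = tibble::tibble(
                               chrom = c("chr1", "chr2"),
                               length = c(4e5, 3e5),
                               gc = c(0.45, 0.38)),
                             array_span = 1000,
                             gap_mean = 600,
                             nrl_normal = 193,
                             nrl_delta = 7,
                             jitter_sd = 10,
                             coverage = 20,
                             frag_mixture = tibble::tibble(
                               component = c("subnucleosomal", "core",
                                             "chromatosome", "dinucleosome"),
                               mean = c(130, 147, 168, 320),
                               sd = c(10, 7, 8, 20),
                               weight = c(0.15, 0.45, 0.20, 0.20)),
                             frag_jitter_sd = 5,
                             min_frag_length = 50,
                             frac_gained = 0.05,
                             frac_lost = 0.05,
                             frac_shifted = 0.05,
                             shift_min = 0.30,
                             shift_max = 0.60,
                             n_patients = 3,
                             reproducibility = 0.9,
                             patient_jitter_max = 3,
                             beta_mean_high = 0.8,
                             beta_mean_low = 0.2,
                             beta_sd = 0.1,
                             cpg_rate = 0.01,
                             with_sequence = TRUE) {
  stopifnot(abs(sum(frag_mixture$weight) - 1) < 1e-9,
            nrl_normal > 0, nrl_delta >= 0,
            frac_gained >= 0, frac_gained <= 1,
            frac_lost >= 0, frac_lost <= 1,
            frac_shifted >= 0, frac_shifted <= 1,
            frac_lost + frac_shifted <= 1,
            n_patients >= 1, reproducibility >= 0, reproducibility <= 1,
            shift_min >= 0.25, shift_max >= shift_min)
  if (nrl_normal - nrl_delta <= 2 * jitter_sd) {
    rlang::abort("repeat length must exceed twice the jitter sd: arrays would be unordered")
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 array_span = array_span, gap_mean = gap_mean,
                 nrl_normal = nrl_normal, nrl_delta = nrl_delta,
                 nrl_tumour = nrl_normal - nrl_delta,
                 jitter_sd = jitter_sd, coverage = coverage,
                 frag_mixture = frag_mixture,
                 frag_jitter_sd = frag_jitter_sd,
                 min_frag_length = min_frag_length,
                 frac_gained = frac_gained, frac_lost = frac_lost,
                 frac_shifted = frac_shifted,
                 shift_min = shift_min, shift_max = shift_max,
                 n_patients = n_patients,
                 reproducibility = reproducibility,
                 patient_jitter_max = patient_jitter_max,
                 beta_mean_high = beta_mean_high,
                 beta_mean_low = beta_mean_low, beta_sd = beta_sd,
                 cpg_rate = cpg_rate, with_sequence = with_sequence),
            class = "synthetic_config")
}

# fixed integer rounding: half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic substream seed per generation stage
.substream <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + stage * 9973) %% 2147483629L
}

#' Generate a synthetic genome
#'
#' I.i.d. bases with the per-chromosome GC probability of the
#' configuration; reproducible under the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return A [genome_index()] (with sequence when `config$with_sequence`).
#' @export
generate_genome <- function(config) {
  chroms <- config$chromosomes
  if (!config$with_sequence) {
    return(genome_index(chroms))
  }
  set.seed(.substream(config$seed, 1L))
  seqs <- lapply(seq_len(nrow(chroms)), function(i) {
    gc <- chroms$gc[i]
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), chroms$length[i], replace = TRUE, prob = p),
          collapse = "")
  })
  seq <- Biostrings::DNAStringSet(unlist(seqs))
  names(seq) <- chroms$chrom
  genome_index(chroms, sequence = seq)
}

#' Generate the ground-truth nucleosome maps
#'
#' Lays phased arrays along each chromosome (anchor spacing `array_span`
#' plus a uniformly jittered gap), draws normal-condition dyads at
#' `anchor + k * L_normal` plus shared Gaussian jitter, derives the tumour
#' map by re-spacing each array at `L_tumour` about the array centre (so
#' conserved loci stay locus-matched while the spacing changes), and
#' plants lost, shifted and gained events at the configured fractions.
#' Per-patient maps reproduce each base position exactly with probability
#' `reproducibility`, else deviate by up to `patient_jitter_max` bp.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_truth`: list with `loci` (one row
#'   per nucleosome locus: `chrom`, `locus`, `array`, `k`, `dyad_normal`,
#'   `dyad_tumour`, `event`), `patient_dyads` (long per patient/condition),
#'   `nrl` (true repeat length per condition) and the `config`.
#' @export
generate_nucleosome_maps <- function(config) {
  set.seed(.substream(config$seed, 2L))
  Ln <- config$nrl_normal
  Lt <- config$nrl_tumour
  chroms <- config$chromosomes
  loci_list <- list()
  array_id <- 0L
  for (i in seq_len(nrow(chroms))) {
    len <- chroms$length[i]
    pos <- config$gap_mean / 2
    anchors <- numeric(0)
    repeat {
      if (pos + config$array_span + config$gap_mean / 2 > len) break
      anchors <- c(anchors, pos)
      gap <- stats::runif(1, 0.5, 1.5) * config$gap_mean
      pos <- pos + config$array_span + gap
    }
    if (length(anchors) == 0) next
    K <- floor(config$array_span / Ln) + 1
    m <- (K - 1) / 2
    for (a in anchors) {
      array_id <- array_id + 1L
      k <- 0:(K - 1)
      e <- .round_half_away(stats::rnorm(K, 0, config$jitter_sd))
      dn <- .round_half_away(a + k * Ln) + e
      dt <- .round_half_away(a + m * Ln + (k - m) * Lt) + e
      # keep dyads ordered and inside the array's stretch of the chromosome
      loci_list[[array_id]] <- tibble::tibble(
        chrom = chroms$chrom[i], array = array_id, k = k,
        dyad_normal = dn, dyad_tumour = dt)
    }
  }
  if (length(loci_list) == 0) rlang::abort("chromosomes too short for any array")
  loci <- dplyr::bind_rows(loci_list)
  n <- nrow(loci)
  # plant lost and shifted events
  u <- stats::runif(n)
  event <- rep("conserved", n)
  event[u < config$frac_lost] <- "lost"
  event[u >= config$frac_lost &
          u < config$frac_lost + config$frac_shifted] <- "shifted"
  loci$event <- event
  loci$dyad_tumour[event == "lost"] <- NA_real_
  loci$shift_bp <- NA_real_
  sh <- which(event == "shifted")
  if (length(sh) > 0) {
    disp <- .round_half_away(stats::runif(length(sh), config$shift_min,
                                          config$shift_max) * 147) *
      sample(c(-1, 1), length(sh), replace = TRUE)
    loci$dyad_tumour[sh] <- loci$dyad_tumour[sh] + disp
    loci$shift_bp[sh] <- disp
  }
  # plant gained loci in inter-array gaps with clearance from both maps
  n_gained <- stats::rbinom(1, n, config$frac_gained)
  gained <- NULL
  if (n_gained > 0) {
    edges <- loci |>
      dplyr::group_by(.data$chrom, .data$array) |>
      dplyr::summarise(
        lo = max(.data$dyad_normal, .data$dyad_tumour, na.rm = TRUE),
        hi = min(.data$dyad_normal, .data$dyad_tumour, na.rm = TRUE),
        .groups = "drop") |>
      dplyr::arrange(.data$chrom, .data$lo)
    gaps <- edges |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(gap_lo = .data$lo + 274,
                    gap_hi = dplyr::lead(.data$hi) - 274) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$gap_hi), .data$gap_hi > .data$gap_lo)
    n_gained <- min(n_gained, nrow(gaps))
    if (n_gained > 0) {
      pick <- sort(sample(nrow(gaps), n_gained))
      gpos <- floor(stats::runif(n_gained, gaps$gap_lo[pick],
                                 gaps$gap_hi[pick] + 1))
      gained <- tibble::tibble(chrom = gaps$chrom[pick], array = NA_integer_,
                               k = NA_integer_, dyad_normal = NA_real_,
                               dyad_tumour = gpos, event = "gained")
    }
  }
  loci <- dplyr::bind_rows(loci, gained)
  loci$locus <- seq_len(nrow(loci))
  # per-patient reproducibility noise
  long <- tidyr::expand_grid(patient = paste0("P", seq_len(config$n_patients)),
                             condition = c("normal", "tumour")) |>
    tidyr::expand_grid(loci[, c("locus", "chrom", "dyad_normal",
                                "dyad_tumour", "event")]) |>
    dplyr::mutate(dyad = ifelse(.data$condition == "normal",
                                .data$dyad_normal, .data$dyad_tumour)) |>
    dplyr::filter(!is.na(.data$dyad))
  jmax <- config$patient_jitter_max
  dev_pool <- setdiff(-jmax:jmax, 0)
  shared <- stats::runif(nrow(long)) < config$reproducibility
  dev <- sample(dev_pool, nrow(long), replace = TRUE)
  long$dyad <- long$dyad + ifelse(shared, 0, dev)
  patient_dyads <- long[, c("patient", "condition", "chrom", "locus",
                            "event", "dyad")]
  structure(list(loci = loci,
                 patient_dyads = patient_dyads,
                 nrl = tibble::tibble(condition = c("normal", "tumour"),
                                      nrl = c(Ln, Lt)),
                 config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$loci), " loci, ",
      x$config$n_patients, " patient(s); true NRL ",
      x$config$nrl_normal, "/", x$config$nrl_tumour, " bp (N/T)\n", sep = "")
  print(table(x$loci$event))
  invisible(x)
}

#' Generate MNase-protected fragments from the truth maps
#'
#' Per nucleosome and sample, draws `Poisson(coverage)` fragments; each
#' fragment draws a mixture component, a Gaussian length (rounded, clipped
#' at `min_frag_length`) and, for mono-nucleosome components, a jittered
#' centre at the dyad. Dinucleosome fragments span two adjacent dyads of
#' the same array (centred at their midpoint). Fragments are clipped to
#' chromosome bounds.
#'
#' @param truth A `synthetic_truth`.
#' @param config The [synthetic_config()] (defaults to the one inside
#'   `truth`).
#' @return A fragment tibble with `patient`, `condition`, `chrom`, `start`,
#'   `end`, `length` columns.
#' @export
generate_fragments <- function(truth, config = truth$config) {
  set.seed(.substream(config$seed, 3L))
  mix <- config$frag_mixture
  chrom_len <- stats::setNames(config$chromosomes$length,
                               config$chromosomes$chrom)
  # neighbour dyad within the same array, for dinucleosome spans
  pd <- truth$patient_dyads |>
    dplyr::left_join(truth$loci[, c("locus", "array", "k")], by = "locus") |>
    dplyr::arrange(.data$patient, .data$condition, .data$chrom,
                   .data$array, .data$k) |>
    dplyr::group_by(.data$patient, .data$condition, .data$array) |>
    dplyr::mutate(nb = dplyr::coalesce(dplyr::lead(.data$dyad),
                                       dplyr::lag(.data$dyad))) |>
    dplyr::ungroup()
  n_frag <- stats::rpois(nrow(pd), config$coverage)
  rows <- rep(seq_len(nrow(pd)), n_frag)
  comp <- sample(seq_len(nrow(mix)), length(rows), replace = TRUE,
                 prob = mix$weight)
  len <- pmax(.round_half_away(stats::rnorm(length(rows), mix$mean[comp],
                                            mix$sd[comp])),
              config$min_frag_length)
  dyad <- pd$dyad[rows]
  nb <- pd$nb[rows]
  di <- mix$component[comp] == "dinucleosome" & !is.na(nb)
  centre <- numeric(length(rows))
  centre[!di] <- dyad[!di] +
    .round_half_away(stats::rnorm(sum(!di), 0, config$frag_jitter_sd))
  centre[di] <- .round_half_away((dyad[di] + nb[di]) / 2)
  start <- centre - floor(len / 2)
  lim <- chrom_len[pd$chrom[rows]]
  start <- pmin(pmax(start, 0), lim - len)
  tibble::tibble(patient = pd$patient[rows], condition = pd$condition[rows],
                 chrom = pd$chrom[rows], start = start, end = start + len,
                 length = len)
}

# distance from each position to the nearest dyad in a sorted vector
.nearest_distance <- function(pos, dyads) {
  if (length(dyads) == 0) return(rep(Inf, length(pos)))
  dyads <- sort(dyads)
  idx <- findInterval(pos, dyads)
  d_lo <- ifelse(idx >= 1, pos - dyads[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(dyads), dyads[pmin(idx + 1, length(dyads))] - pos,
                 Inf)
  pmin(abs(d_lo), abs(d_hi))
}

#' Generate per-CpG methylation levels
#'
#' CpGs within 74 bp of a retained (conserved) dyad draw high betas, CpGs
#' near shifted-event dyads draw low betas, background CpGs are uniform on
#' `[0, 1]`; all betas are clipped to `[0, 1]`. With genome sequence, CpG
#' positions are the actual CG dinucleotides; without, they are placed as a
#' Bernoulli process at `cpg_rate`.
#'
#' @param truth A `synthetic_truth`.
#' @param genome The matching [genome_index()].
#' @param config The [synthetic_config()].
#' @return A methylation tibble (`chrom`, `position`, `beta`).
#' @export
generate_methylation <- function(truth, genome, config = truth$config) {
  set.seed(.substream(config$seed, 4L))
  cpg <- list()
  for (i in seq_len(nrow(genome$chroms))) {
    ch <- genome$chroms$chrom[i]
    if (!is.null(genome$sequence)) {
      hits <- Biostrings::matchPattern("CG", genome$sequence[[ch]])
      pos <- BiocGenerics::start(hits) - 1
    } else {
      len <- genome$chroms$length[i]
      pos <- which(stats::runif(len) < config$cpg_rate) - 1
    }
    if (length(pos) > 0) cpg[[ch]] <- tibble::tibble(chrom = ch, position = pos)
  }
  if (length(cpg) == 0) {
    return(tibble::tibble(chrom = character(), position = numeric(),
                          beta = numeric()))
  }
  cpg <- dplyr::bind_rows(cpg)
  conserved <- truth$loci[truth$loci$event == "conserved", ]
  shifted <- truth$loci[truth$loci$event == "shifted", ]
  beta <- numeric(nrow(cpg))
  for (ch in unique(cpg$chrom)) {
    ci <- which(cpg$chrom == ch)
    cons_d <- c(conserved$dyad_normal[conserved$chrom == ch],
                conserved$dyad_tumour[conserved$chrom == ch])
    shif_d <- c(shifted$dyad_normal[shifted$chrom == ch],
                shifted$dyad_tumour[shifted$chrom == ch])
    near_cons <- .nearest_distance(cpg$position[ci], cons_d) <= 74
    near_shift <- .nearest_distance(cpg$position[ci], shif_d) <= 74 & !near_cons
    b <- stats::runif(length(ci))
    b[near_cons] <- stats::rnorm(sum(near_cons), config$beta_mean_high,
                                 config$beta_sd)
    b[near_shift] <- stats::rnorm(sum(near_shift), config$beta_mean_low,
                                  config$beta_sd)
    beta[ci] <- pmin(pmax(b, 0), 1)
  }
  cpg$beta <- beta
  cpg
}

#' Generate a complete synthetic cohort
#'
#' Runs the genome, map, fragment and methylation generators and
#' (optionally) writes the cohort to disk: `genome.fa`, `chrom.sizes`, one
#' fragment BED per patient/condition, `methylation.tsv`, truth tables and
#' a `manifest.tsv` with MD5 checksums of every artefact.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (`NULL` keeps everything in memory).
#' @return An object of class `synthetic_cohort`: list with `genome`,
#'   `truth`, `fragments`, `methylation`, `config` and (when written)
#'   `manifest`.
#' @export
generate_cohort <- function(config = synthetic_config(), out_dir = NULL) {
  genome <- generate_genome(config)
  truth <- generate_nucleosome_maps(config)
  fragments <- generate_fragments(truth, config)
  methylation <- generate_methylation(truth, genome, config)
  cohort <- structure(list(genome = genome, truth = truth,
                           fragments = fragments, methylation = methylation,
                           config = config),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(genome$sequence)) {
      p <- file.path(out_dir, "genome.fa")
      write_genome(genome, fasta = p)
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "chrom.sizes")
    write_genome(genome, chrom_sizes = p)
    paths <- c(paths, p)
    for (pt in unique(fragments$patient)) {
      for (cond in unique(fragments$condition)) {
        sub <- fragments[fragments$patient == pt &
                           fragments$condition == cond, ]
        p <- file.path(out_dir, paste0(pt, "_", cond, ".bed"))
        write_fragments(sub, p, genome)
        paths <- c(paths, p)
      }
    }
    p <- file.path(out_dir, "methylation.tsv")
    readr::write_tsv(methylation, p, col_names = FALSE, progress = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "truth_loci.tsv")
    readr::write_tsv(truth$loci, p, progress = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "truth_nrl.tsv")
    readr::write_tsv(truth$nrl, p, progress = FALSE)
    paths <- c(paths, p)
    manifest <- tibble::tibble(file = basename(paths),
                               md5 = unname(tools::md5sum(paths)))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                     progress = FALSE)
    cohort$manifest <- manifest
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_patients, " patient(s) x 2 conditions, ",
      nrow(x$fragments), " fragments, ", nrow(x$truth$loci), " loci\n",
      sep = "")
  invisible(x)
}
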