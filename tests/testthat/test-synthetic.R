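small_cfg <- function(...) {
  synthetic_config(seed = 17,
                   chromosomes = tibble::tibble(chrom = "chr1",
                                                length = 60000, gc = 0.5),
                   n_patients = 2, ...)
}

test_that("synthetic genomes hit the requested GC content", {
  cfg <- synthetic_config(seed = 2,
                          chromosomes = tibble::tibble(chrom = "chr1",
                                                       length = 1e6,
                                                       gc = 0.5))
  gi <- generate_genome(cfg)
  f <- Biostrings::letterFrequency(gi$sequence[[1]], c("G", "C"))
  gc <- sum(f) / 1e6
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6) + 1e-3)
  # all-AT genome
  cfg0 <- synthetic_config(seed = 2,
                           chromosomes = tibble::tibble(chrom = "chr1",
                                                        length = 10000,
                                                        gc = 0))
  gi0 <- generate_genome(cfg0)
  expect_equal(sum(Biostrings::letterFrequency(gi0$sequence[[1]],
                                               c("G", "C"))), 0)
  # determinism
  gi2 <- generate_genome(cfg)
  expect_identical(as.character(gi$sequence), as.character(gi2$sequence))
})

test_that("noiseless maps space dyads exactly at the repeat length", {
  cfg <- synthetic_config(seed = 3, jitter_sd = 0, frac_gained = 0,
                          frac_lost = 0, frac_shifted = 0,
                          reproducibility = 1, n_patients = 1,
                          with_sequence = FALSE)
  truth <- generate_nucleosome_maps(cfg)
  per_array <- split(truth$loci, truth$loci$array)
  for (arr in per_array) {
    expect_equal(diff(arr$dyad_normal), rep(193, nrow(arr) - 1))
    expect_equal(diff(arr$dyad_tumour), rep(186, nrow(arr) - 1))
  }
  # array length 1000 at L = 193 holds 6 nucleosomes
  expect_equal(unique(vapply(per_array, nrow, integer(1))), 6)
})

test_that("a null configuration leaves the tumour map identical", {
  cfg <- synthetic_config(seed = 4, nrl_delta = 0, frac_gained = 0,
                          frac_lost = 0, frac_shifted = 0,
                          with_sequence = FALSE)
  truth <- generate_nucleosome_maps(cfg)
  expect_equal(truth$loci$dyad_normal, truth$loci$dyad_tumour)
  expect_true(all(truth$loci$event == "conserved"))
})

test_that("planted event counts follow the configured fractions", {
  cfg <- synthetic_config(seed = 5, with_sequence = FALSE,
                          chromosomes = tibble::tibble(
                            chrom = "chr1", length = 2e6, gc = 0.5))
  truth <- generate_nucleosome_maps(cfg)
  n <- sum(truth$loci$event != "gained")
  for (ev in c("gained", "lost", "shifted")) {
    k <- sum(truth$loci$event == ev)
    expect_lt(abs(k - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)
  }
  # shifted displacements are at least a quarter fragment length
  sh <- truth$loci[truth$loci$event == "shifted", ]
  expect_true(all(abs(sh$shift_bp) >= 0.25 * 147))
})

test_that("gained loci never touch retained fragments of either map", {
  truth <- generate_nucleosome_maps(small_cfg(with_sequence = FALSE))
  g <- truth$loci[truth$loci$event == "gained", ]
  others <- truth$loci[truth$loci$event != "gained", ]
  dy <- c(others$dyad_normal, others$dyad_tumour)
  dy <- dy[!is.na(dy)]
  for (p in g$dyad_tumour) expect_gt(min(abs(dy - p)), 148)
})

test_that("fragment counts and the length mixture behave as configured", {
  cfg <- small_cfg(with_sequence = FALSE, coverage = 20)
  truth <- generate_nucleosome_maps(cfg)
  frags <- generate_fragments(truth, cfg)
  n_nuc <- nrow(truth$patient_dyads)
  expect_lt(abs(nrow(frags) - 20 * n_nuc), 3 * sqrt(20 * n_nuc) + 1)
  # modes at the core and chromatosome sizes
  h <- table(frags$length)
  expect_gt(h["147"], h["160"])
  expect_gt(h["168"], h["180"])
  # a pure-core mixture gives constant length 147
  cfg_core <- small_cfg(with_sequence = FALSE,
                        frag_mixture = tibble::tibble(
                          component = "core", mean = 147, sd = 0, weight = 1))
  frags_core <- generate_fragments(generate_nucleosome_maps(cfg_core),
                                   cfg_core)
  expect_true(all(frags_core$length == 147))
})

test_that("methylation betas separate retained from shifted loci", {
  cfg <- small_cfg(beta_sd = 0)
  cohort <- generate_cohort(cfg)
  meth <- cohort$methylation
  loci <- cohort$truth$loci
  cons <- loci[loci$event == "conserved", ]
  # CpGs at conserved dyads carry exactly the high beta when sd = 0
  at_cons <- meth[meth$position %in% cons$dyad_normal, ]
  expect_true(nrow(at_cons) > 0)
  expect_true(all(at_cons$beta == 0.8))
  # no CG dinucleotides -> empty table
  cfg_at <- synthetic_config(seed = 18,
                             chromosomes = tibble::tibble(chrom = "chr1",
                                                          length = 50000,
                                                          gc = 0))
  cohort_at <- generate_cohort(cfg_at)
  expect_equal(nrow(cohort_at$methylation), 0)
})

test_that("cohorts write one BED per sample and a reproducible manifest", {
  cfg <- small_cfg(with_sequence = FALSE)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, out_dir = dir1)
  c2 <- generate_cohort(cfg, out_dir = dir2)
  beds <- list.files(dir1, pattern = "\\.bed$")
  expect_equal(sort(beds), sort(paste0(rep(c("P1", "P2"), each = 2), "_",
                                       c("normal", "tumour"), ".bed")))
  expect_equal(c1$manifest$md5, c2$manifest$md5)
  # truth NRL table echoes the configuration
  expect_equal(c1$truth$nrl$nrl, c(193, 186))
})

test_that("generation is a pure function of the configuration", {
  cfg <- small_cfg(with_sequence = FALSE)
  t1 <- generate_nucleosome_maps(cfg)
  t2 <- generate_nucleosome_maps(cfg)
  expect_identical(t1$loci, t2$loci)
  expect_identical(generate_fragments(t1, cfg), generate_fragments(t2, cfg))
})

test_that("unordered-array configurations are rejected", {
  expect_error(synthetic_config(nrl_normal = 30, nrl_delta = 0,
                                jitter_sd = 15),
               "unordered")
})
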