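test_that("overlap_bp follows half-open interval arithmetic", {
  a <- frag_tbl("chr1", c(100, 100, 0), c(250, 200, 10))
  b <- frag_tbl("chr1", c(101, 200, 0), c(251, 300, 10))
  expect_equal(overlap_bp(a, b), c(149, 0, 10))
  # different chromosomes never overlap
  expect_equal(overlap_bp(frag_tbl("chr1", 0, 10), frag_tbl("chr2", 0, 10)), 0)
})

test_that("fraction matching uses >= against the unrounded threshold", {
  a <- frag_tbl("chr1", 100, 250)  # length 150, 0.99 threshold = 148.5
  expect_true(has_match(a, frag_tbl("chr1", 101, 251), f = 0.99))
  expect_false(has_match(a, frag_tbl("chr1", 103, 253), f = 0.99))
  # reciprocal boundary: overlap 120 equals 0.80 * 150 exactly
  expect_true(has_match(a, frag_tbl("chr1", 130, 280), f = 0.80,
                        reciprocal = TRUE))
  # reciprocal fails when the subject is too long even if the query is covered
  expect_false(has_match(a, frag_tbl("chr1", 50, 400), f = 0.80,
                         reciprocal = TRUE))
  expect_true(has_match(a, frag_tbl("chr1", 50, 400), f = 0.80))
})

test_that("stable calling needs a 99% match in at least one other patient", {
  p2 <- frag_tbl("chr1", c(100, 1000), c(250, 1150))
  p1 <- frag_tbl("chr1", 101, 251)
  p3 <- frag_tbl("chr1", 5000, 5150)
  stable <- call_stable(p2, list(p1, p3))
  expect_equal(stable$start, 100)
  # reproduced in two other patients still counted once
  stable2 <- call_stable(p2, list(p1, frag_tbl("chr1", 100, 250)))
  expect_equal(nrow(stable2), 1)
  expect_error(call_stable(p2, list()), "non-empty")
})

test_that("common and shifted leave an intermediate zone", {
  a <- frag_tbl("chr1", 100, 250)
  cfg <- classification_config()
  # near-exact reproduction: common, not shifted
  cs <- call_common_shifted(a, frag_tbl("chr1", 101, 251), cfg)
  expect_equal(nrow(cs$common), 1)
  expect_equal(nrow(cs$shifted), 0)
  # overlap 110/150 = 73%: shifted, not common
  cs2 <- call_common_shifted(a, frag_tbl("chr1", 140, 290), cfg)
  expect_equal(nrow(cs2$common), 0)
  expect_equal(nrow(cs2$shifted), 1)
  # overlap 135/150 = 90%: neither label
  cs3 <- call_common_shifted(a, frag_tbl("chr1", 115, 265), cfg)
  expect_equal(nrow(cs3$common), 0)
  expect_equal(nrow(cs3$shifted), 0)
})

test_that("gained/lost require zero overlap, abutment counts as zero", {
  stable_a <- frag_tbl("chr1", c(850, 0), c(1000, 150))
  stable_b <- frag_tbl("chr1", c(1000, 500), c(1150, 650))
  gl <- call_gained_lost(stable_a, stable_b)
  # [1000,1150) abuts [850,1000): gained; [500,650) disjoint: gained
  expect_equal(sort(gl$gained_b$start), c(500, 1000))
  expect_equal(sort(gl$lost_b$start), c(0, 850))
  # a single bp of overlap disqualifies
  gl2 <- call_gained_lost(frag_tbl("chr1", 850, 1000),
                          frag_tbl("chr1", 999, 1149))
  expect_equal(nrow(gl2$gained_b), 0)
  expect_equal(nrow(gl2$lost_b), 0)
})

test_that("gained and lost are symmetric under swapping conditions", {
  set.seed(11)
  mk <- function() {
    s <- sort(sample(0:20000, 40)) * 10
    frag_tbl("chr1", s, s + sample(120:179, 40, replace = TRUE))
  }
  a <- mk(); b <- mk()
  gl <- call_gained_lost(a, b)
  lg <- call_gained_lost(b, a)
  expect_equal(gl$gained_b, lg$lost_b)
  expect_equal(gl$lost_b, lg$gained_b)
})

test_that("all matching operations agree with the brute-force oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:120, 1)
    mk <- function(n) {
      chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
      start <- sample(0:3000, n, replace = TRUE)
      frag_tbl(chrom, start, start + sample(120:179, n, replace = TRUE))
    }
    q <- mk(n); s <- mk(sample(20:120, 1))
    for (f in c(0.5, 0.8, 0.99)) {
      expect_identical(has_match(q, s, f), brute_has_match(q, s, f))
      expect_identical(has_match(q, s, f, reciprocal = TRUE),
                       brute_has_match(q, s, f, reciprocal = TRUE))
    }
    expect_identical(count_overlap_flags(q, s), brute_any_overlap(q, s))
  }
})

test_that("classify_pair is exact on identity and translation", {
  set.seed(5)
  s <- sort(sample(0:5000, 50)) * 4
  a <- frag_tbl("chr1", s, s + 150)
  others <- list(a)
  # A == B: everything common, nothing shifted/gained/lost
  cls <- classify_pair(a, a, others, others)
  expect_equal(nrow(cls$common), nrow(cls$stable_a))
  expect_equal(nrow(cls$shifted), 0)
  expect_equal(nrow(cls$gained_b), 0)
  expect_equal(nrow(cls$lost_b), 0)
  # B translated far away: nothing common, everything gained/lost
  b <- dplyr::mutate(a, start = start + 100000, end = end + 100000)
  cls2 <- classify_pair(a, b, others, list(b))
  expect_equal(nrow(cls2$common), 0)
  expect_equal(nrow(cls2$gained_b), nrow(cls2$stable_b))
  expect_equal(nrow(cls2$lost_b), nrow(cls2$stable_a))
})

test_that("label counts are invariant under input permutation", {
  set.seed(21)
  mk <- function(n) {
    start <- sample(0:4000, n) * 3
    frag_tbl("chr1", start, start + sample(c(130, 147, 168), n, TRUE))
  }
  a <- mk(80); b <- mk(80); o1 <- mk(80); o2 <- mk(80)
  cls <- classify_pair(a, b, list(o1, o2), list(o2, o1))
  perm <- function(x) x[sample(nrow(x)), ]
  cls2 <- classify_pair(perm(a), perm(b), list(perm(o1), perm(o2)),
                        list(perm(o2), perm(o1)))
  expect_equal(dplyr::arrange(cls$counts, class),
               dplyr::arrange(cls2$counts, class))
})

test_that("threshold monotonicity: shifted grows, common shrinks", {
  set.seed(31)
  start_a <- sample(0:2000, 60) * 5
  a <- frag_tbl("chr1", start_a, start_a + 150)
  b <- dplyr::mutate(a, start = start + sample(0:80, 60, TRUE)) |>
    dplyr::mutate(end = start + 150)
  n_shift <- n_common <- numeric(0)
  for (f in c(0.6, 0.8, 0.95)) {
    cs <- call_common_shifted(a, b, classification_config(f_shift = f,
                                                          f_common = f))
    n_shift <- c(n_shift, nrow(cs$shifted))
    n_common <- c(n_common, nrow(cs$common))
  }
  expect_true(all(diff(n_shift) >= 0))
  expect_true(all(diff(n_common) <= 0))
})
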