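test_that("size filtering is lower-inclusive, upper-exclusive", {
  frags <- frag_tbl("chr1", c(0, 0, 0, 0), c(119, 120, 139, 140))
  kept <- filter_by_size(frags, 120, 140)
  expect_equal(kept$length, c(120, 139))
  # mono-nucleosome analysis band
  frags2 <- frag_tbl("chr1", c(0, 0, 0), c(147, 168, 185))
  expect_equal(filter_by_size(frags2, 120, 180)$length, c(147, 168))
  # degenerate wide bin is the identity
  expect_equal(filter_by_size(frags2, 0, 1e9), frags2)
})

test_that("the five default bins partition the 100-200 band", {
  set.seed(42)
  frags <- frag_tbl("chr1", rep(0, 500), sample(80:220, 500, replace = TRUE))
  bins <- fragment_size_bins()
  binned <- bin_by_size(frags)
  in_band <- filter_by_size(frags, 100, 200)
  per_bin <- vapply(seq_len(nrow(bins)),
                    function(i) nrow(filter_by_size(frags, bins$low[i],
                                                    bins$high[i])),
                    numeric(1))
  expect_equal(sum(per_bin), nrow(in_band))
  expect_equal(sum(!is.na(binned$size_bin)), nrow(in_band))
})

test_that("dyads use the floor-midpoint rule", {
  frags <- frag_tbl("chr1", c(100, 100, 0), c(250, 247, 2))
  d <- compute_dyad(frags)$dyad
  expect_equal(d, c(175, 173, 1))
})

test_that("dyad tracks tally multiplicities and conserve totals", {
  frags <- compute_dyad(frag_tbl("chr1", c(100, 100, 100), c(250, 250, 250)))
  tr <- build_dyad_track(frags)
  expect_equal(tr$pos, 175)
  expect_equal(tr$n, 3)
  frags2 <- frag_tbl("chr1", c(5, 15, 15), c(15, 25, 25))
  tr2 <- build_dyad_track(frags2)
  expect_equal(tr2$pos, c(10, 20))
  expect_equal(tr2$n, c(1, 2))
  expect_equal(sum(tr2$n), nrow(frags2))
  expect_equal(nrow(build_dyad_track(frags2[0, ])), 0)
})

test_that("stacked-position filtering is strict and idempotent", {
  tr <- tibble::tibble(chrom = "chr1", pos = c(100, 300), n = c(60, 10))
  expect_equal(drop_stacked_positions(tr, 50)$pos, 300)
  # boundary kept: 'more than 50' excludes only > 50
  tr50 <- tibble::tibble(chrom = "chr1", pos = 100, n = 50)
  expect_equal(drop_stacked_positions(tr50, 50), tr50)
  # cutoff-invariance when no position exceeds the smaller cap
  set.seed(1)
  tr3 <- tibble::tibble(chrom = "chr1", pos = 1:200 * 7,
                        n = sample(1:15, 200, replace = TRUE))
  expect_equal(drop_stacked_positions(tr3, 20), drop_stacked_positions(tr3, 50))
  # idempotence
  once <- drop_stacked_positions(tr, 50)
  expect_equal(drop_stacked_positions(once, 50), once)
})

test_that("per-chromosome read capping subsamples reproducibly", {
  frags <- frag_tbl("chr1", 1:100 * 10, 1:100 * 10 + 147)
  expect_equal(cap_reads_per_chromosome(frags, 1000, seed = 3), frags)
  big <- frag_tbl(rep(c("chrA", "chrB"), c(150, 80)),
                  seq_len(230) * 5, seq_len(230) * 5 + 147)
  capped <- cap_reads_per_chromosome(big, 100, seed = 3)
  expect_equal(as.vector(table(capped$chrom)[c("chrA", "chrB")]), c(100, 80))
  again <- cap_reads_per_chromosome(big, 100, seed = 3)
  expect_identical(capped, again)
  # capping never increases and is idempotent
  expect_identical(cap_reads_per_chromosome(capped, 100, seed = 3), capped)
})

test_that("GC windows tile, label and handle the strict threshold", {
  at <- strrep("AT", 10000)   # 20 kb all-AT
  gc <- strrep("GC", 10000)
  gi <- toy_genome(c(chrA = 20000, chrB = 20000), seqs = c(at, gc))
  win <- gc_windows(gi, window = 10000, threshold = 0.40)
  expect_equal(win$gc, c(0, 0, 1, 1))
  expect_equal(win$label, c("low-GC", "low-GC", "high-GC", "high-GC"))
  # 3,999 G+C of 10,000 is strictly below the 40% threshold
  seq3999 <- paste0(strrep("G", 3999), strrep("A", 6001))
  gi2 <- toy_genome(c(chr1 = 10000), seqs = seq3999)
  win2 <- gc_windows(gi2)
  expect_equal(win2$gc, 0.3999)
  expect_equal(win2$label, "low-GC")
})

test_that("GC labels are invariant under reverse complement", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                    prob = c(.3, .2, .2, .3)), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g1 <- gc_windows(toy_genome(c(chr1 = 20000), seqs = s))
  g2 <- gc_windows(toy_genome(c(chr1 = 20000), seqs = rc))
  expect_equal(g1$gc, rev(g2$gc))
  expect_equal(g1$label, rev(g2$label))
})

test_that("final partial GC tile kept only when at least half a window", {
  s <- strrep("G", 26000)
  win <- gc_windows(toy_genome(c(chr1 = 26000), seqs = s), window = 10000)
  expect_equal(nrow(win), 3)  # 6 kb remainder >= 5 kb kept
  s2 <- strrep("G", 24000)
  win2 <- gc_windows(toy_genome(c(chr1 = 24000), seqs = s2), window = 10000)
  expect_equal(nrow(win2), 2)  # 4 kb remainder dropped
})

test_that("fragment GC by length averages and excludes N bases", {
  seqs <- c(paste0(strrep("G", 100), strrep("A", 100),
                   "GGGGGAAAAANNNNN", strrep("T", 85)))
  gi <- toy_genome(c(chr1 = 300), seqs = seqs)
  frags <- frag_tbl("chr1", c(0, 100, 200), c(100, 200, 215))
  res <- fragment_gc_by_length(frags, gi)
  expect_equal(res$mean_gc[res$length == 100], 0.5)  # mean of 1.0 and 0.0
  # 15 bp fragment: 5 G, 5 A, 5 N -> GC = 5/10
  expect_equal(res$mean_gc[res$length == 15], 0.5)
})

test_that("region fragment density counts dyads and is additive", {
  frags <- frag_tbl("chr1", seq(0, 1990, by = 199), seq(0, 1990, by = 199) + 100)
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 2000)
  res <- region_fragment_density(frags, regions)
  expect_equal(res$n_fragments, 10)
  expect_equal(res$density, 5.0)
  # no dyads -> zero
  far <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(region_fragment_density(frags, far)$density, 0)
  # split additivity: length-weighted mean of halves equals the whole
  halves <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                           end = c(1000, 2000))
  dh <- region_fragment_density(frags, halves)
  expect_equal(sum(dh$density * 1000) / 2000, res$density)
  expect_equal(sum(dh$n_fragments), res$n_fragments)
})

test_that("rank_regions selects top and bottom k", {
  regions <- tibble::tibble(chrom = "chr1", start = c(0, 10, 20),
                            end = c(5, 15, 25),
                            density = c(5.0, 0.0, 7.5))
  expect_equal(rank_regions(regions, "density", k = 1)$density, 7.5)
  expect_equal(rank_regions(regions, "density", k = 1,
                            direction = "bottom")$density, 0.0)
  expect_equal(nrow(rank_regions(regions, "density", k = 10)), 3)
})
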