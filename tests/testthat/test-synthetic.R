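# The synthetic-data generator: determinism, parameter contracts, and
# the noise model.

test_that("generate_truth respects its construction contracts", {
  t1 <- generate_truth(80, 5, sigma = 1, unstable_frac = 0.10, seed = 11)
  expect_equal(t1$n_segments, 80L)
  expect_equal(t1$n_samples, 5L)
  expect_length(t1$purity, 5)
  # unstable fraction hits the requested value up to rounding
  expect_equal(mean(t1$unstable_mask), 0.10, tolerance = 1 / 80)
  # parameter ranges
  expect_true(all(t1$purity > 0.04 & t1$purity < 0.45))
  expect_true(all(t1$subclonal_ratio[-1] > 0.05 &
                    t1$subclonal_ratio[-1] < 0.8))
  expect_lt(t1$subclonal_ratio[1], 0.04)
  expect_true(all(t1$ancestral_cn %in% 1:5))
  expect_true(all(abs(t1$subclonal_cn - t1$ancestral_cn) <= 2))
  expect_true(all(t1$subclonal_cn >= 0))
  expect_true(all(t1$segment_lengths >= 120 & t1$segment_lengths <= 800))
  # determinism
  t2 <- generate_truth(80, 5, sigma = 1, unstable_frac = 0.10, seed = 11)
  expect_identical(t1, t2)
  # invalid arguments
  expect_error(generate_truth(80, 1, 1, 0.1, seed = 1), "n_samples")
  expect_error(generate_truth(80, 5, 1, 0.5, seed = 1), "unstable_frac")
  expect_error(generate_truth(80, 5, -1, 0.1, seed = 1), "sigma")
})

test_that("diploid ancestral state is the most frequent over many seeds", {
  counts <- integer(5)
  for (s in 1:30) {
    tr <- generate_truth(80, 2, 1, 0.1, seed = 1000 + s)
    counts <- counts + tabulate(tr$ancestral_cn, 5)
  }
  expect_true(all(counts[2] > counts[-2]))
  # offset 0 (clonal segments) dominates the offsets similarly
  offs <- integer(5)
  for (s in 1:30) {
    tr <- generate_truth(80, 2, 1, 0.1, seed = 2000 + s)
    offs <- offs + tabulate(tr$subclonal_cn - tr$ancestral_cn + 3, 5)
  }
  expect_true(all(offs[3] > offs[-3]))
})

test_that("noiseless rendered segment means follow the mixture model exactly", {
  tr <- generate_truth(30, 3, sigma = 0, unstable_frac = 0, seed = 5)
  profiles <- render_bins(tr)
  seg_of_bin <- rep(seq_len(tr$n_segments), tr$segment_lengths)
  for (i in seq_len(tr$n_samples)) {
    expected <- 2 + tr$purity[i] *
      ((1 - tr$subclonal_ratio[i]) * tr$ancestral_cn +
         tr$subclonal_ratio[i] * tr$subclonal_cn - 2)
    got <- tapply(profiles[[i]]$bins$raw_cn, seg_of_bin, mean)
    expect_equal(as.vector(got), expected, tolerance = 1e-12)
    # segmented value equals the mean of the segment's raw bins
    expect_equal(as.vector(tapply(profiles[[i]]$bins$segmented_cn,
                                  seg_of_bin, unique)), expected,
                 tolerance = 1e-12)
  }
})

test_that("a specific noiseless configuration reproduces the known peak value", {
  # purity 0.21, clonal segment of copy number 3 -> measured CN 2.21
  tr <- generate_truth(10, 2, sigma = 0, unstable_frac = 0, seed = 3)
  tr$ancestral_cn[] <- 3L
  tr$subclonal_cn[] <- 3L
  tr$purity[] <- 0.21
  profiles <- render_bins(tr)
  expect_equal(unique(round(profiles[[1]]$bins$raw_cn, 12)), 2.21)
  # mixture arithmetic: p=0.5, r=0.5, C(A)=3, C(S)=1 -> 2.0
  tr$ancestral_cn[] <- 3L; tr$subclonal_cn[] <- 1L
  tr$purity[] <- 0.5; tr$subclonal_ratio[] <- 0.5
  profiles <- render_bins(tr)
  expect_equal(unique(round(profiles[[2]]$bins$raw_cn, 12)), 2)
})

test_that("segment means concentrate as the CLT predicts under noise", {
  tr <- generate_truth(40, 2, sigma = 1, unstable_frac = 0, seed = 9,
                       length_range = c(800L, 800L))
  profiles <- render_bins(tr)
  seg_of_bin <- rep(seq_len(tr$n_segments), tr$segment_lengths)
  i <- 2
  noiseless <- 2 + tr$purity[i] *
    ((1 - tr$subclonal_ratio[i]) * tr$ancestral_cn +
       tr$subclonal_ratio[i] * tr$subclonal_cn - 2)
  got <- as.vector(tapply(profiles[[i]]$bins$raw_cn, seg_of_bin, mean))
  bound <- 4 * noise_sd(1, noiseless) / sqrt(800)
  expect_true(all(abs(got - noiseless) < bound))
})

test_that("unstable segments ignore the subclonal ratio", {
  tr <- generate_truth(40, 4, sigma = 0, unstable_frac = 0.15, seed = 21)
  profiles <- render_bins(tr)
  seg_of_bin <- rep(seq_len(tr$n_segments), tr$segment_lengths)
  j <- which(tr$unstable_mask)[1]
  for (i in seq_len(tr$n_samples)) {
    got <- mean(profiles[[i]]$bins$raw_cn[seg_of_bin == j])
    expect_equal(got, 2 + tr$purity[i] * (tr$unstable_cn[i, j] - 2),
                 tolerance = 1e-12)
  }
})

test_that("mix_bin_profiles is a convex combination on a shared grid", {
  a <- make_profile("a", raw = rep(4, 10))
  b <- make_profile("b", raw = rep(2, 10))
  n <- make_profile("n", raw = rep(2, 10))
  # identity
  m1 <- mix_bin_profiles(list(a, b, n), c(1, 0, 0))
  expect_equal(m1$bins$raw_cn, a$bins$raw_cn)
  # two diploid profiles stay diploid under any weights
  m2 <- mix_bin_profiles(list(b, n), c(0.3, 0.7))
  expect_true(all(m2$bins$raw_cn == 2))
  # ancestral CN 4, subclonal CN 2, normal 2 at weights (0.3, 0.1, 0.6)
  # equals the mixture model at p = 0.4, r = 0.25: 2 + 0.4*(0.75*4 + 0.25*2 - 2)
  m3 <- mix_bin_profiles(list(a, b, n), c(0.3, 0.1, 0.6))
  expect_equal(unique(m3$bins$raw_cn),
               2 + 0.4 * (0.75 * 4 + 0.25 * 2 - 2))
  # mismatched grids fail
  short <- make_profile("s", raw = rep(2, 5))
  expect_error(mix_bin_profiles(list(a, short), c(0.5, 0.5)), "grid")
  expect_error(mix_bin_profiles(list(a, b), c(0.5, 0.6)), "weights")
})

test_that("truth sidecar round-trips through its TSV representation", {
  tr <- generate_truth(25, 3, sigma = 0.5, unstable_frac = 0.08, seed = 13)
  stem <- file.path(withr::local_tempdir(), "truth")
  write_truth(tr, stem)
  back <- read_truth(stem)
  expect_equal(back$samples$purity, tr$purity)
  expect_equal(back$samples$subclonal_ratio, tr$subclonal_ratio)
  expect_equal(back$segments$ancestral_cn, tr$ancestral_cn)
  expect_equal(back$segments$unstable, tr$unstable_mask)
  expect_equal(back$segments[["zeta.S2"]], tr$unstable_cn[2, ])
})

test_that("rendering is deterministic given the truth", {
  tr <- generate_truth(20, 3, sigma = 1, unstable_frac = 0.1, seed = 77)
  p1 <- render_bins(tr)
  p2 <- render_bins(tr)
  expect_identical(p1, p2)
})
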