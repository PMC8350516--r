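# Delta computation, clonal filtering, quasi-monotone classification,
# and the exhaustive sample-order search.

delta_from_matrix <- function(mat, baseline = "S1") {
  compute_delta(mat, baseline_id = baseline)
}

test_that("compute_delta subtracts the baseline row columnwise", {
  mat <- rbind(S1 = c(3.0, 2.0), S2 = c(3.5, 1.8), S3 = c(3.0, 2.2))
  d <- delta_from_matrix(mat)
  expect_equal(nrow(d$delta), 2L)
  expect_equal(unname(d$delta["S2", ]), c(0.5, -0.2))
  expect_equal(unname(d$delta["S3", ]), c(0.0, 0.2))
  expect_error(compute_delta(mat, baseline_id = "S9"), "baseline")
})

test_that("noiseless Delta equals the subclonal-ratio identity", {
  tr <- generate_truth(50, 4, sigma = 0, unstable_frac = 0, seed = 41,
                       purity_range = c(0.2, 0.45),
                       baseline_ratio_max = 0)
  profiles <- render_bins(tr)
  sm <- curate_segment_cn(harmonize_segments(profiles), profiles)
  tcn <- purity_correct(sm, tr$purity, baseline_id = "S1",
                        purity_floor = 0)
  d <- compute_delta(tcn)
  seg_of_bin <- rep(seq_len(tr$n_segments), tr$segment_lengths)
  for (g in seq_len(ncol(d$delta))) {
    j <- seg_of_bin[sm$segments$start[g] / 50000 + 1]
    expected <- tr$subclonal_ratio[-1] *
      (tr$subclonal_cn[j] - tr$ancestral_cn[j])
    expect_equal(unname(d$delta[, g]), expected, tolerance = 1e-9)
  }
})

test_that("classify_under_order applies the quasi-monotone rule", {
  mat <- rbind(S1 = rep(0, 3),
               S2 = c(0.1, 0.3, 0.10),
               S3 = c(0.2, 0.1, 0.09),
               S4 = c(0.3, 0.25, 0.15))
  d <- delta_from_matrix(mat)
  # strictly increasing -> subclonal at any epsilon
  lab <- classify_under_order(d, 1:3, epsilon = 0.001)
  expect_equal(lab[1], "subclonal")
  # (0.3, 0.1, 0.25): fails both directions at epsilon 0.02
  lab2 <- classify_under_order(d, 1:3, epsilon = 0.02)
  expect_equal(lab2[2], "unstable")
  # (0.10, 0.09, 0.15): dip of 0.01 within epsilon 0.02 -> subclonal
  expect_equal(lab2[3], "subclonal")
  # clonal labels are preserved
  lab3 <- classify_under_order(d, 1:3, epsilon = 0.02, clonal = 2)
  expect_equal(lab3[2], "clonal")
})

test_that("filter_clonal separates low-spread segments", {
  set.seed(6)
  # 12 clonal segments (tiny spread) + 8 subclonal (monotone, large)
  clonal <- matrix(rnorm(36, 0, 0.002), nrow = 3)
  sub <- outer(c(0.2, 0.4, 0.6), c(1, -1, 1, 1, -1, 1, 1, -1))
  mat <- rbind(S1 = rep(0, 20), S2 = cbind(clonal, sub)[1, ],
               S3 = cbind(clonal, sub)[2, ], S4 = cbind(clonal, sub)[3, ])
  d <- delta_from_matrix(mat)
  fc <- filter_clonal(d, min_keep = 5)
  expect_setequal(fc$retained, 13:20)
  expect_setequal(fc$clonal, 1:12)
  expect_true(is.finite(fc$threshold))
  # a tiny-delta segment is clonal under any sensible threshold
  expect_true(all(fc$spread[1:12] < 0.02))
})

test_that("filter_clonal falls back to the largest-spread segments", {
  mat <- rbind(S1 = rep(0, 12), S2 = rnorm(12, 0, 1e-4),
               S3 = rnorm(12, 0, 1e-4))
  d <- delta_from_matrix(mat)
  expect_warning(fc <- filter_clonal(d, min_keep = 10), "largest-spread")
  expect_length(fc$retained, 10)
  expect_true(is.na(fc$threshold))
})

test_that("search_order maximises the subclonal count", {
  set.seed(15)
  # monotone truth on 3 non-baseline samples, shuffled input order
  r <- c(0.2, 0.6, 0.4)
  sub <- outer(r, c(1, -1, 1, 2, -1, 1, -2, 1, 1, -1, 1, 1))
  mat <- rbind(S1 = rep(0, 12), S2 = sub[1, ], S3 = sub[2, ], S4 = sub[3, ])
  mat[2:4, ] <- mat[2:4, ] + rnorm(36, 0, 0.005)
  d <- delta_from_matrix(mat)
  res <- search_order(d, min_keep = 5)
  expect_equal(res$order, c("S1", "S2", "S4", "S3"))
  expect_equal(res$n_subclonal, 12L)
  expect_true(all(res$labels == "subclonal"))
  expect_length(res$n_subclonal_by_order, 6)
})

test_that("an all-clonal dataset triggers the fallback retention warning", {
  set.seed(16)
  mat <- rbind(S1 = rep(0, 15), S2 = rnorm(15, 0, 1e-4),
               S3 = rnorm(15, 0, 1e-4))
  d <- delta_from_matrix(mat)
  w <- capture_warnings(res <- search_order(d))
  expect_true(any(grepl("largest-spread", w)))
  # no retained segment carries a real signal: every spread is below
  # the smallest clonal threshold (the trivially quasi-monotone labels
  # reflect Eq.-style tolerance, not actual subclonal change)
  expect_true(all(res$spread < 0.005))
})

test_that("too many samples for exhaustive search is an error", {
  mat <- matrix(rnorm(10 * 12), nrow = 10,
                dimnames = list(paste0("S", 1:10), NULL))
  d <- delta_from_matrix(mat)
  expect_error(search_order(d), "at most")
})

test_that("search_order agrees with a brute-force oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n_nb <- sample(2:4, 1)
    n_seg <- 15
    mat <- matrix(rnorm(n_nb * n_seg, 0, 0.3), nrow = n_nb,
                  dimnames = list(paste0("S", 2:(n_nb + 1)), NULL))
    full <- rbind(S1 = rep(0, n_seg), mat)
    d <- delta_from_matrix(full)
    eps <- runif(1, 0.02, 0.05)
    fc <- suppressWarnings(filter_clonal(d, epsilon = eps, min_keep = 5))
    res <- suppressWarnings(search_order(d, epsilon = eps, min_keep = 5,
                                         clonal_filter = fc))
    oracle <- oracle_best_count(d$delta, fc$retained, eps)
    expect_equal(res$n_subclonal, oracle,
                 label = sprintf("replicate %d", rep))
  }
})

test_that("reversing the chosen order never improves the subclonal count", {
  set.seed(101)
  for (rep in 1:10) {
    mat <- matrix(rnorm(3 * 20, 0, 0.4), nrow = 3,
                  dimnames = list(c("S2", "S3", "S4"), NULL))
    d <- delta_from_matrix(rbind(S1 = rep(0, 20), mat))
    res <- suppressWarnings(search_order(d, min_keep = 5))
    fwd <- res$order_index
    rev_labels <- classify_under_order(d, rev(fwd), epsilon = res$epsilon)
    kept <- res$spread >= ifelse(is.na(res$threshold), -Inf, res$threshold)
    expect_lte(sum(rev_labels[kept] == "subclonal"), res$n_subclonal)
  }
})

test_that("the subclonal count is nondecreasing in epsilon", {
  set.seed(102)
  mat <- matrix(rnorm(3 * 30, 0, 0.3), nrow = 3,
                dimnames = list(c("S2", "S3", "S4"), NULL))
  d <- delta_from_matrix(rbind(S1 = rep(0, 30), mat))
  counts <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.3), function(eps) {
    sum(classify_under_order(d, 1:3, epsilon = eps) == "subclonal")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("classification labels are invariant under consistent relabeling", {
  set.seed(103)
  mat <- matrix(rnorm(3 * 12, 0, 0.3), nrow = 3,
                dimnames = list(c("S2", "S3", "S4"), NULL))
  d <- delta_from_matrix(rbind(S1 = rep(0, 12), mat))
  ord <- c(2L, 3L, 1L)
  lab1 <- classify_under_order(d, ord, epsilon = 0.03)
  # permute the rows and apply the correspondingly permuted order
  perm_rows <- c(3L, 1L, 2L)
  mat2 <- mat[perm_rows, ]
  rownames(mat2) <- c("S2", "S3", "S4")
  d2 <- delta_from_matrix(rbind(S1 = rep(0, 12), mat2))
  ord2 <- match(ord, perm_rows)
  lab2 <- classify_under_order(d2, ord2, epsilon = 0.03)
  expect_equal(lab1, lab2)
})

test_that("order recovery sorts samples by true subclonal ratio on synthetic data", {
  recovered <- 0L; eligible <- 0L
  for (s in 1:40) {
    ds <- simulate_dataset(sigma = 0.5, seed = 5000 + s,
                           purity_range = c(0.15, 0.45))
    tr <- ds$truth
    # order identifiability requires separated ratios
    if (min(diff(sort(tr$subclonal_ratio[-1]))) < 0.08) next
    eligible <- eligible + 1L
    an <- suppressWarnings(suppressMessages(analyze_cna(ds$profiles)))
    retained <- rownames(an$delta$delta)
    true_order <- retained[order(tr$subclonal_ratio[
      match(retained, tr$sample_ids)])]
    if (identical(unname(an$classification$order[-1]), true_order)) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(eligible, 3L)
  expect_gte(recovered / eligible, 0.75)
})
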