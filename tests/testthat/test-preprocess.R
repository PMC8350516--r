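# Bin-table I/O, rescaling, ensemble segmentation, curation, and gene
# annotation.

test_that("bin tables round-trip through the TSV dialect", {
  set.seed(1)
  p <- list(make_segmented_profile("A", c(2, 3), c(5, 5), noise_sd = 0.1),
            make_segmented_profile("B", c(2, 2.4), c(5, 5), noise_sd = 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_table(p, path)
  back <- read_bin_table(path)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$bins, p[[1]]$bins, tolerance = 1e-12)
  expect_equal(back$B$bins, p[[2]]$bins, tolerance = 1e-12)
})

test_that("missing bins are retained with NA copy numbers", {
  raw <- c(2, NA, 2.1)
  p <- make_profile("A", raw = raw)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_table(list(p), path)
  back <- read_bin_table(path)
  expect_equal(nrow(back$A$bins), 3L)
  expect_true(is.na(back$A$bins$raw_cn[2]))
})

test_that("malformed bin tables fail with row context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tfoo\tA.raw\tA.seg",
               "chr1\t0\t50000\t2\t2"), path)
  expect_error(read_bin_table(path), "malformed header")
  writeLines(c("chrom\tstart\tend\tA.raw\tB.seg",
               "chr1\t0\t50000\t2\t2"), path)
  expect_error(read_bin_table(path), "unmatched")
  writeLines(c("chrom\tstart\tend\tA.raw\tA.seg",
               "chr1\t50000\t100000\t2\t2",
               "chr1\t0\t50000\t2\t2"), path)
  expect_error(read_bin_table(path), "not sorted")
  writeLines(c("chrom\tstart\tend\tA.raw\tA.seg",
               "chr1\t0\t50000\t-2\t2"), path)
  expect_error(read_bin_table(path), "negative copy number at row 1")
})

test_that("rescale_to_diploid scales and optionally recentres", {
  p <- make_segmented_profile("A", c(1, 1.5, 1), c(10, 10, 10))
  doubled <- rescale_to_diploid(p, ploidy_factor = 2)
  expect_equal(doubled$bins$segmented_cn, p$bins$segmented_cn * 2)
  # factor 1 is the identity
  expect_equal(rescale_to_diploid(p, 1)$bins, p$bins)
  # a profile whose mode sits at 3 is shifted back to 2
  set.seed(2)
  q <- make_segmented_profile("B", c(3, 3, 4, 3), c(30, 30, 10, 30),
                              noise_sd = 0.02)
  rec <- rescale_to_diploid(q, 1, recenter = TRUE)
  d <- density(rec$bins$segmented_cn, n = 2048)
  expect_equal(d$x[which.max(d$y)], 2, tolerance = 0.05)
})

test_that("harmonize_segments takes the union of breakpoints", {
  # A breaks at 10 Mb, B at 20 Mb on a 30 Mb region -> 3 ensemble segments
  nb <- 200  # 10 Mb of 50 kb bins
  a <- make_segmented_profile("A", c(2.0, 2.5, 2.5), c(nb, nb, nb))
  b <- make_segmented_profile("B", c(3.0, 3.0, 3.5), c(nb, nb, nb))
  sm <- harmonize_segments(list(a, b))
  expect_equal(nrow(sm$segments), 3L)
  expect_equal(sm$segments$start, c(0, 1, 2) * nb * 50000)
  expect_equal(unname(sm$cn["A", ]), c(2.0, 2.5, 2.5))
  expect_equal(unname(sm$cn["B", ]), c(3.0, 3.0, 3.5))
})

test_that("segments shorter than the minimum length are excluded", {
  # middle segment of 5 Mb (100 bins) must be dropped at the 6 Mb default
  a <- make_segmented_profile("A", c(2, 3, 2.2), c(200, 100, 200))
  sm <- harmonize_segments(list(a))
  expect_equal(nrow(sm$segments), 2L)
  expect_false(any(sm$cn == 3))
  # everything dropped -> informative error
  short <- make_segmented_profile("A", c(2, 3), c(20, 20))
  expect_error(harmonize_segments(list(short)), "min_length")
})

test_that("identical segmentations pass through unchanged and NA bins drop everywhere", {
  a <- make_segmented_profile("A", c(2, 2.6), c(150, 150))
  b <- make_segmented_profile("B", c(2.2, 2.9), c(150, 150))
  sm <- harmonize_segments(list(a, b))
  expect_equal(nrow(sm$segments), 2L)
  expect_equal(sm$segments$n_bins, c(150L, 150L))
  # blacklist a bin in A only: excluded for both samples, and the
  # 9-bin fragment left of it falls under the 6 Mb floor and drops too
  a2 <- a; a2$bins$raw_cn[10] <- NA
  sm2 <- harmonize_segments(list(a2, b))
  expect_equal(sum(sm2$segments$n_bins), 290L)
  # retained genome is identical across samples by construction
  expect_equal(ncol(sm2$cn), nrow(sm2$segments))
})

test_that("harmonized segmentation refines every input segmentation", {
  set.seed(4)
  ds <- simulate_dataset(n_segments = 20, sigma = 0.3, seed = 42)
  sm <- harmonize_segments(ds$profiles)
  for (p in ds$profiles) {
    for (g in seq_len(nrow(sm$segments))) {
      idx <- sm$bin_index[[g]]
      vals <- p$bins$segmented_cn[idx]
      expect_lt(diff(range(vals)), 1e-6)
    }
  }
})

test_that("curate_segment_cn is a trimmed Gaussian mean", {
  set.seed(7)
  vals <- rnorm(200, 2.5, 0.1)
  a <- make_profile("A", raw = vals, seg = rep(2.5, 200))
  sm <- harmonize_segments(list(a))
  cur <- curate_segment_cn(sm, list(a))
  # no outliers: curated mean ~ plain mean
  expect_equal(unname(cur$cn[1, 1]), mean(vals), tolerance = 5e-3)
  # a gross outlier leaves the curated mean unchanged to 2 decimals
  vals_out <- vals; vals_out[7] <- vals_out[7] + 10
  b <- make_profile("A", raw = vals_out, seg = rep(2.5, 200))
  smb <- harmonize_segments(list(b))
  curb <- curate_segment_cn(smb, list(b))
  expect_equal(unname(curb$cn[1, 1]), mean(vals), tolerance = 5e-3)
  expect_gt(abs(mean(vals_out) - mean(vals)), 0.04)
  # trim = 0 reproduces the plain mean exactly
  cur0 <- curate_segment_cn(smb, list(b), trim = 0)
  expect_equal(unname(cur0$cn[1, 1]), mean(vals_out), tolerance = 1e-12)
})

test_that("curation is invariant under within-segment bin permutation", {
  set.seed(8)
  vals <- rnorm(150, 3, 0.2)
  a <- make_profile("A", raw = vals, seg = rep(3, 150))
  b <- make_profile("A", raw = sample(vals), seg = rep(3, 150))
  ca <- curate_segment_cn(harmonize_segments(list(a)), list(a))
  cb <- curate_segment_cn(harmonize_segments(list(b)), list(b))
  expect_equal(ca$cn, cb$cn, tolerance = 1e-12)
})

test_that("segments with too few bins fall back to the untrimmed mean with a warning", {
  set.seed(9)
  vals <- rnorm(130, 2, 0.05)
  a <- make_profile("A", raw = vals, seg = rep(2, 130))
  sm <- harmonize_segments(list(a))
  # trim of 0.25 per tail leaves 65 bins; force the fallback via min_bins
  expect_warning(cur <- curate_segment_cn(sm, list(a), trim = 0.25,
                                          min_bins = 130),
                 "untrimmed mean")
  expect_equal(unname(cur$cn[1, 1]), mean(vals), tolerance = 1e-12)
})

test_that("annotate_segments reports gene overlaps from a BED file", {
  segs <- data.frame(chrom = c("chr1", "chr1"),
                     start = c(0, 10e6), end = c(10e6, 20e6))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000000\t1200000\tGENE_IN",
               "chr1\t9900000\t10100000\tGENE_SPAN",
               "chr2\t1000000\t1200000\tGENE_OUT"), bed)
  ann <- annotate_segments(segs, bed, delta = c(0.5, -0.5))
  expect_setequal(ann$gene, c("GENE_IN", "GENE_SPAN"))
  # fully contained gene reports its own length
  expect_equal(ann$overlap_bp[ann$gene == "GENE_IN"], 200000)
  # spanning gene appears once per overlapped segment
  span <- ann[ann$gene == "GENE_SPAN", ]
  expect_equal(nrow(span), 2L)
  expect_equal(sum(span$overlap_bp), 200000)
  expect_equal(span$direction, c("gain", "loss"))
})
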