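## Synthetic longitudinal copy-number datasets with known ground truth.
##
## A dataset emulates a patient series: one baseline liquid biopsy with a
## negligible emerging-subclone fraction, followed by samples in which an
## ancestral tumour population (per-segment integer copy number C(A)) and a
## single emerging subclone (integer C(S)) are mixed with normal diploid
## DNA.  The measured copy number of segment j in sample i is
##
##   C_ij = 2 + p_i * ((1 - r_i) C(A)_j + r_i C(S)_j - 2) + noise,
##
## where p_i is the tumour fraction (purity) and r_i the subclonal ratio.
## A small fraction of "unstable" segments instead carry a per-sample
## tumour copy number zeta_ij independent of r_i.

#' Generate the ground truth of a synthetic longitudinal dataset
#'
#' Draws per-segment ancestral and subclonal integer copy-number states,
#' per-sample purities and subclonal ratios, and marks a subset of
#' segments as unstable.  The first sample is the baseline and has a
#' subclonal ratio below `baseline_ratio_max`.
#'
#' Ancestral states are drawn from \{1..5\} with diploid and near-diploid
#' states up-weighted; subclonal states are `ancestral + d` with
#' `d` in \{-2..2\} and `d = 0` (clonal segments) up-weighted.  Draws with
#' a negative subclonal copy number are rejected and redrawn.  Unstable
#' segments carry, for every sample, a tumour copy number drawn uniformly
#' from `ancestral +/- 1.5` (floored at 0), independent of the subclonal
#' ratio.
#'
#' @param n_segments number of segments (default 80).
#' @param n_samples number of samples including the baseline (>= 2).
#' @param sigma dimensionless noise level; scales the per-bin measurement
#'   noise added by [render_bins()].
#' @param unstable_frac fraction of segments marked unstable (0-0.15).
#' @param seed integer RNG seed; the truth (and the bins rendered from
#'   it) is fully reproducible given the seed.
#' @param purity_range range the per-sample purity is drawn from.
#' @param ratio_range range the non-baseline subclonal ratio is drawn from.
#' @param baseline_ratio_max upper bound of the baseline subclonal ratio.
#' @param length_range range (in bins) segment lengths are drawn from.
#' @param cn_weights sampling weights of ancestral copy numbers 1..5.
#' @param offset_weights sampling weights of subclonal offsets -2..2.
#' @return An object of class `synthetic_truth`: a list with fields
#'   `n_segments`, `segment_lengths`, `ancestral_cn`, `subclonal_cn`,
#'   `unstable_mask`, `unstable_cn` (samples x segments, `NA` for stable
#'   segments), `purity`, `subclonal_ratio`, `sample_ids`,
#'   `noise_level`, and `seed`.
#' @seealso [render_bins()], [simulate_dataset()]
#' @export
generate_truth <- function(n_segments = 80, n_samples = 5, sigma = 1,
                           unstable_frac = 0.1, seed,
                           purity_range = c(0.04, 0.45),
                           ratio_range = c(0.05, 0.8),
                           baseline_ratio_max = 0.04,
                           length_range = c(120L, 800L),
                           cn_weights = c(1, 4, 2, 1, 1) / 9,
                           offset_weights = c(1, 2, 8, 2, 1) / 14) {
  assert_scalar_num(n_segments, "n_segments", lower = 1)
  assert_scalar_num(n_samples, "n_samples", lower = 2)
  assert_scalar_num(sigma, "sigma", lower = 0)
  assert_scalar_num(unstable_frac, "unstable_frac", lower = 0, upper = 0.15)
  if (missing(seed)) stop("`seed` is required for a reproducible truth")
  assert_scalar_num(seed, "seed", lower = 0, upper = 2147483646)
  stopifnot(length(purity_range) == 2L, length(ratio_range) == 2L,
            purity_range[1] > 0, purity_range[2] <= 1,
            ratio_range[1] >= 0, ratio_range[2] <= 1,
            length(cn_weights) == 5L, length(offset_weights) == 5L)
  n_segments <- as.integer(n_segments)
  n_samples <- as.integer(n_samples)

  set.seed(as.integer(seed))
  # sample.int avoids sample()'s scalar expansion when the range is a
  # single length
  seg_len <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n_segments,
               replace = TRUE)
  ancestral <- sample(1:5, n_segments, replace = TRUE, prob = cn_weights)
  offset <- sample(-2:2, n_segments, replace = TRUE, prob = offset_weights)
  # reject subclonal CN < 0 (only possible at ancestral CN 1, offset -2)
  bad <- ancestral + offset < 0
  while (any(bad)) {
    offset[bad] <- sample(-2:2, sum(bad), replace = TRUE,
                          prob = offset_weights)
    bad <- ancestral + offset < 0
  }
  subclonal <- ancestral + offset

  n_unstable <- round(unstable_frac * n_segments)
  unstable <- rep(FALSE, n_segments)
  if (n_unstable > 0) {
    unstable[sample.int(n_segments, n_unstable)] <- TRUE
  }

  purity <- stats::runif(n_samples, purity_range[1], purity_range[2])
  ratio <- stats::runif(n_samples, ratio_range[1], ratio_range[2])
  ratio[1] <- stats::runif(1, 0, baseline_ratio_max)

  zeta <- matrix(NA_real_, nrow = n_samples, ncol = n_segments)
  if (any(unstable)) {
    for (j in which(unstable)) {
      zeta[, j] <- pmax(0, stats::runif(n_samples, ancestral[j] - 1.5,
                                        ancestral[j] + 1.5))
    }
  }

  structure(list(
    n_segments = n_segments,
    n_samples = n_samples,
    segment_lengths = seg_len,
    ancestral_cn = ancestral,
    subclonal_cn = subclonal,
    unstable_mask = unstable,
    unstable_cn = zeta,
    purity = purity,
    subclonal_ratio = ratio,
    sample_ids = paste0("S", seq_len(n_samples)),
    noise_level = sigma,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d segments x %d samples (sigma = %g, seed = %d)\n",
    x$n_segments, x$n_samples, x$noise_level, x$seed))
  cat(sprintf("  purity: %s\n",
              paste(sprintf("%.3f", x$purity), collapse = " ")))
  cat(sprintf("  subclonal ratio: %s (baseline first)\n",
              paste(sprintf("%.3f", x$subclonal_ratio), collapse = " ")))
  cat(sprintf("  segments: %d clonal / %d subclonal / %d unstable\n",
              sum(x$ancestral_cn == x$subclonal_cn & !x$unstable_mask),
              sum(x$ancestral_cn != x$subclonal_cn & !x$unstable_mask),
              sum(x$unstable_mask)))
  invisible(x)
}

# Per-sample x per-segment tumour copy number implied by a truth:
# (1-r)C(A) + rC(S) for stable segments, zeta for unstable ones.
truth_tumor_cn <- function(truth) {
  mix <- outer(1 - truth$subclonal_ratio, truth$ancestral_cn) +
    outer(truth$subclonal_ratio, truth$subclonal_cn)
  if (any(truth$unstable_mask)) {
    mix[, truth$unstable_mask] <- truth$unstable_cn[, truth$unstable_mask]
  }
  mix
}

# Noiseless measured segment CN matrix (samples x segments).
truth_measured_cn <- function(truth) {
  2 + truth$purity * (truth_tumor_cn(truth) - 2)
}

#' Per-bin measurement-noise standard deviation
#'
#' The bin-level noise grows linearly with the noise level `sigma` and
#' with the square root of the local copy number, reflecting the higher
#' read-count variance of higher copy-number states:
#' `f(sigma, C) = sigma * noise_scale * sqrt(max(C, 0.5) / 2)`.
#' `noise_scale` calibrates the absolute scale: the default 0.4 gives a
#' raw-bin standard deviation of 0.4 at diploid copy number for
#' `sigma = 1`, the bin-level scatter typical of ~0.5-1x low-pass WGS
#' profiles on 50 kb bins.
#'
#' @param sigma non-negative noise level.
#' @param cn local (measured-scale) copy number.
#' @param noise_scale calibration constant, see above.
#' @return Vector of standard deviations.
#' @export
noise_sd <- function(sigma, cn, noise_scale = 0.4) {
  sigma * noise_scale * sqrt(pmax(cn, 0.5) / 2)
}

#' Render a truth into per-sample bin-level copy-number profiles
#'
#' Expands each segment into its bins, adds Gaussian measurement noise
#' with standard deviation [noise_sd()] to every bin's raw copy number,
#' and sets each bin's segmented copy number to the mean of the raw
#' values of its segment (the segmentation is taken as known, as for
#' segmented output of bin-level CN callers).  Bins are laid out as
#' contiguous `bin_size` windows on one pseudo-chromosome.
#'
#' Rendering is deterministic given the truth: the noise RNG is seeded
#' from `truth$seed`.
#'
#' @param truth a [generate_truth()] result.
#' @param bin_size bin width in base pairs (default 50 kb).
#' @param noise_scale calibration constant of [noise_sd()].
#' @return A list of `bin_profile` objects, one per sample.
#' @export
render_bins <- function(truth, bin_size = 50000, noise_scale = 0.4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(truth$seed, 1L))

  n_bins <- sum(truth$segment_lengths)
  seg_of_bin <- rep(seq_len(truth$n_segments), truth$segment_lengths)
  start <- (seq_len(n_bins) - 1) * bin_size
  mean_cn <- truth_measured_cn(truth)              # samples x segments

  profiles <- vector("list", truth$n_samples)
  for (i in seq_len(truth$n_samples)) {
    mu_bin <- mean_cn[i, seg_of_bin]
    sd_bin <- noise_sd(truth$noise_level, mean_cn[i, seg_of_bin],
                       noise_scale)
    raw <- pmax(0, mu_bin + stats::rnorm(n_bins, 0, sd_bin))
    seg_mean <- vapply(split(raw, seg_of_bin), mean, 0)
    seg_cn <- seg_mean[as.character(seg_of_bin)]
    profiles[[i]] <- bin_profile(
      sample_id = truth$sample_ids[i],
      bins = data.frame(chrom = "chr1",
                        start = start,
                        end = start + bin_size,
                        raw_cn = raw,
                        segmented_cn = unname(seg_cn))
    )
  }
  names(profiles) <- truth$sample_ids
  profiles
}

#' Mix bin profiles on a shared bin grid
#'
#' Convex combination of bin-level copy numbers, the bin-level analogue
#' of pooling sequencing reads from several sources: each output bin's
#' raw (and segmented) copy number is the weighted average of the
#' inputs.  All profiles must share an identical bin grid.
#'
#' @param profiles list of `bin_profile` objects on one grid.
#' @param weights non-negative weights summing to 1, one per profile.
#' @param sample_id id given to the mixture profile.
#' @return A `bin_profile`.
#' @export
mix_bin_profiles <- function(profiles, weights, sample_id = "mixture") {
  stopifnot(length(profiles) >= 1L, length(weights) == length(profiles))
  lapply(profiles, function(p) stopifnot(inherits(p, "bin_profile")))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be non-negative and sum to 1")
  }
  grid <- profiles[[1]]$bins[c("chrom", "start", "end")]
  for (p in profiles[-1]) {
    if (!identical(dim(p$bins[c("chrom", "start", "end")]), dim(grid)) ||
        !isTRUE(all.equal(p$bins[c("chrom", "start", "end")], grid,
                          check.attributes = FALSE))) {
      stop("profiles do not share an identical bin grid")
    }
  }
  raw <- rowSums(mapply(function(p, w) w * p$bins$raw_cn,
                        profiles, weights))
  seg <- rowSums(mapply(function(p, w) w * p$bins$segmented_cn,
                        profiles, weights))
  bin_profile(sample_id,
              data.frame(grid, raw_cn = raw, segmented_cn = seg))
}

#' Simulate a complete longitudinal dataset
#'
#' Convenience wrapper: draws a truth with [generate_truth()] (drawing
#' the unstable-segment fraction uniformly from `unstable_range` when
#' `unstable_frac` is `NULL`) and renders it with [render_bins()].
#'
#' @inheritParams generate_truth
#' @inheritParams render_bins
#' @param unstable_frac fixed unstable fraction, or `NULL` to draw it.
#' @param unstable_range range the unstable fraction is drawn from.
#' @return A list with elements `truth` and `profiles`.
#' @export
simulate_dataset <- function(n_segments = 80, n_samples = 5, sigma = 1,
                             unstable_frac = NULL,
                             unstable_range = c(0.025, 0.15), seed,
                             purity_range = c(0.04, 0.45),
                             ratio_range = c(0.05, 0.8),
                             baseline_ratio_max = 0.04,
                             bin_size = 50000, noise_scale = 0.4, ...) {
  if (missing(seed)) stop("`seed` is required")
  if (is.null(unstable_frac)) {
    set.seed(derive_seed(seed, 2L))
    unstable_frac <- stats::runif(1, unstable_range[1], unstable_range[2])
  }
  truth <- generate_truth(n_segments = n_segments, n_samples = n_samples,
                          sigma = sigma, unstable_frac = unstable_frac,
                          seed = seed, purity_range = purity_range,
                          ratio_range = ratio_range,
                          baseline_ratio_max = baseline_ratio_max, ...)
  list(truth = truth,
       profiles = render_bins(truth, bin_size = bin_size,
                              noise_scale = noise_scale))
}

#' Write / read the ground-truth sidecar of a synthetic dataset
#'
#' Two plain TSV tables: `<stem>.samples.tsv` with per-sample purity and
#' subclonal ratio, and `<stem>.segments.tsv` with per-segment states
#' (length in bins, ancestral and subclonal copy number, unstable flag,
#' and per-sample unstable copy numbers in `zeta.<sample>` columns).
#'
#' @param truth a `synthetic_truth`.
#' @param stem output path stem.
#' @return `write_truth` returns the two paths invisibly; `read_truth`
#'   returns a list with `samples` and `segments` data frames.
#' @export
write_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "synthetic_truth"))
  samples <- data.frame(sample = truth$sample_ids,
                        purity = truth$purity,
                        subclonal_ratio = truth$subclonal_ratio,
                        baseline = seq_len(truth$n_samples) == 1L)
  zeta <- t(truth$unstable_cn)
  colnames(zeta) <- paste0("zeta.", truth$sample_ids)
  segments <- data.frame(segment = seq_len(truth$n_segments),
                         length_bins = truth$segment_lengths,
                         ancestral_cn = truth$ancestral_cn,
                         subclonal_cn = truth$subclonal_cn,
                         unstable = truth$unstable_mask,
                         zeta, check.names = FALSE)
  paths <- paste0(stem, c(".samples.tsv", ".segments.tsv"))
  utils::write.table(samples, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(segments, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_truth
#' @export
read_truth <- function(stem) {
  samples <- utils::read.delim(paste0(stem, ".samples.tsv"),
                               check.names = FALSE)
  segments <- utils::read.delim(paste0(stem, ".segments.tsv"),
                                check.names = FALSE)
  list(samples = samples, segments = segments)
}
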