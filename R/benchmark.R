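## Accuracy benchmarks on synthetic data: recovery of purity and of
## subclonal ratios across noise levels, dataset sizes and sample
## counts.

#' Benchmark purity recovery on synthetic datasets
#'
#' Simulates `n_datasets` longitudinal datasets per noise level, runs
#' preprocessing and per-sample purity estimation, and returns one row
#' per sample with the generating and estimated purity.
#'
#' @param n_datasets datasets per noise level.
#' @param sigma vector of noise levels.
#' @param n_samples samples per dataset.
#' @param seed base RNG seed; dataset d of noise level s uses a seed
#'   derived from it.
#' @param purity_range,ratio_range,unstable_range passed to
#'   [simulate_dataset()].
#' @param ... further arguments to [estimate_purity()].
#' @return Data frame: `sigma`, `dataset`, `sample`, `true_purity`,
#'   `est_purity`, `abs_error`.
#' @export
benchmark_purity <- function(n_datasets, sigma = c(0.5, 1), n_samples = 5,
                             seed = 1, purity_range = c(0.04, 0.45),
                             ratio_range = c(0.05, 0.8),
                             unstable_range = c(0.025, 0.15), ...) {
  rows <- list()
  for (si in seq_along(sigma)) {
    for (d in seq_len(n_datasets)) {
      ds_seed <- derive_seed(seed, si * 100000L + d)
      ds <- simulate_dataset(n_samples = n_samples, sigma = sigma[si],
                             seed = ds_seed, purity_range = purity_range,
                             ratio_range = ratio_range,
                             unstable_range = unstable_range)
      sm <- harmonize_segments(ds$profiles)
      sm <- curate_segment_cn(sm, ds$profiles)
      est <- vapply(seq_along(sm$sample_ids), function(i) {
        tryCatch(estimate_purity(sm$cn[i, ], weights = sm$segments$n_bins,
                                 sample_id = sm$sample_ids[i], ...)$purity,
                 error = function(e) NA_real_)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sigma[si], dataset = d, sample = sm$sample_ids,
        true_purity = ds$truth$purity, est_purity = est,
        abs_error = abs(est - ds$truth$purity))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benchmark subclonal-ratio recovery on synthetic datasets
#'
#' Runs the full pipeline ([analyze_cna()]) on simulated datasets and
#' compares estimated absolute and relative subclonal ratios to the
#' generating values.  The true relative ratio of a sample is its true
#' ratio divided by that of the reference sample the estimator selected
#' (relative ratios are only defined against a named reference).
#' Datasets where the pipeline fails (e.g. baseline below the purity
#' floor) are recorded with `NA` estimates.
#'
#' @inheritParams benchmark_purity
#' @param purity_range purities are drawn from here; the default starts
#'   at 0.1 so samples clear the pipeline's purity floor.
#' @param ... further arguments to [analyze_cna()].
#' @return Data frame with one row per non-baseline sample: `sigma`,
#'   `dataset`, `sample`, truths and estimates of purity and of
#'   absolute/relative subclonal ratio, `method`, `converged`,
#'   `failed` (pipeline-level failure flag).
#' @export
benchmark_ratios <- function(n_datasets, sigma = c(0, 0.5, 1, 2),
                             n_samples = 5, seed = 1,
                             purity_range = c(0.1, 0.45),
                             ratio_range = c(0.05, 0.8),
                             unstable_range = c(0.025, 0.15), ...) {
  rows <- list()
  for (si in seq_along(sigma)) {
    for (d in seq_len(n_datasets)) {
      ds_seed <- derive_seed(seed, 7000000L + si * 100000L + d)
      ds <- simulate_dataset(n_samples = n_samples, sigma = sigma[si],
                             seed = ds_seed, purity_range = purity_range,
                             ratio_range = ratio_range,
                             unstable_range = unstable_range)
      truth <- ds$truth
      an <- tryCatch(
        suppressWarnings(suppressMessages(
          analyze_cna(ds$profiles, baseline_id = truth$sample_ids[1], ...))),
        error = function(e) NULL)
      base <- data.frame(sigma = sigma[si], dataset = d,
                         sample = truth$sample_ids[-1],
                         true_purity = truth$purity[-1],
                         true_ratio = truth$subclonal_ratio[-1])
      if (is.null(an)) {
        base$est_purity <- NA_real_
        base$est_ratio <- NA_real_
        base$true_relative <- NA_real_
        base$est_relative <- NA_real_
        base$method <- NA_character_
        base$converged <- FALSE
        base$failed <- TRUE
      } else {
        ref <- an$reference_id
        r_ref <- truth$subclonal_ratio[match(ref, truth$sample_ids)]
        i <- match(base$sample, an$ratios$sample)
        base$est_purity <- an$purity$purity[match(base$sample,
                                                  an$purity$sample)]
        base$est_ratio <- an$ratios$absolute[i]
        base$true_relative <- base$true_ratio / r_ref
        base$est_relative <- an$ratios$relative[i]
        base$method <- an$ratios$method[i]
        base$converged <- an$ratios$converged[i]
        base$failed <- FALSE
        # samples dropped for low purity have no estimates (NA via match)
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a benchmark table per noise level
#'
#' @param bench result of [benchmark_purity()] or [benchmark_ratios()].
#' @return Data frame of per-sigma error summaries (mean, median,
#'   quartiles) for every error column available.
#' @export
summarize_benchmark <- function(bench) {
  err_cols <- list()
  if ("abs_error" %in% names(bench)) {
    err_cols$purity_error <- bench$abs_error
  }
  if ("est_purity" %in% names(bench) && "true_purity" %in% names(bench) &&
      !"abs_error" %in% names(bench)) {
    err_cols$purity_error <- abs(bench$est_purity - bench$true_purity)
  }
  if ("est_ratio" %in% names(bench)) {
    err_cols$ratio_error <- abs(bench$est_ratio - bench$true_ratio)
  }
  if ("est_relative" %in% names(bench)) {
    err_cols$relative_error <- abs(bench$est_relative - bench$true_relative)
  }
  out <- list()
  for (nm in names(err_cols)) {
    e <- err_cols[[nm]]
    for (s in sort(unique(bench$sigma))) {
      v <- e[bench$sigma == s & !is.na(e)]
      out[[length(out) + 1L]] <- data.frame(
        metric = nm, sigma = s, n = length(v),
        mean = mean(v), median = stats::median(v),
        q25 = stats::quantile(v, 0.25, names = FALSE),
        q75 = stats::quantile(v, 0.75, names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
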