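## Subclonal-ratio estimation from the Delta values of subclonal
## segments.
##
## Each subclonal segment changes by an integer number of copies between
## ancestral and subclonal cells, so its Delta value is an integer
## multiple of the sample's subclonal ratio r: Delta in
## {..., -2r, -r, r, 2r, ...}.  The absolute ratio is the constrained
## shared mean of a Gaussian mixture with components at those multiples;
## relative ratios (against the sample with the largest subclone) are
## medians of segment-wise Delta ratios and are more robust to noise.

#' Relative subclonal ratios against a reference sample
#'
#' For each sample, the per-segment ratios `Delta_i / Delta_ref` over
#' the subclonal segments estimate `r_i / r_ref`; the point estimate is
#' their median.  Segments whose reference Delta is within
#' `min_ref_delta` of zero are skipped (the ratio is unstable there).
#'
#' @param delta a `delta_matrix`.
#' @param subclonal indices (or logical mask) of subclonal segments.
#' @param reference_id reference sample id, normally the last sample of
#'   the optimal order (largest subclone, most robust Delta values).
#' @param min_ref_delta reference |Delta| below which a segment is
#'   skipped (default 0.01).
#' @return Data frame with one row per non-baseline sample: `sample`,
#'   `relative` (1 for the reference by construction),
#'   `n_segments_used`; per-segment ratios are attached as the
#'   `"per_segment"` attribute for diagnostics.
#' @export
relative_ratios <- function(delta, subclonal, reference_id,
                            min_ref_delta = 0.01) {
  stopifnot(inherits(delta, "delta_matrix"))
  if (!reference_id %in% delta$sample_ids) {
    stop("reference sample ", reference_id, " not among non-baseline samples")
  }
  sub <- seq_len(ncol(delta$delta))[subclonal]
  if (length(sub) < 1L) stop("at least one subclonal segment is required")
  ref <- delta$delta[reference_id, sub]
  usable <- abs(ref) >= min_ref_delta
  if (!any(usable)) {
    stop("all reference Delta values are ~0; relative ratios undefined")
  }
  if (any(!usable)) {
    message(sum(!usable), " segment(s) skipped: reference Delta ~ 0")
  }
  per_seg <- lapply(delta$sample_ids, function(s) {
    delta$delta[s, sub[usable]] / ref[usable]
  })
  names(per_seg) <- delta$sample_ids
  out <- data.frame(
    sample = delta$sample_ids,
    relative = vapply(per_seg, stats::median, 0),
    n_segments_used = sum(usable),
    row.names = NULL
  )
  out$relative[out$sample == reference_id] <- 1
  attr(out, "per_segment") <- per_seg
  attr(out, "reference_id") <- reference_id
  out
}

#' Fit a mean-constrained Gaussian mixture to Delta values
#'
#' Maximum-likelihood fit of a mixture whose component means are fixed
#' at `k * r` for `k` in `{-max_multiple..-1, 1..max_multiple}` with a
#' single shared standard deviation: the free parameters are `r`, the
#' shared `sd`, and the component weights.  The likelihood is maximised
#' by an EM over weights and sd nested inside a grid search over `r`
#' (the profile likelihood in `r` is multimodal), followed by a local
#' continuous refinement around the best grid point.
#'
#' The 95% confidence interval is `r +/- 1.96 * sd / sqrt(m)` with `m`
#' the effective number of values assigned to the `+/-r` components.
#' The fit is reported as not converged when the EM hits its iteration
#' cap or `r` lands at the edge of the search grid.
#'
#' @param delta_values Delta values of subclonal segments (>= 3).
#' @param max_multiple largest copy-number change modelled (default 2:
#'   components at -2r, -r, r, 2r).
#' @param r_grid search grid for `r`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param sd_floor lower bound on the shared sd (keeps the likelihood
#'   finite on noise-free lattice data).
#' @return List with `r`, `sd`, `ci` (length 2), `converged`,
#'   `loglik`, `weights` (named by multiple), `n`, `m_eff`.
#' @export
fit_constrained_mixture <- function(delta_values, max_multiple = 2,
                                    r_grid = seq(0.01, 1, by = 0.005),
                                    max_iter = 500, tol = 1e-8,
                                    sd_floor = 1e-4) {
  x <- delta_values[!is.na(delta_values)]
  if (length(x) < 3L) stop("at least 3 Delta values are required")
  stopifnot(max_multiple >= 1)
  ks <- c(-(max_multiple:1), seq_len(max_multiple))

  em <- function(r, iter_cap = max_iter, em_tol = tol) {
    mu <- ks * r
    resid <- outer(x, mu, "-")
    sd <- max(sd_floor, sqrt(mean(apply(resid^2, 1, min))))
    w <- rep(1 / length(ks), length(ks))
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(iter_cap)) {
      dens <- vapply(seq_along(ks), function(k)
        w[k] * stats::dnorm(x, mu[k], sd), numeric(length(x)))
      if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1L)
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d < 1e-300] <- 1e-300
      ll <- sum(log(rowsum_d))
      if (is.finite(ll_old) && abs(ll - ll_old) < em_tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      gamma <- dens / rowsum_d
      w <- colMeans(gamma)
      sd <- max(sd_floor, sqrt(sum(gamma * resid^2) / length(x)))
    }
    list(r = r, sd = sd, w = w, ll = ll, gamma = gamma,
         converged = converged)
  }

  grid_ll <- vapply(r_grid, function(r) em(r, iter_cap = 50,
                                           em_tol = 1e-6)$ll, 0)
  # exact lattice data ties r with its sub-harmonics (r/2 explains the
  # same atoms through its 2r component); take the largest tied r
  r0 <- r_grid[max(which(grid_ll >= max(grid_ll) - 1e-8))]
  step <- diff(r_grid[1:2])
  opt <- stats::optimize(function(r) -em(r, iter_cap = 100,
                                         em_tol = 1e-7)$ll,
                         c(max(min(r_grid), r0 - step),
                           min(max(r_grid), r0 + step)),
                         tol = 1e-6)
  r_hat <- if (-opt$objective >= max(grid_ll) - 1e-9) opt$minimum else r0

  fit <- em(r_hat)
  m_eff <- sum(fit$gamma[, abs(ks) == 1])
  half <- 1.96 * fit$sd / sqrt(max(m_eff, 1))
  at_bound <- r_hat <= min(r_grid) + step || r_hat >= max(r_grid) - step
  list(r = fit$r, sd = fit$sd,
       ci = c(fit$r - half, fit$r + half),
       converged = fit$converged && !at_bound,
       loglik = fit$ll,
       weights = stats::setNames(fit$w, ks),
       n = length(x), m_eff = m_eff)
}

#' Absolute subclonal ratios (direct and two-step)
#'
#' Direct estimation fits [fit_constrained_mixture()] to each sample's
#' subclonal Delta values.  Two-step estimation fits only the reference
#' sample (whose large Delta values make the fit most robust) and scales
#' its ratio by the relative ratios: `r_i = rel_i * r_ref`.  The default
#' `"auto"` reports the direct estimate where it converged and falls
#' back to the two-step value elsewhere, mirroring the observation that
#' the two approaches agree but the two-step one also covers samples
#' where the direct fit fails.
#'
#' @param delta a `delta_matrix`.
#' @param subclonal indices (or logical mask) of subclonal segments.
#' @param relatives a [relative_ratios()] result (carries the reference
#'   sample).
#' @param method `"auto"`, `"direct"`, or `"two_step"`.
#' @param ... passed to [fit_constrained_mixture()].
#' @return Data frame with one row per non-baseline sample: `sample`,
#'   `relative`, `absolute`, `ci_low`, `ci_high`, `method`,
#'   `converged`, `n_segments`, `mixture_sd`.
#' @export
absolute_ratios <- function(delta, subclonal, relatives,
                            method = c("auto", "direct", "two_step"),
                            ...) {
  method <- match.arg(method)
  stopifnot(inherits(delta, "delta_matrix"))
  reference_id <- attr(relatives, "reference_id")
  if (is.null(reference_id)) stop("`relatives` must come from relative_ratios()")
  sub <- seq_len(ncol(delta$delta))[subclonal]

  fit_one <- function(s) {
    tryCatch(fit_constrained_mixture(delta$delta[s, sub], ...),
             error = function(e) NULL)
  }
  ref_fit <- fit_one(reference_id)
  ref_ok <- !is.null(ref_fit) && ref_fit$converged

  rows <- lapply(delta$sample_ids, function(s) {
    rel <- relatives$relative[relatives$sample == s]
    direct <- if (method != "two_step") fit_one(s) else NULL
    use_direct <- !is.null(direct) &&
      (method == "direct" || direct$converged)
    if (use_direct) {
      data.frame(sample = s, relative = rel, absolute = direct$r,
                 ci_low = direct$ci[1], ci_high = direct$ci[2],
                 method = "direct", converged = direct$converged,
                 n_segments = direct$n, mixture_sd = direct$sd)
    } else if (ref_ok) {
      # two-step: scale the reference fit by the relative ratio
      data.frame(sample = s, relative = rel, absolute = rel * ref_fit$r,
                 ci_low = rel * ref_fit$ci[1],
                 ci_high = rel * ref_fit$ci[2],
                 method = "two_step", converged = TRUE,
                 n_segments = length(sub), mixture_sd = ref_fit$sd)
    } else {
      data.frame(sample = s, relative = rel, absolute = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 method = NA_character_, converged = FALSE,
                 n_segments = length(sub), mixture_sd = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_id") <- reference_id
  out
}
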