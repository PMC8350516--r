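## Identification of subclone-specific segments and of the sample order
## reflecting increasing subclonal proportion.
##
## After purity correction, the copy-number change of segment j in
## sample i relative to the baseline is Delta_ij = r_i (C(S)_j - C(A)_j):
## clonal segments sit at 0, subclonal segments scale with the subclonal
## ratio r_i, and unstable segments follow neither pattern.  Ordering
## samples by r makes subclonal Delta values quasi-monotone; the order
## is recovered by exhaustive permutation search maximising the number
## of quasi-monotone ("subclonal") segments.

#' Copy-number change relative to the baseline sample
#'
#' @param tumor_cn a `tumor_cn_matrix` from [purity_correct()], or a
#'   samples x segments matrix with row names.
#' @param baseline_id row (sample) used as baseline; defaults to the
#'   `baseline_id` carried by a `tumor_cn_matrix`.
#' @return An object of class `delta_matrix`: list with `delta`
#'   (non-baseline samples x segments), `tumor_cn`, `baseline_id`,
#'   `sample_ids` (non-baseline, chronological), `segments` (when
#'   available).
#' @export
compute_delta <- function(tumor_cn, baseline_id = NULL) {
  segments <- NULL
  if (inherits(tumor_cn, "tumor_cn_matrix")) {
    baseline_id <- baseline_id %||% tumor_cn$baseline_id
    segments <- tumor_cn$segments
    mat <- tumor_cn$cn
  } else {
    mat <- tumor_cn
  }
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.null(baseline_id) || !baseline_id %in% rownames(mat)) {
    stop("baseline sample not present in the matrix")
  }
  base <- mat[baseline_id, ]
  rest <- setdiff(rownames(mat), baseline_id)
  delta <- mat[rest, , drop = FALSE] -
    matrix(base, nrow = length(rest), ncol = ncol(mat), byrow = TRUE)
  structure(list(delta = delta,
                 tumor_cn = mat,
                 baseline_id = baseline_id,
                 sample_ids = rest,
                 segments = segments),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d non-baseline sample(s) x %d segments (baseline %s)\n",
              nrow(x$delta), ncol(x$delta), x$baseline_id))
  invisible(x)
}

# Per-segment spread of Delta values across non-baseline samples, the
# clonality statistic.  With a single non-baseline sample the sd across
# samples is undefined; |Delta| (deviation from the clonal value 0) is
# used instead.
delta_spread <- function(delta) {
  d <- delta$delta
  if (nrow(d) == 1L) abs(d[1, ]) else apply(d, 2, stats::sd)
}

#' Classify segments along a given sample order
#'
#' A segment is *subclonal* under an order if its Delta sequence --
#' starting from the baseline's implicit 0 -- is quasi-monotone at
#' tolerance `epsilon`: successive differences all `> -epsilon`
#' (quasi-increasing) or all `< epsilon` (quasi-decreasing).  Segments
#' in `clonal` keep the label `"clonal"`; remaining segments failing
#' both directions are `"unstable"`.
#'
#' @param delta a `delta_matrix`.
#' @param order permutation of the non-baseline samples (indices into
#'   the rows of `delta$delta`, or sample ids).
#' @param epsilon quasi-monotonicity tolerance (> 0; 0.02-0.05 is
#'   appropriate for typical low-pass WGS noise).
#' @param clonal logical (or index) vector marking segments already
#'   labelled clonal by [filter_clonal()]; default none.
#' @return Character vector of per-segment labels
#'   (`"clonal"`/`"subclonal"`/`"unstable"`).
#' @export
classify_under_order <- function(delta, order, epsilon = 0.03,
                                 clonal = NULL) {
  stopifnot(inherits(delta, "delta_matrix"))
  assert_scalar_num(epsilon, "epsilon", lower = 1e-12)
  if (is.character(order)) order <- match(order, delta$sample_ids)
  stopifnot(!anyNA(order), setequal(order, seq_len(nrow(delta$delta))))
  flags <- quasi_monotone_flags(delta$delta, order, epsilon)
  labels <- ifelse(flags, "subclonal", "unstable")
  if (!is.null(clonal)) {
    cl <- logical(ncol(delta$delta))
    cl[clonal] <- TRUE
    labels[cl] <- "clonal"
  }
  labels
}

# Logical vector over segments: quasi-monotone (either direction) along
# c(0, delta[order, ]) at tolerance eps.
quasi_monotone_flags <- function(d, order, eps) {
  dd <- d[order, , drop = FALSE]
  steps <- rbind(dd[1, ], diff(dd))          # diffs of c(0, dd[, j])
  inc <- colSums(steps <= -eps) == 0
  dec <- colSums(steps >= eps) == 0
  inc | dec
}

# Shared engine: quasi-monotone flags for every permutation of the
# non-baseline samples (baseline fixed first).  Returns the permutation
# list and a permutations x segments logical matrix.
scan_orders <- function(delta, epsilon, max_samples = 8L) {
  n <- nrow(delta$delta)
  if (n > max_samples) {
    stop("exhaustive order search supports at most ", max_samples,
         " non-baseline samples; analyse the series in windows instead")
  }
  perms <- all_permutations(n)
  flags <- t(vapply(perms,
                    function(p) quasi_monotone_flags(delta$delta, p, epsilon),
                    logical(ncol(delta$delta))))
  list(perms = perms, flags = flags)
}

#' Separate clonal segments by a data-driven spread threshold
#'
#' Clonal segments have Delta approximately 0 in every sample, hence low
#' spread across samples.  The spread threshold is chosen by scanning
#' `sd_grid`: for each threshold the segments at or above it are
#' retained and the proportion of them classified subclonal under the
#' best sample order is computed; the chosen threshold maximises that
#' proportion subject to at least `min_keep` retained segments (ties
#' resolved towards retaining more segments).  If no threshold retains
#' `min_keep` segments, the `min_keep` largest-spread segments are
#' retained with a warning.
#'
#' @param delta a `delta_matrix`.
#' @param epsilon tolerance used in the trial classifications.
#' @param min_keep minimum number of retained segments (default 10).
#' @param sd_grid candidate spread thresholds.
#' @return List with `clonal` (indices), `retained` (indices),
#'   `threshold` (NA when the fallback was taken), and the per-segment
#'   `spread` values.
#' @export
filter_clonal <- function(delta, epsilon = 0.03, min_keep = 10,
                          sd_grid = seq(0.005, 0.2, by = 0.005)) {
  stopifnot(inherits(delta, "delta_matrix"))
  spread <- delta_spread(delta)
  scan <- scan_orders(delta, epsilon)
  best_count <- function(retained) {
    if (!any(retained)) return(0L)
    max(rowSums(scan$flags[, retained, drop = FALSE]))
  }
  n_seg <- length(spread)

  cand <- data.frame(threshold = sd_grid,
                     n_retained = vapply(sd_grid,
                                         function(t) sum(spread >= t), 0L))
  cand <- cand[cand$n_retained >= min_keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("fewer than ", min_keep, " segments exceed any clonal-spread ",
            "threshold; retaining the ", min_keep,
            " largest-spread segments")
    retained <- order(spread, decreasing = TRUE)[seq_len(min(min_keep, n_seg))]
    return(list(clonal = setdiff(seq_len(n_seg), retained),
                retained = sort(retained), threshold = NA_real_,
                spread = spread))
  }
  frac <- vapply(cand$threshold, function(t) {
    retained <- spread >= t
    best_count(retained) / sum(retained)
  }, 0)
  # maximise the subclonal fraction; ties go to the smaller threshold
  # (retain more segments).  With a single non-baseline sample the
  # quasi-monotone criterion is vacuous (every segment satisfies it, so
  # the fraction is 1 everywhere) and the clonal filter must do all the
  # separation: there ties go to the *largest* threshold, keeping the
  # min_keep strongest segments and excluding near-zero Delta noise the
  # zero-less mixture cannot represent.
  tied_idx <- which(frac >= max(frac) - 1e-12)
  best <- if (nrow(delta$delta) == 1L) tied_idx[length(tied_idx)] else
    tied_idx[1]
  thr <- cand$threshold[best]
  retained <- which(spread >= thr)
  list(clonal = which(spread < thr), retained = retained,
       threshold = thr, spread = spread)
}

#' Exhaustive search for the sample order maximising subclonal segments
#'
#' Evaluates every permutation of the non-baseline samples (baseline
#' fixed first), counting segments whose Delta sequence is
#' quasi-monotone, and returns the permutation with the highest count
#' among the retained (non-clonal) segments.  Ties are resolved by
#' preferring (1) orders along which the mean |Delta| of subclonal
#' segments increases (an *emerging* clone), then (2) the order closest
#' to chronology (fewest inversions).
#'
#' @inheritParams filter_clonal
#' @param clonal_filter optionally a precomputed [filter_clonal()]
#'   result.
#' @return An object of class `subclone_classification`: list with
#'   `order` (sample ids, baseline first), `order_index` (permutation of
#'   non-baseline rows), `labels` (per segment), `epsilon`, `threshold`,
#'   `spread`, `n_subclonal`, `n_subclonal_by_order` (named count per
#'   permutation).
#' @export
search_order <- function(delta, epsilon = 0.03, min_keep = 10,
                         sd_grid = seq(0.005, 0.2, by = 0.005),
                         clonal_filter = NULL) {
  stopifnot(inherits(delta, "delta_matrix"))
  fc <- clonal_filter %||% filter_clonal(delta, epsilon = epsilon,
                                         min_keep = min_keep,
                                         sd_grid = sd_grid)
  scan <- scan_orders(delta, epsilon)
  retained <- fc$retained
  counts <- rowSums(scan$flags[, retained, drop = FALSE])
  if (max(counts) == 0L) {
    warning("no segment is quasi-monotone under any order; ",
            "the dataset may contain no subclonal signal")
  }
  tied <- which(counts == max(counts))
  if (length(tied) > 1L) {
    emergence <- vapply(tied, function(k) {
      sub <- retained[scan$flags[k, retained]]
      if (length(sub) == 0L) return(0)
      m <- rowMeans(abs(delta$delta[scan$perms[[k]], sub, drop = FALSE]))
      if (length(m) < 2L || stats::sd(m) == 0) return(0)
      stats::cor(seq_along(m), m)
    }, 0)
    tied <- tied[emergence >= max(emergence) - 1e-12]
    if (length(tied) > 1L) {
      inv <- vapply(scan$perms[tied], count_inversions, 0L)
      tied <- tied[inv == min(inv)]
    }
  }
  k <- tied[1]
  perm <- scan$perms[[k]]
  labels <- rep("unstable", ncol(delta$delta))
  labels[retained[scan$flags[k, retained]]] <- "subclonal"
  labels[fc$clonal] <- "clonal"

  count_names <- vapply(scan$perms, function(p)
    paste(delta$sample_ids[p], collapse = ">"), "")
  n_sub <- sum(labels == "subclonal")
  if (n_sub < 3L) {
    warning("only ", n_sub, " subclonal segment(s) identified; ratio ",
            "estimates from fewer than 3-5 segments are unreliable")
  }
  structure(list(order = c(delta$baseline_id, delta$sample_ids[perm]),
                 order_index = perm,
                 labels = labels,
                 epsilon = epsilon,
                 threshold = fc$threshold,
                 spread = fc$spread,
                 retained = retained,
                 n_subclonal = n_sub,
                 n_subclonal_by_order = stats::setNames(counts, count_names)),
            class = "subclone_classification")
}

#' @export
print.subclone_classification <- function(x, ...) {
  cat(sprintf("<subclone_classification> order: %s\n",
              paste(x$order, collapse = " > ")))
  cat(sprintf("  %d clonal / %d subclonal / %d unstable (epsilon = %g, threshold = %s)\n",
              sum(x$labels == "clonal"), sum(x$labels == "subclonal"),
              sum(x$labels == "unstable"), x$epsilon,
              format(x$threshold)))
  invisible(x)
}
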