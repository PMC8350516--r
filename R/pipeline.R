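## End-to-end orchestration: preprocess -> purity -> subclone
## identification -> ratio estimation, with a machine-readable record of
## the parameters used.

#' Run the full subclone-tracking analysis on a longitudinal series
#'
#' Executes the whole pipeline on a list of bin profiles (or a bin-table
#' TSV path): ensemble segmentation and curation, per-sample purity
#' estimation, purity correction and baseline Delta computation, clonal
#' filtering and exhaustive sample-order search, and relative plus
#' absolute subclonal-ratio estimation.
#'
#' Samples whose estimated purity falls below `purity_floor` are
#' excluded with a message.  A series reduced to the baseline plus one
#' sample is analysed with a prominent warning (subclonal and unstable
#' segments cannot be distinguished from a single non-baseline sample);
#' fewer samples is an error.
#'
#' @param profiles list of `bin_profile` objects sharing one bin grid,
#'   or the path of a bin-table TSV ([read_bin_table()] dialect).
#' @param baseline_id id of the baseline sample (default: first
#'   profile).
#' @param ploidy_factor,recenter passed to [rescale_to_diploid()]
#'   (defaults 1/FALSE: input already centred at 2; use 2 for callers
#'   normalised to diploid = 1).
#' @param min_length_bp,trim preprocessing parameters
#'   ([harmonize_segments()], [curate_segment_cn()]).
#' @param purity_floor,max_cn,rule purity parameters
#'   ([estimate_purity()], [purity_correct()]).
#' @param epsilon,min_keep,sd_grid classification parameters
#'   ([filter_clonal()], [search_order()]).
#' @param ratio_method,max_multiple ratio parameters
#'   ([absolute_ratios()], [fit_constrained_mixture()]).
#' @param cross_check cross-sample purity consistency correction: a
#'   sample whose purity landed on an alias (e.g. half the true value,
#'   from a half-lattice of subclonal peaks) shows a non-unit robust
#'   slope of its purity-corrected aneuploid deviations against the
#'   baseline's; such samples are rescaled by that slope before Delta
#'   computation (default `TRUE`).
#' @return An object of class `cna_analysis`: list with
#'   `segment_matrix`, `purity` (data frame), `purity_fits`,
#'   `tumor_cn`, `delta`, `classification`, `ratios` (data frame),
#'   `reference_id`, `dropped_samples`, and `provenance` (parameters +
#'   package version).
#' @export
analyze_cna <- function(profiles, baseline_id = NULL,
                        ploidy_factor = 1, recenter = FALSE,
                        min_length_bp = 6e6, trim = 0.025,
                        purity_floor = 0.1, max_cn = 5,
                        rule = "median",
                        epsilon = 0.03, min_keep = 10,
                        sd_grid = seq(0.005, 0.2, by = 0.005),
                        ratio_method = "auto", max_multiple = 2,
                        cross_check = TRUE) {
  if (is.character(profiles)) profiles <- read_bin_table(profiles)
  stopifnot(length(profiles) >= 2L)
  ids <- unname(vapply(profiles, `[[`, "", "sample_id"))
  baseline_id <- unname(baseline_id %||% ids[1])
  if (!baseline_id %in% ids) stop("baseline sample ", baseline_id,
                                  " not among the profiles")

  if (ploidy_factor != 1 || recenter) {
    profiles <- lapply(profiles, rescale_to_diploid,
                       ploidy_factor = ploidy_factor,
                       recenter = recenter)
  }
  sm <- harmonize_segments(profiles, min_length_bp = min_length_bp)
  sm <- curate_segment_cn(sm, profiles, trim = trim)

  fits <- lapply(seq_along(sm$sample_ids), function(i) {
    tryCatch(
      estimate_purity(sm$cn[i, ], weights = sm$segments$n_bins,
                      sample_id = sm$sample_ids[i], max_cn = max_cn,
                      rule = rule, purity_floor = purity_floor),
      error = function(e) {
        # unidentifiable purity (e.g. no aneuploid peaks): report the
        # grid floor, flagged, so the purity filter excludes the sample
        message("purity estimation failed for ", sm$sample_ids[i], ": ",
                conditionMessage(e))
        structure(list(sample_id = sm$sample_ids[i], purity = 0.05,
                       flagged_low_purity = TRUE,
                       candidate_grid = numeric(), bandwidths = numeric(),
                       error_by_bandwidth = matrix(0, 0, 0),
                       rule = rule),
                  class = "purity_fit")
      })
  })
  names(fits) <- sm$sample_ids
  purity_df <- data.frame(
    sample = sm$sample_ids,
    purity = vapply(fits, `[[`, 0, "purity"),
    flagged_low_purity = vapply(fits, `[[`, TRUE, "flagged_low_purity"),
    row.names = NULL
  )

  purities <- vapply(fits, `[[`, 0, "purity")
  names(purities) <- sm$sample_ids
  if (cross_check) {
    adj <- consistency_rescale_purity(sm, purities, baseline_id)
    if (any(adj$corrected)) {
      message("purity rescaled against baseline for: ",
              paste(sprintf("%s (x%.2f)", names(which(adj$corrected)),
                            adj$slope[adj$corrected]), collapse = ", "))
      purities <- adj$purity
      purity_df$purity <- unname(purities)
      purity_df$flagged_low_purity <- purity_df$purity < purity_floor
    }
  }

  tcn <- purity_correct(sm, purities, baseline_id = baseline_id,
                        purity_floor = purity_floor)
  if (length(tcn$sample_ids) < 2L) {
    stop("fewer than 2 samples remain after purity filtering; ",
         "subclone tracking is not possible")
  }
  if (length(tcn$sample_ids) == 2L) {
    warning("only the baseline and one further sample remain: ",
            "subclonal and unstable segments cannot be distinguished; ",
            "estimates will have reduced accuracy")
  }

  delta <- compute_delta(tcn)
  cls <- search_order(delta, epsilon = epsilon, min_keep = min_keep,
                      sd_grid = sd_grid)
  reference_id <- cls$order[length(cls$order)]

  sub <- which(cls$labels == "subclonal")
  ratios <- if (length(sub) >= 1L) {
    rel <- relative_ratios(delta, sub, reference_id)
    # The reference should be the sample with the largest subclone.  A
    # relative ratio clearly above 1 means another sample's subclone
    # exceeds the chosen reference's -- the order search picked the
    # wrong last sample (likely under heavy noise).  Re-anchor on the
    # largest sample; the relative ratios measure relative size more
    # robustly than the monotonicity count does.
    for (it in 1:3) {
      if (max(rel$relative) <= 1.1) break
      new_ref <- rel$sample[which.max(rel$relative)]
      message("relative ratio ", sprintf("%.2f", max(rel$relative)),
              " > 1: re-anchoring reference on ", new_ref)
      reference_id <- new_ref
      rel <- relative_ratios(delta, sub, reference_id)
    }
    absolute_ratios(delta, sub, rel, method = ratio_method,
                    max_multiple = max_multiple)
  } else {
    data.frame(sample = delta$sample_ids, relative = NA_real_,
               absolute = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, method = NA_character_,
               converged = FALSE, n_segments = 0L,
               mixture_sd = NA_real_)
  }

  structure(list(
    segment_matrix = sm,
    purity = purity_df,
    purity_fits = fits,
    tumor_cn = tcn,
    delta = delta,
    classification = cls,
    ratios = ratios,
    reference_id = reference_id,
    dropped_samples = tcn$dropped,
    provenance = list(
      package_version = as.character(utils::packageVersion("cnatrace")),
      n_samples_in = length(profiles),
      baseline_id = baseline_id,
      parameters = list(ploidy_factor = ploidy_factor,
                        recenter = recenter,
                        min_length_bp = min_length_bp, trim = trim,
                        purity_floor = purity_floor, max_cn = max_cn,
                        rule = rule, epsilon = epsilon,
                        min_keep = min_keep,
                        sd_grid = range(sd_grid),
                        ratio_method = ratio_method,
                        max_multiple = max_multiple,
                        cross_check = cross_check)
    )
  ), class = "cna_analysis")
}

#' @export
print.cna_analysis <- function(x, ...) {
  cat("<cna_analysis>\n")
  cat(sprintf("  %d segments, baseline %s%s\n",
              nrow(x$segment_matrix$segments),
              x$delta$baseline_id,
              if (length(x$dropped_samples))
                paste0(" (dropped: ",
                       paste(x$dropped_samples, collapse = ", "), ")")
              else ""))
  cat("  purity:\n")
  for (i in seq_len(nrow(x$purity))) {
    cat(sprintf("    %s  %.3f%s\n", x$purity$sample[i],
                x$purity$purity[i],
                if (x$purity$flagged_low_purity[i]) " [low]" else ""))
  }
  cat(sprintf("  order: %s\n", paste(x$classification$order,
                                     collapse = " > ")))
  cat("  subclonal ratios:\n")
  for (i in seq_len(nrow(x$ratios))) {
    r <- x$ratios[i, ]
    cat(sprintf("    %s  relative %.3f  absolute %s [%s] (%s)\n",
                r$sample, r$relative,
                ifelse(is.na(r$absolute), "NA",
                       sprintf("%.3f", r$absolute)),
                ifelse(is.na(r$ci_low), "NA",
                       sprintf("%.3f-%.3f", r$ci_low, r$ci_high)),
                ifelse(is.na(r$method), "failed", r$method)))
  }
  invisible(x)
}

#' Write the report bundle of an analysis
#'
#' Emits the tabular reports of a [analyze_cna()] result into a
#' directory: `purity.tsv`, `segments.tsv` (coordinates, label,
#' per-sample Delta), `ratios.tsv`, and `order.json` (optimal order,
#' per-permutation subclonal counts, parameters, provenance).
#'
#' @param analysis a `cna_analysis`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cna_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(analysis$purity, "purity.tsv")
  seg <- analysis$segment_matrix$segments
  seg$label <- analysis$classification$labels
  dl <- t(analysis$delta$delta)
  colnames(dl) <- paste0("delta.", rownames(analysis$delta$delta))
  tsv(cbind(seg, dl), "segments.tsv")
  tsv(analysis$ratios, "ratios.tsv")
  jsonlite::write_json(
    list(order = analysis$classification$order,
         epsilon = analysis$classification$epsilon,
         clonal_sd_threshold = analysis$classification$threshold,
         n_subclonal = analysis$classification$n_subclonal,
         n_subclonal_by_order =
           as.list(analysis$classification$n_subclonal_by_order),
         reference = analysis$reference_id,
         dropped_samples = analysis$dropped_samples,
         provenance = analysis$provenance),
    file.path(dir, "order.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
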