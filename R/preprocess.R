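## Loading, rescaling and curation of bin-level copy-number profiles.
##
## Input is the bin table emitted by depth-based CN callers: per genomic
## bin a raw (pre-segmentation) and a segmented copy number per sample.
## All coordinates are 0-based half-open internally.

#' Construct a per-sample bin-level copy-number profile
#'
#' @param sample_id sample label.
#' @param bins data frame with columns `chrom`, `start`, `end`,
#'   `raw_cn`, `segmented_cn`; bins must be sorted by (chrom, start),
#'   half-open, non-overlapping within a chromosome, with non-negative
#'   copy numbers where present (`NA` marks blacklisted/unmappable bins).
#' @return An object of class `bin_profile`.
#' @export
bin_profile <- function(sample_id, bins) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  required <- c("chrom", "start", "end", "raw_cn", "segmented_cn")
  if (!all(required %in% names(bins))) {
    stop("`bins` must have columns ", paste(required, collapse = ", "))
  }
  bins <- as.data.frame(bins)[required]
  validate_bins(bins, context = sample_id)
  structure(list(sample_id = sample_id, bins = bins),
            class = "bin_profile")
}

validate_bins <- function(bins, context = "") {
  if (nrow(bins) == 0L) stop("empty bin table (", context, ")")
  if (any(bins$end <= bins$start)) {
    row <- which(bins$end <= bins$start)[1]
    stop(sprintf("bin with end <= start at row %d (%s)", row, context))
  }
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, ]
    if (is.unsorted(b$start, strictly = TRUE)) {
      row <- which(diff(b$start) <= 0)[1] + 1L
      stop(sprintf("bins not sorted by start on %s (row %d within %s, %s)",
                   chr, row, chr, context))
    }
    if (any(b$start[-1] < b$end[-nrow(b)])) {
      row <- which(b$start[-1] < b$end[-nrow(b)])[1] + 1L
      stop(sprintf("overlapping bins on %s (row %d within %s, %s)",
                   chr, row, chr, context))
    }
  }
  neg <- which(bins$raw_cn < 0 | bins$segmented_cn < 0)
  if (length(neg)) {
    stop(sprintf("negative copy number at row %d (%s)", neg[1], context))
  }
  invisible(bins)
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("<bin_profile> %s: %d bins on %d chromosome(s), %d NA\n",
              x$sample_id, nrow(x$bins), length(unique(x$bins$chrom)),
              sum(is.na(x$bins$raw_cn))))
  invisible(x)
}

#' Read / write a multi-sample bin table
#'
#' Tab-separated dialect: columns `chrom`, `start`, `end` followed by a
#' `<sample>.raw` / `<sample>.seg` column pair per sample; coordinates
#' 0-based half-open; missing copy numbers as `NA`.
#'
#' @param path file path.
#' @return `read_bin_table` returns a named list of `bin_profile`
#'   objects, one per sample.
#' @export
read_bin_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 5L ||
      !identical(names(tab)[1:3], c("chrom", "start", "end"))) {
    stop("malformed header: expected chrom, start, end, then ",
         "<sample>.raw/<sample>.seg column pairs in ", path)
  }
  rest <- names(tab)[-(1:3)]
  raw_cols <- grep("\\.raw$", rest, value = TRUE)
  seg_cols <- grep("\\.seg$", rest, value = TRUE)
  ids <- sub("\\.raw$", "", raw_cols)
  if (length(rest) != length(raw_cols) + length(seg_cols) ||
      !setequal(paste0(ids, ".seg"), seg_cols)) {
    stop("malformed header: unmatched .raw/.seg column pairs in ", path)
  }
  profiles <- lapply(ids, function(id) {
    bin_profile(id, data.frame(
      tab[1:3],
      raw_cn = tab[[paste0(id, ".raw")]],
      segmented_cn = tab[[paste0(id, ".seg")]]
    ))
  })
  names(profiles) <- ids
  profiles
}

#' @rdname read_bin_table
#' @param profiles list of `bin_profile` objects sharing one bin grid.
#' @export
write_bin_table <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  check_shared_grid(profiles)
  tab <- profiles[[1]]$bins[c("chrom", "start", "end")]
  for (p in profiles) {
    tab[[paste0(p$sample_id, ".raw")]] <- p$bins$raw_cn
    tab[[paste0(p$sample_id, ".seg")]] <- p$bins$segmented_cn
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_shared_grid <- function(profiles) {
  grid <- profiles[[1]]$bins[c("chrom", "start", "end")]
  for (p in profiles[-1]) {
    if (nrow(p$bins) != nrow(grid) ||
        !isTRUE(all.equal(p$bins[c("chrom", "start", "end")], grid,
                          check.attributes = FALSE))) {
      stop("profiles do not share an identical bin grid")
    }
  }
  invisible(grid)
}

#' Rescale a profile so the diploid state sits at copy number 2
#'
#' CN callers normalised to a diploid state of 1 are multiplied by
#' `ploidy_factor = 2`; profiles already centred at 2 use factor 1.
#' With `recenter = TRUE` the modal segmented copy number (the highest
#' peak of its kernel density) is additionally shifted to exactly 2,
#' guarding against a mis-centred ploidy.
#'
#' @param profile a `bin_profile`.
#' @param ploidy_factor positive multiplicative factor (default 2).
#' @param recenter shift the modal segmented CN to 2 (default `FALSE`).
#' @return The rescaled `bin_profile`.
#' @export
rescale_to_diploid <- function(profile, ploidy_factor = 2,
                               recenter = FALSE) {
  stopifnot(inherits(profile, "bin_profile"))
  assert_scalar_num(ploidy_factor, "ploidy_factor", lower = 1e-12)
  b <- profile$bins
  b$raw_cn <- b$raw_cn * ploidy_factor
  b$segmented_cn <- b$segmented_cn * ploidy_factor
  if (recenter) {
    seg <- b$segmented_cn[!is.na(b$segmented_cn)]
    if (length(unique(seg)) > 1L) {
      d <- stats::density(seg, n = 2048)
      shift <- 2 - d$x[which.max(d$y)]
    } else {
      shift <- 2 - seg[1]
    }
    b$raw_cn <- b$raw_cn + shift
    b$segmented_cn <- b$segmented_cn + shift
  }
  bin_profile(profile$sample_id, b)
}

#' Ensemble segmentation shared by all samples
#'
#' Redefines segment boundaries as maximal runs of bins whose segmented
#' copy number is constant in *every* sample, so breakpoints present in
#' any single sample (e.g. a subclone-specific alteration) split the
#' segment for all.  Bins missing (`NA`) in any sample are excluded from
#' all samples; segments shorter than `min_length_bp` are dropped to
#' remove short segments sensitive to localised measurement bias.
#'
#' @param profiles list of `bin_profile` objects on one bin grid.
#' @param min_length_bp minimum retained segment length (default 6 Mb).
#' @param tol equality tolerance on segmented values when testing
#'   "constant in all samples" (segmented output is constant per segment
#'   up to float noise).
#' @return An object of class `segment_matrix`: list with `segments`
#'   (data frame `chrom`, `start`, `end`, `n_bins`), `cn` (samples x
#'   segments matrix of segment copy numbers), `sample_ids`, and the
#'   per-segment bin indices used downstream for curation.
#' @export
harmonize_segments <- function(profiles, min_length_bp = 6e6,
                               tol = 1e-6) {
  stopifnot(length(profiles) >= 1L)
  lapply(profiles, function(p) stopifnot(inherits(p, "bin_profile")))
  grid <- check_shared_grid(profiles)
  n <- nrow(grid)

  seg_mat <- vapply(profiles, function(p) p$bins$segmented_cn,
                    numeric(n))
  raw_mat <- vapply(profiles, function(p) p$bins$raw_cn, numeric(n))
  valid <- stats::complete.cases(seg_mat) & stats::complete.cases(raw_mat)

  # new segment starts: first valid bin of a run, chromosome change, or
  # a segmented-value change in any sample
  new_seg <- logical(n)
  prev <- 0L
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (prev == 0L || grid$chrom[i] != grid$chrom[prev] ||
        prev != i - 1L ||
        any(abs(seg_mat[i, ] - seg_mat[prev, ]) > tol)) {
      new_seg[i] <- TRUE
    }
    prev <- i
  }
  seg_id <- cumsum(new_seg)
  seg_id[!valid] <- NA_integer_

  idx_by_seg <- split(which(valid), seg_id[valid])
  segs <- do.call(rbind, lapply(idx_by_seg, function(idx) {
    data.frame(chrom = grid$chrom[idx[1]],
               start = grid$start[idx[1]],
               end = grid$end[idx[length(idx)]],
               n_bins = length(idx))
  }))
  keep <- (segs$end - segs$start) >= min_length_bp
  if (!any(keep)) {
    stop("no segment is at least ", min_length_bp,
         " bp after harmonization; consider a smaller `min_length_bp`")
  }
  segs <- segs[keep, , drop = FALSE]
  idx_by_seg <- idx_by_seg[keep]
  rownames(segs) <- NULL

  cn <- vapply(idx_by_seg,
               function(idx) colMeans(seg_mat[idx, , drop = FALSE]),
               numeric(length(profiles)))
  if (is.null(dim(cn))) cn <- matrix(cn, nrow = 1L)   # single sample
  rownames(cn) <- vapply(profiles, `[[`, "", "sample_id")

  structure(list(segments = segs, cn = cn,
                 sample_ids = rownames(cn),
                 bin_index = unname(idx_by_seg)),
            class = "segment_matrix")
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf(
    "<segment_matrix> %d segments x %d samples (%.1f Mb retained)\n",
    nrow(x$segments), length(x$sample_ids),
    sum(x$segments$end - x$segments$start) / 1e6))
  invisible(x)
}

#' Curate segment copy numbers from trimmed raw bin values
#'
#' Replaces each segment copy number by the mean of a normal
#' distribution fitted to the segment's raw bin values after discarding
#' the most extreme `trim` fraction per tail (the Gaussian
#' maximum-likelihood mean of the trimmed values, i.e. their sample
#' mean).  Robustifies segment values in error-prone genomic regions.
#' Segments with fewer than `min_bins` usable bins after trimming fall
#' back to the untrimmed mean, with a warning.
#'
#' @param sm a `segment_matrix` from [harmonize_segments()].
#' @param profiles the bin profiles the matrix was built from.
#' @param trim fraction trimmed per tail (default 0.025).
#' @param min_bins minimum usable bins after trimming (default 10).
#' @return The `segment_matrix` with curated `cn`.
#' @export
curate_segment_cn <- function(sm, profiles, trim = 0.025, min_bins = 10) {
  stopifnot(inherits(sm, "segment_matrix"))
  assert_scalar_num(trim, "trim", lower = 0, upper = 0.25)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (!identical(unname(ids), unname(sm$sample_ids))) {
    stop("`profiles` do not match the samples of the segment matrix")
  }
  n_fallback <- 0L
  for (s in seq_along(profiles)) {
    raw <- profiles[[s]]$bins$raw_cn
    for (g in seq_along(sm$bin_index)) {
      x <- raw[sm$bin_index[[g]]]
      x <- x[!is.na(x)]
      if (trim > 0) {
        q <- stats::quantile(x, c(trim, 1 - trim), names = FALSE)
        kept <- x[x >= q[1] & x <= q[2]]
      } else {
        kept <- x
      }
      if (length(kept) < min_bins) {
        n_fallback <- n_fallback + 1L
        sm$cn[s, g] <- mean(x)
      } else {
        sm$cn[s, g] <- mean(kept)
      }
    }
  }
  if (n_fallback > 0L) {
    warning(n_fallback, " segment value(s) had fewer than ", min_bins,
            " bins after trimming; untrimmed mean used")
  }
  sm
}

#' Annotate segments with overlapping genes
#'
#' Interval overlap of query segments against a BED file of gene
#' intervals (BED 0-based half-open; the 4th column is taken as the gene
#' name).  Every gene overlapping a segment by at least 1 bp is
#' reported, once per overlapped segment.  When per-segment copy-number
#' changes are supplied, the sign of the change is reported as
#' `gain`/`loss`.
#'
#' @param segments data frame with `chrom`, `start`, `end` (0-based
#'   half-open), or a `segment_matrix`.
#' @param gene_bed path to a BED3+ file of gene intervals.
#' @param delta optional per-segment copy-number change used to label
#'   direction.
#' @return Data frame with one row per (gene, segment) overlap: gene,
#'   segment index and coordinates, `overlap_bp`, and `direction` when
#'   `delta` is given.
#' @export
annotate_segments <- function(segments, gene_bed, delta = NULL) {
  if (inherits(segments, "segment_matrix")) segments <- segments$segments
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)))
  genes <- tryCatch(rtracklayer::import(gene_bed, format = "BED"),
                    error = function(e) {
                      stop("malformed BED file ", gene_bed, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.null(delta) && length(delta) != nrow(segments)) {
    stop("`delta` must have one value per segment")
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1L, end = segments$end))
  hits <- GenomicRanges::findOverlaps(genes, seg_gr)
  if (length(hits) == 0L) {
    return(data.frame(gene = character(), segment = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), overlap_bp = integer()))
  }
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(genes[gi], seg_gr[si])
  name <- if (!is.null(genes$name)) genes$name[gi] else
    as.character(gi)
  out <- data.frame(gene = name,
                    segment = si,
                    chrom = segments$chrom[si],
                    start = segments$start[si],
                    end = segments$end[si],
                    overlap_bp = GenomicRanges::width(ov))
  if (!is.null(delta)) {
    out$delta <- delta[si]
    out$direction <- ifelse(delta[si] >= 0, "gain", "loss")
  }
  out
}
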