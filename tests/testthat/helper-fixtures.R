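# Fixtures and independent oracles used across the suite.

# A tiny bin profile on a regular grid from explicit per-bin values.
make_profile <- function(id, raw, seg = raw, chrom = "chr1",
                         bin_size = 50000) {
  n <- length(raw)
  start <- (seq_len(n) - 1) * bin_size
  bin_profile(id, data.frame(chrom = chrom, start = start,
                             end = start + bin_size,
                             raw_cn = raw, segmented_cn = seg))
}

# Profiles with piecewise-constant segments: `cn` is a vector of segment
# values, `len` the bins per segment.
make_segmented_profile <- function(id, cn, len, noise_sd = 0, ...) {
  seg <- rep(cn, len)
  raw <- seg + stats::rnorm(length(seg), 0, noise_sd)
  make_profile(id, raw = raw, seg = seg, ...)
}

# Independent brute-force oracle for the optimal-order search: plain
# loops, no shared code with the package internals.
oracle_best_count <- function(delta_mat, retained, epsilon) {
  perms <- oracle_perms(nrow(delta_mat))
  best <- 0L
  for (p in perms) {
    cnt <- 0L
    for (j in retained) {
      seq_j <- c(0, delta_mat[p, j])
      d <- diff(seq_j)
      if (all(d > -epsilon) || all(d < epsilon)) cnt <- cnt + 1L
    }
    if (cnt > best) best <- cnt
  }
  best
}

oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in oracle_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

# Map ensemble segments back to generator segments via bin coordinates
# and return the majority truth label per ensemble segment.
truth_labels_for <- function(truth, segments, bin_size = 50000) {
  seg_of_bin <- rep(seq_len(truth$n_segments), truth$segment_lengths)
  lab <- ifelse(truth$unstable_mask, "unstable",
                ifelse(truth$ancestral_cn != truth$subclonal_cn,
                       "subclonal", "clonal"))
  vapply(seq_len(nrow(segments)), function(g) {
    bins <- (segments$start[g] / bin_size + 1):(segments$end[g] / bin_size)
    labs <- lab[seg_of_bin[bins]]
    names(sort(table(labs), decreasing = TRUE))[1]
  }, "")
}
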