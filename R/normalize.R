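#' Construct a copy-number matrix
#'
#' @param windows data.frame with `chrom`, `start`, `end`, `gc`.
#' @param cn non-negative matrix, windows x samples, on the diploid scale
#'   (2 = normal), with sample column names.
#' @param mask optional logical vector of excluded windows.
#' @return object of class `copy_number`.
#' @export
copy_number_matrix <- function(windows, cn, mask = NULL) {
  cn <- as.matrix(cn)
  if (any(cn < 0)) stop_invalid("copy numbers must be non-negative")
  structure(list(windows = windows, cn = cn, samples = colnames(cn),
                 mask = mask %||% rep(FALSE, nrow(windows))),
            class = "copy_number")
}

#' Mask windows with extreme cross-sample median depth
#'
#' Windows whose cross-sample median count falls strictly below the
#' `low_q` quantile or strictly above the `high_q` quantile of all window
#' medians are flagged masked and excluded from all downstream statistics.
#' This stands in for the unmappable / repeat-dense windows a read-level
#' caller removes by read-similarity merging.
#'
#' @param depth a `window_depth`.
#' @param low_q,high_q quantiles in `[0, 1]` with `low_q < high_q`
#'   (defaults 0.005 / 0.995).
#' @return the `window_depth` with an updated `mask`.
#' @export
mask_windows <- function(depth, low_q = 0.005, high_q = 0.995) {
  stopifnot(inherits(depth, "window_depth"))
  if (nrow(depth$counts) == 0 || ncol(depth$counts) == 0)
    stop_invalid("empty depth matrix")
  if (low_q < 0 || high_q > 1 || low_q >= high_q)
    stop_invalid("need 0 <= low_q < high_q <= 1")
  med <- apply(depth$counts, 1L, median)
  lo <- quantile(med, low_q, names = FALSE)
  hi <- quantile(med, high_q, names = FALSE)
  depth$mask <- depth$mask | med < lo | med > hi
  depth
}

# pool GC bins with fewer than min_bin_windows members into the nearest
# occupied bin (by bin centre); returns a group id per window
pool_gc_bins <- function(gc, width, min_bin_windows) {
  bin <- floor(gc / width)
  repeat {
    tab <- table(bin)
    ids <- as.numeric(names(tab))
    if (length(ids) <= 1L) break
    small <- ids[tab < min_bin_windows]
    if (length(small) == 0L) break
    b <- small[1]
    others <- setdiff(ids, b)
    target <- others[which.min(abs(others - b))]
    bin[bin == b] <- target
  }
  bin
}

#' Correct GC depth bias by per-bin median scaling
#'
#' Per individual, counts in GC bin `b` are multiplied by
#' (global median of that individual's counts) / (median in bin `b`),
#' computed over unmasked windows, so that after correction every
#' occupied GC bin has the same median as the genome-wide median.  Bins
#' with fewer than `min_bin_windows` windows are pooled with the nearest
#' bin.  Individuals with all-zero counts are left unchanged, recorded in
#' the `excluded_samples` attribute, and reported with a warning.
#'
#' @param depth a `window_depth` (typically after [mask_windows()]).
#' @param gc_bin_width GC bin width in `(0, 0.5]` (default 0.01).
#' @param min_bin_windows minimum windows per bin before pooling.
#' @return the corrected `window_depth`.
#' @export
gc_correct <- function(depth, gc_bin_width = 0.01, min_bin_windows = 20L) {
  stopifnot(inherits(depth, "window_depth"))
  if (gc_bin_width <= 0 || gc_bin_width > 0.5)
    stop_invalid("gc_bin_width must be in (0, 0.5]")
  keep <- !depth$mask
  if (!any(keep)) stop_invalid("all windows are masked")
  grp_keep <- pool_gc_bins(depth$windows$gc[keep], gc_bin_width, min_bin_windows)
  counts <- depth$counts
  excluded <- character(0)
  for (i in seq_len(ncol(counts))) {
    x <- counts[keep, i]
    gmed <- median(x)
    if (gmed == 0) {
      excluded <- c(excluded, colnames(counts)[i])
      next
    }
    bmed <- tapply(x, grp_keep, median)
    fac <- gmed / bmed
    fac[!is.finite(fac)] <- 1
    counts[keep, i] <- x * fac[as.character(grp_keep)]
  }
  if (length(excluded) > 0)
    warning("samples with all-zero depth left uncorrected: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  out <- new_window_depth(depth$windows, counts, depth$mask)
  attr(out, "excluded_samples") <- excluded
  attr(out, "gc_corrected") <- TRUE
  out
}

#' Rescale depth to diploid copy number
#'
#' `cn[w, i] = 2 * counts[w, i] / median_w(counts[., i])` over unmasked
#' windows, anchoring every individual's median copy number at exactly 2.
#'
#' @param depth a `window_depth`, GC-corrected.
#' @return object of class `copy_number`: list with `windows`, `cn`
#'   (matrix windows x samples), `samples`, `mask`, and `step`/`window_size`
#'   attributes when available.
#' @export
normalize_cn <- function(depth) {
  stopifnot(inherits(depth, "window_depth"))
  keep <- !depth$mask
  med <- apply(depth$counts[keep, , drop = FALSE], 2L, median)
  zero <- med == 0
  if (any(zero))
    stop_invalid("zero median depth for sample(s): %s",
                 paste(colnames(depth$counts)[zero], collapse = ", "))
  cn <- sweep(depth$counts, 2L, med, "/") * 2
  structure(list(
    windows = depth$windows,
    cn = cn,
    samples = colnames(cn),
    mask = depth$mask
  ), class = "copy_number")
}

#' Full depth-to-copy-number normalization
#'
#' [mask_windows()], [gc_correct()], then [normalize_cn()].
#'
#' @inheritParams mask_windows
#' @inheritParams gc_correct
#' @return a `copy_number`.
#' @export
normalize_depth <- function(depth, low_q = 0.005, high_q = 0.995,
                            gc_bin_width = 0.01, min_bin_windows = 20L) {
  depth <- mask_windows(depth, low_q, high_q)
  depth <- gc_correct(depth, gc_bin_width, min_bin_windows)
  normalize_cn(depth)
}

#' Spearman correlation between copy number and window GC
#'
#' Correlates the per-window mean copy number (across individuals) with
#' window GC over unmasked windows; the diagnostic behind the GC
#' flattening check.
#'
#' @param cn a `copy_number` or `window_depth`.
#' @return Spearman's rho.
#' @export
gc_depth_correlation <- function(cn) {
  mat <- if (inherits(cn, "copy_number")) cn$cn else cn$counts
  keep <- !cn$mask
  m <- rowMeans(mat[keep, , drop = FALSE])
  stats::cor(m, cn$windows$gc[keep], method = "spearman")
}
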