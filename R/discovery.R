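#' Mean silhouette score of a 1-D clustering
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster (excluding itself) and `b` the minimum over other
#' clusters of the mean distance; points in singleton clusters contribute
#' 0.  Returns the mean over points.
#'
#' @param values numeric vector.
#' @param labels cluster assignment, same length; at least two non-empty
#'   clusters.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labs <- unique(labels)
  if (length(labs) < 2L) stop_invalid("silhouette needs at least 2 clusters")
  n <- length(values)
  D <- abs(outer(values, values, "-"))
  s <- numeric(n)
  sizes <- table(factor(labels, levels = labs))
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(labs[labs != labels[i]],
                    function(k) mean(D[i, labels == k]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# deterministic 1-D k-means: quantile-spaced initial centres, Lloyd
# iterations capped at 300, convergence tolerance 1e-6
kmeans_1d <- function(x, k, max_iter = 300L, tol = 1e-6) {
  centres <- unname(quantile(x, (seq_len(k) - 0.5) / k, type = 7))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centres, "-"))
    lab <- max.col(-d, ties.method = "first")
    new_c <- vapply(seq_len(k), function(j) {
      if (any(lab == j)) mean(x[lab == j])
      else x[which.max(abs(x - centres[j]))]  # re-seed empty cluster
    }, numeric(1))
    done <- max(abs(new_c - centres)) < tol
    centres <- new_c
    if (done) break
  }
  d <- abs(outer(x, centres, "-"))
  lab <- max.col(-d, ties.method = "first")
  list(centres = centres, labels = lab)
}

#' Detect candidate CNV windows
#'
#' A window is a candidate iff `max(n_loss, n_gain) >=
#' max(h, ceiling(f * n_individuals))`, where `n_loss` counts individuals
#' with copy number at or below `loss_threshold` and `n_gain` those at or
#' above `gain_threshold`.  Masked windows are never candidates.
#'
#' @param cn a `copy_number`.
#' @param f minimum deviant-individual fraction (default 0.1).
#' @param h minimum deviant-individual count (default 3).
#' @param loss_threshold,gain_threshold copy-number cutoffs defining loss
#'   and gain individuals (defaults 1.5 / 2.5, the midpoints between the
#'   diploid state and one copy lost / gained).
#' @return data.frame of candidate windows: `window` (row index into
#'   `cn$windows`), `chrom`, `start`, `end`, `n_loss`, `n_gain`.
#' @export
detect_candidates <- function(cn, f = 0.1, h = 3L, loss_threshold = 1.5,
                              gain_threshold = 2.5) {
  stopifnot(inherits(cn, "copy_number"))
  if (f <= 0 || f > 1) stop_invalid("f must be in (0, 1]")
  if (h < 1) stop_invalid("h must be at least 1")
  if (!(loss_threshold < 2 && 2 < gain_threshold))
    stop_invalid("need loss_threshold < 2 < gain_threshold")
  n_ind <- ncol(cn$cn)
  n_loss <- rowSums(cn$cn <= loss_threshold)
  n_gain <- rowSums(cn$cn >= gain_threshold)
  thr <- max(h, ceiling(f * n_ind))
  idx <- which(!cn$mask & pmax(n_loss, n_gain) >= thr)
  data.frame(window = idx,
             chrom = cn$windows$chrom[idx],
             start = cn$windows$start[idx],
             end = cn$windows$end[idx],
             n_loss = n_loss[idx], n_gain = n_gain[idx],
             stringsAsFactors = FALSE)
}

# correlation that tolerates zero-variance vectors: equal constant vectors
# correlate perfectly, otherwise a constant vector correlates with nothing
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    if (isTRUE(all.equal(x, y))) 1 else -Inf
  } else cor(x, y)
}

#' Merge candidate windows into pre-genotyping regions
#'
#' Scans each chromosome in genomic order and extends the current region
#' with the next candidate window iff the genomic gap is at most
#' `max_gap` window-steps and the Pearson correlation between the two
#' windows' copy-number vectors is at least `r`.  Region coordinates span
#' the first window start to the last window end.
#'
#' @param candidates output of [detect_candidates()].
#' @param cn the `copy_number` the candidates came from.
#' @param r minimum adjacent-window Pearson correlation (default 0.1).
#' @param max_gap maximum gap between consecutive candidate windows, in
#'   window-steps (default 1: adjacent windows only).
#' @param step window step in bp; inferred from the window table when
#'   `NULL`.
#' @return list of regions, each a list with `chrom`, `start`, `end`,
#'   `windows` (indices into `cn$windows`).
#' @export
merge_candidates <- function(candidates, cn, r = 0.1, max_gap = 1L,
                             step = NULL) {
  if (r < -1 || r > 1) stop_invalid("r must be in [-1, 1]")
  if (max_gap < 0) stop_invalid("max_gap must be non-negative")
  if (nrow(candidates) == 0) return(list())
  if (is.null(step)) step <- infer_step(cn$windows)
  regions <- list()
  for (ch in unique(candidates$chrom)) {
    cc <- candidates[candidates$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    cur <- cc[1, , drop = FALSE]
    cur_wins <- cur$window
    for (i in seq_len(nrow(cc))[-1]) {
      gap_steps <- (cc$start[i] - cc$start[i - 1]) / step
      ok <- gap_steps <= max_gap &&
        safe_cor(cn$cn[cc$window[i - 1], ], cn$cn[cc$window[i], ]) >= r
      if (ok) {
        cur_wins <- c(cur_wins, cc$window[i])
      } else {
        regions[[length(regions) + 1L]] <- list(
          chrom = ch, start = cc$start[match(cur_wins[1], cc$window)],
          end = cn$windows$end[cur_wins[length(cur_wins)]],
          windows = cur_wins)
        cur_wins <- cc$window[i]
      }
    }
    regions[[length(regions) + 1L]] <- list(
      chrom = ch, start = cn$windows$start[cur_wins[1]],
      end = cn$windows$end[cur_wins[length(cur_wins)]],
      windows = cur_wins)
  }
  regions
}

infer_step <- function(windows) {
  d <- diff(windows$start[windows$chrom == windows$chrom[1]])
  if (length(d) == 0) stop_invalid("cannot infer window step from one window")
  min(d)
}

#' Trim region boundaries to the half-height of the depth signal
#'
#' Windows only partially overlapping a true event carry a diluted copy
#' of the signal and can extend a merged region up to a window size past
#' the event edge.  This refinement drops leading/trailing windows whose
#' mean copy-number deviation `|mean_i cn - 2|` is below `frac` times the
#' region's core deviation (the median window deviation), the analogue
#' of half-maximum breakpoint trimming.
#'
#' @param region a region from [merge_candidates()].
#' @param cn the `copy_number`.
#' @param frac half-height fraction (default 0.5).
#' @return the region with possibly trimmed `windows`, `start`, `end`.
#' @export
refine_boundaries <- function(region, cn, frac = 0.5) {
  w <- region$windows
  if (length(w) < 3L) return(region)
  dev <- abs(rowMeans(cn$cn[w, , drop = FALSE]) - 2)
  core <- median(dev)  # robust to single aberrant windows inside the region
  if (core == 0) return(region)
  keep <- dev >= frac * core
  first <- which(keep)[1]
  last <- tail(which(keep), 1L)
  w <- w[first:last]
  region$windows <- w
  region$start <- cn$windows$start[w[1]]
  region$end <- cn$windows$end[w[length(w)]]
  region
}

#' Genotype a merged region by 1-D clustering
#'
#' Summarizes each individual by its mean copy number over the region's
#' windows, runs deterministic 1-D k-means for each candidate `k`, keeps
#' the `k` maximizing the mean silhouette, and labels clusters by centre
#' value (`< loss_threshold` loss, `> gain_threshold` gain, else normal).
#' Region kind follows the labels present (loss only: deletion; gain
#' only: duplication; both: both; neither: none).  When every summary
#' value is identical no valid clustering exists and the silhouette is
#' defined as -1 so the region fails the downstream filter.
#'
#' @param region a region (list with `chrom`, `start`, `end`, `windows`).
#' @param cn a `copy_number`.
#' @param k_candidates cluster counts to try (default `c(2, 3)`).
#' @param loss_threshold,gain_threshold cluster-centre label cutoffs.
#' @return one-row data.frame `chrom,start,end,kind,n_windows,silhouette`
#'   with the per-individual mean cn and genotype class attached as
#'   attributes `cn` and `genotype`.
#' @export
genotype_cnvr <- function(region, cn, k_candidates = c(2L, 3L),
                          loss_threshold = 1.5, gain_threshold = 2.5) {
  w <- region$windows
  stopifnot(length(w) >= 1)
  summ <- colMeans(cn$cn[w, , drop = FALSE])
  best <- list(sil = -1, centres = NULL, labels = NULL)
  n_distinct <- length(unique(summ))
  for (k in sort(k_candidates)) {
    if (n_distinct < k) next
    km <- kmeans_1d(summ, k)
    if (length(unique(km$labels)) < 2L) next
    s <- silhouette_score(summ, km$labels)
    if (s > best$sil) best <- list(sil = s, centres = km$centres,
                                   labels = km$labels)
  }
  if (is.null(best$labels)) {
    genotype <- rep("normal", length(summ))
    kind <- "none"
  } else {
    cls <- ifelse(best$centres < loss_threshold, "loss",
                  ifelse(best$centres > gain_threshold, "gain", "normal"))
    genotype <- cls[best$labels]
    has_loss <- "loss" %in% genotype
    has_gain <- "gain" %in% genotype
    kind <- if (has_loss && has_gain) "both"
            else if (has_loss) "deletion"
            else if (has_gain) "duplication"
            else "none"
  }
  out <- data.frame(chrom = region$chrom, start = region$start,
                    end = region$end, kind = kind,
                    n_windows = length(w), silhouette = best$sil,
                    stringsAsFactors = FALSE)
  attr(out, "cn") <- summ
  attr(out, "genotype") <- setNames(genotype, names(summ))
  out
}

#' Construct a CNVR set
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`,
#'   `kind`, `n_windows`, `silhouette`.
#' @param cn numeric matrix, CNVRs x samples, of per-CNVR mean copy
#'   number.
#' @param genotype character matrix, CNVRs x samples, of genotype classes
#'   (`loss`/`normal`/`gain`).
#' @return object of class `cnvr_set`.
#' @export
cnvr_set <- function(regions, cn, genotype) {
  stopifnot(nrow(regions) == nrow(cn), all(dim(cn) == dim(genotype)))
  need <- c("chrom", "start", "end", "kind", "n_windows", "silhouette")
  if (!all(need %in% names(regions)))
    stop_invalid("regions must have columns: %s", paste(need, collapse = ", "))
  if (any(regions$end <= regions$start))
    stop_invalid("CNVR end must exceed start")
  structure(list(regions = regions, cn = cn, genotype = genotype,
                 samples = colnames(cn)), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d CNVRs x %d samples (%s)\n",
              nrow(x$regions), ncol(x$cn),
              paste(sprintf("%s=%d", names(table(x$regions$kind)),
                            table(x$regions$kind)), collapse = ", ")))
  invisible(x)
}

subset_cnvr_set <- function(x, i) {
  cnvr_set(x$regions[i, , drop = FALSE],
           x$cn[i, , drop = FALSE],
           x$genotype[i, , drop = FALSE])
}

#' Filter a CNVR set by silhouette and length
#'
#' Retains CNVRs with silhouette strictly greater than `silhouette_min`,
#' deletion/both CNVRs of length at most `del_both_max_len`, and
#' duplication CNVRs of length strictly less than `dup_max_len`.  Regions
#' whose genotyping produced no loss or gain class (`kind == "none"`) are
#' always removed.
#'
#' @param cnvrs a `cnvr_set`.
#' @param silhouette_min silhouette cutoff (default 0.6, strict).
#' @param del_both_max_len max deletion/both length in bp (default 50 kb,
#'   inclusive).
#' @param dup_max_len max duplication length in bp (default 500 kb,
#'   exclusive).
#' @param min_windows minimum constituent windows (default 1; the
#'   pipeline wrapper raises this to 2 for half-overlapping windows).
#' @return the filtered `cnvr_set`.
#' @export
filter_cnvrs <- function(cnvrs, silhouette_min = 0.6,
                         del_both_max_len = 5e4, dup_max_len = 5e5,
                         min_windows = 1L) {
  r <- cnvrs$regions
  len <- r$end - r$start
  keep <- r$silhouette > silhouette_min &
    r$kind %in% CNVR_KINDS &
    r$n_windows >= min_windows &
    ifelse(r$kind %in% c("deletion", "both"), len <= del_both_max_len,
           len < dup_max_len)
  subset_cnvr_set(cnvrs, which(keep))
}

#' Call CNVRs from a copy-number matrix
#'
#' The full discovery pipeline: [detect_candidates()],
#' [merge_candidates()], [refine_boundaries()] (half-height trimming),
#' [genotype_cnvr()] per region, then [filter_cnvrs()].  With
#' half-overlapping windows any event of at least one window length is
#' seen by two adjacent windows, so single-window regions are
#' indistinguishable from depth noise and are discarded by default
#' (`min_windows = 2` whenever the window step is smaller than the window
#' size).  The deviant-frequency rule used for candidate windows is also
#' enforced on the final genotype classes: a retained CNVR must carry at
#' least `max(h, ceiling(f * n))` individuals in a loss or gain class.
#'
#' @inheritParams detect_candidates
#' @inheritParams merge_candidates
#' @inheritParams filter_cnvrs
#' @param k_candidates cluster counts tried per region.
#' @param refine_frac half-height fraction for boundary trimming; `NULL`
#'   disables refinement.
#' @param min_windows minimum constituent candidate windows per retained
#'   CNVR; default 2 for overlapping windows, 1 otherwise.
#' @return a filtered `cnvr_set`; the numbers of candidate windows and
#'   pre-filter regions are attached as attribute `counts`.
#' @export
call_cnvrs <- function(cn, f = 0.1, h = 3L, r = 0.1, max_gap = 1L,
                       loss_threshold = 1.5, gain_threshold = 2.5,
                       k_candidates = c(2L, 3L), silhouette_min = 0.6,
                       del_both_max_len = 5e4, dup_max_len = 5e5,
                       refine_frac = 0.5, min_windows = NULL) {
  step <- infer_step(cn$windows)
  win_size <- cn$windows$end[1] - cn$windows$start[1]
  if (is.null(min_windows)) min_windows <- if (step < win_size) 2L else 1L
  cand <- detect_candidates(cn, f, h, loss_threshold, gain_threshold)
  regions <- merge_candidates(cand, cn, r, max_gap, step)
  if (!is.null(refine_frac))
    regions <- lapply(regions, refine_boundaries, cn = cn, frac = refine_frac)
  if (length(regions) == 0) {
    empty <- cnvr_set(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 kind = character(0), n_windows = integer(0),
                 silhouette = numeric(0), stringsAsFactors = FALSE),
      matrix(0, 0, ncol(cn$cn), dimnames = list(NULL, colnames(cn$cn))),
      matrix("", 0, ncol(cn$cn), dimnames = list(NULL, colnames(cn$cn))))
    attr(empty, "counts") <- c(candidates = nrow(cand), regions = 0L, retained = 0L)
    return(empty)
  }
  rows <- lapply(regions, genotype_cnvr, cn = cn, k_candidates = k_candidates,
                 loss_threshold = loss_threshold, gain_threshold = gain_threshold)
  regions_df <- do.call(rbind, rows)
  cn_mat <- do.call(rbind, lapply(rows, attr, "cn"))
  gt_mat <- do.call(rbind, lapply(rows, attr, "genotype"))
  colnames(cn_mat) <- colnames(gt_mat) <- colnames(cn$cn)
  all_set <- cnvr_set(regions_df, cn_mat, gt_mat)
  out <- filter_cnvrs(all_set, silhouette_min, del_both_max_len, dup_max_len,
                      min_windows)
  # the deviant-frequency rule holds at region level too: a retained CNVR
  # must have at least max(h, ceil(f*n)) individuals in a non-normal class
  min_carriers <- max(h, ceiling(f * ncol(cn$cn)))
  carriers <- rowSums(out$genotype != "normal")
  out <- subset_cnvr_set(out, which(carriers >= min_carriers))
  attr(out, "counts") <- c(candidates = nrow(cand),
                           regions = length(regions),
                           retained = nrow(out$regions))
  out
}
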