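#' V_ST between two populations at one locus
#'
#' `V_ST = (V_T - V_S) / V_T`, where `V_T` is the variance of the pooled
#' copy-number values across both populations and `V_S` is the mean
#' within-population variance weighted by population size.  Variances use
#' denominator n (population variance) by default, which makes the
#' size-weighting exact; set `unbiased = TRUE` for the n-1 convention.
#' When `V_T` is zero the locus is monomorphic and `V_ST` is defined as 0.
#'
#' @param values_a,values_b numeric copy-number values, at least 2 each.
#' @param unbiased use the n-1 variance denominator.
#' @return list with `v_t`, `v_s`, `vst`.
#' @export
vst <- function(values_a, values_b, unbiased = FALSE) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2)
    stop_invalid("vst needs at least 2 values per population")
  pv <- if (unbiased) function(x) stats::var(x)
        else function(x) mean((x - mean(x))^2)
  v_t <- pv(c(values_a, values_b))
  v_s <- (na * pv(values_a) + nb * pv(values_b)) / (na + nb)
  list(v_t = v_t, v_s = v_s,
       vst = if (v_t == 0) 0 else (v_t - v_s) / v_t)
}

check_popmap <- function(popmap, samples) {
  if (anyDuplicated(popmap$sample))
    stop_invalid("duplicate sample in population map: %s",
                 popmap$sample[duplicated(popmap$sample)][1])
  missing <- setdiff(samples, popmap$sample)
  if (length(missing) > 0)
    stop_invalid("samples missing from population map: %s",
                 paste(missing, collapse = ", "))
  setNames(popmap$population, popmap$sample)[samples]
}

#' Scan CNVRs for population differentiation with V_ST
#'
#' Computes one V_ST record per CNVR per (focal, other) population pair
#' from the per-CNVR mean copy numbers.
#'
#' @param cnvrs a `cnvr_set`.
#' @param popmap data.frame with columns `sample`, `population` covering
#'   every sample in `cnvrs`.
#' @param focal focal population label.
#' @param others other population labels (default: all non-focal
#'   populations present).
#' @param unbiased passed to [vst()].
#' @return data.frame `cnvr_id, chrom, start, end, kind, pop_a, pop_b,
#'   v_t, v_s, vst`.
#' @export
vst_scan <- function(cnvrs, popmap, focal, others = NULL, unbiased = FALSE) {
  pops <- check_popmap(popmap, cnvrs$samples)
  if (is.null(others)) others <- setdiff(unique(pops), focal)
  for (p in c(focal, others)) {
    if (sum(pops == p) < 2)
      stop_invalid("population '%s' has fewer than 2 samples", p)
  }
  r <- cnvrs$regions
  out <- list()
  for (p in others) {
    a <- cnvrs$cn[, pops == focal, drop = FALSE]
    b <- cnvrs$cn[, pops == p, drop = FALSE]
    vals <- t(vapply(seq_len(nrow(r)), function(j) {
      v <- vst(a[j, ], b[j, ], unbiased)
      c(v$v_t, v$v_s, v$vst)
    }, numeric(3)))
    out[[p]] <- data.frame(
      cnvr_id = sprintf("%s:%d-%d", r$chrom, r$start, r$end),
      chrom = r$chrom, start = r$start, end = r$end, kind = r$kind,
      pop_a = focal, pop_b = p,
      v_t = vals[, 1], v_s = vals[, 2], vst = vals[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Flag top-quantile V_ST outliers
#'
#' Within each population pair, the threshold is the `1 - q` quantile
#' (linear interpolation) of the V_ST values; records at or above it are
#' flagged.  Ranks are assigned by descending V_ST with ties broken by
#' genomic order.
#'
#' @param records output of [vst_scan()].
#' @param q outlier fraction in `(0, 1)` (default 0.01, the top 1%).
#' @return `records` with `threshold`, `outlier`, `rank` columns added.
#' @export
top_outliers <- function(records, q = 0.01) {
  if (nrow(records) == 0) stop_invalid("empty V_ST record set")
  if (q <= 0 || q >= 1) stop_invalid("q must be in (0, 1)")
  parts <- split(records, list(records$pop_a, records$pop_b), drop = TRUE)
  parts <- lapply(parts, function(d) {
    thr <- quantile(d$vst, 1 - q, names = FALSE, type = 7)
    d$threshold <- thr
    d$outlier <- d$vst >= thr
    d$rank <- NA_integer_
    ord <- order(-d$vst, d$chrom, d$start)
    d$rank[ord] <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$pop_a, out$pop_b, out$rank), , drop = FALSE]
}

#' Map outlier CNVRs to overlapping genes
#'
#' Any overlap of at least 1 bp with a transcript body counts (flanks
#' excluded); the gene list is deduplicated per population pair with each
#' gene's best V_ST retained.
#'
#' @param outliers rows of a [top_outliers()] result (typically the
#'   flagged subset).
#' @param model a `gene_model`.
#' @return data.frame `pop_a, pop_b, gene, n_cnvrs, best_vst`.
#' @export
map_outliers_to_genes <- function(outliers, model) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(outliers) == 0)
    return(data.frame(pop_a = character(0), pop_b = character(0),
                      gene = character(0), n_cnvrs = integer(0),
                      best_vst = numeric(0)))
  tr <- model$transcripts
  gr_tx <- GenomicRanges::GRanges(tr$chrom,
                                  IRanges::IRanges(tr$start + 1L, tr$end))
  gr_out <- GenomicRanges::GRanges(outliers$chrom,
                                   IRanges::IRanges(outliers$start + 1L,
                                                    outliers$end))
  ov <- GenomicRanges::findOverlaps(gr_out, gr_tx)
  if (length(ov) == 0)
    return(data.frame(pop_a = character(0), pop_b = character(0),
                      gene = character(0), n_cnvrs = integer(0),
                      best_vst = numeric(0)))
  hit <- data.frame(pop_a = outliers$pop_a[S4Vectors::queryHits(ov)],
                    pop_b = outliers$pop_b[S4Vectors::queryHits(ov)],
                    gene = tr$gene[S4Vectors::subjectHits(ov)],
                    vst = outliers$vst[S4Vectors::queryHits(ov)],
                    cnvr_id = outliers$cnvr_id[S4Vectors::queryHits(ov)],
                    stringsAsFactors = FALSE)
  agg <- aggregate(vst ~ pop_a + pop_b + gene, data = hit, FUN = max)
  cnt <- aggregate(cnvr_id ~ pop_a + pop_b + gene, data = unique(hit[, -4]),
                   FUN = function(x) length(unique(x)))
  out <- merge(agg, cnt, by = c("pop_a", "pop_b", "gene"))
  names(out)[names(out) == "vst"] <- "best_vst"
  names(out)[names(out) == "cnvr_id"] <- "n_cnvrs"
  out <- out[order(out$pop_a, out$pop_b, -out$best_vst, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("pop_a", "pop_b", "gene", "n_cnvrs", "best_vst")]
}

#' Per-population copy-number summaries for one CNVR
#'
#' The data behind per-locus dosage comparisons of outlier regions.
#'
#' @param cnvrs a `cnvr_set`.
#' @param cnvr_index row index of the CNVR.
#' @param popmap data.frame `sample`, `population`.
#' @return list with `summary` (data.frame `population`, `n`, `mean`,
#'   `median`) and `values` (named list of per-individual copy numbers).
#' @export
copy_number_profile <- function(cnvrs, cnvr_index, popmap) {
  pops <- check_popmap(popmap, cnvrs$samples)
  x <- cnvrs$cn[cnvr_index, ]
  by_pop <- split(x, pops)
  summ <- data.frame(population = names(by_pop),
                     n = vapply(by_pop, length, integer(1)),
                     mean = vapply(by_pop, mean, numeric(1)),
                     median = vapply(by_pop, median, numeric(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(summary = summ, values = by_pop)
}
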