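#' Construct a gene model
#'
#' Internal convention is 0-based half-open throughout.
#'
#' @param transcripts data.frame with columns `tx_id`, `gene`, `chrom`,
#'   `strand` (`+`/`-`), `start`, `end`, `coding` (logical), and for
#'   coding transcripts `cds_start`, `cds_end`.
#' @param exons data.frame with columns `tx_id`, `start`, `end`;
#'   non-overlapping within a transcript.
#' @param flank upstream/downstream flank size in bp (default 1000).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(transcripts, exons, flank = 1000L) {
  need_tx <- c("tx_id", "gene", "chrom", "strand", "start", "end", "coding")
  if (!all(need_tx %in% names(transcripts)))
    stop_invalid("transcripts must have columns: %s", paste(need_tx, collapse = ", "))
  if (!all(c("tx_id", "start", "end") %in% names(exons)))
    stop_invalid("exons must have columns tx_id, start, end")
  for (tx in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    tr <- transcripts[transcripts$tx_id == tx, , drop = FALSE]
    if (nrow(tr) != 1) stop_invalid("exon references unknown transcript %s", tx)
    if (any(e$start < tr$start) || any(e$end > tr$end))
      stop_invalid("exons outside transcript bounds for %s", tx)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop_invalid("overlapping exons in transcript %s", tx)
  }
  structure(list(transcripts = transcripts,
                 exons = exons[order(exons$tx_id, exons$start), , drop = FALSE],
                 flank = as.integer(flank)),
            class = "gene_model")
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

# feature hits of one interval against one transcript; returns a character
# vector of categories (possibly several) plus whether the gene body or
# flank was touched
tx_hits <- function(start, end, tr, exons, flank, splice_window) {
  hits <- character(0)
  body <- overlaps(start, end, tr$start, tr$end)
  if (body) {
    ex <- exons[exons$tx_id == tr$tx_id, , drop = FALSE]
    ex_hit <- overlaps(start, end, ex$start, ex$end)
    if (tr$coding) {
      cds_s <- tr$cds_start; cds_e <- tr$cds_end
      for (i in which(ex_hit)) {
        cs <- max(ex$start[i], cds_s); ce <- min(ex$end[i], cds_e)
        if (cs < ce && overlaps(start, end, cs, ce)) hits <- c(hits, "exonic")
        # UTR portions of the exon (outside the CDS span)
        if (ex$start[i] < cds_s && overlaps(start, end, ex$start[i], min(ex$end[i], cds_s)))
          hits <- c(hits, if (tr$strand == "+") "UTR5" else "UTR3")
        if (ex$end[i] > cds_e && overlaps(start, end, max(ex$start[i], cds_e), ex$end[i]))
          hits <- c(hits, if (tr$strand == "+") "UTR3" else "UTR5")
      }
    } else if (any(ex_hit)) {
      hits <- c(hits, "ncRNA_exonic")
    }
    # introns: gaps between consecutive exons
    if (nrow(ex) > 1) {
      for (i in seq_len(nrow(ex) - 1L)) {
        is_ <- ex$end[i]; ie <- ex$start[i + 1L]
        if (overlaps(start, end, is_, ie)) {
          hits <- c(hits, if (tr$coding) "intronic" else "ncRNA_intronic")
          near5 <- overlaps(start, end, is_, min(is_ + splice_window, ie))
          near3 <- overlaps(start, end, max(ie - splice_window, is_), ie)
          if (tr$coding && (near5 || near3)) hits <- c(hits, "splicing")
        }
      }
    }
  } else {
    up <- if (tr$strand == "+") c(tr$start - flank, tr$start)
          else c(tr$end, tr$end + flank)
    dn <- if (tr$strand == "+") c(tr$end, tr$end + flank)
          else c(tr$start - flank, tr$start)
    if (overlaps(start, end, up[1], up[2])) hits <- c(hits, "upstream")
    if (overlaps(start, end, dn[1], dn[2])) hits <- c(hits, "downstream")
  }
  unique(hits)
}

resolve_category <- function(hits) {
  if (length(hits) == 0) return("intergenic")
  if (all(c("exonic", "splicing") %in% hits)) hits <- c(hits, "exonic_and_splicing")
  if (all(c("upstream", "downstream") %in% hits))
    hits <- c(hits, "upstream_and_downstream")
  FEATURE_CATEGORIES[min(match(hits, FEATURE_CATEGORIES))]
}

#' Annotate CNVRs with genomic-feature categories
#'
#' Collects all feature overlaps of each CNVR across transcripts
#' (coding-exon, splice-site zone, non-coding exon, UTRs, introns,
#' strand-aware flanks), then reports the single highest-precedence
#' category per CNVR:
#' exonic_and_splicing > exonic > splicing > ncRNA_exonic > UTR5 > UTR3 >
#' ncRNA_intronic > intronic > upstream_and_downstream > upstream >
#' downstream > intergenic.  CNVRs on chromosomes absent from the model
#' are intergenic, with a warning.
#'
#' @param cnvrs a `cnvr_set` or a data.frame with `chrom`, `start`, `end`.
#' @param model a `gene_model`.
#' @param splice_window bp around intron/exon boundaries (inside the
#'   intron) counted as splicing (default 2).
#' @return data.frame `cnvr_id`, `chrom`, `start`, `end`, `category`,
#'   `genes` (comma-separated).
#' @export
annotate_cnvrs <- function(cnvrs, model, splice_window = 2L) {
  stopifnot(inherits(model, "gene_model"))
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  if (nrow(model$transcripts) == 0) stop_invalid("empty gene model")
  tr_all <- model$transcripts
  missing_chr <- setdiff(unique(regions$chrom), unique(tr_all$chrom))
  if (length(missing_chr) > 0)
    warning("chromosome(s) absent from gene model, annotated intergenic: ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  cat_out <- character(nrow(regions))
  genes_out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    tr_chr <- tr_all[tr_all$chrom == regions$chrom[i], , drop = FALSE]
    reach <- overlaps(s, e, tr_chr$start - model$flank, tr_chr$end + model$flank)
    hits <- character(0); genes <- character(0)
    for (j in which(reach)) {
      h <- tx_hits(s, e, tr_chr[j, ], model$exons, model$flank, splice_window)
      if (length(h) > 0) {
        hits <- c(hits, h)
        genes <- c(genes, tr_chr$gene[j])
      }
    }
    cat_out[i] <- resolve_category(hits)
    genes_out[i] <- paste(sort(unique(genes)), collapse = ",")
  }
  data.frame(cnvr_id = sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end),
             chrom = regions$chrom, start = regions$start, end = regions$end,
             category = factor(cat_out, levels = FEATURE_CATEGORIES),
             genes = genes_out, stringsAsFactors = FALSE)
}

#' Tally CNVRs into length bins per kind
#'
#' @param cnvrs a `cnvr_set`.
#' @param bin_edges sorted bin edges in bp; bins are half-open
#'   `[lo, hi)` with a final open-ended bin appended so counts always
#'   partition the set.
#' @return data.frame `bin`, one count column per kind, and `total`.
#' @export
summarize_lengths <- function(cnvrs,
                              bin_edges = c(0, 1e3, 2e3, 5e3, 1e4, 5e4, 1e5, 5e5)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_invalid("bin_edges must be strictly increasing")
  r <- cnvrs$regions
  edges <- c(bin_edges, Inf)
  labs <- sprintf("[%s,%s)", format(edges[-length(edges)], trim = TRUE,
                                    scientific = FALSE),
                  format(edges[-1], trim = TRUE, scientific = FALSE))
  bin <- cut(r$end - r$start, breaks = edges, labels = labs, right = FALSE)
  kinds <- CNVR_KINDS
  out <- data.frame(bin = labs, stringsAsFactors = FALSE)
  for (k in kinds)
    out[[k]] <- as.integer(table(bin[r$kind == k]))
  out$total <- as.integer(table(bin))
  out
}

#' Per-chromosome CNVR counts and spanned bp per kind
#'
#' @param cnvrs a `cnvr_set`.
#' @return data.frame `chrom`, `kind`, `count`, `total_bp`.
#' @export
summarize_chromosomes <- function(cnvrs) {
  r <- cnvrs$regions
  if (nrow(r) == 0)
    return(data.frame(chrom = character(0), kind = character(0),
                      count = integer(0), total_bp = integer(0)))
  agg <- aggregate(cbind(count = rep(1L, nrow(r)), total_bp = r$end - r$start),
                   by = list(chrom = r$chrom, kind = r$kind), FUN = sum)
  agg[order(agg$chrom, agg$kind), , drop = FALSE]
}

#' Fractions of CNVRs per feature category
#'
#' @param annotations output of [annotate_cnvrs()].
#' @return named numeric vector over all categories, summing to 1.
#' @export
feature_fractions <- function(annotations) {
  if (nrow(annotations) == 0) stop_invalid("empty annotation set")
  tab <- table(factor(annotations$category, levels = FEATURE_CATEGORIES))
  setNames(as.numeric(tab) / nrow(annotations), FEATURE_CATEGORIES)
}
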