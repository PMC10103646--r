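# Shared fixtures, built in code.

# a flat window table with constant gc
flat_windows <- function(n, gc = 0.45, chrom = "chr1", size = 800L, step = 800L) {
  data.frame(chrom = chrom, start = seq(0L, by = step, length.out = n),
             end = seq(0L, by = step, length.out = n) + size, gc = gc,
             stringsAsFactors = FALSE)
}

# copy_number fixture from a plain matrix (windows x samples)
cn_fixture <- function(mat, gc = 0.45, step = 800L) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  copy_number_matrix(flat_windows(nrow(mat), gc = gc, step = step), mat)
}

# a cnvr_set with given kinds / lengths / silhouettes and dummy matrices
cnvr_fixture <- function(kind, length_bp, silhouette, n_samples = 4L,
                         chrom = "chr1", n_windows = 5L) {
  n <- length(kind)
  start <- as.integer(seq(0, by = 1e6, length.out = n))
  regions <- data.frame(chrom = rep_len(chrom, n), start = start,
                        end = start + as.integer(length_bp), kind = kind,
                        n_windows = rep_len(n_windows, n),
                        silhouette = rep_len(silhouette, n),
                        stringsAsFactors = FALSE)
  cn <- matrix(2, n, n_samples,
               dimnames = list(NULL, sprintf("s%02d", seq_len(n_samples))))
  gt <- matrix("normal", n, n_samples, dimnames = dimnames(cn))
  cnvr_set(regions, cn, gt)
}

# toy gene model: G1 coding (+), G2 non-coding (-), G3 coding single-exon,
# G5/G6 an adjacent pair whose flank zones overlap
toy_gene_model <- function(flank = 1000L) {
  tx <- data.frame(
    tx_id = c("T1", "T2", "T3", "T5", "T6"),
    gene = c("G1", "G2", "G3", "G5", "G6"),
    chrom = "chr1",
    strand = c("+", "-", "+", "+", "+"),
    start = c(1000L, 12000L, 20000L, 38000L, 41500L),
    end = c(9000L, 15000L, 24000L, 40000L, 43000L),
    coding = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    cds_start = c(1500L, NA, 20500L, 38200L, 41700L),
    cds_end = c(8500L, NA, 23500L, 39800L, 42800L),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    tx_id = c("T1", "T1", "T1", "T2", "T2", "T3", "T5", "T6"),
    start = c(1000L, 3000L, 8000L, 12000L, 14500L, 20000L, 38000L, 41500L),
    end = c(2000L, 4000L, 9000L, 12500L, 15000L, 24000L, 40000L, 43000L),
    stringsAsFactors = FALSE)
  gene_model(tx, ex, flank = flank)
}

regions_df <- function(chrom, start, end, kind = "deletion") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             kind = kind, n_windows = 2L, silhouette = 0.9,
             stringsAsFactors = FALSE)
}
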