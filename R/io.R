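#' Write / read a window depth matrix TSV
#'
#' Dialect: columns `chrom`, `start`, `end`, `gc`, `mask`, then one
#' column per sample; coordinates 0-based half-open.
#'
#' @param depth a `window_depth`.
#' @param path output file.
#' @export
write_depth_matrix <- function(depth, path) {
  stopifnot(inherits(depth, "window_depth"))
  df <- cbind(depth$windows[, c("chrom", "start", "end", "gc")],
              mask = as.integer(depth$mask),
              as.data.frame(depth$counts))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_depth_matrix
#' @return `read_depth_matrix`: a `window_depth`.
#' @export
read_depth_matrix <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("chrom", "start", "end", "gc", "mask")
  if (!all(need %in% names(df)))
    stop_invalid("%s: missing required columns (%s)", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad) > 0)
    stop_invalid("%s line %d: end <= start", path, bad[1] + 1L)
  if (any(df$gc < 0 | df$gc > 1))
    stop_invalid("%s line %d: gc outside [0, 1]", path,
                 which(df$gc < 0 | df$gc > 1)[1] + 1L)
  samples <- setdiff(names(df), need)
  if (length(samples) == 0) stop_invalid("%s: no sample columns", path)
  counts <- as.matrix(df[, samples, drop = FALSE])
  new_window_depth(df[, c("chrom", "start", "end", "gc")], counts,
                   as.logical(df$mask))
}

#' Write / read a copy-number matrix TSV
#'
#' Same dialect as the depth matrix, with copy-number values.
#' @param cn a `copy_number`.
#' @param path file path.
#' @export
write_cn_matrix <- function(cn, path) {
  stopifnot(inherits(cn, "copy_number"))
  df <- cbind(cn$windows[, c("chrom", "start", "end", "gc")],
              mask = as.integer(cn$mask),
              as.data.frame(cn$cn))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_cn_matrix
#' @export
read_cn_matrix <- function(path) {
  d <- read_depth_matrix(path)
  structure(list(windows = d$windows, cn = d$counts, samples = d$samples,
                 mask = d$mask), class = "copy_number")
}

#' Write / read a population map TSV
#'
#' Two columns: `sample`, `population`.  Duplicate samples are rejected.
#' @param popmap data.frame `sample`, `population`.
#' @param path file path.
#' @export
write_population_map <- function(popmap, path) {
  data.table::fwrite(popmap[, c("sample", "population")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_population_map
#' @export
read_population_map <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = "character"))
  if (!all(c("sample", "population") %in% names(df)))
    stop_invalid("%s: need columns sample, population", path)
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup) > 0)
    stop_invalid("%s: duplicate sample '%s'", path, dup[1])
  df
}

#' Write / read a CNVR table TSV
#'
#' BED-like dialect: `chrom`, `start`, `end`, `kind`, `n_windows`,
#' `silhouette`, then `cn_<sample>` and `gt_<sample>` columns.
#'
#' @param cnvrs a `cnvr_set`.
#' @param path file path.
#' @export
write_cnvr_table <- function(cnvrs, path) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  cn <- as.data.frame(cnvrs$cn)
  gt <- as.data.frame(cnvrs$genotype)
  names(cn) <- paste0("cn_", cnvrs$samples)
  names(gt) <- paste0("gt_", cnvrs$samples)
  df <- cbind(cnvrs$regions, cn, gt)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_cnvr_table
#' @export
read_cnvr_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("chrom", "start", "end", "kind", "n_windows", "silhouette")
  if (!all(need %in% names(df)))
    stop_invalid("%s: missing required columns (%s)", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad) > 0)
    stop_invalid("%s line %d: end <= start", path, bad[1] + 1L)
  cn_cols <- grep("^cn_", names(df), value = TRUE)
  gt_cols <- grep("^gt_", names(df), value = TRUE)
  samples <- sub("^cn_", "", cn_cols)
  cn <- as.matrix(df[, cn_cols, drop = FALSE])
  gt <- as.matrix(df[, gt_cols, drop = FALSE])
  colnames(cn) <- colnames(gt) <- samples
  cnvr_set(df[, need], cn, gt)
}

#' Write a truth-set BED
#'
#' Columns: chrom, start, end, kind, copy_change, then per-population
#' allele frequencies.
#' @param truth a `cnv_truth`.
#' @param path file path.
#' @export
write_truth_bed <- function(truth, path) {
  data.table::fwrite(truth$events, path, sep = "\t")
  invisible(path)
}

#' Read a gene model from GFF3 or BED12
#'
#' GFF3 input (1-based, inclusive) is converted to the internal 0-based
#' half-open convention.  GFF3 files must carry gene / mRNA (or
#' transcript) / exon / CDS features linked by `ID`/`Parent`; BED12
#' transcripts use the thick interval as the CDS.
#'
#' @param path file path (`.gff3`/`.gff` or `.bed`).
#' @param flank upstream/downstream flank in bp (default 1000).
#' @return a `gene_model`.
#' @export
read_gene_model <- function(path, flank = 1000L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff3", "gff")) read_gene_model_gff3(path, flank)
  else if (ext == "bed") read_gene_model_bed12(path, flank)
  else stop_invalid("unsupported gene model format: .%s", ext)
}

read_gene_model_gff3 <- function(path, flank) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  id <- as.character(meta$ID)
  parent <- vapply(as.list(meta$Parent), function(p)
    if (length(p) == 0) NA_character_ else p[[1]], character(1))
  is_tx <- type %in% c("mRNA", "transcript", "ncRNA", "lnc_RNA")
  if (!any(is_tx)) stop_invalid("%s: no transcript features", path)
  gname <- if ("Name" %in% colnames(meta)) as.character(meta$Name)
           else rep(NA_character_, length(gr))
  gene_name <- setNames(
    ifelse(is.na(gname[type == "gene"]), id[type == "gene"],
           gname[type == "gene"]),
    id[type == "gene"])
  tx_idx <- which(is_tx)
  tx_ids <- id[tx_idx]
  cds_parent <- parent[type == "CDS"]
  tx <- data.frame(
    tx_id = tx_ids,
    gene = ifelse(is.na(gene_name[parent[tx_idx]]), parent[tx_idx],
                  gene_name[parent[tx_idx]]),
    chrom = as.character(GenomicRanges::seqnames(gr))[tx_idx],
    strand = as.character(GenomicRanges::strand(gr))[tx_idx],
    start = GenomicRanges::start(gr)[tx_idx] - 1L,
    end = GenomicRanges::end(gr)[tx_idx],
    coding = tx_ids %in% cds_parent,
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tx))) {
    if (!tx$coding[i]) next
    sel <- type == "CDS" & parent == tx$tx_id[i]
    tx$cds_start[i] <- min(GenomicRanges::start(gr)[sel]) - 1L
    tx$cds_end[i] <- max(GenomicRanges::end(gr)[sel])
  }
  ex_sel <- type == "exon"
  exons <- data.frame(tx_id = parent[ex_sel],
                      start = GenomicRanges::start(gr)[ex_sel] - 1L,
                      end = GenomicRanges::end(gr)[ex_sel],
                      stringsAsFactors = FALSE)
  gene_model(tx, exons, flank)
}

read_gene_model_bed12 <- function(path, flank) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  name <- S4Vectors::mcols(gr)$name
  thick <- S4Vectors::mcols(gr)$thick
  coding <- IRanges::width(thick) > 1L
  tx <- data.frame(
    tx_id = name, gene = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    coding = coding,
    cds_start = ifelse(coding, IRanges::start(thick) - 1L, NA_integer_),
    cds_end = ifelse(coding, IRanges::end(thick), NA_integer_),
    stringsAsFactors = FALSE)
  ex <- as.data.frame(blocks)
  exons <- data.frame(tx_id = name[ex$group],
                      start = ex$start - 1L, end = ex$end,
                      stringsAsFactors = FALSE)
  gene_model(tx, exons, flank)
}

#' Write a gene model as GFF3
#'
#' Inverse of [read_gene_model()] for the GFF3 dialect (coordinates
#' converted back to 1-based inclusive).
#'
#' @param model a `gene_model`.
#' @param path output file.
#' @export
write_gene_model_gff3 <- function(model, path) {
  tr <- model$transcripts
  lines <- c("##gff-version 3")
  for (g in unique(tr$gene)) {
    sub <- tr[tr$gene == g, , drop = FALSE]
    gid <- paste0("gene:", g)
    lines <- c(lines, sprintf(
      "%s\tcnvpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      sub$chrom[1], min(sub$start) + 1L, max(sub$end), sub$strand[1], gid, g))
    for (i in seq_len(nrow(sub))) {
      t <- sub[i, ]
      lines <- c(lines, sprintf(
        "%s\tcnvpop\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        t$chrom, t$start + 1L, t$end, t$strand, t$tx_id, gid))
      ex <- model$exons[model$exons$tx_id == t$tx_id, , drop = FALSE]
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\tcnvpop\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          t$chrom, ex$start[j] + 1L, ex$end[j], t$strand, t$tx_id, j, t$tx_id))
        if (t$coding) {
          cs <- max(ex$start[j], t$cds_start); ce <- min(ex$end[j], t$cds_end)
          if (cs < ce)
            lines <- c(lines, sprintf(
              "%s\tcnvpop\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
              t$chrom, cs + 1L, ce, t$strand, t$tx_id, j, t$tx_id))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
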