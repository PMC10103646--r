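#' Build and validate a pipeline configuration
#'
#' All detection and filtering parameters default to the standard
#' population-scale read-depth settings: 800-bp windows, deviant fraction
#' f = 0.1, deviant count h = 3, merge correlation r = 0.1, silhouette
#' gate 0.6, deletion/both length cap 50 kb, duplication cap 500 kb, top
#' 1% V_ST outliers.  Unknown keys are rejected; every numeric field is
#' validated against the stage that consumes it.
#'
#' @param ... configuration overrides, or a single named list.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # simulate
    pop_sizes = c(A = 20L, B = 20L), n_chrom = 1L, chrom_length = 1e7,
    window_size = 800L, step = 400L, n_events = 50L,
    length_range = c(2e3, 5e4), freq_levels = c(0.2, 0.3, 0.4, 0.5, 0.6),
    mean_depth = 12, gc_bias_amplitude = 0.4, dispersion = 150,
    # normalize
    low_q = 0.005, high_q = 0.995, gc_bin_width = 0.01, min_bin_windows = 20L,
    # call
    f = 0.1, h = 3L, r = 0.1, max_gap = 1L,
    loss_threshold = 1.5, gain_threshold = 2.5,
    silhouette_min = 0.6, del_both_max_len = 5e4, dup_max_len = 5e5,
    refine_frac = 0.5,
    # annotate
    gene_model_path = NULL, splice_window = 2L, flank = 1000L,
    # pca
    pca_subset = "all", pca_k = 10L, pca_scale = TRUE,
    # vst
    vst_focal = NULL, vst_q = 0.01,
    # general
    seed = 1L,
    depth_matrix_path = NULL, population_map_path = NULL
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_invalid("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  with(cfg, {
    if (window_size <= 0 || !step %in% c(window_size, window_size / 2))
      stop_invalid("step must equal window_size or window_size/2")
    if (f <= 0 || f > 1) stop_invalid("f must be in (0, 1]")
    if (h < 1) stop_invalid("h must be >= 1")
    if (r < -1 || r > 1) stop_invalid("r must be in [-1, 1]")
    if (silhouette_min < -1 || silhouette_min > 1)
      stop_invalid("silhouette_min must be in [-1, 1]")
    if (!(loss_threshold < 2 && 2 < gain_threshold))
      stop_invalid("need loss_threshold < 2 < gain_threshold")
    if (low_q < 0 || high_q > 1 || low_q >= high_q)
      stop_invalid("need 0 <= low_q < high_q <= 1")
    if (gc_bin_width <= 0 || gc_bin_width > 0.5)
      stop_invalid("gc_bin_width must be in (0, 0.5]")
    if (vst_q <= 0 || vst_q >= 1) stop_invalid("vst_q must be in (0, 1)")
    if (mean_depth <= 0 || dispersion <= 0)
      stop_invalid("mean_depth and dispersion must be positive")
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if ("pop_sizes" %in% names(cfg)) cfg$pop_sizes <- unlist(cfg$pop_sizes)
  for (k in c("length_range", "freq_levels"))
    if (k %in% names(cfg)) cfg[[k]] <- as.numeric(unlist(cfg[[k]]))
  pipeline_config(cfg)
}

#' Run the CNVR analysis pipeline
#'
#' Executes the selected stages in order: simulate (or load), normalize,
#' call, annotate, pca, vst.  Every output is written under `out_dir` as
#' TSV/BED/GFF3/JSON and a `manifest.json` records the configuration,
#' seed, per-stage row counts and output checksums, so a rerun with the
#' same configuration is bit-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "normalize", "call",
                                    "annotate", "pca", "vst")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  counts <- list()
  files <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files <<- c(files, p)
    p
  }

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(
      pop_sizes = config$pop_sizes, n_chrom = config$n_chrom,
      chrom_length = config$chrom_length, window_size = config$window_size,
      step = config$step, n_events = config$n_events,
      length_range = config$length_range, freq_levels = config$freq_levels,
      mean_depth = config$mean_depth,
      gc_bias_amplitude = config$gc_bias_amplitude,
      dispersion = config$dispersion, seed = config$seed)
    res$depth <- sim$depth
    res$truth <- sim$truth
    res$popmap <- sim$truth$samples
    emit(write_depth_matrix, sim$depth, "depth_matrix.tsv")
    emit(write_truth_bed, sim$truth, "truth_events.bed")
    emit(write_population_map, sim$truth$samples, "population_map.tsv")
    counts$simulate <- c(windows = nrow(sim$depth$windows),
                         samples = ncol(sim$depth$counts),
                         events = nrow(sim$truth$events))
  } else {
    if (is.null(config$depth_matrix_path))
      stop_invalid("stage 'simulate' disabled and no depth_matrix_path given")
    res$depth <- read_depth_matrix(config$depth_matrix_path)
    res$popmap <- read_population_map(config$population_map_path)
  }

  if ("normalize" %in% stages) {
    res$cn <- tryCatch(
      normalize_depth(res$depth, config$low_q, config$high_q,
                      config$gc_bin_width, config$min_bin_windows),
      error = function(e) stop_invalid("stage normalize: %s", conditionMessage(e)))
    emit(write_cn_matrix, res$cn, "copy_number.tsv")
    counts$normalize <- c(windows_masked = sum(res$cn$mask))
  }

  if ("call" %in% stages) {
    res$cnvrs <- tryCatch(
      call_cnvrs(res$cn, f = config$f, h = config$h, r = config$r,
                 max_gap = config$max_gap,
                 loss_threshold = config$loss_threshold,
                 gain_threshold = config$gain_threshold,
                 silhouette_min = config$silhouette_min,
                 del_both_max_len = config$del_both_max_len,
                 dup_max_len = config$dup_max_len,
                 refine_frac = config$refine_frac),
      error = function(e) stop_invalid("stage call: %s", conditionMessage(e)))
    emit(write_cnvr_table, res$cnvrs, "cnvrs.tsv")
    counts$call <- attr(res$cnvrs, "counts")
  }

  if ("annotate" %in% stages) {
    model <- if (!is.null(config$gene_model_path))
      read_gene_model(config$gene_model_path, config$flank)
    else synthetic_gene_model(res$cnvrs, flank = config$flank,
                              seed = config$seed)
    res$model <- model
    res$annotation <- annotate_cnvrs(res$cnvrs, model, config$splice_window)
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         res$annotation, "annotation.tsv")
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         summarize_lengths(res$cnvrs), "length_bins.tsv")
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         summarize_chromosomes(res$cnvrs), "chromosome_summary.tsv")
    counts$annotate <- c(annotated = nrow(res$annotation))
  }

  if ("pca" %in% stages) {
    mat <- build_cnvr_matrix(res$cnvrs, config$pca_subset)
    res$pca <- cnvr_pca(mat, k = config$pca_k, scale = config$pca_scale)
    coords <- data.frame(sample = rownames(res$pca$coordinates),
                         population = res$popmap$population[
                           match(rownames(res$pca$coordinates),
                                 res$popmap$sample)],
                         res$pca$coordinates, stringsAsFactors = FALSE)
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         coords, "pca_coordinates.tsv")
    emit(function(x, p) data.table::fwrite(
      data.frame(component = seq_along(x), variance_explained = x), p,
      sep = "\t"), res$pca$variance_explained, "pca_variance.tsv")
    counts$pca <- c(components = ncol(res$pca$coordinates))
  }

  if ("vst" %in% stages) {
    focal <- config$vst_focal %||% res$popmap$population[1]
    rec <- vst_scan(res$cnvrs, res$popmap, focal)
    rec <- top_outliers(rec, config$vst_q)
    res$vst <- rec
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         rec, "vst_records.tsv")
    if ("annotate" %in% stages) {
      genes <- map_outliers_to_genes(rec[rec$outlier, , drop = FALSE],
                                     res$model)
      emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
           genes, "vst_outlier_genes.tsv")
    }
    counts$vst <- c(records = nrow(rec), outliers = sum(rec$outlier))
  }

  manifest <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    seed = config$seed,
    stages = stages,
    counts = counts,
    files = lapply(setNames(basename(files), basename(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Synthetic gene model covering a CNVR set
#'
#' Builds a small artificial gene model (coding and non-coding
#' transcripts placed along the chromosomes of a CNVR set) so annotation
#' can run without an external GFF3.  Clearly synthetic: gene names are
#' `SYNG<i>`.
#'
#' @param cnvrs a `cnvr_set` (used for chromosome names and extent).
#' @param genes_per_mb gene density (default 10).
#' @param flank flank size passed to [gene_model()].
#' @param seed integer seed.
#' @return a `gene_model`.
#' @export
synthetic_gene_model <- function(cnvrs, genes_per_mb = 10, flank = 1000L,
                                 seed = 1L) {
  set.seed(seed)
  r <- cnvrs$regions
  chroms <- unique(r$chrom)
  tx_list <- list(); ex_list <- list(); gi <- 0L
  for (ch in chroms) {
    extent <- max(r$end[r$chrom == ch]) + 5e4
    n_genes <- max(2L, round(genes_per_mb * extent / 1e6))
    starts <- sort(sample.int(max(extent - 3e4, n_genes), n_genes))
    for (s in starts) {
      gi <- gi + 1L
      glen <- sample(5e3:2e4, 1L)
      n_ex <- sample(2:6, 1L)
      bounds <- sort(sample(seq(200L, glen - 200L, by = 100L), 2L * n_ex - 2L))
      ex_starts <- c(0L, bounds[seq(2, length(bounds), by = 2)])
      ex_ends <- c(bounds[seq(1, length(bounds), by = 2)], glen)
      coding <- runif(1) < 0.8
      tx_id <- sprintf("SYNT%d", gi)
      tx_list[[gi]] <- data.frame(
        tx_id = tx_id, gene = sprintf("SYNG%d", gi), chrom = ch,
        strand = sample(c("+", "-"), 1L), start = s, end = s + glen,
        coding = coding,
        cds_start = if (coding) s + ex_ends[1] %/% 2L else NA_integer_,
        cds_end = if (coding) s + ex_starts[n_ex] +
          (ex_ends[n_ex] - ex_starts[n_ex]) %/% 2L else NA_integer_,
        stringsAsFactors = FALSE)
      ex_list[[gi]] <- data.frame(tx_id = tx_id, start = s + ex_starts,
                                  end = s + ex_ends,
                                  stringsAsFactors = FALSE)
    }
  }
  gene_model(do.call(rbind, tx_list), do.call(rbind, ex_list), flank)
}
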