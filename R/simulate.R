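#' Simulate a tiled-window reference
#'
#' Builds a set of chromosomes tiled by fixed-size windows in fixed steps,
#' with a smoothly varying GC fraction per window (bounded AR(1) walk).
#' Mammalian autosomal GC skews below 0.5, so the default walk is bounded in
#' `[0.30, 0.60]` around 0.45; a unimodal GC depth bias centred at 0.5 then
#' has a monotone component over the realized range, as in real WGS data.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param window_size window size in bp (default 800).
#' @param step distance between window starts; either `window_size`
#'   (non-overlapping) or `window_size / 2` (half-overlapping, default).
#' @param gc_autocorrelation AR(1) coefficient of the GC walk in `[0, 1)`.
#' @param gc_range bounds of the GC walk.
#' @param repeat_frac fraction of windows overlapping collapsed repeats,
#'   whose depth is inflated by a constant factor (default 0: clean
#'   genome).
#' @param dropout_frac fraction of near-unmappable windows with strongly
#'   reduced depth (default 0).
#' @param seed integer seed; identical seeds give identical references.
#' @return an object of class `cnv_reference`: a list with `windows`
#'   (data.frame `chrom`, `start`, `end`, `gc`; 0-based half-open),
#'   `chromosomes`, `window_size`, `step`.
#' @examples
#' ref <- simulate_reference(1, 8000, 800, 400, seed = 1)
#' nrow(ref$windows)  # 19 full windows
#' @export
simulate_reference <- function(n_chrom = 1L, chrom_length = 1e7, window_size = 800L,
                               step = window_size / 2, gc_autocorrelation = 0.99,
                               gc_range = c(0.30, 0.60), repeat_frac = 0,
                               dropout_frac = 0, seed = 1L) {
  if (n_chrom < 1 || chrom_length <= 0 || window_size <= 0 || step <= 0)
    stop_invalid("n_chrom, chrom_length, window_size and step must be positive")
  if (!step %in% c(window_size, window_size / 2))
    stop_invalid("step must equal window_size or window_size/2 (got %s)", step)
  if (chrom_length < 10 * window_size)
    stop_invalid("chrom_length must be at least 10 * window_size")
  if (gc_autocorrelation < 0 || gc_autocorrelation >= 1)
    stop_invalid("gc_autocorrelation must be in [0, 1)")
  set.seed(seed)
  centre <- mean(gc_range)
  innov_sd <- 0.012
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  win_list <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    starts <- seq(0L, chrom_length - window_size, by = step)
    n <- length(starts)
    gc <- numeric(n)
    gc[1] <- centre
    for (i in seq_len(n - 1L)) {
      nxt <- centre + gc_autocorrelation * (gc[i] - centre) + rnorm(1L, 0, innov_sd)
      gc[i + 1L] <- min(max(nxt, gc_range[1]), gc_range[2])
    }
    # per-window mappability multiplier: collapsed repeats inflate depth,
    # unmappable windows lose most of it; a genome property shared by all
    # individuals, the thing downstream quantile masking is meant to catch
    mult <- rep(1, n)
    n_rep <- round(repeat_frac * n)
    n_drop <- round(dropout_frac * n)
    special <- sample.int(n, n_rep + n_drop)
    if (n_rep > 0)
      mult[special[seq_len(n_rep)]] <- exp(runif(n_rep, log(3), log(10)))
    if (n_drop > 0)
      mult[special[n_rep + seq_len(n_drop)]] <- runif(n_drop, 0, 0.15)
    win_list[[ci]] <- data.frame(
      chrom = chroms[ci], start = as.integer(starts),
      end = as.integer(starts + window_size), gc = gc, mappability = mult,
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    windows = do.call(rbind, win_list),
    chromosomes = data.frame(chrom = chroms, length = chrom_length,
                             stringsAsFactors = FALSE),
    window_size = as.integer(window_size),
    step = as.integer(step)
  ), class = "cnv_reference")
}

#' Build a table of CNV events to implant
#'
#' @param chrom,start,end event coordinates (0-based half-open).
#' @param kind `"deletion"` or `"duplication"`.
#' @param copy_change per-allele copy change: -1 or -2 for deletion alleles,
#'   +1..+3 for duplication alleles.
#' @param freq data.frame or matrix of allele frequencies, one column per
#'   population, one row per event.
#' @return data.frame of class `cnv_events` with `freq_<pop>` columns.
#' @export
cnv_events <- function(chrom, start, end, kind, copy_change, freq) {
  freq <- as.data.frame(freq)
  ev <- data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
                   kind = kind, copy_change = as.integer(copy_change),
                   stringsAsFactors = FALSE)
  if (any(ev$end <= ev$start)) stop_invalid("event end must exceed start")
  if (!all(ev$kind %in% c("deletion", "duplication")))
    stop_invalid("event kind must be 'deletion' or 'duplication'")
  bad <- (ev$kind == "deletion" & !ev$copy_change %in% c(-1L, -2L)) |
         (ev$kind == "duplication" & !ev$copy_change %in% 1:3)
  if (any(bad)) stop_invalid("copy_change inconsistent with kind for event %d",
                             which(bad)[1])
  if (any(freq < 0 | freq > 1)) stop_invalid("allele frequencies must be in [0, 1]")
  names(freq) <- paste0("freq_", names(freq))
  out <- cbind(ev, freq)
  class(out) <- c("cnv_events", "data.frame")
  out
}

event_freq_cols <- function(events) {
  grep("^freq_", names(events), value = TRUE)
}

check_events_disjoint <- function(events) {
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop_invalid("events overlap on chromosome %s", ch)
  }
  invisible(TRUE)
}

#' Implant CNV events into a diploid cohort
#'
#' Each individual draws, per event, the number of carried alleles as
#' Binomial(2, population allele frequency); the per-window copy-number
#' track is 2 plus the sum of carried copy changes of events overlapping
#' the window.  A -2 deletion allele removes both copies, so the total
#' deletion delta is floored at -2 (copy number never drops below 0).
#'
#' @param ref a `cnv_reference`.
#' @param pop_sizes named integer vector, individuals per population.
#' @param events a `cnv_events` table (disjoint per chromosome).
#' @param seed integer seed.
#' @return object of class `cnv_truth`: list with `events`, `samples`
#'   (data.frame `sample`, `population`), `cn` (integer matrix windows x
#'   samples), `deltas` (integer matrix events x samples).
#' @export
implant_cnvs <- function(ref, pop_sizes, events, seed = 1L) {
  stopifnot(inherits(ref, "cnv_reference"))
  if (is.null(names(pop_sizes)) || any(pop_sizes < 1))
    stop_invalid("pop_sizes must be a named vector of positive counts")
  check_events_disjoint(events)
  lens <- setNames(ref$chromosomes$length, ref$chromosomes$chrom)
  if (any(!events$chrom %in% names(lens)) ||
      any(events$end > lens[events$chrom]) || any(events$start < 0))
    stop_invalid("event coordinates outside chromosome bounds")
  fq <- event_freq_cols(events)
  need <- paste0("freq_", names(pop_sizes))
  if (!all(need %in% fq))
    stop_invalid("events lack frequency columns for populations: %s",
                 paste(setdiff(need, fq), collapse = ", "))

  set.seed(seed)
  samples <- data.frame(
    sample = unlist(lapply(names(pop_sizes), function(p)
      sprintf("%s_%02d", p, seq_len(pop_sizes[[p]])))),
    population = rep(names(pop_sizes), pop_sizes),
    stringsAsFactors = FALSE
  )
  n_ind <- nrow(samples)
  n_ev <- nrow(events)
  deltas <- matrix(0L, nrow = n_ev, ncol = n_ind,
                   dimnames = list(NULL, samples$sample))
  for (e in seq_len(n_ev)) {
    p <- unlist(events[e, paste0("freq_", samples$population)])
    alleles <- rbinom(n_ind, 2L, p)
    d <- alleles * events$copy_change[e]
    if (events$kind[e] == "deletion") d <- pmax(d, -2L)
    deltas[e, ] <- as.integer(d)
  }
  cn <- matrix(2L, nrow = nrow(ref$windows), ncol = n_ind,
               dimnames = list(NULL, samples$sample))
  # dosage: like cn but with edge windows weighted by the event's overlap
  # fraction, the effective copy number seen by uniformly sampled reads
  dosage <- matrix(2, nrow = nrow(ref$windows), ncol = n_ind,
                   dimnames = list(NULL, samples$sample))
  if (n_ev > 0) {
    w <- ref$windows
    for (e in seq_len(n_ev)) {
      hit <- which(w$chrom == events$chrom[e] &
                   w$start < events$end[e] & w$end > events$start[e])
      if (length(hit) > 0) {
        d <- matrix(deltas[e, ], nrow = length(hit), ncol = n_ind, byrow = TRUE)
        cn[hit, ] <- cn[hit, ] + d
        frac <- (pmin(w$end[hit], events$end[e]) -
                 pmax(w$start[hit], events$start[e])) / (w$end[hit] - w$start[hit])
        dosage[hit, ] <- dosage[hit, ] + d * frac
      }
    }
    cn[cn < 0L] <- 0L
    dosage[dosage < 0] <- 0
  }
  structure(list(events = events, samples = samples, cn = cn,
                 dosage = dosage, deltas = deltas),
            class = "cnv_truth")
}

# multiplicative GC depth bias: unimodal quadratic penalty away from gc 0.5,
# measured in units of 0.2 GC so `amplitude` is the fractional depth loss
# 0.2 GC away from the optimum; clipped at 0.1
gc_bias_factor <- function(gc, amplitude, scale = 0.2) {
  pmax(0.1, 1 - amplitude * ((gc - 0.5) / scale)^2)
}

#' Simulate window read counts from a copy-number truth set
#'
#' Expected count per window is
#' `depth * (window_size + read_length) / read_length * (dosage / 2) * gc_bias`,
#' drawn from a negative binomial with the given dispersion (`size`
#' parameter; `Inf` gives the Poisson limit).  `dosage` is the truth
#' set's overlap-weighted effective copy number, so windows only partially
#' covered by an event show proportionally diluted depth, as uniformly
#' sampled reads would.  Counts for overlapping windows are drawn
#' independently.
#'
#' @param truth a `cnv_truth`.
#' @param ref the `cnv_reference` used to build `truth`.
#' @param mean_depth mean fold-coverage (default 12).
#' @param read_length read length in bp used to convert coverage to read
#'   counts (default 150).
#' @param gc_bias_amplitude fractional depth loss 0.2 GC away from 0.5
#'   (default 0.4); 0 disables GC bias.
#' @param dispersion negative-binomial size; `Inf` for Poisson.
#' @param seed integer seed.
#' @return object of class `window_depth`: list with `windows`, `counts`
#'   (matrix windows x samples), `samples`, `mask` (all `FALSE`).
#' @export
simulate_depth <- function(truth, ref, mean_depth = 12, read_length = 150L,
                           gc_bias_amplitude = 0.4, dispersion = 150,
                           seed = 1L) {
  stopifnot(inherits(truth, "cnv_truth"), inherits(ref, "cnv_reference"))
  if (mean_depth <= 0) stop_invalid("mean_depth must be positive")
  if (dispersion <= 0) stop_invalid("dispersion must be positive")
  set.seed(seed)
  mu_base <- mean_depth * (ref$window_size + read_length) / read_length
  gcfac <- gc_bias_factor(ref$windows$gc, gc_bias_amplitude)
  dos <- truth$dosage %||% truth$cn
  mapp <- ref$windows$mappability %||% 1
  mu <- (dos / 2) * mu_base * gcfac * mapp
  n <- length(mu)
  counts <- if (is.infinite(dispersion)) rpois(n, mu)
            else rnbinom(n, mu = mu, size = dispersion)
  counts <- matrix(counts, nrow = nrow(truth$cn), ncol = ncol(truth$cn),
                   dimnames = dimnames(truth$cn))
  new_window_depth(ref$windows, counts)
}

#' Construct a window depth matrix
#'
#' @param windows data.frame with `chrom`, `start`, `end`, `gc`.
#' @param counts non-negative matrix, windows x samples, with sample
#'   column names.
#' @param mask optional logical vector of excluded windows.
#' @return object of class `window_depth`.
#' @export
window_depth <- function(windows, counts, mask = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  if (any(windows$end <= windows$start)) stop_invalid("window end must exceed start")
  if (any(windows$gc < 0 | windows$gc > 1)) stop_invalid("gc must be in [0, 1]")
  new_window_depth(windows, counts, mask)
}

new_window_depth <- function(windows, counts, mask = NULL) {
  stopifnot(nrow(windows) == nrow(counts))
  structure(list(
    windows = windows,
    counts = counts,
    samples = colnames(counts),
    mask = mask %||% rep(FALSE, nrow(windows))
  ), class = "window_depth")
}

#' Randomly place disjoint CNV events along a reference
#'
#' Events are placed uniformly with a minimum separation so that distinct
#' events never merge into one region downstream.
#'
#' @param ref a `cnv_reference`.
#' @param n_events number of events.
#' @param length_range event length range in bp.
#' @param kinds vector to sample event kinds from.
#' @param freq_by_pop function(kind) returning a named vector of allele
#'   frequencies per population, or a fixed named vector.
#' @param min_gap minimum separation between events in bp (default 10 kb).
#' @param seed integer seed.
#' @return a `cnv_events` table.
#' @export
place_events <- function(ref, n_events, length_range = c(2e3, 5e4),
                         kinds = c("deletion", "duplication"),
                         freq_by_pop, min_gap = 1e4, seed = 1L) {
  set.seed(seed)
  ch <- ref$chromosomes
  if (n_events == 0) {
    pops <- names(if (is.function(freq_by_pop)) freq_by_pop(kinds[1]) else freq_by_pop)
    fr <- as.data.frame(matrix(numeric(0), 0, length(pops),
                               dimnames = list(NULL, pops)))
    return(cnv_events(character(0), integer(0), integer(0), character(0),
                      integer(0), fr))
  }
  lens <- round(runif(n_events, length_range[1], length_range[2]))
  # greedy placement on a random chromosome, retry until disjoint
  placed <- list()
  occupied <- lapply(seq_len(nrow(ch)), function(i) cbind(numeric(0), numeric(0)))
  for (i in seq_len(n_events)) {
    for (try in seq_len(1000L)) {
      ci <- sample.int(nrow(ch), 1L)
      s <- floor(runif(1, ref$window_size, ch$length[ci] - lens[i] - ref$window_size))
      e <- s + lens[i]
      occ <- occupied[[ci]]
      if (nrow(occ) == 0 || all(e + min_gap <= occ[, 1] | s - min_gap >= occ[, 2])) {
        occupied[[ci]] <- rbind(occ, c(s, e))
        placed[[i]] <- data.frame(chrom = ch$chrom[ci], start = s, end = e)
        break
      }
      if (try == 1000L) stop_invalid("could not place %d disjoint events", n_events)
    }
  }
  ev <- do.call(rbind, placed)
  kind <- sample(kinds, n_events, replace = TRUE)
  copy_change <- ifelse(kind == "deletion", -1L, 1L)
  fr <- if (is.function(freq_by_pop)) do.call(rbind, lapply(kind, freq_by_pop))
        else matrix(rep(freq_by_pop, each = n_events), nrow = n_events,
                    dimnames = list(NULL, names(freq_by_pop)))
  cnv_events(ev$chrom, ev$start, ev$end, kind, copy_change, fr)
}

#' Simulate a complete multi-population cohort
#'
#' Convenience wrapper: reference + implanted events + depth matrix.  The
#' defaults mirror the validation scale used throughout the package: two
#' populations of 20 individuals, one 10-Mb chromosome, 800-bp windows at
#' 400-bp step, 12-fold coverage.
#'
#' @param pop_sizes named integer vector of population sizes.
#' @param n_chrom,chrom_length,window_size,step reference geometry.
#' @param events a `cnv_events` table, or `NULL` to place `n_events`
#'   randomly with allele frequencies sampled from `freq_levels`.
#' @param n_events,length_range,freq_levels random event placement controls.
#' @param mean_depth,gc_bias_amplitude,dispersion depth model parameters.
#' @param repeat_frac,dropout_frac fractions of collapsed-repeat and
#'   near-unmappable windows (defaults 0.4% each, within the default
#'   masking budget of 0.5% per tail; see [simulate_reference()]).
#' @param seed integer seed controlling all stages.
#' @return list with `ref`, `truth`, `depth`.
#' @export
simulate_cohort <- function(pop_sizes = c(A = 20L, B = 20L), n_chrom = 1L,
                            chrom_length = 1e7, window_size = 800L,
                            step = 400L, events = NULL, n_events = 50L,
                            length_range = c(2e3, 5e4),
                            freq_levels = c(0.2, 0.3, 0.4, 0.5, 0.6),
                            mean_depth = 12, gc_bias_amplitude = 0.4,
                            dispersion = 150, repeat_frac = 0.004,
                            dropout_frac = 0.004, seed = 1L) {
  ref <- simulate_reference(n_chrom, chrom_length, window_size, step,
                            repeat_frac = repeat_frac,
                            dropout_frac = dropout_frac, seed = seed)
  if (is.null(events)) {
    pops <- names(pop_sizes)
    freq_fun <- function(kind) {
      f <- sample(freq_levels, 1L)
      setNames(rep(f, length(pops)), pops)
    }
    events <- place_events(ref, n_events, length_range,
                           freq_by_pop = freq_fun, seed = seed + 1L)
  }
  truth <- implant_cnvs(ref, pop_sizes, events, seed = seed + 2L)
  depth <- simulate_depth(truth, ref, mean_depth = mean_depth,
                          gc_bias_amplitude = gc_bias_amplitude,
                          dispersion = dispersion, seed = seed + 3L)
  list(ref = ref, truth = truth, depth = depth)
}

#' Simulate a CNVR-level dosage cohort
#'
#' Generates per-CNVR mean copy numbers directly (skipping the window
#' stage) for differentiation studies: each individual's dosage at a CNVR
#' is `2 + alleles * copy_change` with alleles ~ Binomial(2, population
#' frequency), plus Gaussian measurement noise emulating the residual
#' depth noise after averaging over a region's windows.
#'
#' @param pop_sizes named integer vector of population sizes.
#' @param freq matrix n_cnvr x n_pop of allele frequencies (columns named
#'   by population).
#' @param kind character vector of CNVR kinds (recycled).
#' @param noise_sd Gaussian noise on the dosage scale (default 0.1).
#' @param region_span bp spanned per simulated CNVR used for coordinates.
#' @param seed integer seed.
#' @return list with `cnvrs` (a `cnvr_set`) and `popmap` (data.frame
#'   `sample`, `population`).
#' @export
simulate_cnvr_matrix <- function(pop_sizes, freq, kind = "deletion",
                                 noise_sd = 0.1, region_span = 5e3,
                                 seed = 1L) {
  set.seed(seed)
  freq <- as.matrix(freq)
  if (is.null(colnames(freq)) || !all(names(pop_sizes) %in% colnames(freq)))
    stop_invalid("freq must have one named column per population")
  n_cnvr <- nrow(freq)
  kind <- rep_len(kind, n_cnvr)
  popmap <- data.frame(
    sample = unlist(lapply(names(pop_sizes), function(p)
      sprintf("%s_%02d", p, seq_len(pop_sizes[[p]])))),
    population = rep(names(pop_sizes), pop_sizes),
    stringsAsFactors = FALSE
  )
  n_ind <- nrow(popmap)
  change <- ifelse(kind == "duplication", 1L, -1L)
  cn <- matrix(0, n_cnvr, n_ind, dimnames = list(NULL, popmap$sample))
  for (j in seq_len(n_cnvr)) {
    p <- freq[j, popmap$population]
    alleles <- rbinom(n_ind, 2L, p)
    cn[j, ] <- pmax(0, 2 + alleles * change[j] + rnorm(n_ind, 0, noise_sd))
  }
  regions <- data.frame(
    chrom = "chr1",
    start = as.integer((seq_len(n_cnvr) - 1L) * 2L * region_span),
    end = as.integer((seq_len(n_cnvr) - 1L) * 2L * region_span + region_span),
    kind = kind,
    n_windows = as.integer(round(region_span / 400)),
    silhouette = 1,
    stringsAsFactors = FALSE
  )
  gt <- matrix("normal", n_cnvr, n_ind, dimnames = dimnames(cn))
  list(cnvrs = cnvr_set(regions, cn, gt), popmap = popmap)
}
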