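#' Specify a class-discriminating marker compound
#'
#' A marker elutes as a Gaussian peak in time and fragments into a
#' stick spectrum at integer masses. Its abundance differs between
#' classes by the multiplicative `class_effect` (class 1 / class 0):
#' values > 1 model a compound generated by the treatment, values < 1 a
#' compound removed by it.
#'
#' @param rt Retention time of the peak apex (minutes).
#' @param fragments Data frame with columns `mz` (integer amu) and
#'   `rel` (relative abundances, normalized so the base peak is 1).
#' @param class_effect Abundance ratio class 1 / class 0 (> 0).
#' @param base_height Apex intensity of the base peak in class 0
#'   (arbitrary counts).
#' @param rt_sigma Gaussian peak width (SD, minutes).
#' @param name Optional compound name.
#' @return A list of class `marker_spec`.
#' @export
marker_spec <- function(rt, fragments, class_effect, base_height,
                        rt_sigma = 0.05, name = NULL) {
  stopifnot(is.data.frame(fragments), all(c("mz", "rel") %in% names(fragments)))
  if (any(fragments$rel <= 0)) stop("fragment abundances must be > 0")
  if (rt_sigma <= 0) stop("'rt_sigma' must be > 0")
  if (class_effect < 0) stop("'class_effect' must be >= 0")
  fragments$rel <- fragments$rel / max(fragments$rel)
  structure(list(rt = rt, fragments = fragments,
                 class_effect = class_effect, base_height = base_height,
                 rt_sigma = rt_sigma, name = name),
            class = "marker_spec")
}

#' The cork-taint preset: three treatment markers
#'
#' Three markers mirroring the volatile signature of washed cork: a
#' furfural-like compound (ions 51/67/95/96/97) at 7.17 min and a
#' 5-methylfurfural-like compound (ions 109/110) at 10.50 min, both
#' strongly generated by the treatment, and an unidentified compound
#' (ions 51/78) at 8.83 min removed by it. Apexes sit at time-bin
#' centers of the default grid so each marker occupies a single time
#' interval. Class effects model compounds essentially absent on one
#' side of the treatment (100x generated, 0.01x removed), and base
#' heights are sized so that every fragment node of a marker clears the
#' top-1% codification cutoff in its enriched class while the depleted
#' class stays below it, across the dataset-to-dataset variation of the
#' cutoff induced by the random background library — the construction
#' that makes these markers "strong effect": their nodes binarize high
#' in the enriched class and low in the other.
#'
#' @return List of three [marker_spec] objects.
#' @export
cork_markers <- function() {
  list(
    marker_spec(7.17,
                data.frame(mz = c(95, 96, 97, 67, 51),
                           rel = c(1, 0.6, 0.35, 0.3, 0.45)),
                class_effect = 100, base_height = 3e4,
                name = "furfural-like"),
    marker_spec(10.50,
                data.frame(mz = c(109, 110), rel = c(1, 0.95)),
                class_effect = 100, base_height = 4e4,
                name = "5-methylfurfural-like"),
    marker_spec(8.83,
                data.frame(mz = c(78, 51), rel = c(1, 0.5)),
                class_effect = 0.01, base_height = 3e6,
                name = "removed-compound"))
}

#' Simulation configuration
#'
#' @param n_per_class Samples per class.
#' @param markers List of [marker_spec] objects.
#' @param n_background Number of class-independent background compounds
#'   (random retention times and fragment sets, drawn once per dataset).
#' @param scan_start,scan_end Acquisition window (minutes).
#' @param scan_interval Time between scans (minutes).
#' @param mz_jitter_sd Gaussian jitter of fragment m/z per register (amu).
#' @param intensity_noise_cv Coefficient of variation of the lognormal
#'   per-compound, per-sample abundance noise.
#' @param global_scale_range Range of the per-sample global intensity
#'   multiplier (absorbed by normalization downstream).
#' @param baseline_rate Mean number of baseline noise peaks per scan.
#' @param baseline_mean Mean intensity of a baseline noise peak.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 10, markers = cork_markers(),
                       n_background = 24, scan_start = 6, scan_end = 17,
                       scan_interval = 0.04, mz_jitter_sd = 0.05,
                       intensity_noise_cv = 0.2,
                       global_scale_range = c(0.5, 2),
                       baseline_rate = 12, baseline_mean = 30, seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  stopifnot(n_per_class >= 1, n_background >= 0, scan_interval > 0,
            scan_end > scan_start, mz_jitter_sd >= 0,
            intensity_noise_cv >= 0, length(global_scale_range) == 2L,
            all(global_scale_range > 0), baseline_rate >= 0,
            baseline_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

# run body with a private, restorable RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a two-class synthetic GC-MS dataset with ground truth
#'
#' Each sample is the superposition of the dataset's background
#' compounds (class-independent), the marker compounds (scaled by
#' `class_effect` for class-1 samples), per-compound lognormal abundance
#' noise, a per-sample global scale factor, per-register m/z jitter and
#' sparse centroided baseline noise. Elution is Gaussian in time,
#' sampled at the scan interval (truncated at 4 SD); fragments are
#' sticks at integer amu, so half-integer mass bins of a 0.5-amu grid
#' receive no compound signal.
#'
#' @param config A [sim_config()].
#' @return An object of class `ssir_sim`: list with `runs` (labelled
#'   [sample_run]s, class 0 first), `manifest` (ground truth: one row
#'   per marker fragment with `marker`, `rt`, `mz`, `direction`, the
#'   class enriched for the node) and `config`.
#' @export
simulate_chromatograms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (mk in config$markers) {
    if (mk$rt < config$scan_start || mk$rt >= config$scan_end)
      stop("marker at ", mk$rt, " min lies outside the scan window [",
           config$scan_start, ", ", config$scan_end, ")")
  }
  .with_seed(config$seed, {
    scans <- seq(config$scan_start, config$scan_end - 1e-9,
                 by = config$scan_interval)
    # dataset-level background library
    bg <- lapply(seq_len(config$n_background), function(i) {
      nf <- sample(3:7, 1L)
      rel <- stats::runif(nf, 0.3, 1)
      marker_spec(rt = stats::runif(1, config$scan_start + 0.3,
                                    config$scan_end - 0.3),
                  fragments = data.frame(mz = sample(49:170, nf),
                                         rel = rel / max(rel)),
                  class_effect = 1,
                  base_height = 10^stats::runif(1, 4, 7),
                  name = sprintf("background%02d", i))
    })
    compounds <- c(bg, config$markers)
    sdlog <- sqrt(log(1 + config$intensity_noise_cv^2))
    n <- config$n_per_class
    labels <- rep(c(0L, 1L), each = n)
    ids <- sprintf("s%02d", seq_len(2L * n))
    runs <- vector("list", 2L * n)
    for (si in seq_len(2L * n)) {
      g <- stats::runif(1, config$global_scale_range[1L],
                        config$global_scale_range[2L])
      parts <- vector("list", length(compounds) + 1L)
      for (ci in seq_along(compounds)) {
        cp <- compounds[[ci]]
        eff <- if (labels[si] == 1L) cp$class_effect else 1
        if (eff == 0) next
        noise <- if (sdlog > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        keep <- abs(scans - cp$rt) <= 4 * cp$rt_sigma
        if (!any(keep)) next
        t_s <- scans[keep]
        amp <- cp$base_height * eff * noise * g *
          exp(-(t_s - cp$rt)^2 / (2 * cp$rt_sigma^2))
        nf <- nrow(cp$fragments)
        tt <- rep(t_s, each = nf)
        mz <- rep(cp$fragments$mz, times = length(t_s)) +
          if (config$mz_jitter_sd > 0)
            stats::rnorm(nf * length(t_s), 0, config$mz_jitter_sd) else 0
        it <- rep(amp, each = nf) * rep(cp$fragments$rel, times = length(t_s))
        parts[[ci]] <- data.frame(time = tt, mz = mz, intensity = it)
      }
      if (config$baseline_rate > 0) {
        npk <- stats::rpois(length(scans), config$baseline_rate)
        tot <- sum(npk)
        if (tot > 0)
          parts[[length(compounds) + 1L]] <- data.frame(
            time = rep(scans, times = npk),
            mz = stats::runif(tot, 48.8, 170.2),
            intensity = stats::rexp(tot, rate = 1 / config$baseline_mean) * g)
      }
      rec <- do.call(rbind, parts)
      rec <- rec[rec$mz > 0 & rec$intensity > 0, , drop = FALSE]
      rec <- rec[order(rec$time, rec$mz), , drop = FALSE]
      runs[[si]] <- sample_run(ids[si], rec$time, rec$mz, rec$intensity,
                               label = labels[si])
    }
    manifest <- do.call(rbind, lapply(config$markers, function(mk)
      data.frame(marker = if (is.null(mk$name)) "" else mk$name,
                 rt = mk$rt, mz = mk$fragments$mz,
                 direction = if (mk$class_effect > 1) 1L else 0L)))
    structure(list(runs = runs, manifest = manifest, config = config),
              class = "ssir_sim")
  })
}

#' @export
print.ssir_sim <- function(x, ...) {
  cat(sprintf(paste0("<ssir_sim> %d samples (%d per class), %d marker ",
                     "node(s) in manifest, seed %d\n"),
              length(x$runs), x$config$n_per_class, nrow(x$manifest),
              x$config$seed))
  invisible(x)
}

#' Grid node indices of the ground-truth manifest
#'
#' @param sim An `ssir_sim` (or its manifest data frame).
#' @param grid A `grid_spec`.
#' @return The manifest with `node_index` added (the node containing
#'   each marker fragment apex).
#' @export
manifest_nodes <- function(sim, grid) {
  man <- if (inherits(sim, "ssir_sim")) sim$manifest else sim
  man$node_index <- .assign_nodes(man$rt, man$mz, grid)
  man
}

#' Write a simulated dataset to disk
#'
#' One scan file per sample (long table or mzML), plus `labels.csv` and
#' the ground-truth `manifest.csv`.
#'
#' @param sim An `ssir_sim`.
#' @param dir Output directory (created if needed).
#' @param format `"long_table"` or `"mzml"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_dataset <- function(sim, dir, format = c("long_table", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "ssir_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "mzml") ".mzML" else ".csv"
  files <- character(0)
  for (run in sim$runs) {
    f <- file.path(dir, paste0(run$sample_id, ext))
    if (format == "mzml") write_mzml(run, f) else write_long_table(run, f)
    files <- c(files, f)
  }
  lf <- file.path(dir, "labels.csv")
  utils::write.table(
    data.frame(sample_id = vapply(sim$runs, function(r) r$sample_id, ""),
               label = vapply(sim$runs, function(r) r$label, 0L)),
    lf, sep = ",", row.names = FALSE, quote = FALSE)
  mf <- file.path(dir, "manifest.csv")
  utils::write.table(sim$manifest, mf, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(files, lf, mf))
}
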