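#' Define a rectangular retention-time by ion-mass grid
#'
#' The grid tiles the retention-time window `[time_start, time_end)` into
#' half-open intervals of width `time_step`, and covers an arithmetic
#' sequence of mass centers `mass_center_min, mass_center_min +
#' mass_step, ..., mass_center_max`, each with a half-open mass window
#' `[center - mass_radius, center + mass_radius)`. With the default
#' radius of half a step the mass windows tile their range without
#' overlap. A node is one (time interval, mass window) combination; node
#' indices run mass-fastest within each time interval.
#'
#' @param time_start,time_end Window in minutes (`time_end > time_start`).
#' @param time_step Time interval width in minutes (> 0).
#' @param mass_center_min,mass_center_max First and last mass center (amu).
#' @param mass_step Spacing of mass centers in amu (> 0).
#' @param mass_radius Half-width of each mass window; default `mass_step/2`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- build_grid(6, 17, 1/3, 49, 170, 0.5)
#' g$n_nodes  # 33 * 243 = 8019
#' @export
build_grid <- function(time_start, time_end, time_step,
                       mass_center_min, mass_center_max, mass_step,
                       mass_radius = mass_step / 2) {
  if (!is.finite(time_step) || time_step <= 0) stop("'time_step' must be > 0")
  if (!is.finite(mass_step) || mass_step <= 0) stop("'mass_step' must be > 0")
  if (time_end <= time_start) stop("'time_end' must exceed 'time_start'")
  if (mass_center_max < mass_center_min)
    stop("'mass_center_max' must be >= 'mass_center_min'")
  if (mass_radius <= 0 || mass_radius > mass_step)
    stop("'mass_radius' must lie in (0, mass_step]")
  n_time <- as.integer(round((time_end - time_start) / time_step))
  if (n_time < 1L) stop("window shorter than one time step")
  n_mass <- as.integer(round((mass_center_max - mass_center_min) / mass_step)) + 1L
  structure(
    list(time_start = time_start, time_end = time_end, time_step = time_step,
         mass_center_min = mass_center_min, mass_center_max = mass_center_max,
         mass_step = mass_step, mass_radius = mass_radius,
         n_time = n_time, n_mass = n_mass, n_nodes = n_time * n_mass),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(paste0("<grid_spec> time [%g, %g) min in %d steps of %.4g min; ",
                     "mass centers %g..%g amu step %g (radius %g): ",
                     "%d x %d = %d nodes\n"),
              x$time_start, x$time_end, x$n_time, x$time_step,
              x$mass_center_min, x$mass_center_max, x$mass_step,
              x$mass_radius, x$n_time, x$n_mass, x$n_nodes))
  invisible(x)
}

#' Mass centers of a grid
#' @param grid A `grid_spec`.
#' @return Numeric vector of the `n_mass` mass centers.
#' @export
mass_centers <- function(grid) {
  grid$mass_center_min + grid$mass_step * (seq_len(grid$n_mass) - 1L)
}

#' Time interval edges of a grid
#' @param grid A `grid_spec`.
#' @return Numeric vector of `n_time + 1` interval edges in minutes.
#' @export
time_edges <- function(grid) {
  grid$time_start + grid$time_step * (0:grid$n_time)
}

# Assign each register to a node index (NA = outside the grid window).
# Time bins are half-open [t0, t1); mass windows are half-open
# [c - r, c + r) around the nearest center, so a register exactly on a
# shared boundary belongs to the interval whose left edge it is.
.assign_nodes <- function(time, mz, grid) {
  tb <- floor((time - grid$time_start) / grid$time_step) + 1
  mb <- floor((mz - grid$mass_center_min) / grid$mass_step + 0.5) + 1
  ok <- tb >= 1 & tb <= grid$n_time & mb >= 1 & mb <= grid$n_mass
  if (grid$mass_radius < grid$mass_step / 2) {
    centers <- grid$mass_center_min + (mb - 1) * grid$mass_step
    d <- mz - centers
    ok <- ok & d >= -grid$mass_radius & d < grid$mass_radius
  }
  idx <- (tb - 1) * grid$n_mass + mb
  idx[!ok] <- NA_integer_
  as.integer(idx)
}

#' Human-readable node labels
#'
#' Labels have the form `t[6.000,6.333)_m95.0`.
#'
#' @param grid A `grid_spec`.
#' @param nodes Node indices; default all nodes.
#' @return Character vector of labels.
#' @export
node_labels <- function(grid, nodes = seq_len(grid$n_nodes)) {
  info <- node_info(grid, nodes)
  sprintf("t[%.3f,%.3f)_m%.1f", info$time_lo, info$time_hi, info$mass_center)
}

#' Decode node indices into time intervals and mass centers
#'
#' @param grid A `grid_spec`.
#' @param nodes Node indices.
#' @return Data frame with columns `node_index`, `time_lo`, `time_hi`,
#'   `mass_center`.
#' @export
node_info <- function(grid, nodes) {
  nodes <- as.integer(nodes)
  stopifnot(all(nodes >= 1L & nodes <= grid$n_nodes))
  tb <- (nodes - 1L) %/% grid$n_mass
  mb <- (nodes - 1L) %% grid$n_mass
  data.frame(node_index = nodes,
             time_lo = grid$time_start + tb * grid$time_step,
             time_hi = grid$time_start + (tb + 1L) * grid$time_step,
             mass_center = grid$mass_center_min + mb * grid$mass_step)
}

#' Normalize a sample's in-window registers to a target mean intensity
#'
#' Every register inside the grid's time and mass coverage is rescaled by
#' a single factor so that the mean of in-window intensities equals
#' `target_mean`. Out-of-window registers are scaled by the same factor
#' but play no role in determining it: the scale is a statement about the
#' signal that will be accumulated, so signal outside the analysis window
#' (e.g. an internal standard eluting later) cannot leak into it.
#'
#' @param run A [sample_run].
#' @param grid A `grid_spec`.
#' @param target_mean Target mean intensity (default 1000).
#' @return List with elements `run` (the rescaled [sample_run]) and
#'   `norm_factor` (the multiplier applied).
#' @export
normalize_sample <- function(run, grid, target_mean = 1000) {
  stopifnot(inherits(run, "sample_run"), inherits(grid, "grid_spec"))
  if (!is.finite(target_mean) || target_mean <= 0)
    stop("'target_mean' must be > 0")
  idx <- .assign_nodes(run$records$time, run$records$mz, grid)
  inw <- !is.na(idx)
  if (!any(inw))
    stop("sample '", run$sample_id, "' has no registers inside the grid window")
  m <- mean(run$records$intensity[inw])
  if (m == 0)
    stop("sample '", run$sample_id,
         "' has all-zero in-window intensities; scale undefined")
  f <- target_mean / m
  run$records$intensity <- run$records$intensity * f
  list(run = run, norm_factor = f)
}

#' Accumulate a sample's registers into grid nodes
#'
#' Each in-window register is added to exactly one node (half-open time
#' and mass intervals). Out-of-window registers are dropped and counted.
#'
#' @param run A (normalized) [sample_run].
#' @param grid A `grid_spec`.
#' @return List with `values` (numeric vector of length `n_nodes`, node
#'   sums ordered by node index) and `dropped` (count of out-of-window
#'   registers).
#' @export
accumulate <- function(run, grid) {
  stopifnot(inherits(run, "sample_run"), inherits(grid, "grid_spec"))
  idx <- .assign_nodes(run$records$time, run$records$mz, grid)
  inw <- !is.na(idx)
  v <- numeric(grid$n_nodes)
  if (any(inw)) {
    s <- rowsum(run$records$intensity[inw], idx[inw])
    v[as.integer(rownames(s))] <- s[, 1L]
  }
  list(values = v, dropped = sum(!inw))
}

#' Build the samples-by-nodes intensity matrix
#'
#' Normalizes each run to `target_mean` over the grid window and
#' accumulates it into node sums; one row per sample.
#'
#' @param runs List of [sample_run] objects with unique ids.
#' @param grid A `grid_spec`.
#' @param target_mean Normalization target (default 1000).
#' @return An object of class `node_matrix`: list with `values`
#'   (samples x nodes matrix), `grid`, `sample_ids`, `labels`,
#'   `norm_factors`, `dropped`.
#' @export
node_matrix <- function(runs, grid, target_mean = 1000) {
  if (inherits(runs, "sample_run")) runs <- list(runs)
  ids <- vapply(runs, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample_id in dataset: ",
                               ids[duplicated(ids)][1L])
  vals <- matrix(0, nrow = length(runs), ncol = grid$n_nodes,
                 dimnames = list(ids, NULL))
  nf <- numeric(length(runs)); dr <- integer(length(runs))
  for (i in seq_along(runs)) {
    nm <- normalize_sample(runs[[i]], grid, target_mean)
    acc <- accumulate(nm$run, grid)
    vals[i, ] <- acc$values
    nf[i] <- nm$norm_factor
    dr[i] <- acc$dropped
  }
  structure(
    list(values = vals, grid = grid, sample_ids = ids,
         labels = vapply(runs, function(r)
           if (is.null(r$label)) NA_integer_ else as.integer(r$label), 0L),
         norm_factors = stats::setNames(nf, ids),
         dropped = stats::setNames(dr, ids)),
    class = "node_matrix")
}

#' @export
print.node_matrix <- function(x, ...) {
  cat(sprintf("<node_matrix> %d samples x %d nodes; %d non-empty nodes\n",
              nrow(x$values), ncol(x$values), sum(colSums(x$values) > 0)))
  invisible(x)
}

#' Persist a node matrix as delimited text
#'
#' Writes the samples-by-nodes matrix with node labels as header and a
#' side-car file (`<path>.sidecar`) holding per-sample normalization
#' factors and dropped-register counts.
#'
#' @param nm A `node_matrix`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_node_matrix <- function(nm, path, sep = "\t") {
  df <- as.data.frame(nm$values)
  names(df) <- node_labels(nm$grid)
  df <- cbind(sample_id = nm$sample_ids, df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  side <- data.frame(sample_id = nm$sample_ids,
                     norm_factor = nm$norm_factors,
                     dropped = nm$dropped)
  utils::write.table(side, paste0(path, ".sidecar"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
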