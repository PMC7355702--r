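#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline. Defaults are the
#' standard analysis settings: a 6-17 min window in 20-s (1/3 min)
#' steps, mass centers 49-170 amu in 0.5 amu steps (radius 0.25 amu,
#' 8019 nodes), per-sample normalization to mean intensity 1000, top 1%
#' high levels, order-1 rules at significance threshold 0.0005,
#' autoscaled PCA and a one-component discriminant.
#'
#' @param time_start,time_end,time_step Retention-time window and step
#'   (minutes).
#' @param mass_center_min,mass_center_max,mass_step Mass-center range
#'   and step (amu).
#' @param mass_radius Mass window half-width (amu).
#' @param target_mean Per-sample normalization target.
#' @param top_fraction Fraction of nodes codified high.
#' @param percentile_scope `"per_sample"` or `"pooled"`.
#' @param max_order Highest rule order (1-3).
#' @param p_threshold Rule significance threshold.
#' @param scaling_mode PCA scaling: `"autoscale"` or `"center"`.
#' @param n_components Discriminant components (1-5).
#' @return A list of class `ssir_config`.
#' @export
ssir_config <- function(time_start = 6, time_end = 17, time_step = 1/3,
                        mass_center_min = 49, mass_center_max = 170,
                        mass_step = 0.5, mass_radius = mass_step / 2,
                        target_mean = 1000, top_fraction = 0.01,
                        percentile_scope = c("per_sample", "pooled"),
                        max_order = 1, p_threshold = 5e-4,
                        scaling_mode = c("autoscale", "center"),
                        n_components = 1) {
  percentile_scope <- match.arg(percentile_scope)
  scaling_mode <- match.arg(scaling_mode)
  if (!max_order %in% 1:3) stop("'max_order' must be 1, 2 or 3")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("'p_threshold' must lie in (0, 1]")
  if (n_components < 1 || n_components > 5)
    stop("'n_components' must lie in 1..5")
  structure(as.list(environment()), class = "ssir_config")
}

#' @export
print.ssir_config <- function(x, ...) {
  cat("<ssir_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm,
                                   paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Unknown keys are an error. Values are passed to
#' [ssir_config()].
#'
#' @param path Path to the file.
#' @return An `ssir_config`.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "[=:]", fixed = FALSE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = ""))
    key <- trimws(p[1L]); val <- trimws(p[2L])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  bad <- setdiff(names(args), names(formals(ssir_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(ssir_config, args)
}

#' Fit the full SSIR classification pipeline
#'
#' Runs the complete analysis on labelled scan data: build the
#' time-by-mass grid, normalize and accumulate each sample into node
#' sums, dichotomize into low/high levels, drop constant nodes, group
#' degenerate nodes under representatives, enumerate and score
#' conjunction rules against the hypergeometric enrichment null, select
#' significant variables, then fit a PCA on the selected variables'
#' pre-dichotomization intensity sums and a Fisher linear discriminant
#' on the leading components. Deterministic given data and
#' configuration.
#'
#' @param runs List of labelled [sample_run] objects (>= 2 per class),
#'   or an `ssir_sim` dataset.
#' @param config An [ssir_config()].
#' @param labels Optional named 0/1 vector overriding run labels.
#' @return An object of class `ssir`: list with `grid`, `node_matrix`,
#'   `code` (representatives), `split`, `rules`, `selection`, `x`
#'   (samples x selected variables intensity sums), `pca`, `scores`,
#'   `lda`, `fitted` (training predictions), `metrics`, `counts`
#'   (per-stage node counts) and `config`. Errors with "no significant
#'   variables" if nothing passes the threshold.
#' @seealso [loo_validate()], [predict.ssir()]
#' @export
ssir <- function(runs, config = ssir_config(), labels = NULL) {
  if (inherits(runs, "ssir_sim")) runs <- runs$runs
  if (!is.null(labels)) runs <- apply_labels(runs, labels)
  labs <- unname(vapply(runs, function(r) as.integer(r$label), 0L))
  if (anyNA(labs)) stop("every sample needs a 0/1 label")
  if (sum(labs == 0L) < 2L || sum(labs == 1L) < 2L)
    stop("need at least 2 samples per class")
  grid <- build_grid(config$time_start, config$time_end, config$time_step,
                     config$mass_center_min, config$mass_center_max,
                     config$mass_step, config$mass_radius)
  nm <- node_matrix(runs, grid, config$target_mean)
  code <- dichotomize(nm, config$top_fraction, config$percentile_scope)
  code <- drop_constant(code)
  n_varying <- ncol(code$levels)
  code <- group_degenerate(code)
  split <- class_split(labs)
  rules <- enumerate_rules(code, split, config$max_order)
  sel <- select_variables(rules, config$p_threshold, code$degeneracy, grid)
  if (nrow(sel$variables) == 0L)
    stop("no significant variables at threshold ", config$p_threshold)
  x <- nm$values[, sel$variables$node_index, drop = FALSE]
  colnames(x) <- node_labels(grid, sel$variables$node_index)
  pca <- pca_fit(x, config$scaling_mode)
  scores <- pca_transform(pca, x)
  k <- min(config$n_components, ncol(scores))
  lda <- discriminant_fit(scores, labs, k)
  fitted <- predict(lda, scores)
  structure(
    list(grid = grid, node_matrix = nm, code = code, split = split,
         rules = rules, selection = sel, x = x, pca = pca, scores = scores,
         lda = lda, fitted = stats::setNames(fitted, nm$sample_ids),
         metrics = evaluate_metrics(fitted, labs),
         counts = c(nodes = grid$n_nodes, varying = n_varying,
                    representatives = ncol(code$levels),
                    selected_representatives = nrow(sel$representatives),
                    expanded_variables = nrow(sel$variables)),
         config = config),
    class = "ssir")
}

#' @export
print.ssir <- function(x, ...) {
  cat("SSIR pipeline fit\n")
  cat(sprintf("  samples:        %d (%d treated / %d non-treated)\n",
              x$split$N, x$split$K, x$split$N - x$split$K))
  cat(sprintf("  nodes:          %d -> %d varying -> %d representatives\n",
              x$counts["nodes"], x$counts["varying"],
              x$counts["representatives"]))
  cat(sprintf("  selected:       %d representatives, %d variables (p <= %g)\n",
              x$counts["selected_representatives"],
              x$counts["expanded_variables"], x$config$p_threshold))
  ef <- 100 * x$pca$explained_fraction
  cat(sprintf("  PCA:            PC1 %.1f%%, PC2 %s of variance\n", ef[1L],
              if (length(ef) > 1L) sprintf("%.1f%%", ef[2L]) else "-"))
  cat(sprintf("  training:       sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$metrics$sensitivity, 100 * x$metrics$specificity))
  invisible(x)
}

#' @export
summary.ssir <- function(object, ...) {
  print(object)
  cat("\nSelected variables (ranked by p-value):\n")
  print(object$selection$variables)
  invisible(object)
}

#' @export
coef.ssir <- function(object, ...) {
  v <- object$selection$variables
  v$loading_pc1 <- object$pca$loadings[, 1L]
  if (ncol(object$pca$loadings) > 1L)
    v$loading_pc2 <- object$pca$loadings[, 2L]
  v
}

#' Classify new samples with a fitted pipeline
#'
#' Each new sample is normalized with its own in-window mean,
#' accumulated on the fitted grid, reduced to the selected variables'
#' intensity sums, projected onto the fitted components and classified
#' by the fitted discriminant. Nothing is re-estimated, so held-out
#' samples never influence the model.
#'
#' @param object A fitted `ssir`.
#' @param newdata A [sample_run] or list of them.
#' @param ... Unused.
#' @return Named integer vector of predicted labels (1 = treated).
#' @export
predict.ssir <- function(object, newdata, ...) {
  if (inherits(newdata, "sample_run")) newdata <- list(newdata)
  s <- vapply(newdata, function(run) {
    nrm <- normalize_sample(run, object$grid, object$config$target_mean)
    acc <- accumulate(nrm$run, object$grid)
    acc$values[object$selection$variables$node_index]
  }, numeric(nrow(object$selection$variables)))
  x <- t(matrix(s, ncol = length(newdata)))
  colnames(x) <- colnames(object$x)
  sc <- pca_transform(object$pca, x)
  stats::setNames(predict(object$lda, sc),
                  vapply(newdata, function(r) r$sample_id, ""))
}

#' Score plot of a fitted pipeline
#'
#' Scatter of the first two principal component scores (or a strip
#' plot if only one component exists), coloured by class.
#'
#' @param x A fitted `ssir`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ssir <- function(x, ...) {
  sc <- x$scores
  cls <- x$split$labels
  pch <- ifelse(cls == 1L, 19, 1)
  ef <- 100 * x$pca$explained_fraction
  if (ncol(sc) >= 2L) {
    graphics::plot(sc[, 1L], sc[, 2L], pch = pch,
                   col = ifelse(cls == 1L, "firebrick", "navy"),
                   xlab = sprintf("PC1 (%.1f%%)", ef[1L]),
                   ylab = sprintf("PC2 (%.1f%%)", ef[2L]), ...)
  } else {
    graphics::stripchart(split(sc[, 1L], cls), vertical = FALSE,
                         pch = c(1, 19), method = "jitter",
                         xlab = sprintf("PC1 (%.1f%%)", ef[1L]), ...)
  }
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  invisible(x)
}
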