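#' Full-pipeline leave-one-out cross-validation
#'
#' For each sample the entire pipeline is re-derived from the raw scans
#' of the remaining samples — grid accumulation, per-sample percentile
#' codification, constant-node removal, degeneracy grouping, rule
#' scoring, variable selection, PCA and discriminant are all functions
#' of the n-1 retained samples only. The held-out sample is then
#' normalized with its own mean, reduced to the fold's selected
#' variables, projected and classified, for every requested number of
#' discriminant components. A fold whose selection is empty is recorded
#' as a no-model fold (prediction `NA`), never silently skipped.
#'
#' @param runs List of labelled [sample_run] objects (>= 3 per class),
#'   or an `ssir_sim` dataset.
#' @param config An [ssir_config()].
#' @param k_range Numbers of discriminant components to evaluate
#'   (default `1:5`). If a fold yields fewer components than requested,
#'   the available number is used and reported in `k_used`.
#' @return An object of class `ssir_cv`: list with `folds` (one row per
#'   fold per k: `sample_id`, `k`, `k_used`, `n_selected`, `predicted`,
#'   `truth`, `correct`, `no_model`) and `summary` (per k: accuracy,
#'   sensitivity, specificity, no-model count).
#' @export
loo_validate <- function(runs, config = ssir_config(), k_range = 1:5) {
  if (inherits(runs, "ssir_sim")) runs <- runs$runs
  labs <- unname(vapply(runs, function(r) as.integer(r$label), 0L))
  if (anyNA(labs)) stop("every sample needs a 0/1 label")
  if (sum(labs == 0L) < 3L || sum(labs == 1L) < 3L)
    stop("need at least 3 samples per class for leave-one-out")
  n <- length(runs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    held <- runs[[i]]
    fit <- tryCatch(ssir(runs[-i], config), error = function(e) {
      if (grepl("no significant variables", conditionMessage(e))) NULL
      else stop(e)
    })
    if (is.null(fit)) {
      rows[[i]] <- data.frame(sample_id = held$sample_id, k = k_range,
                              k_used = NA_integer_, n_selected = 0L,
                              predicted = NA_integer_, truth = labs[i],
                              correct = NA, no_model = TRUE)
      next
    }
    nrm <- normalize_sample(held, fit$grid, config$target_mean)
    acc <- accumulate(nrm$run, fit$grid)
    xh <- matrix(acc$values[fit$selection$variables$node_index], nrow = 1L,
                 dimnames = list(NULL, colnames(fit$x)))
    sh <- pca_transform(fit$pca, xh)
    ks <- pmin(k_range, ncol(fit$scores))
    pred <- vapply(ks, function(k) {
      lda <- discriminant_fit(fit$scores, fit$split$labels, k)
      predict(lda, sh)
    }, 0L)
    rows[[i]] <- data.frame(sample_id = held$sample_id, k = k_range,
                            k_used = ks,
                            n_selected = nrow(fit$selection$variables),
                            predicted = pred, truth = labs[i],
                            correct = pred == labs[i], no_model = FALSE)
  }
  folds <- do.call(rbind, rows)
  rownames(folds) <- NULL
  summ <- do.call(rbind, lapply(k_range, function(k) {
    f <- folds[folds$k == k, ]
    ok <- !f$no_model
    data.frame(k = k,
               accuracy = mean(f$correct[ok]),
               sensitivity = mean(f$correct[ok & f$truth == 1L]),
               specificity = mean(f$correct[ok & f$truth == 0L]),
               n_no_model = sum(!ok))
  }))
  structure(list(folds = folds, summary = summ, k_range = k_range),
            class = "ssir_cv")
}

#' @export
print.ssir_cv <- function(x, ...) {
  n <- length(unique(x$folds$sample_id))
  cat(sprintf("<ssir_cv> leave-one-out over %d folds\n", n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report as delimited text
#'
#' One row per fold per component count.
#'
#' @param cv An `ssir_cv`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path, sep = "\t") {
  utils::write.table(cv$folds, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
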