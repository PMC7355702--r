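#' Dichotomize node intensities into low/high levels
#'
#' Per sample, the `k = ceiling(top_fraction * n_nodes)` largest node
#' values become the high level (1) and the rest low (0). The percentile
#' is a rank rule, not an interpolated quantile, so the per-sample high
#' count is exact; ties at the cutoff are broken deterministically in
#' favour of the lower node index. With `scope = "pooled"` a single
#' cutoff value is taken from the pooled distribution of all samples'
#' node values instead (values >= cutoff are high), which does not
#' guarantee equal per-sample high counts.
#'
#' @param nm A `node_matrix`.
#' @param top_fraction Fraction of nodes codified high, in (0, 1);
#'   default 0.01.
#' @param scope `"per_sample"` (default) or `"pooled"`.
#' @return An object of class `binary_code`: list with `levels`
#'   (samples x nodes 0/1 integer matrix), `node_indices` (columns'
#'   node indices into the grid), `sample_ids`, `labels`, `grid`,
#'   `top_fraction`, `degeneracy` (NULL until [group_degenerate()]).
#' @export
dichotomize <- function(nm, top_fraction = 0.01,
                        scope = c("per_sample", "pooled")) {
  stopifnot(inherits(nm, "node_matrix"))
  scope <- match.arg(scope)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop("'top_fraction' must lie in (0, 1)")
  v <- nm$values
  n_nodes <- ncol(v)
  lv <- matrix(0L, nrow = nrow(v), ncol = n_nodes,
               dimnames = list(nm$sample_ids, NULL))
  if (scope == "per_sample") {
    k <- ceiling(top_fraction * n_nodes)
    for (i in seq_len(nrow(v))) {
      ord <- order(-v[i, ], seq_len(n_nodes))
      lv[i, ord[seq_len(k)]] <- 1L
    }
  } else {
    pool <- as.vector(v)
    k <- ceiling(top_fraction * length(pool))
    cutoff <- sort(pool, decreasing = TRUE)[k]
    lv[v >= cutoff] <- 1L
  }
  structure(
    list(levels = lv, node_indices = seq_len(n_nodes),
         sample_ids = nm$sample_ids, labels = nm$labels, grid = nm$grid,
         top_fraction = top_fraction, degeneracy = NULL,
         n_constant_dropped = NA_integer_),
    class = "binary_code")
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %d samples x %d nodes (top fraction %g)",
              nrow(x$levels), ncol(x$levels), x$top_fraction))
  if (!is.na(x$n_constant_dropped))
    cat(sprintf("; %d constant nodes dropped", x$n_constant_dropped))
  if (!is.null(x$degeneracy))
    cat(sprintf("; %d representatives", ncol(x$levels)))
  cat("\n")
  invisible(x)
}

#' Remove nodes whose level is constant across samples
#'
#' Nodes that are all-low or all-high over every sample carry no
#' class information and are discarded.
#'
#' @param code A `binary_code`.
#' @return A `binary_code` restricted to the varying nodes, with
#'   `n_constant_dropped` recorded. Warns if nothing varies.
#' @export
drop_constant <- function(code) {
  stopifnot(inherits(code, "binary_code"))
  if (nrow(code$levels) < 2L) stop("need >= 2 samples to assess constancy")
  cs <- colSums(code$levels)
  keep <- cs > 0L & cs < nrow(code$levels)
  code$n_constant_dropped <- sum(!keep)
  code$levels <- code$levels[, keep, drop = FALSE]
  code$node_indices <- code$node_indices[keep]
  if (!any(keep)) warning("all nodes are constant; no variables remain")
  code
}

#' Collapse degenerate nodes under representatives
#'
#' Nodes whose 0/1 pattern over the samples is bit-identical are
#' redundant for rule generation; each group is collapsed to its
#' lowest-indexed node (the representative). The mapping is retained so
#' selected representatives can later be expanded back to every node
#' they represent.
#'
#' @param code A `binary_code` with constant nodes already removed.
#' @return A `binary_code` restricted to representative columns, with
#'   `degeneracy`: a named list mapping each representative node index
#'   to the integer vector of node indices it represents (including
#'   itself).
#' @export
group_degenerate <- function(code) {
  stopifnot(inherits(code, "binary_code"))
  if (ncol(code$levels) == 0L) {
    code$degeneracy <- stats::setNames(list(), character())
    return(code)
  }
  key <- apply(code$levels, 2L, paste0, collapse = "")
  groups <- split(code$node_indices, key)
  reps <- vapply(groups, min, 0L)
  ord <- order(reps)
  groups <- lapply(groups[ord], sort)
  reps <- reps[ord]
  names(groups) <- as.character(reps)
  keep <- match(reps, code$node_indices)
  code$levels <- code$levels[, keep, drop = FALSE]
  code$node_indices <- code$node_indices[keep]
  code$degeneracy <- groups
  code
}

#' Expand a degeneracy map back to the full varying-node matrix
#'
#' Lossless inverse of [group_degenerate()]: each representative's
#' column is copied to every node it represents.
#'
#' @param code A `binary_code` with a `degeneracy` map.
#' @return A `binary_code` over all represented nodes, without a map.
#' @export
expand_degenerate <- function(code) {
  stopifnot(inherits(code, "binary_code"), !is.null(code$degeneracy))
  all_nodes <- sort(unlist(code$degeneracy, use.names = FALSE))
  lv <- matrix(0L, nrow = nrow(code$levels), ncol = length(all_nodes),
               dimnames = list(code$sample_ids, NULL))
  for (j in seq_along(code$degeneracy)) {
    cols <- match(code$degeneracy[[j]], all_nodes)
    lv[, cols] <- code$levels[, j]
  }
  code$levels <- lv
  code$node_indices <- all_nodes
  code$degeneracy <- NULL
  code
}

#' Persist a binary code as delimited 0/1 text
#'
#' Writes the level matrix with node labels as header; if a degeneracy
#' map is present, a companion file (`<path>.groups`) lists
#' (representative_label, member_label) pairs.
#'
#' @param code A `binary_code`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_binary_code <- function(code, path, sep = "\t") {
  df <- as.data.frame(code$levels)
  names(df) <- node_labels(code$grid, code$node_indices)
  df <- cbind(sample_id = code$sample_ids, df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(code$degeneracy)) {
    reps <- rep(as.integer(names(code$degeneracy)),
                lengths(code$degeneracy))
    members <- unlist(code$degeneracy, use.names = FALSE)
    gr <- data.frame(representative_label = node_labels(code$grid, reps),
                     member_label = node_labels(code$grid, members))
    utils::write.table(gr, paste0(path, ".groups"), sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
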