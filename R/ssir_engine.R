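#' Binary class split of a sample set
#'
#' @param labels Integer 0/1 vector, one per sample (no `NA`).
#' @return An object of class `class_split`: list with `N` (total
#'   samples), `K` (samples in class 1) and `labels`.
#' @export
class_split <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0/1 with no missing values")
  labels <- as.integer(labels)
  K <- sum(labels)
  if (K == 0L || K == length(labels))
    stop("both classes must be present (0 < K < N)")
  structure(list(N = length(labels), K = K, labels = labels),
            class = "class_split")
}

# Vectorized hypergeometric upper tail P(X >= k) for X ~ Hyper(N, K, n):
# the probability that a uniformly random n-subset of N samples (K of
# them in the class) contains at least k class members. Exact
# double-integer combinatorics while C(N, n) < 2^53 (so small-N results
# are bit-identical to subset enumeration); log-sum-exp otherwise.
.hyper_upper <- function(N, K, n, k) {
  out <- numeric(length(n))
  for (i in seq_along(n)) {
    ni <- n[i]; ki <- k[i]
    lo <- max(0L, ni - (N - K))
    if (ki <= lo) { out[i] <- 1; next }
    hi <- min(ni, K)
    if (ki > hi) { out[i] <- 0; next }   # unreachable given valid args
    j <- ki:hi
    if (lchoose(N, ni) < 53 * log(2)) {
      p <- sum(choose(K, j) * choose(N - K, ni - j)) / choose(N, ni)
    } else {
      lt <- lchoose(K, j) + lchoose(N - K, ni - j) - lchoose(N, ni)
      m <- max(lt)
      p <- exp(m) * sum(exp(lt - m))
    }
    out[i] <- min(p, 1)
  }
  out
}

#' Exact enrichment p-value of a selection rule
#'
#' Under the random-extractor null a rule that matches `n_selected` of
#' the `N` samples is treated as drawing them uniformly at random; the
#' number of class members among them is then hypergeometric. The
#' p-value is the upper tail `P(X >= k_in_class)` — the probability of
#' selecting at least as many class members by chance.
#'
#' @param N Total number of samples.
#' @param K Number of samples in the enriched class.
#' @param n_selected Number of samples matched by the rule.
#' @param k_in_class Number of matched samples in the enriched class.
#' @return The p-value, in (0, 1]. An empty selection
#'   (`n_selected = 0`) has p-value 1.
#' @examples
#' rule_pvalue(56, 28, 29, 27)  # 1.4e-12 (2 s.f.)
#' @export
rule_pvalue <- function(N, K, n_selected, k_in_class) {
  if (length(N) != 1L || length(K) != 1L || length(n_selected) != 1L ||
      length(k_in_class) != 1L)
    stop("all arguments must be scalars")
  if (N < 1 || K < 0 || K > N) stop("need 0 <= K <= N, N >= 1")
  if (n_selected < 0 || n_selected > N)
    stop("need 0 <= n_selected <= N")
  if (k_in_class < 0 || k_in_class > min(n_selected, K))
    stop("need 0 <= k_in_class <= min(n_selected, K)")
  .hyper_upper(N, K, n_selected, k_in_class)
}

# Per-node counts and direction-specific p-values, vectorized over all
# columns of a binary code. For each class direction the better of the
# two level readings (high selects the class vs low selects the class)
# is retained; by complement symmetry of the hypergeometric tail the
# high reading for one class equals the low reading for the other.
.node_stats <- function(code, split) {
  lv <- code$levels
  N <- split$N; K <- split$K
  h1 <- as.vector(crossprod(lv, split$labels))        # high in class 1
  nh <- colSums(lv)
  h0 <- nh - h1
  p_high_1 <- .hyper_upper(N, K, nh, h1)
  p_low_1  <- .hyper_upper(N, K, N - nh, K - h1)
  p_high_0 <- .hyper_upper(N, N - K, nh, h0)
  p_low_0  <- .hyper_upper(N, N - K, N - nh, (N - K) - h0)
  p1 <- pmin(p_high_1, p_low_1)
  p0 <- pmin(p_high_0, p_low_0)
  data.frame(node_index = code$node_indices,
             high_class0 = h0, high_class1 = h1,
             low_class0 = (N - K) - h0, low_class1 = K - h1,
             p_class1 = p1, p_class0 = p0,
             level_class1 = ifelse(p_high_1 <= p_low_1, "high", "low"),
             level_class0 = ifelse(p_high_0 <= p_low_0, "high", "low"),
             p_value = pmin(p1, p0),
             direction = ifelse(p1 <= p0, 1L, 0L))
}

#' Score one representative node against the class split
#'
#' Computes the Table-3-style reckoning of high and low levels per
#' class and, for each class direction, the enrichment p-value of the
#' better level reading.
#'
#' @param code A `binary_code` (representatives).
#' @param node A node index present in `code$node_indices`.
#' @param split A [class_split].
#' @return Data frame with two rows (directions class 1 and class 0):
#'   columns `node_index`, `direction`, `level` (which level selects the
#'   class), `n_selected`, `k_in_class`, `p_value`, plus the four
#'   high/low per-class counts.
#' @export
evaluate_node <- function(code, node, split) {
  j <- match(node, code$node_indices)
  if (is.na(j)) stop("node ", node, " is not a representative column")
  sub <- code
  sub$levels <- code$levels[, j, drop = FALSE]
  sub$node_indices <- node
  st <- .node_stats(sub, split)
  N <- split$N; K <- split$K
  n_high <- st$high_class0 + st$high_class1
  lvl1 <- st$level_class1; lvl0 <- st$level_class0
  data.frame(
    node_index = node,
    direction = c(1L, 0L),
    level = c(lvl1, lvl0),
    n_selected = c(if (lvl1 == "high") n_high else N - n_high,
                   if (lvl0 == "high") n_high else N - n_high),
    k_in_class = c(if (lvl1 == "high") st$high_class1 else st$low_class1,
                   if (lvl0 == "high") st$high_class0 else st$low_class0),
    p_value = c(st$p_class1, st$p_class0),
    high_class0 = st$high_class0, high_class1 = st$high_class1,
    low_class0 = st$low_class0, low_class1 = st$low_class1)
}

#' Table-style reckoning for every representative node
#'
#' @param code A `binary_code` (representatives).
#' @param split A [class_split].
#' @return Data frame, one row per representative: per-class high/low
#'   counts, direction-specific p-values, the minimum `p_value` and the
#'   enriched `direction`.
#' @export
node_reckoning <- function(code, split) {
  .node_stats(code, split)
}

#' Enumerate and score conjunction rules
#'
#' A rule of order r fixes the level (low/high) of r distinct
#' representative nodes; a sample matches the rule iff it shows every
#' stated level. All `C(m, r) * 2^r` rules for orders `1..max_order` are
#' evaluated, in lexicographic order of node-index combinations and, for
#' each combination, level assignments in binary order (all-low first,
#' low before high on the last node varying fastest). Each rule is
#' scored for both class directions and the minimum retained. Rules of
#' order >= 2 in which some condition already matches no sample are
#' skipped (their conjunction cannot be significant).
#'
#' @param code A `binary_code` (representatives).
#' @param split A [class_split].
#' @param max_order Highest rule order; one of 1, 2, 3.
#' @return Data frame of rules: `order`, `nodes` (node indices joined by
#'   `+`), `levels` (string of `l`/`h`), `n_selected`, `k_class1`,
#'   `p_class1`, `p_class0`, `p_value`, `direction`.
#' @export
enumerate_rules <- function(code, split, max_order = 1) {
  if (!max_order %in% c(1, 2, 3)) stop("'max_order' must be 1, 2 or 3")
  m <- ncol(code$levels)
  if (m == 0L)
    return(data.frame(order = integer(), nodes = character(),
                      levels = character(), n_selected = integer(),
                      k_class1 = integer(), p_class1 = numeric(),
                      p_class0 = numeric(), p_value = numeric(),
                      direction = integer()))
  lv <- code$levels
  N <- split$N; K <- split$K
  lab1 <- split$labels
  score <- function(match_vec) {
    n <- sum(match_vec)
    k1 <- sum(match_vec & lab1 == 1L)
    p1 <- .hyper_upper(N, K, n, k1)
    p0 <- .hyper_upper(N, N - K, n, n - k1)
    c(n, k1, p1, p0)
  }
  out <- list()
  # order 1: both level readings of every node, fully vectorized
  nh <- colSums(lv)
  h1 <- as.vector(crossprod(lv, lab1))
  ord1 <- function(level) {
    n <- if (level == 1L) nh else split$N - nh
    k1 <- if (level == 1L) h1 else split$K - h1
    data.frame(order = 1L,
               nodes = as.character(code$node_indices),
               levels = if (level == 1L) "h" else "l",
               n_selected = n, k_class1 = k1,
               p_class1 = .hyper_upper(N, K, n, k1),
               p_class0 = .hyper_upper(N, N - K, n, n - k1))
  }
  o1 <- rbind(ord1(0L), ord1(1L))
  o1 <- o1[order(match(o1$nodes, as.character(code$node_indices)),
                 o1$levels), ]
  out[[1L]] <- o1
  for (r in seq_len(max_order)[-1L]) {
    if (m < r) break
    support0 <- nh == 0L | nh == nrow(lv)   # a level with zero support exists
    combos <- utils::combn(m, r)
    levset <- as.matrix(expand.grid(rep(list(0:1), r))[, r:1, drop = FALSE])
    rows <- list(); ri <- 1L
    for (ci in seq_len(ncol(combos))) {
      js <- combos[, ci]
      cols <- lv[, js, drop = FALSE]
      csum <- colSums(cols)
      for (li in seq_len(nrow(levset))) {
        lvs <- levset[li, ]
        # early skip: a stated level matched by no sample at all
        marg <- ifelse(lvs == 1L, csum, nrow(lv) - csum)
        if (any(marg == 0L)) next
        mvec <- rowSums(cols == rep(lvs, each = nrow(lv))) == r
        sc <- score(mvec)
        rows[[ri]] <- data.frame(
          order = r,
          nodes = paste(code$node_indices[js], collapse = "+"),
          levels = paste(ifelse(lvs == 1L, "h", "l"), collapse = ""),
          n_selected = sc[1L], k_class1 = sc[2L],
          p_class1 = sc[3L], p_class0 = sc[4L])
        ri <- ri + 1L
      }
    }
    if (length(rows)) out[[r]] <- do.call(rbind, rows)
  }
  rules <- do.call(rbind, out)
  rules$p_value <- pmin(rules$p_class1, rules$p_class0)
  rules$direction <- ifelse(rules$p_class1 <= rules$p_class0, 1L, 0L)
  rownames(rules) <- NULL
  rules
}

#' Select variables from scored rules and expand degeneracy
#'
#' A representative node is selected if it appears in at least one rule
#' with `p_value <= threshold`. For order-1 rules the low and high
#' readings of a node are complementary descriptions of the same split
#' and are collapsed before vote counting. Selected representatives are
#' expanded through the degeneracy map into the final variable table,
#' sorted by ascending p-value and then node index.
#'
#' @param rules Data frame from [enumerate_rules()].
#' @param threshold Significance threshold on the rule p-value
#'   (default 0.0005). No multiplicity correction is applied.
#' @param degeneracy Degeneracy map (representative -> member node
#'   indices) from [group_degenerate()], or `NULL` for none.
#' @param grid Optional `grid_spec` used to annotate variables with
#'   their time interval and mass center.
#' @return An object of class `ssir_selection`: list with `variables`
#'   (the expanded, ranked variable table), `representatives` (per
#'   selected representative: best p-value, direction, votes),
#'   `n_significant_rules` and `threshold`. Selections can be empty.
#' @export
select_variables <- function(rules, threshold = 5e-4, degeneracy = NULL,
                             grid = NULL) {
  sig <- rules[rules$p_value <= threshold, , drop = FALSE]
  # collapse complementary order-1 duplicates (same node, both levels)
  if (nrow(sig)) {
    is1 <- sig$order == 1L
    dup <- rep(FALSE, nrow(sig))
    dup[is1] <- duplicated(sig$nodes[is1])
    sig <- sig[!dup, , drop = FALSE]
  }
  node_lists <- lapply(strsplit(sig$nodes, "+", fixed = TRUE), as.integer)
  all_nodes <- sort(unique(unlist(node_lists)))
  reps <- if (length(all_nodes)) {
    votes <- vapply(all_nodes, function(nd)
      sum(vapply(node_lists, function(x) nd %in% x, TRUE)), 0L)
    best <- lapply(all_nodes, function(nd) {
      rows <- sig[vapply(node_lists, function(x) nd %in% x, TRUE), ]
      i <- which.min(rows$p_value)
      rows[i, c("p_value", "direction")]
    })
    data.frame(node_index = all_nodes,
               p_value = vapply(best, function(b) b$p_value, 0),
               direction = vapply(best, function(b) b$direction, 0L),
               votes = votes)
  } else {
    data.frame(node_index = integer(), p_value = numeric(),
               direction = integer(), votes = integer())
  }
  # expand through the degeneracy map
  if (!is.null(degeneracy) && nrow(reps)) {
    ex <- lapply(seq_len(nrow(reps)), function(i) {
      members <- degeneracy[[as.character(reps$node_index[i])]]
      if (is.null(members)) members <- reps$node_index[i]
      data.frame(node_index = members,
                 representative = reps$node_index[i],
                 p_value = reps$p_value[i],
                 direction = reps$direction[i],
                 votes = reps$votes[i])
    })
    vars <- do.call(rbind, ex)
  } else {
    vars <- reps
    if (nrow(vars)) vars$representative <- vars$node_index
  }
  if (nrow(vars)) {
    vars <- vars[order(vars$p_value, vars$node_index), , drop = FALSE]
    vars$variable <- seq_len(nrow(vars))
    if (!is.null(grid)) {
      info <- node_info(grid, vars$node_index)
      vars$time_lo <- info$time_lo
      vars$time_hi <- info$time_hi
      vars$mass_center <- info$mass_center
    }
    rownames(vars) <- NULL
    first <- c("variable", "node_index", "representative")
    vars <- vars[, c(first, setdiff(names(vars), first)), drop = FALSE]
  }
  structure(list(variables = vars, representatives = reps,
                 n_significant_rules = nrow(sig), threshold = threshold),
            class = "ssir_selection")
}

#' @export
print.ssir_selection <- function(x, ...) {
  cat(sprintf(paste0("<ssir_selection> %d representative node(s), ",
                     "%d expanded variable(s) at p <= %g ",
                     "(%d significant rule(s))\n"),
              nrow(x$representatives), nrow(x$variables), x$threshold,
              x$n_significant_rules))
  if (nrow(x$variables)) print(utils::head(x$variables, 15L))
  invisible(x)
}

#' Write a selection report as delimited text
#'
#' One row per expanded variable: rank, time interval, mass center,
#' direction, p-value and vote count.
#'
#' @param sel An `ssir_selection` (annotated with a grid).
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, sep = "\t") {
  utils::write.table(sel$variables, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
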