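# binary code stub over given level columns
code_from_levels <- function(lv, node_indices = seq_len(ncol(lv))) {
  structure(list(levels = lv, node_indices = node_indices,
                 sample_ids = sprintf("s%02d", seq_len(nrow(lv))),
                 labels = rep(NA_integer_, nrow(lv)),
                 grid = build_grid(0, 1, 1, 1, max(node_indices), 1),
                 top_fraction = 0.01, degeneracy = NULL,
                 n_constant_dropped = 0L),
            class = "binary_code")
}

test_that("rule_pvalue reproduces all 13 published reckonings to 2 s.f.", {
  tab <- reckoning_56()
  for (i in seq_len(nrow(tab))) {
    a <- reckoning_args(tab[i, ])
    expect_equal(signif(rule_pvalue(56, 28, a["n"], a["k"]), 2),
                 tab$p_2sf[i], tolerance = 1e-12,
                 label = sprintf("variable %d", i))
  }
})

test_that("rule_pvalue handles exact small cases and degenerate selections", {
  expect_identical(rule_pvalue(6, 3, 2, 2), 3 / 15)  # C(3,2)/C(6,2)
  expect_identical(rule_pvalue(10, 4, 0, 0), 1)
  expect_identical(rule_pvalue(8, 4, 8, 4), 1)       # forced full draw
  expect_equal(rule_pvalue(56, 28, 56, 28), 1)
  expect_error(rule_pvalue(10, 11, 2, 1), "K <= N")
  expect_error(rule_pvalue(10, 5, 11, 2), "n_selected")
  expect_error(rule_pvalue(10, 5, 4, 5), "k_in_class")
  expect_error(rule_pvalue(10, 5, c(1, 2), c(1, 2)), "scalars")
})

test_that("rule_pvalue equals exhaustive subset enumeration for N <= 8", {
  for (N in 4:8) for (K in 1:(N - 1)) for (n in 0:N) {
    lo <- max(0, n - (N - K))
    for (k in lo:min(n, K)) {
      expect_identical(rule_pvalue(N, K, n, k), brute_upper(N, K, n, k),
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("rule_pvalue agrees with the library hypergeometric tail", {
  set.seed(99)
  for (rep in 1:200) {
    N <- sample(5:80, 1)
    K <- sample(seq_len(N - 1), 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    expect_equal(rule_pvalue(N, K, n, k),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("p-value is monotone in k and symmetric under complementation", {
  # monotonicity: strictly decreasing in k at fixed N, K, n
  p <- vapply(0:10, function(k) rule_pvalue(20, 10, 10, k), 0)
  expect_true(all(diff(p) < 0))

  # complement symmetry: selecting the class via one level equals
  # selecting the other class via the complementary level
  set.seed(7)
  for (rep in 1:100) {
    N <- sample(6:40, 1); K <- sample(seq_len(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    lhs <- rule_pvalue(N, K, n, k)
    rhs <- rule_pvalue(N, N - K, N - n, (N - K) - (n - k))
    expect_equal(lhs, rhs, tolerance = 1e-9 * max(lhs, 1e-300))
  }
})

test_that("evaluate_node reproduces the printed per-variable reckonings", {
  # variable 1: high in 27 of 28 treated and 2 of 28 non-treated
  labs <- rep(c(1L, 0L), each = 28)
  col <- c(rep(1L, 27), 0L, rep(1L, 2), rep(0L, 26))
  code <- code_from_levels(matrix(col, ncol = 1))
  split <- class_split(labs)
  ev <- evaluate_node(code, 1L, split)
  r1 <- ev[ev$direction == 1L, ]
  expect_equal(r1$n_selected, 29)
  expect_equal(r1$k_in_class, 27)
  expect_equal(r1$level, "high")
  expect_equal(signif(r1$p_value, 2), 1.4e-12)
  expect_equal(r1$high_class0 + r1$low_class0, 28)
  expect_equal(r1$high_class1 + r1$low_class1, 28)

  # variable 12: high in 10 non-treated, 0 treated
  col12 <- c(rep(0L, 28), rep(1L, 10), rep(0L, 18))
  ev12 <- evaluate_node(code_from_levels(matrix(col12, ncol = 1)), 1L, split)
  r0 <- ev12[ev12$direction == 0L, ]
  expect_equal(r0$n_selected, 10)
  expect_equal(r0$k_in_class, 10)
  expect_equal(signif(r0$p_value, 2), 3.7e-4)

  # a column identical to the labels is the perfect classifier bound
  evp <- evaluate_node(code_from_levels(matrix(labs, ncol = 1)), 1L, split)
  expect_equal(min(evp$p_value), 1 / choose(56, 28), tolerance = 1e-9)
})

test_that("the two class directions coincide with complementary levels", {
  set.seed(23)
  labs <- sample(rep(c(0L, 1L), times = c(9, 11)))
  split <- class_split(labs)
  lv <- matrix(rbinom(20 * 15, 1, 0.3), nrow = 20)
  code <- code_from_levels(lv)
  st <- node_reckoning(code, split)
  # reckoning complementarity: high + low = class size for every node
  expect_true(all(st$high_class1 + st$low_class1 == split$K))
  expect_true(all(st$high_class0 + st$low_class0 == split$N - split$K))
  for (j in seq_len(15)) {
    # the high reading for class 1 and the low reading for class 0
    # describe the same split and must carry identical evidence
    nh <- sum(lv[, j])
    h1 <- sum(lv[labs == 1L, j])
    p_high_1 <- rule_pvalue(20, split$K, nh, h1)
    p_low_0 <- rule_pvalue(20, 20 - split$K, 20 - nh,
                           (20 - nh) - (split$K - h1))
    expect_equal(p_high_1, p_low_0, tolerance = 1e-9)
  }
})

test_that("rule enumeration covers the combinatorial stream deterministically", {
  set.seed(31)
  lv <- matrix(rbinom(8 * 3, 1, 0.5), nrow = 8)
  lv[1, ] <- c(1L, 0L, 1L); lv[2, ] <- c(0L, 1L, 0L)  # ensure both levels occur
  code <- code_from_levels(lv, node_indices = c(2L, 5L, 7L))
  split <- class_split(rep(c(0L, 1L), each = 4))

  r1 <- enumerate_rules(code, split, 1)
  expect_equal(nrow(r1), 6L)                       # 3 nodes x 2 levels
  expect_equal(unique(r1$order), 1L)

  r2 <- enumerate_rules(code, split, 2)
  expect_equal(sum(r2$order == 2L), 12L)           # C(3,2) * 4 level maps
  expect_equal(nrow(r2), 18L)
  # deterministic and reproducible stream
  expect_identical(r2, enumerate_rules(code, split, 2))
  expect_error(enumerate_rules(code, split, 4), "max_order")

  # conjunction matching: only samples showing every stated level count
  lv2 <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  code2 <- code_from_levels(lv2)
  split2 <- class_split(c(1L, 1L, 0L, 0L))
  rr <- enumerate_rules(code2, split2, 2)
  hh <- rr[rr$order == 2L & rr$levels == "hh", ]
  expect_equal(hh$n_selected, 1L)                  # only sample 1 matches
  expect_equal(hh$k_class1, 1L)
})

test_that("order >= 2 rules with an unmatched condition are skipped", {
  lv <- cbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 0L))  # node 1 never low
  code <- code_from_levels(lv)
  split <- class_split(c(1L, 1L, 0L, 0L))
  rr <- enumerate_rules(code, split, 2)
  o2 <- rr[rr$order == 2L, ]
  expect_false(any(substr(o2$levels, 1, 1) == "l"))  # 'node1 = low' pruned
  expect_equal(nrow(o2), 2L)
})

test_that("threshold selection retains the published variables", {
  tab <- reckoning_56()
  rules <- data.frame(
    order = 1L, nodes = as.character(1:13), levels = "h",
    n_selected = tab$high_nt + tab$high_t,
    k_class1 = tab$high_t,
    p_class1 = NA_real_, p_class0 = NA_real_,
    p_value = vapply(seq_len(13), function(i) {
      a <- reckoning_args(tab[i, ])
      rule_pvalue(56, 28, a["n"], a["k"])
    }, 0),
    direction = tab$direction)
  sel <- select_variables(rules, 5e-4)
  expect_equal(nrow(sel$variables), 13L)          # max p = 4.7e-4 <= 5e-4
  sel2 <- select_variables(rules, 1e-4)
  expect_equal(nrow(sel2$variables), 8L)          # rows at p <= 1e-4
  empty <- select_variables(rules[0, ], 5e-4)
  expect_equal(nrow(empty$variables), 0L)
})

test_that("selection expands degeneracy and ranks by p then node index", {
  lv <- cbind(c(1L, 1L, 1L, 0L, 0L, 0L),   # perfect split, node 3: p = 1/20
              c(1L, 1L, 1L, 1L, 0L, 0L))   # weaker, node 8: p = 3/15 = 0.2
  code <- code_from_levels(lv, node_indices = c(3L, 8L))
  code$grid <- build_grid(0, 1, 1, 1, 12, 1)   # cover expanded members
  code$degeneracy <- list(`3` = c(3L, 5L, 12L), `8` = 8L)
  split <- class_split(c(1L, 1L, 1L, 0L, 0L, 0L))
  rules <- enumerate_rules(code, split, 1)
  sel <- select_variables(rules, threshold = 0.2, degeneracy = code$degeneracy,
                          grid = code$grid)
  expect_equal(nrow(sel$representatives), 2L)
  expect_equal(nrow(sel$variables), 4L)           # 3 members + 1 singleton
  expect_equal(sel$variables$node_index, c(3L, 5L, 12L, 8L))
  expect_true(all(diff(sel$variables$p_value) >= 0))
  expect_true(all(sel$variables$representative %in% c(3L, 8L)))
  # ties in p are ordered by node index
  expect_equal(sel$variables$node_index[1:3], sort(c(3L, 5L, 12L)))
  # annotated with grid coordinates
  expect_true(all(c("time_lo", "time_hi", "mass_center") %in%
                  names(sel$variables)))
})

test_that("order-1 complement duplicates are collapsed in vote counts", {
  lv <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1)
  code <- code_from_levels(lv)
  split <- class_split(c(1L, 1L, 1L, 0L, 0L, 0L))
  rules <- enumerate_rules(code, split, 1)
  expect_equal(nrow(rules), 2L)  # both levels in the stream
  sel <- select_variables(rules, threshold = 0.1)
  expect_equal(sel$representatives$votes, 1L)
})

test_that("null label shuffles select at most the nominal rate", {
  set.seed(61)
  lv <- matrix(rbinom(20 * 30, 1, 0.4), nrow = 20)
  keep <- colSums(lv) > 0 & colSums(lv) < 20
  code <- code_from_levels(lv[, keep, drop = FALSE])
  labs <- rep(c(0L, 1L), each = 10)
  alpha <- 0.05
  m <- ncol(code$levels)
  frac <- replicate(1000, {
    st <- node_reckoning(code, class_split(sample(labs)))
    mean(st$p_value <= alpha)
  })
  # each direction is a valid level-alpha test; two directions per node
  bound <- 2 * alpha
  se <- sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), bound + 3 * se)
})
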