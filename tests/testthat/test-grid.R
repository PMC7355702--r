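test_that("grid arithmetic produces the expected node counts", {
  g <- build_grid(6, 17, 1/3, 49, 170, 0.5)
  expect_equal(g$n_time, 33L)
  expect_equal(g$n_mass, 243L)
  expect_equal(g$n_nodes, 8019L)
  expect_equal(mass_centers(g)[c(1, 243)], c(49, 170))
  expect_equal(time_edges(g)[c(1, 34)], c(6, 17))

  expect_equal(build_grid(0, 1, 1, 100, 100, 0.5)$n_nodes, 1L)
  expect_equal(build_grid(0, 10, 0.5, 50, 59.5, 0.5)$n_nodes, 400L)

  expect_error(build_grid(6, 17, 0, 49, 170, 0.5), "time_step")
  expect_error(build_grid(17, 6, 1/3, 49, 170, 0.5), "time_end")
  expect_error(build_grid(6, 17, 1/3, 170, 49, 0.5), "mass_center_max")
})

test_that("normalization rescales in-window registers to the target mean", {
  g <- build_grid(0, 10, 1, 50, 100, 1)
  run <- make_run("a", t = c(1, 2, 3), mz = c(60, 70, 80), i = c(1, 2, 3))
  out <- normalize_sample(run, g, 1000)
  expect_equal(out$run$records$intensity, c(500, 1000, 1500))
  expect_equal(out$norm_factor, 500)

  already <- make_run("b", t = 1:3, mz = c(60, 70, 80),
                      i = c(900, 1000, 1100))
  expect_equal(normalize_sample(already, g, 1000)$norm_factor, 1)

  # out-of-window registers do not enter the mean
  mixed <- make_run("c", t = c(1, 2, 15), mz = c(60, 70, 80),
                    i = c(1, 3, 1e6))
  expect_equal(normalize_sample(mixed, g, 1000)$norm_factor, 500)

  zeros <- make_run("d", t = c(1, 2), mz = c(60, 70), i = c(0, 0))
  expect_error(normalize_sample(zeros, g), "scale undefined")
  outside <- make_run("e", t = 20, mz = 60, i = 5)
  expect_error(normalize_sample(outside, g), "no registers inside")
})

test_that("normalized mean matches an independent recomputation at 1e4
           registers", {
  g <- paper_grid()
  run <- random_run("big", 1e4, g, seed = 9)
  out <- normalize_sample(run, g, 1000)
  rec <- out$run$records
  inw <- rec$time >= 6 & rec$time < 17 &
    rec$mz >= 49 - 0.25 & rec$mz < 170 + 0.25
  expect_equal(mean(rec$intensity[inw]), 1000, tolerance = 1e-9)
})

test_that("accumulation assigns registers to half-open bins", {
  g <- paper_grid()
  one <- make_run("a", t = 6.1, mz = 95.1, i = 10)
  acc <- accumulate(one, g)
  target <- node_info(g, which(acc$values > 0))
  expect_equal(target$time_lo, 6)
  expect_equal(target$time_hi, 6 + 1/3)
  expect_equal(target$mass_center, 95)
  expect_equal(acc$values[target$node_index], 10)

  # t = 17.0 exactly is outside the half-open [6, 17) coverage
  edge <- make_run("b", t = 17, mz = 95, i = 10)
  acc2 <- accumulate(edge, g)
  expect_equal(sum(acc2$values), 0)
  expect_equal(acc2$dropped, 1L)

  # mz exactly on a shared bin boundary belongs to the window it opens
  bnd <- make_run("c", t = c(6.1, 6.1), mz = c(95.25, 95.2499), i = c(1, 2))
  acc3 <- accumulate(bnd, g)
  info <- node_info(g, which(acc3$values > 0))
  expect_equal(info$mass_center[acc3$values[info$node_index] == 1], 95.5)
  expect_equal(info$mass_center[acc3$values[info$node_index] == 2], 95.0)
})

test_that("a narrow mass radius drops registers falling between windows", {
  g <- build_grid(0, 10, 1, 50, 60, 1, mass_radius = 0.25)
  run <- make_run("a", t = c(1, 1), mz = c(55.1, 55.5), i = c(3, 7))
  acc <- accumulate(run, g)
  expect_equal(sum(acc$values), 3)
  expect_equal(acc$dropped, 1L)
})

test_that("binning conserves intensity and partitions in-window registers", {
  g <- build_grid(5, 9, 0.5, 60, 80, 1)
  run <- random_run("r", 2000, g, seed = 21)
  run$records$time <- runif(2000, 4, 10)   # include out-of-window mass too
  run$records$mz <- runif(2000, 55, 85)
  acc <- accumulate(run, g)

  # independent double-loop assignment
  brute <- numeric(g$n_nodes)
  dropped <- 0L
  centers <- mass_centers(g)
  edges <- time_edges(g)
  for (i in seq_len(2000)) {
    t <- run$records$time[i]; m <- run$records$mz[i]
    tb <- which(t >= edges[-length(edges)] & t < edges[-1L])
    mb <- which(m >= centers - 0.5 & m < centers + 0.5)
    if (length(tb) == 1L && length(mb) == 1L) {
      nd <- (tb - 1L) * g$n_mass + mb
      brute[nd] <- brute[nd] + run$records$intensity[i]
    } else dropped <- dropped + 1L
  }
  expect_equal(acc$values, brute, tolerance = 1e-12)
  expect_equal(acc$dropped, dropped)
  inw <- !is.na(ssir:::.assign_nodes(run$records$time, run$records$mz, g))
  expect_equal(sum(acc$values), sum(run$records$intensity[inw]),
               tolerance = 1e-12)
})

test_that("node matrix rows are invariant to per-sample global rescaling", {
  g <- paper_grid()
  r1 <- random_run("a", 800, g, seed = 31)
  r2 <- r1
  r2$records$intensity <- r2$records$intensity * 137.5
  nm <- node_matrix(list(r1), g)
  nm2 <- node_matrix(list(r2), g)
  expect_equal(nm$values, nm2$values, tolerance = 1e-9)
  expect_equal(nm2$norm_factors[["a"]], nm$norm_factors[["a"]] / 137.5,
               tolerance = 1e-9)
})

test_that("node matrix validates ids and persists with labels", {
  g <- build_grid(0, 2, 1, 50, 51, 1)
  r <- make_run("dup", 1, 50, 5)
  expect_error(node_matrix(list(r, r), g), "duplicate sample_id")
  nm <- node_matrix(list(make_run("a", 1, 50, 5), make_run("b", 1, 51, 7)), g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_node_matrix(nm, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(back$sample_id, c("a", "b"))
  expect_equal(names(back)[-1L], node_labels(g))
  expect_true(file.exists(paste0(f, ".sidecar")))
})
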