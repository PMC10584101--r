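test_that("petal tracing finds circular runs, including wrap-around", {
  n <- 256L
  d <- rep(0.1, n)
  expect_length(trace_petals(d, 0.75), 0L)

  d[10:20] <- 0.9
  d[c(250:256, 1:5)] <- 0.85
  ps <- trace_petals(d, 0.75)
  expect_length(ps, 2L)
  expect_equal(ps[[1]]$start, 10L); expect_equal(ps[[1]]$end, 20L)
  expect_equal(ps[[1]]$width, 11L)
  expect_equal(ps[[2]]$start, 250L); expect_equal(ps[[2]]$end, 5L)
  expect_equal(ps[[2]]$width, 12L)
  expect_equal(ps[[2]]$indices, c(250:256, 1:5))

  full <- trace_petals(rep(0.9, n), 0.75)
  expect_length(full, 1L)
  expect_equal(full[[1]]$width, n)

  expect_error(trace_petals(d, 0), "strictly inside")
  expect_error(trace_petals(d, 1), "strictly inside")
})

test_that("exceedance is strict: points equal to tau are outside petals", {
  d <- c(0.75, 0.76, 0.75, 0.8, 0.2, 0.2)
  ps <- trace_petals(d, 0.75)
  expect_equal(vapply(ps, `[[`, integer(1), "start"), c(2L, 4L))
  expect_true(all(vapply(ps, `[[`, integer(1), "width") == 1L))
})

test_that("petal tracer agrees with the doubled-sequence brute-force oracle", {
  set.seed(20)
  for (rep_ in 1:1000) {
    n <- sample(c(8L, 16L, 32L), 1)
    d <- random_decay(n, smooth = sample(0:2, 1))
    tau <- runif(1, 0.2, 0.8)
    got <- trace_petals(d, tau)
    want <- oracle_petals(d, tau)
    got_k <- sort(vapply(got, function(p) paste(p$start, p$width), ""))
    want_k <- sort(vapply(want, function(p) paste(p[["start"]], p[["len"]]), ""))
    if (!identical(got_k, want_k))
      fail(sprintf("tracer/oracle mismatch at rep %d (n=%d, tau=%.3f)",
                   rep_, n, tau))
  }
  succeed()
})

test_that("petal widths and gaps tile the circle", {
  set.seed(21)
  for (rep_ in 1:200) {
    n <- 32L
    d <- random_decay(n, smooth = 1L)
    tau <- runif(1, 0.3, 0.7)
    ps <- trace_petals(d, tau)
    if (length(ps) == 0L) next
    covered <- sum(vapply(ps, `[[`, integer(1), "width"))
    expect_equal(covered, sum(d > tau))
    # members are pairwise disjoint
    all_idx <- unlist(lapply(ps, `[[`, "indices"))
    expect_false(anyDuplicated(all_idx) > 0)
  }
})

test_that("widest petal maximizes width with decay-then-position tie-breaks", {
  mk <- function(start, width, sum_decay)
    list(start = start, end = start + width - 1L, width = width,
         indices = seq.int(start, start + width - 1L), sum_decay = sum_decay)
  expect_equal(widest_petal(list(mk(1L, 5L, 4), mk(20L, 40L, 30),
                                 mk(100L, 12L, 10)))$width, 40L)
  expect_null(widest_petal(list()))
  # width tie: larger summed decay wins
  expect_equal(widest_petal(list(mk(1L, 30L, 25), mk(50L, 30L, 28)))$start, 50L)
  # full tie: smaller start index wins
  expect_equal(widest_petal(list(mk(50L, 30L, 25), mk(1L, 30L, 25)))$start, 1L)
})

test_that("weighted circular mean handles identity, symmetry and wrap", {
  expect_equal(weighted_circular_mean(123, 1), 123)
  expect_lt(circ_diff(weighted_circular_mean(c(350, 10), c(1, 1)), 0), 1e-10)
  expect_equal(weighted_circular_mean(c(30, 90), c(1, 1)), 60)
  # heavier weight pulls the mean
  expect_lt(weighted_circular_mean(c(30, 90), c(3, 1)), 60)
  expect_error(weighted_circular_mean(c(0, 180), c(1, 1)), "undefined")
  expect_error(weighted_circular_mean(c(1, 2), 1), "equal length")
  expect_error(weighted_circular_mean(numeric(0), numeric(0)), "positive weight")
})

test_that("decay summary composes the directional indices", {
  n <- 256L
  none <- summarize_decay(rep(0.2, n), 0.75)
  expect_equal(none$nu, 0L); expect_equal(none$Lambda, 0)
  expect_true(is.na(none$mu_star) && is.na(none$lambda_star))
  expect_null(none$pi_star)

  d <- rep(0.2, n); d[100:149] <- 0.9; d[200:204] <- 0.8
  s <- summarize_decay(d, 0.75)
  expect_equal(s$nu, 2L)
  expect_equal(s$lambda_star, 50 / 256)
  expect_equal(s$Lambda, 55 / 256)
  expect_equal(s$theta_s, 100L); expect_equal(s$theta_t, 149L)

  single <- replace(rep(0.1, n), 42, 0.95)
  s1 <- summarize_decay(single, 0.75)
  expect_equal(s1$lambda_star, 1 / 256)
  expect_equal(s1$mu_star, grid_angles(n)[42])

  all_up <- summarize_decay(replace(rep(0.9, n), 1, 0.95), 0.75)
  expect_equal(all_up$nu, 1L)
  expect_equal(all_up$lambda_star, 1); expect_equal(all_up$Lambda, 1)
})

test_that("a full-circle petal with uniform decay has no defined direction", {
  expect_warning(s <- summarize_decay(rep(0.9, 16), 0.75), "degenerate")
  expect_true(is.na(s$mu_star))
  expect_equal(s$Lambda, 1)
})

test_that("local loss never exceeds global loss on random sequences", {
  set.seed(22)
  bad <- 0L
  for (rep_ in 1:10000) {
    d <- runif(24)
    s <- summarize_decay(d, 0.75)
    ok <- s$Lambda >= 0 && s$Lambda <= 1 &&
      ((s$Lambda == 0) == (s$nu == 0L)) &&
      (s$nu == 0L || (s$lambda_star > 0 && s$lambda_star <= s$Lambda + 1e-15))
    if (!ok) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("mu* is equivariant under rotation of the decay sequence", {
  set.seed(23)
  n <- 64L
  d <- replace(random_decay(n, 2L) * 0.5, 10:20, 0.9)
  s0 <- summarize_decay(d, 0.75)
  for (k in c(1L, 7L, 33L, 63L)) {
    dk <- d[((seq_len(n) - 1L - k) %% n) + 1L]   # rotate forward by k points
    sk <- summarize_decay(dk, 0.75)
    expect_lt(circ_diff(sk$mu_star, (s0$mu_star + k * 360 / n) %% 360), 1e-8)
  }
})

test_that("mu* of a symmetric petal is its geometric centre", {
  n <- 360L
  d <- rep(0.1, n)
  centre <- 120L                       # index; angle (120-1)*1 = 119 deg
  half <- 15L
  idx <- (centre - half):(centre + half)
  d[idx] <- 0.8 + 0.15 * exp(-abs(idx - centre) / 8)   # symmetric bump
  s <- summarize_decay(d, 0.75)
  expect_equal(s$mu_star, grid_angles(n)[centre], tolerance = 1e-10)
})

test_that("per-eye summary table has one row per eye", {
  fx_vals <- matrix(runif(3 * 16, 0, 1), 3, 16)
  d <- structure(list(quantile = 1 - fx_vals, decay = fx_vals,
                      meta = data.frame(eye_id = c("a", "b", "c")),
                      n_points = 16L),
                 class = "decay_set")
  tab <- summarize_decay(d, 0.5)
  expect_equal(nrow(tab), 3L)
  expect_identical(names(tab), c("eye_id", "tau", "nu", "theta_s", "theta_t",
                                 "mu_star", "lambda_star", "Lambda"))
})
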