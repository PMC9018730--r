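test_that("state deltas follow the error-correction arithmetic", {
  spec <- ngc_spec(c(2, 2, 2, 2), phi = "identity",
                   error_type = "type2_learned")
  params <- ngc_init(spec, seed = 1)
  params$E <- list(diag(2), diag(2), diag(2))
  st <- ngc_state(spec, c(1, 0))
  st <- ngc_errors(spec, params, ngc_project_all(spec, params, st))
  # zero errors -> zero deltas
  st0 <- st
  for (l in 1:3) st0$e[[l]] <- matrix(0, 2, 1)
  for (l in 1:3)
    expect_equal(max(abs(ngc_state_delta(spec, params, st0, l))), 0)
  # identity E, hand arithmetic on a middle layer: delta = E e_{l-1} - e_l
  st$e[[2]] <- matrix(c(1, 2), 2, 1)
  st$e[[3]] <- matrix(c(1, 1), 2, 1)
  expect_equal(as.numeric(ngc_state_delta(spec, params, st, 2)), c(0, 1))
})

test_that("lateral pressure splits inhibition and self-excitation", {
  # null matrix recovers the lateral-free update exactly
  expect_equal(apply_lateral(matrix(0, 3, 3), matrix(1:3, 3, 1)),
               matrix(0, 3, 1))
  # 2 neurons, one group, inhibition 1, self-excitation 1, z = (2, 0):
  # neuron 1 gets -2 (pressure subtracted -> net +2 self), neuron 2 gets +2
  V <- matrix(1, 2, 2)
  p <- apply_lateral(V, matrix(c(2, 0), 2, 1))
  expect_equal(as.numeric(p), c(-2, 2))
  expect_error(apply_lateral(matrix(0, 2, 3), matrix(0, 2, 1)), "square")
})

test_that("group competition sharpens a within-group winner", {
  spec <- ngc_spec(c(8, 6), phi = "relu", error_type = "type2_learned",
                   lateral_mode = "group_competition", group_size = 3)
  wins <- 0L
  for (trial in 1:50) {
    set.seed(100 + trial)
    params <- ngc_init(spec)
    x <- matrix(rbinom(8, 1, 0.5), 8, 1)
    st <- ngc_settle(spec, params, x, settle_config(), record = FALSE)$state
    z <- abs(as.numeric(st$z[[2]]))
    ok <- TRUE
    for (g in 1:2) {
      zg <- z[((g - 1) * 3 + 1):(g * 3)]
      if (!(max(zg) > mean(zg))) ok <- FALSE
    }
    if (ok) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("a zero-weight sigmoid network settles at e0 = x - 0.5", {
  spec <- ngc_spec(c(4, 3, 2), error_type = "type2_learned")
  params <- ngc_init(spec, seed = 1, init_sd = 0, normalize = FALSE)
  x <- c(1, 0, 1, 1)
  res <- ngc_settle(spec, params, x, settle_config(n_steps = 10))
  expect_equal(as.numeric(res$state$e[[1]]), x - 0.5)
  for (l in 1:2) expect_equal(max(abs(res$state$z[[l + 1]])), 0)
})

test_that("beta = 0 settling is the identity on states", {
  toy <- type1_toy(c(6, 5, 4))
  x <- rbinom(6, 1, 0.5)
  res <- ngc_settle(toy$spec, toy$params, x,
                    settle_config(beta = 0, n_steps = 5), record = FALSE)
  for (l in 1:2) expect_equal(max(abs(res$state$z[[l + 1]])), 0)
  expect_identical(res$state$z[[1]], matrix(as.numeric(x), 6, 1))
})

test_that("one settling step equals one application of the update formula", {
  toy <- type1_toy(c(6, 5, 4))
  cfg <- settle_config(beta = 0.1, gamma = 0.01, n_steps = 1)
  x <- matrix(rbinom(6, 1, 0.5), 6, 1)
  res <- ngc_settle(toy$spec, toy$params, x, cfg, record = FALSE)
  # manual single Jacobi step from the fresh state
  st <- ngc_errors(toy$spec, toy$params,
                   ngc_project_all(toy$spec, toy$params, ngc_state(toy$spec, x)))
  for (l in 1:2) {
    zl <- st$z[[l + 1]] +
      cfg$beta * (ngc_state_delta(toy$spec, toy$params, st, l) -
                    cfg$gamma * st$z[[l + 1]])
    expect_equal(res$state$z[[l + 1]], zl, tolerance = 1e-15)
  }
})

test_that("clamped data entries are bit-identical after settling", {
  toy <- type1_toy(c(9, 5))
  x <- matrix(rbinom(9, 1, 0.5), 9, 1)
  res <- ngc_settle(toy$spec, toy$params, x, settle_config(), record = FALSE)
  expect_identical(res$state$z[[1]], x * 1)
  # partial clamping in completion mode: observed entries still exact
  m <- matrix(c(rep(1, 5), rep(0, 4)), 9, 1)
  res2 <- ngc_settle(toy$spec, toy$params, x, settle_config(), clamp = m,
                     update_output = TRUE, record = FALSE)
  expect_identical(res2$state$z[[1]][m == 1], x[m == 1] * 1)
})

test_that("settling is deterministic and guards against divergence", {
  toy <- type1_toy(c(6, 5, 4))
  x <- rbinom(6, 1, 0.5)
  r1 <- ngc_settle(toy$spec, toy$params, x, settle_config())
  r2 <- ngc_settle(toy$spec, toy$params, x, settle_config())
  expect_identical(r1$state$z, r2$state$z)
  expect_identical(r1$trajectory, r2$trajectory)
  # an unbounded linear network with an oversized step diverges and aborts
  lin <- ngc_spec(c(6, 5, 4), g_out = "identity", phi = "identity",
                  error_type = "type1_transpose")
  set.seed(99)
  linp <- ngc_init(lin)
  expect_error(ngc_settle(lin, linp, rnorm(6),
                          settle_config(beta = 5, n_steps = 50)),
               "diverged")
})

test_that("settling descends the quadratic energy of a Gaussian network", {
  ok <- 0L
  for (trial in 1:20) {
    set.seed(trial)
    spec <- ngc_spec(c(8, 6, 4), g_out = "identity", phi = "identity",
                     error_type = "type1_transpose",
                     precision_mode = "fixed_spherical")
    params <- ngc_init(spec)
    x <- matrix(rnorm(8), 8, 1)
    tr <- ngc_settle(spec, params, x,
                     settle_config(beta = 0.01, gamma = 0))$trajectory
    if (all(diff(tr$gauss_energy) <= 1e-10)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})
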