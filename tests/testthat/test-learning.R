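test_that("total discrepancy matches closed forms and the loop oracle", {
  # single layer, perfect-prediction Gaussian terms vanish
  spec <- ngc_spec(c(2, 2))
  params <- ngc_init(spec, seed = 1)
  st <- ngc_state(spec, c(1, 0))
  st$zbar[[1]] <- matrix(0.5, 2, 1)
  expect_equal(total_discrepancy(spec, params, st), 2 * log(0.5),
               tolerance = 1e-12)
  # hidden Gaussian terms contribute zero at z = zbar with identity precision
  toy <- type1_toy(c(5, 4, 3))
  st2 <- random_state(toy$spec, toy$params, seed = 2)
  st2$z[[2]] <- st2$zbar[[2]]
  st2 <- ngc_errors(toy$spec, toy$params,
                    ngc_project_all(toy$spec, toy$params, st2))
  st2$z[[2]] <- st2$zbar[[2]]
  st2 <- ngc_project(toy$spec, toy$params, st2, 0)
  bern <- sum(st2$z[[1]] * log(st2$zbar[[1]]) +
                (1 - st2$z[[1]]) * log(1 - st2$zbar[[1]]))
  expect_equal(total_discrepancy(toy$spec, toy$params, st2), bern,
               tolerance = 1e-12)
  # random nets match an independently coded scalar-loop evaluation
  for (seed in 1:5) {
    st3 <- random_state(toy$spec, toy$params, seed = seed)
    expect_equal(total_discrepancy(toy$spec, toy$params, st3, "sum"),
                 psi_loop_oracle(toy$spec, toy$params, st3),
                 tolerance = 1e-10)
  }
})

test_that("weight updates are the stated outer products", {
  spec <- ngc_spec(c(2, 2), phi = "identity", error_type = "type2_learned")
  params <- ngc_init(spec, seed = 1)
  st <- ngc_state(spec, c(1, 1))
  st$zbar[[1]] <- matrix(0.5, 2, 1)
  st$h[[1]] <- matrix(0, 2, 1)
  st$z[[2]] <- matrix(c(1, 1), 2, 1)
  st <- ngc_errors(spec, params, st)
  st$e[[1]] <- matrix(c(1, 0), 2, 1)
  upd <- ngc_weight_updates(spec, params, st)
  expect_equal(upd$dW[[1]], matrix(c(1, 0, 1, 0), 2, 2))
  st$e[[1]] <- matrix(0, 2, 1)
  expect_equal(max(abs(ngc_weight_updates(spec, params, st)$dW[[1]])), 0)
})

test_that("weight updates are local: only e_l and z_{l+1} matter", {
  spec <- ngc_spec(c(6, 5, 4, 3), phi = "tanh", error_type = "type2_learned")
  set.seed(5)
  params <- ngc_init(spec)
  st <- random_state(spec, params, seed = 6)
  base <- ngc_weight_updates(spec, params, st)$dW[[2]]
  # perturb every OTHER layer's activity while holding e^1 and z^2 fixed
  st2 <- st
  st2$z[[1]] <- 1 - st2$z[[1]]
  st2$z[[4]] <- st2$z[[4]] + 5
  pert <- ngc_weight_updates(spec, params, st2)$dW[[2]]
  expect_identical(base, pert)
})

test_that("error-synapse updates follow the transpose identity", {
  spec <- ngc_spec(c(4, 3, 2), phi = "tanh", error_type = "type2_learned")
  set.seed(8)
  params <- ngc_init(spec)
  st <- random_state(spec, params, seed = 9)
  # lambda = 0 gives no update
  dE0 <- ngc_error_update(spec, params, st, 0)
  expect_equal(max(abs(dE0[[1]])), 0)
  # hand arithmetic: lambda 0.5, phi(z) = (2,0), e = (1,1)
  spec1 <- ngc_spec(c(2, 2), phi = "identity", error_type = "type2_learned")
  params1 <- ngc_init(spec1, seed = 1)
  st1 <- ngc_state(spec1, c(1, 1))
  st1$zbar[[1]] <- matrix(0.5, 2, 1)
  st1$z[[2]] <- matrix(c(2, 0), 2, 1)
  st1 <- ngc_errors(spec1, params1, st1)
  st1$e[[1]] <- matrix(c(1, 1), 2, 1)
  expect_equal(ngc_error_update(spec1, params1, st1, 0.5)[[1]],
               matrix(c(1, 0, 1, 0), 2, 2))
  # dE = lambda t(dW) from any shared state
  lam <- 0.7
  dW <- ngc_weight_updates(spec, params, st)$dW
  dE <- ngc_error_update(spec, params, st, lam)
  for (l in 1:2) expect_equal(dE[[l]], lam * t(dW[[l]]), tolerance = 1e-14)
  # Type-1 models refuse error-synapse updates
  toy <- type1_toy(c(4, 3))
  st3 <- random_state(toy$spec, toy$params, seed = 2)
  expect_error(ngc_error_update(toy$spec, toy$params, st3, 0.5), "virtual")
})

test_that("precision updates are stationary at the empirical covariance", {
  spec <- ngc_spec(c(4, 3, 3), phi = "identity",
                   error_type = "type2_learned", precision_mode = "learned")
  set.seed(10)
  params <- ngc_init(spec)
  st <- random_state(spec, params, seed = 11)
  # craft a batch whose mismatch second moment equals the current Sigma = I:
  # columns sqrt(3) * e_b give (1/3) sum 3 e_b e_b' = I
  B <- 3L
  st$z[[1]] <- matrix(rbinom(4 * B, 1, 0.5), 4, B)
  st$zbar[[1]] <- matrix(0.5, 4, B)
  st$z[[2]] <- matrix(0, 3, B)
  st$zbar[[2]] <- -sqrt(3) * diag(1, 3)
  st$z[[3]] <- matrix(0, 3, B)
  p2 <- ngc_precision_update(spec, params, st, lr = 0.1)
  expect_equal(p2$Prec[[1]], params$Prec[[1]], tolerance = 1e-12)
})

test_that("fixed spherical precisions are never updated", {
  toy <- type1_toy(c(5, 4, 3))
  st <- random_state(toy$spec, toy$params, seed = 3)
  p2 <- ngc_precision_update(toy$spec, toy$params, st, lr = 0.5)
  expect_identical(p2$Prec, toy$params$Prec)
})

test_that("iterated precision updates recover a known mismatch covariance", {
  spec <- ngc_spec(c(4, 3, 3), phi = "identity",
                   error_type = "type2_learned", precision_mode = "learned")
  set.seed(12)
  params <- ngc_init(spec)
  Cstar <- crossprod(matrix(rnorm(9), 3, 3)) / 3 + diag(0.5, 3)
  R <- chol(Cstar)
  B <- 2000L
  dist <- numeric(101)
  for (step in 0:100) {
    Sigma <- chol2inv(chol(params$Prec[[1]]))
    dist[step + 1] <- sqrt(sum((Sigma - Cstar)^2))
    if (step == 100) break
    st <- ngc_state(spec, matrix(rbinom(4 * B, 1, 0.5), 4, B))
    st$zbar[[1]] <- matrix(0.5, 4, B)
    st$h[[1]] <- matrix(0, 4, B)
    st$z[[2]] <- t(R) %*% matrix(rnorm(3 * B), 3, B)
    st$zbar[[2]] <- matrix(0, 3, B)
    st$z[[3]] <- matrix(0, 3, B)
    params <- ngc_precision_update(spec, params, st, lr = 0.2)
  }
  expect_lt(dist[101], 0.1 * dist[1])
  # distance shrinks essentially monotonically; near the fixed point the
  # finite-batch noise floor allows small fluctuations
  expect_true(all(diff(dist) < 0.06))
  # precisions stay symmetric positive-definite throughout
  P <- params$Prec[[1]]
  expect_equal(P, t(P))
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("column normalization rescales exactly and is idempotent", {
  spec <- ngc_spec(c(2, 2), error_type = "type2_learned")
  params <- ngc_init(spec, seed = 1, normalize = FALSE)
  params$W[[1]] <- matrix(c(3, 4, 0, 0), 2, 2)  # one zero column guard
  p2 <- normalize_columns(params)
  expect_equal(p2$W[[1]][, 1], c(0.6, 0.8))
  expect_equal(p2$W[[1]][, 2], c(0, 0))
  p3 <- normalize_columns(p2)
  expect_equal(p3$W[[1]], p2$W[[1]], tolerance = 1e-12)
  # invariant sweep over a random model
  set.seed(13)
  big <- ngc_init(ngc_spec(c(20, 15, 10), error_type = "type2_learned"))
  expect_lt(gncn:::max_colnorm_dev(big), 1e-9)
})

test_that("training is reproducible, validated, and a no-op at 0 epochs", {
  g <- synth_generate(120, seed = 20)
  m <- make_variant("GNCN-t1/Rao", c(16, 8), seed = 21)
  tc0 <- train_config(settle = m$settle, epochs = 0, batch_size = 40)
  expect_identical(ngc_train(m, g$X, tc0)$model$params$W, m$params$W)
  tc <- train_config(settle = m$settle, epochs = 2, batch_size = 40,
                     seed = 22)
  f1 <- ngc_train(m, g$X, tc)
  f2 <- ngc_train(m, g$X, tc)
  expect_identical(f1$model$params$W, f2$model$params$W)
  expect_identical(f1$history, f2$history)
  expect_error(ngc_train(m, g$X * 0.5, tc), "binary")
})

test_that("training reduces reconstruction BCE for all four variants", {
  g <- synth_generate(400, D = 16, J1 = 12, seed = 23)
  for (v in c("GNCN-t1/Rao", "GNCN-t1-Sigma/Friston", "GNCN-t2-LSigma",
              "GNCN-PDH")) {
    m <- make_variant(v, c(16, 12, 8), group_size = 4, seed = 24)
    tc <- train_config(settle = m$settle, epochs = 6, batch_size = 100,
                       weight_lr = 0.05, seed = 25)
    h <- ngc_train(m, g$X, tc)$history
    expect_lt(tail(h$bce, 1), h$bce[1])
    expect_lt(max(h$colnorm_dev), 1e-6)
  }
})
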