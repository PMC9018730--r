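# Shared builders and independent oracles for the test suite.

# Random small Type-1 network (tanh, E = t(W), fixed spherical precisions).
type1_toy <- function(sizes = c(6, 5, 4), seed = 7) {
  spec <- ngc_spec(sizes, phi = "tanh", error_type = "type1_transpose",
                   use_phi_derivative = TRUE,
                   precision_mode = "fixed_spherical")
  set.seed(seed)
  params <- ngc_init(spec)
  list(spec = spec, params = params)
}

# State with random (non-zero) latents, projected, with errors evaluated.
random_state <- function(spec, params, seed = 1, scale = 0.5) {
  set.seed(seed)
  x <- matrix(stats::rbinom(spec$D, 1, 0.5), spec$D, 1)
  st <- ngc_state(spec, x)
  for (l in seq_len(spec$L))
    st$z[[l + 1L]] <- matrix(stats::rnorm(spec$sizes[l + 1L], sd = scale),
                             spec$sizes[l + 1L], 1)
  ngc_errors(spec, params, ngc_project_all(spec, params, st))
}

# Independent scalar-loop evaluation of the total discrepancy: plain loops,
# no shared code with the implementation beyond the parameter lists.
psi_loop_oracle <- function(spec, params, state) {
  x <- state$z[[1L]]
  zb0 <- state$zbar[[1L]]
  total <- 0
  for (j in seq_len(nrow(x)))
    total <- total + x[j, 1] * log(zb0[j, 1]) +
      (1 - x[j, 1]) * log(1 - zb0[j, 1])
  if (spec$L >= 2L) {
    for (l in seq_len(spec$L - 1L)) {
      P <- params$Prec[[l]]
      m <- state$z[[l + 1L]] - state$zbar[[l + 1L]]
      quad <- 0
      for (i in seq_len(nrow(P)))
        for (j in seq_len(ncol(P)))
          quad <- quad + m[i, 1] * P[i, j] * m[j, 1]
      total <- total + 0.5 * log(det(P)) - 0.5 * quad
    }
  }
  total
}

# Central-difference gradient of psi w.r.t. the states of layer l.
fd_grad_z <- function(spec, params, state, l, h = 1e-5) {
  z0 <- state$z
  il <- l + 1L
  out <- z0[[il]] * 0
  for (i in seq_along(z0[[il]])) {
    zp <- z0; zp[[il]][i] <- zp[[il]][i] + h
    zm <- z0; zm[[il]][i] <- zm[[il]][i] - h
    out[i] <- (ngc_psi(spec, params, zp) - ngc_psi(spec, params, zm)) / (2 * h)
  }
  out
}

# Central-difference gradient of psi w.r.t. W[[l]].
fd_grad_W <- function(spec, params, state, l, h = 1e-5) {
  out <- params$W[[l]] * 0
  for (i in seq_along(out)) {
    pp <- params; pp$W[[l]][i] <- pp$W[[l]][i] + h
    pm <- params; pm$W[[l]][i] <- pm$W[[l]][i] - h
    out[i] <- (ngc_psi(spec, pp, state$z) - ngc_psi(spec, pm, state$z)) /
      (2 * h)
  }
  out
}

# Reconstruction BCE of a model on data (settle, then score the output mean).
recon_bce <- function(model, X, cfg = model$settle) {
  st <- ngc_settle(model$spec, model$params, X, cfg, record = FALSE)$state
  bce(X, st$zbar[[1L]])
}

# Two-layer relu Type-2 learner used by the recovery-style experiments.
relu_t2_model <- function(sizes, seed, beta = 0.1) {
  spec <- ngc_spec(sizes, phi = "relu", error_type = "type2_learned")
  gncn_model(spec, ngc_init(spec, seed = seed),
             settle_config(beta = beta))
}

# Per-record masked squared error (columns of X are records).
mmse_per_record <- function(X, Xhat, M) colSums(((Xhat - X) * (1 - M))^2)
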