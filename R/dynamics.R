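# Settling dynamics: the T-step iterative correction of latent states.

#' Settling configuration
#'
#' @param beta State learning rate `beta > 0` applied to every state update.
#' @param gamma Leak strength `gamma >= 0`; corresponds to a zero-mean
#'   Gaussian prior over the latent states (and realizes the top layer's
#'   prior, which has no top-down prediction).
#' @param lambda_prior Coefficient of the kurtotic prior pressure
#'   `-lambda * sign(z)`; only active when the spec's lateral mode is
#'   `"kurtotic_prior"`.
#' @param n_steps Number of settling iterations `T`.
#' @param lateral_form How lateral synapses enter the update: `"split"`
#'   subtracts within-group inhibition of `phi(z)` and adds the diagonal
#'   self-excitation (the explicit excitatory/inhibitory form); `"linear"`
#'   subtracts the plain matrix product `V z` (the vectorized recipe form).
#'   Both are kept as selectable modes rather than reconciled.
#' @return A `settle_config` list.
#' @export
settle_config <- function(beta = 0.1, gamma = 0.001, lambda_prior = 0,
                          n_steps = 50L, lateral_form = c("split", "linear")) {
  stopifnot(beta >= 0, gamma >= 0, lambda_prior >= 0, n_steps >= 1)
  structure(list(beta = beta, gamma = gamma, lambda_prior = lambda_prior,
                 n_steps = as.integer(n_steps),
                 lateral_form = match.arg(lateral_form)),
            class = "settle_config")
}

#' Lateral pressure from excitatory/inhibitory synapses
#'
#' Returns, for each neuron `i`, `sum_{j != i} V_ij phi(z_j) - V_ii phi(z_i)`
#' (within-group inhibition minus self-excitation). The settling update
#' subtracts this quantity, so inhibition suppresses and the diagonal excites.
#'
#' @param V Square lateral matrix.
#' @param z Activity matrix (`J x B`).
#' @param phi Activation name applied to `z`.
#' @return Matrix of lateral pressures, same shape as `z`.
#' @export
apply_lateral <- function(V, z, phi = "identity") {
  if (nrow(V) != ncol(V) || nrow(V) != nrow(as.matrix(z)))
    stop("V must be square and match the layer width", call. = FALSE)
  pz <- act_apply(phi, z)
  Voff <- V
  diag(Voff) <- 0
  Voff %*% pz - diag(V) * pz
}

#' Error-correction term of the state update
#'
#' `Delta z_1 = E_1 . (output drive) - e_1` and, for `l > 1`,
#' `Delta z_l = E_l . e_{l-1} - e_l` (the top layer has no top-down error).
#' For Type-1 variants (`use_phi_derivative`), the whole bracket is multiplied
#' elementwise by `d phi(z_l)/d z_l`.
#'
#' @param spec,params,state Model spec, parameters, and state with current
#'   errors.
#' @param l Hidden layer index, `1 <= l <= L`.
#' @param Emats Optional pre-materialized error matrices (see
#'   `error_mats`); computed on demand otherwise.
#' @return The `Delta z_l` matrix.
#' @export
ngc_state_delta <- function(spec, params, state, l, Emats = NULL) {
  if (l < 1L || l > spec$L)
    stop("state updates apply to hidden layers 1..L", call. = FALSE)
  if (is.null(Emats)) Emats <- error_mats(spec, params)
  bottom <- if (l == 1L) output_drive(spec, state) else state$e[[l]]
  # Negative-transpose error synapses belong to the convention in which error
  # units signal prediction-minus-target; the upward message flips sign so
  # that E . message still points up the likelihood gradient.
  if (spec$error_type == "type1_negative_transpose") bottom <- -bottom
  drive <- Emats[[l]] %*% bottom
  if (l <= spec$L - 1L) drive <- drive - state$e[[l + 1L]]
  if (spec$use_phi_derivative)
    drive <- act_deriv(spec$phi[l + 1L], state$z[[l + 1L]]) * drive
  drive
}

#' Settle the latent states on (a batch of) input(s)
#'
#' Runs the iterative inference: clamp the data to layer 0, zero-initialize
#' all latents, then for `T` steps (Jacobi order): project all layers
#' top-down, evaluate all error neurons, and update every hidden state
#' simultaneously with
#' `z_l <- z_l + beta (Delta z_l - lateral - gamma z_l [- lambda sign(z_l)])`.
#' When `update_output = TRUE` (pattern completion), unobserved entries of
#' layer 0 are additionally relaxed toward the top-down prediction via
#' `z0 <- x * m + (z0 - beta e0) * (1 - m)` after each latent update;
#' observed entries are preserved exactly.
#'
#' @param spec,params Model spec and parameters.
#' @param x Input matrix `D x B` (or vector), records as columns.
#' @param cfg A [settle_config()].
#' @param clamp Optional binary mask of observed entries of `x` (1 =
#'   observed). Defaults to all observed.
#' @param update_output Relax unobserved layer-0 entries (completion mode).
#' @param record Record per-step diagnostics.
#' @return List with `state` (final `ngc_state`, projections and errors
#'   refreshed) and `trajectory` (data frame with one row per step 0..T:
#'   `psi` per-record mean total discrepancy, `output_ll` the output
#'   log-likelihood term, `gauss_energy` the quadratic Gaussian mismatch
#'   energy of `-psi`, and `mean_abs_e` averaged over layers).
#' @export
ngc_settle <- function(spec, params, x, cfg = settle_config(), clamp = NULL,
                       update_output = FALSE, record = TRUE) {
  stopifnot(inherits(cfg, "settle_config"))
  state <- ngc_state(spec, x, clamp = clamp)
  x0 <- state$z[[1L]]
  m <- state$clamp
  if (update_output) state$z[[1L]] <- x0 * m + 0.5 * (1 - m)

  Emats <- error_mats(spec, params)
  traj <- if (record)
    matrix(NA_real_, cfg$n_steps + 1L, 4L,
           dimnames = list(NULL, c("step", "psi", "output_ll", "gauss_energy")))

  refresh <- function(state) {
    state <- ngc_project_all(spec, params, state)
    ngc_errors(spec, params, state)
  }
  state <- refresh(state)
  if (record) traj[1L, ] <- c(0, .psi_summary(spec, params, state))

  for (t in seq_len(cfg$n_steps)) {
    deltas <- lapply(seq_len(spec$L), function(l)
      ngc_state_delta(spec, params, state, l, Emats))
    for (l in seq_len(spec$L)) {
      il <- l + 1L
      zl <- state$z[[il]]
      upd <- deltas[[l]] - cfg$gamma * zl
      if (!is.null(params$V[[l]])) {
        lat <- if (cfg$lateral_form == "split")
          apply_lateral(params$V[[l]], zl, spec$phi[il])
        else params$V[[l]] %*% zl
        upd <- upd - lat
      }
      if (spec$lateral_mode == "kurtotic_prior" && cfg$lambda_prior > 0)
        upd <- upd - cfg$lambda_prior * sign(zl)
      state$z[[il]] <- zl + cfg$beta * upd
    }
    if (update_output) {
      z0 <- state$z[[1L]] - cfg$beta * state$e[[1L]]
      state$z[[1L]] <- x0 * m + z0 * (1 - m)
    }
    zmax <- max(vapply(state$z, function(z) max(abs(z)), numeric(1)))
    if (!is.finite(zmax) || zmax > 1e6)
      stop("settling diverged at step ", t, " (max |z| = ",
           format(zmax), "); reduce beta", call. = FALSE)
    state <- refresh(state)
    if (record) traj[t + 1L, ] <- c(t, .psi_summary(spec, params, state))
  }
  list(state = state,
       trajectory = if (record) as.data.frame(traj) else NULL)
}

# Per-step diagnostic scalars: psi, its output term, and the quadratic
# Gaussian mismatch energy of -psi (per-record means).
.psi_summary <- function(spec, params, state) {
  p <- .psi_parts(spec, params, state)
  c(mean(p$psi), mean(p$output_ll), mean(p$gauss_energy))
}
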