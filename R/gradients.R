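# Exact derivatives of the total discrepancy, used as oracles for the local
# update rules (and in their own right for analysis). These carry the full
# chain rule, including the activation-derivative factors that the Hebbian
# rules drop.

# d psi / d h_l for a predicted layer l (0..L-1): the output-likelihood
# derivative through g, or the precision-weighted mismatch for hidden layers
# (whose prediction nonlinearity is the identity).
.dpsi_dh <- function(spec, params, state, l) {
  il <- l + 1L
  if (l == 0L) {
    if (spec$output_dist == "bernoulli") {
      # g0'(h0) * (x / zbar - (1-x)/(1-zbar)) collapses to x - zbar0
      state$z[[1L]] - state$zbar[[1L]]
    } else {
      state$z[[1L]] - state$zbar[[1L]]
    }
  } else {
    params$Prec[[l]] %*% (state$z[[il]] - state$zbar[[il]])
  }
}

#' Exact gradient of the total discrepancy w.r.t. a latent state
#'
#' `d psi / d z_l = phi_l'(z_l) * (t(W_l) u_{l-1}) [+ skip path] - e_l`,
#' where `u_{l-1} = d psi / d h_{l-1}`. The top layer has no top-down error
#' term. This is the quantity the settling rule approximates with error
#' synapses; it serves as the finite-difference-checked oracle.
#'
#' @param spec,params,state Model spec, parameters, projected state with
#'   current errors.
#' @param l Hidden layer index, `1 <= l <= L`.
#' @return Gradient matrix shaped like `z_l`.
#' @export
ngc_grad_z <- function(spec, params, state, l) {
  if (l < 1L || l > spec$L) stop("l must be in 1..L", call. = FALSE)
  il <- l + 1L
  g <- t(params$W[[l]]) %*% .dpsi_dh(spec, params, state, l - 1L)
  if (spec$alpha_m == 1L && l >= 2L)
    g <- g + t(params$M[[l - 1L]]) %*% .dpsi_dh(spec, params, state, l - 2L)
  g <- act_deriv(spec$phi[il], state$z[[il]]) * g
  if (l <= spec$L - 1L)
    g <- g - params$Prec[[l]] %*% (state$z[[il]] - state$zbar[[il]])
  g
}

#' Exact gradient of the total discrepancy w.r.t. a generative matrix
#'
#' `d psi / d W_l = u_{l-1} . t(phi_l(z_l))` with
#' `u_{l-1} = d psi / d h_{l-1}`; summed over the records in the batch.
#'
#' @inheritParams ngc_grad_z
#' @return Gradient matrix shaped like `W_l`.
#' @export
ngc_grad_W <- function(spec, params, state, l) {
  if (l < 1L || l > spec$L) stop("l must be in 1..L", call. = FALSE)
  .dpsi_dh(spec, params, state, l - 1L) %*%
    t(act_apply(spec$phi[l + 1L], state$z[[l + 1L]]))
}

#' Exact gradient w.r.t. an auxiliary skip matrix
#'
#' `d psi / d M_l = u_{l-1} . t(phi_{l+1}(z_{l+1}))` (the skip path predicts
#' layer `l - 1` from layer `l + 1`).
#'
#' @inheritParams ngc_grad_z
#' @return Gradient matrix shaped like `M_l`.
#' @export
ngc_grad_M <- function(spec, params, state, l) {
  if (spec$alpha_m != 1L || l > spec$L - 1L)
    stop("no skip matrix at layer ", l, call. = FALSE)
  .dpsi_dh(spec, params, state, l - 1L) %*%
    t(act_apply(spec$phi[l + 2L], state$z[[l + 2L]]))
}

#' Evaluate psi as a function of given latent states
#'
#' Convenience for derivative checks: installs the supplied latent states,
#' re-projects every layer, and returns the (summed) total discrepancy.
#'
#' @param spec,params Model spec and parameters.
#' @param z_list List of `L + 1` activity matrices (`z_list[[1]]` is the
#'   clamped data).
#' @return Scalar psi (summed over the batch).
#' @export
ngc_psi <- function(spec, params, z_list) {
  state <- ngc_state(spec, z_list[[1L]])
  state$z <- z_list
  state <- ngc_project_all(spec, params, state)
  sum(.psi_parts(spec, params, state)$psi)
}
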