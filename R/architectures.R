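# Named presets for the four model variants and the lateral-matrix builder.

#' Block lateral matrix for group competition
#'
#' Within each consecutive group of `K` neurons, off-diagonal entries carry
#' the inhibition coefficient and the diagonal the self-excitation
#' coefficient; neurons in different groups are not connected.
#'
#' @param J Layer width.
#' @param K Group size; must divide `J`.
#' @param self_excite,inhibit Non-negative coefficients, set a priori.
#' @return `J x J` symmetric block-diagonal matrix.
#' @export
build_group_lateral <- function(J, K, self_excite = 0.1, inhibit = 0.2) {
  if (J %% K != 0L) stop("group size K must divide the layer width J",
                         call. = FALSE)
  stopifnot(self_excite >= 0, inhibit >= 0)
  block <- matrix(inhibit, K, K)
  diag(block) <- self_excite
  V <- matrix(0, J, J)
  for (g in seq_len(J %/% K)) {
    i <- ((g - 1L) * K + 1L):(g * K)
    V[i, i] <- block
  }
  V
}

#' Construct one of the four named model variants
#'
#' * `GNCN-t1/Rao`: virtual error synapses `E = t(W)`, `gamma = 0`, fixed
#'   spherical precisions, `phi = tanh`, activation-derivative-modulated
#'   settling -- the classical hierarchical predictive coding network.
#' * `GNCN-t1-Sigma/Friston`: `E = -t(W)`, `gamma = 0`, `phi = relu`, learned
#'   precisions, kurtotic sparsity prior during settling.
#' * `GNCN-t2-LSigma`: learned error synapses, learned precisions, lateral
#'   group competition on every hidden layer, derivative-free updates.
#' * `GNCN-PDH`: as t2-LSigma plus the auxiliary skip-prediction matrices
#'   (`alpha_m = 1`); requires `L >= 2`.
#'
#' The presets only configure the generic engine; their trajectories are
#' identical to a manually assembled spec with the same switches.
#'
#' @param name Variant name (see above).
#' @param layer_sizes `c(J_0, ..., J_L)`; the reference configuration uses a
#'   20-unit topmost layer and, for laterally wired variants, 20 neural
#'   columns (so `group_size` defaults to `J / 20` per layer-width 20-divisor
#'   convention; override with `group_size`).
#' @param group_size Neurons per competing group for the lateral variants;
#'   default `max(1, J_1 / 20)`.
#' @param self_excite,inhibit Lateral coefficients (free parameters; the
#'   defaults keep self-excitation weaker than within-group inhibition so the
#'   competition sharpens a winner without runaway growth).
#' @param seed,init_sd,sigma2 Passed to [ngc_init()] / [ngc_spec()].
#' @param beta,gamma,lambda_prior,n_steps Settling defaults bundled with the
#'   model (`gamma` is forced to 0 for the Type-1 presets).
#' @return A `gncn` model with a default settle configuration attached.
#' @export
make_variant <- function(name = c("GNCN-t1/Rao", "GNCN-t1-Sigma/Friston",
                                  "GNCN-t2-LSigma", "GNCN-PDH"),
                         layer_sizes, group_size = NULL,
                         self_excite = 0.1, inhibit = 0.2,
                         seed = NULL, init_sd = 0.05, sigma2 = 1,
                         beta = 0.1, gamma = 0.001, lambda_prior = 0.01,
                         n_steps = 50L) {
  name <- match.arg(name)
  J1 <- layer_sizes[2L]
  if (is.null(group_size)) group_size <- max(1L, J1 %/% 20L)

  spec <- switch(
    name,
    "GNCN-t1/Rao" = ngc_spec(layer_sizes, phi = "tanh",
                             error_type = "type1_transpose",
                             use_phi_derivative = TRUE,
                             precision_mode = "fixed_spherical",
                             sigma2 = sigma2),
    "GNCN-t1-Sigma/Friston" = ngc_spec(layer_sizes, phi = "relu",
                                       error_type = "type1_negative_transpose",
                                       lateral_mode = "kurtotic_prior",
                                       use_phi_derivative = TRUE,
                                       precision_mode = "learned"),
    "GNCN-t2-LSigma" = ngc_spec(layer_sizes, phi = "relu",
                                error_type = "type2_learned",
                                lateral_mode = "group_competition",
                                group_size = group_size,
                                precision_mode = "learned"),
    "GNCN-PDH" = ngc_spec(layer_sizes, phi = "relu", alpha_m = 1L,
                          error_type = "type2_learned",
                          lateral_mode = "group_competition",
                          group_size = group_size,
                          precision_mode = "learned"))

  params <- ngc_init(spec, seed = seed, init_sd = init_sd,
                     self_excite = self_excite, inhibit = inhibit)
  t1 <- name %in% c("GNCN-t1/Rao", "GNCN-t1-Sigma/Friston")
  cfg <- settle_config(beta = beta,
                       gamma = if (t1) 0 else gamma,
                       lambda_prior = if (name == "GNCN-t1-Sigma/Friston")
                         lambda_prior else 0,
                       n_steps = n_steps)
  gncn_model(spec, params, settle = cfg)
}
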