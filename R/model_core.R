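# Core data model of a generative neural coding network (GNCN).
#
# Indexing conventions used throughout the package
# ------------------------------------------------
# Layers are numbered 0..L, layer 0 being the sensory/output layer clamped to
# the data. R lists are 1-based, so layer l lives at list slot l + 1:
#   sizes[l + 1]   = J_l, the width of layer l
#   z[[l + 1]]     = J_l x B activity matrix (records as columns)
#   zbar[[l + 1]], h[[l + 1]], e[[l + 1]]  exist for predicted layers l = 0..L-1
# Synapses are indexed by their source layer:
#   W[[l]] (l = 1..L)    J_{l-1} x J_l   generative, predicts layer l-1 from l
#   E[[l]] (l = 1..L)    J_l x J_{l-1}   error feedback, carries e^{l-1} up
#   M[[l]] (l = 1..L-1)  J_{l-1} x J_{l+1}  auxiliary skip prediction (PDH)
#   V[[l]] (l = 1..L)    J_l x J_l       lateral synapses on hidden layer l
#   Prec[[l]] (l = 1..L-1)  J_l x J_l    precision (inverse covariance) of the
#                                        Gaussian mismatch at hidden layer l
# The top layer L carries no top-down prediction; its zero-mean Gaussian prior
# is realized by the leak term of the settling dynamics.

#' Describe a GNCN architecture
#'
#' A model specification records the layer widths, the per-layer activation
#' choices, and the structural switches that distinguish the model variants:
#' the auxiliary skip-prediction path (`alpha_m`), how error-feedback synapses
#' are obtained, and the lateral wiring used to induce sparse codes.
#'
#' @param layer_sizes Integer vector `c(J_0, J_1, ..., J_L)`, `J_0` being the
#'   data dimensionality. `L >= 1` hidden layers are required.
#' @param g_out Output nonlinearity for the layer-0 prediction: `"sigmoid"`
#'   (Bernoulli output, the default for binary data) or `"identity"`
#'   (Gaussian output with identity precision).
#' @param phi State nonlinearity for hidden layers, one of `"identity"`,
#'   `"tanh"`, `"relu"`, `"signum"`; a single name (recycled) or a vector of
#'   length `L`.
#' @param alpha_m 0 or 1; 1 adds learnable skip matrices `M` that inject layer
#'   `l+2` activity into the prediction of layer `l` (the "-PDH" suffix).
#' @param error_type `"type2_learned"` (separate trainable `E`),
#'   `"type1_transpose"` (`E = t(W)`, a virtual view, never trained) or
#'   `"type1_negative_transpose"` (`E = -t(W)`).
#' @param lateral_mode `"none"`, `"kurtotic_prior"` (a `-lambda * sign(z)`
#'   pressure during settling), or `"group_competition"` (block lateral
#'   matrices `V` making groups of `group_size` neurons compete).
#' @param group_size Neurons per competing group `K`; must divide each hidden
#'   layer width when `lateral_mode = "group_competition"`.
#' @param use_phi_derivative Logical; Type-1 settling multiplies the
#'   error-correction bracket elementwise by `d phi(z)/d z`, Type-2 omits all
#'   activation derivatives.
#' @param precision_mode `"learned"` (full precision matrices adapted during
#'   training) or `"fixed_spherical"` (`(1/sigma2) * I`, never updated).
#' @param sigma2 Variance of the fixed spherical mismatch model.
#' @param simplified_e0 Logical; with a sigmoid output the layer-0 error
#'   neurons simplify to `x - zbar0`, which is the default for training. The
#'   raw Bernoulli ratio form is kept for oracle checks.
#' @return An object of class `ngc_spec`.
#' @export
ngc_spec <- function(layer_sizes,
                     g_out = c("sigmoid", "identity"),
                     phi = "tanh",
                     alpha_m = 0L,
                     error_type = c("type2_learned", "type1_transpose",
                                    "type1_negative_transpose"),
                     lateral_mode = c("none", "kurtotic_prior",
                                      "group_competition"),
                     group_size = NULL,
                     use_phi_derivative = FALSE,
                     precision_mode = c("learned", "fixed_spherical"),
                     sigma2 = 1,
                     simplified_e0 = TRUE) {
  g_out <- match.arg(g_out)
  error_type <- match.arg(error_type)
  lateral_mode <- match.arg(lateral_mode)
  precision_mode <- match.arg(precision_mode)

  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop("layer_sizes must list J_0..J_L with L >= 1 and all sizes >= 1",
         call. = FALSE)
  L <- length(layer_sizes) - 1L

  if (length(phi) == 1L) phi <- rep(phi, L)
  if (length(phi) != L)
    stop("phi must have one entry per hidden layer (", L, ")", call. = FALSE)
  for (p in phi) ngc_act(p)

  alpha_m <- as.integer(alpha_m)
  if (!alpha_m %in% c(0L, 1L)) stop("alpha_m must be 0 or 1", call. = FALSE)
  if (alpha_m == 1L && L < 2L)
    stop("alpha_m = 1 requires L >= 2 (the skip path references layer l+2)",
         call. = FALSE)

  if (lateral_mode == "group_competition") {
    if (is.null(group_size))
      stop("group_competition requires group_size", call. = FALSE)
    group_size <- as.integer(group_size)
    bad <- layer_sizes[-1L] %% group_size != 0L
    if (any(bad))
      stop("group_size must divide every hidden layer width; offending ",
           "layers: ", paste(which(bad), collapse = ", "), call. = FALSE)
  }

  structure(list(
    sizes = layer_sizes,
    L = L,
    D = layer_sizes[1L],
    g = c(g_out, rep("identity", L - 1L)),  # prediction nonlinearity, layers 0..L-1
    phi = c("identity", phi),               # state nonlinearity, layers 0..L (slot 1 unused)
    alpha_m = alpha_m,
    error_type = error_type,
    lateral_mode = lateral_mode,
    group_size = group_size,
    use_phi_derivative = isTRUE(use_phi_derivative),
    precision_mode = precision_mode,
    sigma2 = sigma2,
    simplified_e0 = isTRUE(simplified_e0),
    output_dist = if (g_out == "sigmoid") "bernoulli" else "gaussian"
  ), class = "ngc_spec")
}

#' @export
print.ngc_spec <- function(x, ...) {
  cat("GNCN architecture: layers (", paste(x$sizes, collapse = ", "), ")\n",
      sep = "")
  cat("  output:", x$g[1L], "| phi:", paste(x$phi[-1L], collapse = ","),
      "| error synapses:", x$error_type, "\n")
  cat("  lateral:", x$lateral_mode,
      if (x$lateral_mode == "group_competition")
        paste0("(K = ", x$group_size, ")") else "",
      "| alpha_m:", x$alpha_m,
      "| precision:", x$precision_mode, "\n")
  invisible(x)
}

#' Initialize the synaptic matrices of a GNCN
#'
#' Generative (and, for Type-2 models, error) synapses are drawn from a
#' zero-mean Gaussian and then column-normalized to unit Euclidean norm.
#' Precision matrices start at the identity (or `(1/sigma2) I` when fixed).
#' Group-competition lateral matrices are built from the a-priori
#' self-excitation / inhibition coefficients.
#'
#' @param spec An `ngc_spec`.
#' @param seed Optional integer seed for the weight draw.
#' @param init_sd Standard deviation of the Gaussian initializer.
#' @param normalize Column-normalize `W` (and `M`) after the draw.
#' @param self_excite,inhibit Lateral coefficients used when the spec asks for
#'   group competition.
#' @param prec_floor Smallest admissible eigenvalue of any precision matrix.
#' @return An object of class `ngc_params` with elements `W`, `E` (Type-2
#'   only; Type-1 error synapses are virtual views of `W`), `M`, `V`, `Prec`.
#' @export
ngc_init <- function(spec, seed = NULL, init_sd = 0.05, normalize = TRUE,
                     self_excite = 0.1, inhibit = 0.2, prec_floor = 1e-4) {
  stopifnot(inherits(spec, "ngc_spec"))
  if (!is.null(seed)) set.seed(seed)
  sz <- spec$sizes
  L <- spec$L

  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = init_sd), r, c)

  W <- lapply(seq_len(L), function(l) rmat(sz[l], sz[l + 1L]))
  E <- if (spec$error_type == "type2_learned")
    lapply(seq_len(L), function(l) rmat(sz[l + 1L], sz[l])) else NULL
  M <- if (spec$alpha_m == 1L)
    lapply(seq_len(L - 1L), function(l) rmat(sz[l], sz[l + 2L])) else NULL

  V <- vector("list", L)
  if (spec$lateral_mode == "group_competition") {
    for (l in seq_len(L))
      V[[l]] <- build_group_lateral(sz[l + 1L], spec$group_size,
                                    self_excite = self_excite,
                                    inhibit = inhibit)
  }

  Prec <- if (L >= 2L) lapply(seq_len(L - 1L), function(l) {
    if (spec$precision_mode == "fixed_spherical")
      diag(1 / spec$sigma2, sz[l + 1L])
    else
      diag(1, sz[l + 1L])
  }) else list()

  p <- structure(list(W = W, E = E, M = M, V = V, Prec = Prec,
                      prec_floor = prec_floor), class = "ngc_params")
  if (normalize) {
    p <- normalize_columns(p)
    # error synapses are column-normalized once at initialization only;
    # afterwards they evolve freely under their Hebbian rule
    if (!is.null(p$E))
      p$E <- lapply(p$E, function(El) {
        n <- sqrt(colSums(El^2)); n[n == 0] <- 1; sweep(El, 2L, n, "/")
      })
  }
  p
}

#' Bundle a spec and its parameters into a model object
#' @param spec An `ngc_spec`.
#' @param params Matching `ngc_params`.
#' @param settle Optional default [settle_config()] carried with the model.
#' @return An object of class `gncn`.
#' @export
gncn_model <- function(spec, params, settle = settle_config()) {
  stopifnot(inherits(spec, "ngc_spec"), inherits(params, "ngc_params"))
  check_shapes(spec, params)
  structure(list(spec = spec, params = params, settle = settle),
            class = "gncn")
}

#' @export
print.gncn <- function(x, ...) {
  print(x$spec)
  nw <- sum(vapply(x$params$W, length, numeric(1))) +
    sum(vapply(x$params$E, length, numeric(1))) +
    sum(vapply(x$params$M, length, numeric(1)))
  cat("  trainable synapses:", nw, "\n")
  invisible(x)
}

check_shapes <- function(spec, params) {
  sz <- spec$sizes
  for (l in seq_len(spec$L)) {
    if (!all(dim(params$W[[l]]) == c(sz[l], sz[l + 1L])))
      stop("W[[", l, "]] has wrong shape", call. = FALSE)
    if (!is.null(params$E) &&
        !all(dim(params$E[[l]]) == c(sz[l + 1L], sz[l])))
      stop("E[[", l, "]] has wrong shape", call. = FALSE)
  }
  if (spec$alpha_m == 1L)
    for (l in seq_len(spec$L - 1L))
      if (!all(dim(params$M[[l]]) == c(sz[l], sz[l + 2L])))
        stop("M[[", l, "]] has wrong shape", call. = FALSE)
  invisible(TRUE)
}

# Error-feedback matrices: trained for Type-2, virtual transposed views of the
# generative synapses for Type-1 (never trained, re-materialized on demand).
error_mats <- function(spec, params) {
  switch(spec$error_type,
         type2_learned = params$E,
         type1_transpose = lapply(params$W, t),
         type1_negative_transpose = lapply(params$W, function(w) -t(w)))
}

#' Create a fresh layer-state for a (batch of) record(s)
#'
#' Layer 0 is clamped to the data; every higher layer starts at zero, matching
#' the initialization step of the settling recipe.
#'
#' @param spec An `ngc_spec`.
#' @param x `D x B` matrix (records as columns), or a vector for one record.
#' @param clamp Optional binary matrix like `x`; 1 marks clamped (observed)
#'   entries of layer 0. Default: everything clamped.
#' @return An `ngc_state` list with elements `z`, `zbar`, `h`, `e`, `clamp`.
#' @export
ngc_state <- function(spec, x, clamp = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != spec$D)
    stop("x must have ", spec$D, " rows (one record per column)",
         call. = FALSE)
  B <- ncol(x)
  if (is.null(clamp)) clamp <- matrix(1, spec$D, B)
  if (!all(dim(clamp) == dim(x)))
    stop("clamp mask must match x in shape", call. = FALSE)
  z <- c(list(x),
         lapply(seq_len(spec$L), function(l) matrix(0, spec$sizes[l + 1L], B)))
  structure(list(z = z,
                 zbar = vector("list", spec$L),
                 h = vector("list", spec$L),
                 e = vector("list", spec$L),
                 clamp = clamp),
            class = "ngc_state")
}

# Clip Bernoulli means away from {0, 1} so the log-likelihood stays finite.
.eps_p <- 1e-6
clip_prob <- function(p, eps = .eps_p) pmin(pmax(p, eps), 1 - eps)

#' Layer-wise generative prediction
#'
#' Computes the mean of layer `l` from the layer(s) above:
#' `zbar_l = g_l(W_{l+1} phi(z_{l+1}) + alpha_m * M_{l+2} phi(z_{l+2}))`,
#' caching the pre-activation `h_l`. Sigmoid means are clipped into
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param spec,params,state Model spec, parameters, and current state.
#' @param l Layer index to predict, `0 <= l <= L - 1` (the top layer has no
#'   prediction).
#' @return The state with `zbar[[l + 1]]` and `h[[l + 1]]` updated.
#' @export
ngc_project <- function(spec, params, state, l) {
  if (l < 0L || l >= spec$L)
    stop("no prediction exists for layer ", l, call. = FALSE)
  il <- l + 1L
  h <- params$W[[il]] %*% act_apply(spec$phi[il + 1L], state$z[[il + 1L]])
  if (spec$alpha_m == 1L && l + 2L <= spec$L)
    h <- h + params$M[[il]] %*% act_apply(spec$phi[il + 2L], state$z[[il + 2L]])
  state$h[[il]] <- h
  zb <- act_apply(spec$g[il], h)
  if (spec$g[il] == "sigmoid") zb <- clip_prob(zb)
  state$zbar[[il]] <- zb
  state
}

#' Project every predicted layer, top-down
#' @inheritParams ngc_project
#' @return The state with all `zbar`/`h` slots updated.
#' @export
ngc_project_all <- function(spec, params, state) {
  for (l in rev(seq_len(spec$L) - 1L))
    state <- ngc_project(spec, params, state, l)
  state
}

#' Evaluate the error neurons
#'
#' Layer 0: with a sigmoid output and the simplified mode (the training
#' default), `e0 = x - zbar0`; the raw Bernoulli-ratio form
#' `x / zbar0 - (1 - x) / (1 - zbar0)` is available for oracle checks. With a
#' Gaussian (identity) output, `e0 = x - zbar0` under identity precision.
#' Hidden layers `l = 1..L-1`: `e_l = Prec_l (z_l - zbar_l)`, each layer's own
#' precision weighting its own mismatch (`convention = "own"`). The
#' `"shifted"` convention re-indexes the same quantities so that slot `l`
#' holds the layer `l - 1` error (slot 0 empty); the dynamics always consume
#' the `"own"` form.
#'
#' @param spec,params,state Model spec, parameters, and projected state.
#' @param simplified Use the sigmoid simplification for `e0`.
#' @param convention `"own"` or `"shifted"` (see above).
#' @return The state with `e` updated (for `"shifted"`, the re-indexed list is
#'   returned directly).
#' @export
ngc_errors <- function(spec, params, state, simplified = spec$simplified_e0,
                       convention = c("own", "shifted")) {
  convention <- match.arg(convention)
  x <- state$z[[1L]]
  zb0 <- state$zbar[[1L]]
  if (is.null(zb0)) stop("project layer 0 before computing errors",
                         call. = FALSE)
  if (spec$output_dist == "bernoulli" && !simplified) {
    if (any(zb0 <= 0) || any(zb0 >= 1))
      stop("zbar0 contains 0/1 without clipping; raw error form undefined",
           call. = FALSE)
    state$e[[1L]] <- x / zb0 - (1 - x) / (1 - zb0)
  } else {
    state$e[[1L]] <- x - zb0
  }
  if (spec$L >= 2L) {
    for (l in seq_len(spec$L - 1L)) {
      il <- l + 1L
      state$e[[il]] <- params$Prec[[l]] %*% (state$z[[il]] - state$zbar[[il]])
    }
  }
  if (convention == "shifted") {
    e <- vector("list", spec$L)
    for (il in seq(2L, length.out = spec$L - 1L)) e[[il]] <- state$e[[il - 1L]]
    return(e)
  }
  state
}

# Bottom-up drive entering the layer-1 state update: the derivative of the
# output likelihood w.r.t. the pre-activation h0. For a sigmoid output this
# folds g0' into the printed simplification (z0 - zbar0); for other outputs
# the explicit derivative product is used.
output_drive <- function(spec, state) {
  if (spec$output_dist == "bernoulli") {
    if (spec$simplified_e0) state$e[[1L]]
    else act_deriv("sigmoid", state$h[[1L]]) * state$e[[1L]]
  } else {
    state$e[[1L]]
  }
}
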