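# Objective, local synaptic updates, precision adaptation, normalization,
# and the online alternating-maximization training loop.

# Per-record components of the total discrepancy.
#   psi = output log-likelihood
#       + sum_{l=1}^{L-1} ( 1/2 log|Prec_l| - 1/2 m_l' Prec_l m_l )
# The log-determinant enters with a positive sign on the precision, the form
# consistent with the precision gradient (whose stationary point is the
# empirical mismatch covariance).
# gauss_energy is the quadratic Gaussian mismatch energy of -psi (including
# the output term when the output is Gaussian).
.psi_parts <- function(spec, params, state) {
  x <- state$z[[1L]]
  zb0 <- state$zbar[[1L]]
  if (spec$output_dist == "bernoulli") {
    out <- colSums(x * log(zb0) + (1 - x) * log(1 - zb0))
    gauss <- rep(0, ncol(x))
  } else {
    q0 <- colSums((x - zb0)^2)
    out <- -0.5 * q0
    gauss <- 0.5 * q0
  }
  psi <- out
  if (spec$L >= 2L) {
    for (l in seq_len(spec$L - 1L)) {
      il <- l + 1L
      P <- params$Prec[[l]]
      ld <- determinant(P, logarithm = TRUE)
      if (ld$sign <= 0) stop("precision matrix at layer ", l,
                             " is not positive-definite", call. = FALSE)
      m <- state$z[[il]] - state$zbar[[il]]
      quad <- colSums(m * (P %*% m))
      psi <- psi + 0.5 * as.numeric(ld$modulus) - 0.5 * quad
      gauss <- gauss + 0.5 * quad
    }
  }
  list(psi = psi, output_ll = out, gauss_energy = gauss)
}

#' Total discrepancy (complete-data log-likelihood)
#'
#' Sum of the output log-likelihood (Bernoulli cross-entropy term for a
#' sigmoid output, Gaussian quadratic for an identity output) and, for each
#' hidden predicted layer, the precision-weighted Gaussian mismatch term
#' `1/2 log|Prec_l| - 1/2 (z_l - zbar_l)' Prec_l (z_l - zbar_l)`. Higher is
#' better; its negation is the free-energy-style objective the settling
#' dynamics descend.
#'
#' @param spec,params,state Model spec, parameters, and a state whose
#'   projections are current (see [ngc_project()]).
#' @param aggregate `"mean"` (per-record average, default), `"sum"`, or
#'   `"per_record"`.
#' @return Scalar (or vector for `"per_record"`).
#' @export
total_discrepancy <- function(spec, params, state,
                              aggregate = c("mean", "sum", "per_record")) {
  aggregate <- match.arg(aggregate)
  psi <- .psi_parts(spec, params, state)$psi
  switch(aggregate, mean = mean(psi), sum = sum(psi), per_record = psi)
}

#' Hebbian updates for the generative (and skip) matrices
#'
#' `Delta W_l = e_{l-1} . t(phi_l(z_l))` and, when the skip path is enabled,
#' `Delta M_l = e_{l-1} . t(phi_{l+1}(z_{l+1}))` -- outer products of the
#' post-synaptic error and pre-synaptic activity, averaged over the records
#' in the batch. Layer 0 uses the folded output drive (for a sigmoid output
#' this is exactly `x - zbar0`).
#'
#' @param spec,params,state Model spec, parameters, and a settled state.
#' @return List with `dW` (length `L`) and `dM` (length `L - 1` or `NULL`).
#' @export
ngc_weight_updates <- function(spec, params, state) {
  B <- ncol(state$z[[1L]])
  esig <- function(l) if (l == 1L) output_drive(spec, state) else state$e[[l]]
  dW <- lapply(seq_len(spec$L), function(l)
    esig(l) %*% t(act_apply(spec$phi[l + 1L], state$z[[l + 1L]])) / B)
  dM <- NULL
  if (spec$alpha_m == 1L)
    dM <- lapply(seq_len(spec$L - 1L), function(l)
      esig(l) %*% t(act_apply(spec$phi[l + 2L], state$z[[l + 2L]])) / B)
  list(dW = dW, dM = dM)
}

#' Update for learned error-feedback synapses
#'
#' `Delta E_l = lambda . phi_l(z_l) . t(e_{l-1})` (batch-averaged); no
#' activation derivative is involved anywhere. Only Type-2 models carry
#' trainable error synapses.
#'
#' @param spec,params,state Model spec, parameters, and a settled state.
#' @param lambda_err Error-synapse rate `lambda` in `[0, 1]`.
#' @return List of `Delta E_l` matrices.
#' @export
ngc_error_update <- function(spec, params, state, lambda_err) {
  if (spec$error_type != "type2_learned")
    stop("error synapses are virtual views of W for Type-1 models",
         call. = FALSE)
  stopifnot(lambda_err >= 0, lambda_err <= 1)
  B <- ncol(state$z[[1L]])
  esig <- function(l) if (l == 1L) output_drive(spec, state) else state$e[[l]]
  lapply(seq_len(spec$L), function(l)
    lambda_err * (act_apply(spec$phi[l + 1L], state$z[[l + 1L]]) %*%
                    t(esig(l))) / B)
}

#' Gradient-ascent update of the precision matrices
#'
#' Each hidden layer's precision takes a step along
#' `1/2 Sigma_l - 1/2 C_l`, where `C_l` is the batch second moment of the
#' mismatch `z_l - zbar_l` and `Sigma_l` the current implied covariance; the
#' update is stationary exactly when `Sigma_l = C_l`. The result is
#' symmetrized and eigenvalue-floored to stay positive-definite. A no-op for
#' fixed spherical precisions.
#'
#' @param spec,params,state Model spec, parameters, settled state.
#' @param lr Step size.
#' @param mode `"full"` or `"diagonal"` (off-diagonal entries zeroed).
#' @return Updated `ngc_params`.
#' @export
ngc_precision_update <- function(spec, params, state, lr = 0.01,
                                 mode = c("full", "diagonal")) {
  mode <- match.arg(mode)
  if (spec$precision_mode == "fixed_spherical" || spec$L < 2L) return(params)
  B <- ncol(state$z[[1L]])
  for (l in seq_len(spec$L - 1L)) {
    il <- l + 1L
    m <- state$z[[il]] - state$zbar[[il]]
    C <- m %*% t(m) / B
    P <- params$Prec[[l]]
    Sigma <- tryCatch(chol2inv(chol(P)),
                      error = function(e) stop("precision matrix at layer ",
                                               l, " lost positive-definiteness",
                                               call. = FALSE))
    P <- P + lr * (0.5 * Sigma - 0.5 * C)
    P <- (P + t(P)) / 2
    if (mode == "diagonal") P <- diag(diag(P), nrow(P))
    ev <- eigen(P, symmetric = TRUE)
    if (min(ev$values) < params$prec_floor) {
      vals <- pmax(ev$values, params$prec_floor)
      P <- ev$vectors %*% (vals * t(ev$vectors))
      P <- (P + t(P)) / 2
    }
    params$Prec[[l]] <- P
  }
  params
}

#' Rescale every column of the generative matrices to unit norm
#'
#' Applied after each synaptic update when enabled; zero columns are left
#' untouched. Skip matrices `M` are normalized the same way; error, lateral
#' and precision matrices are not.
#'
#' @param params An `ngc_params`.
#' @return The normalized parameters.
#' @export
normalize_columns <- function(params) {
  norm1 <- function(Wl) {
    n <- sqrt(colSums(Wl^2))
    n[n == 0] <- 1
    sweep(Wl, 2L, n, "/")
  }
  params$W <- lapply(params$W, norm1)
  if (!is.null(params$M)) params$M <- lapply(params$M, norm1)
  params
}

# Largest deviation of any generative column norm from 1 (invariant probe).
max_colnorm_dev <- function(params) {
  devs <- vapply(c(params$W, params$M),
                 function(Wl) max(abs(sqrt(colSums(Wl^2)) - 1)), numeric(1))
  max(devs)
}

#' Training configuration
#'
#' @param settle A [settle_config()] governing the inference episodes.
#' @param weight_lr Synaptic step size (plain SGD).
#' @param lambda_err Error-synapse rate in `[0, 1]` (Type-2 models).
#' @param batch_size Records per update.
#' @param epochs Passes through the data.
#' @param normalize Column-normalize `W`/`M` after every update.
#' @param update_precision Adapt precisions each batch (default: whenever the
#'   spec declares them learned).
#' @param precision_lr Step size of the precision update.
#' @param seed Integer seed; fixes the batch shuffling (and hence the whole
#'   parameter trajectory).
#' @return A `train_config` list.
#' @export
train_config <- function(settle = settle_config(), weight_lr = 0.01,
                         lambda_err = 0.9, batch_size = 200L, epochs = 50L,
                         normalize = TRUE, update_precision = NULL,
                         precision_lr = 0.01, seed = NULL) {
  stopifnot(lambda_err >= 0, lambda_err <= 1, batch_size >= 1, epochs >= 0)
  structure(list(settle = settle, weight_lr = weight_lr,
                 lambda_err = lambda_err, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), normalize = isTRUE(normalize),
                 update_precision = update_precision,
                 precision_lr = precision_lr, seed = seed),
            class = "train_config")
}

#' Train a GNCN by online alternating maximization
#'
#' Each epoch shuffles the records and visits mini-batches without
#' replacement. Per batch: settle the latent states for `T` steps, apply the
#' Hebbian weight (and error-synapse, and optionally precision) updates from
#' the end-of-episode activities, then column-normalize. All randomness flows
#' from the config seed, so a fixed seed reproduces the parameter trajectory
#' bit for bit.
#'
#' @param model A `gncn` model (see [gncn_model()] / [make_variant()]).
#' @param X Binary data matrix `D x S`, records as columns (binary required
#'   for a Bernoulli output layer).
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `history`, a data frame with one
#'   row per epoch: mean reconstruction `bce`, mean `psi`, and
#'   `colnorm_dev`, the largest column-norm deviation observed after any
#'   update in that epoch.
#' @export
ngc_train <- function(model, X, cfg = train_config()) {
  stopifnot(inherits(model, "gncn"), inherits(cfg, "train_config"))
  spec <- model$spec
  params <- model$params
  X <- as.matrix(X)
  if (spec$output_dist == "bernoulli" && !all(X %in% c(0, 1)))
    stop("a Bernoulli output layer requires binary data; see binarize()",
         call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  upd_prec <- if (is.null(cfg$update_precision))
    spec$precision_mode == "learned" else isTRUE(cfg$update_precision)

  S <- ncol(X)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(S)
    starts <- seq(1L, S, by = cfg$batch_size)
    bce_acc <- psi_acc <- 0
    n_acc <- 0L
    dev <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, S)]
      xb <- X[, idx, drop = FALSE]
      st <- ngc_settle(spec, params, xb, cfg$settle, record = FALSE)$state
      upd <- ngc_weight_updates(spec, params, st)
      for (l in seq_len(spec$L))
        params$W[[l]] <- params$W[[l]] + cfg$weight_lr * upd$dW[[l]]
      if (!is.null(upd$dM))
        for (l in seq_len(spec$L - 1L))
          params$M[[l]] <- params$M[[l]] + cfg$weight_lr * upd$dM[[l]]
      if (spec$error_type == "type2_learned") {
        dE <- ngc_error_update(spec, params, st, cfg$lambda_err)
        for (l in seq_len(spec$L))
          params$E[[l]] <- params$E[[l]] + cfg$weight_lr * dE[[l]]
      }
      if (upd_prec)
        params <- ngc_precision_update(spec, params, st, lr = cfg$precision_lr)
      if (cfg$normalize) params <- normalize_columns(params)
      dev <- max(dev, max_colnorm_dev(params))

      nb <- length(idx)
      rec <- if (spec$output_dist == "bernoulli") bce(xb, st$zbar[[1L]])
      else mean(colSums((xb - st$zbar[[1L]])^2))
      bce_acc <- bce_acc + nb * rec
      psi_acc <- psi_acc + nb * total_discrepancy(spec, params, st)
      n_acc <- n_acc + nb
    }
    hist[[ep]] <- data.frame(epoch = ep, bce = bce_acc / n_acc,
                             psi = psi_acc / n_acc, colnorm_dev = dev)
  }
  model$params <- params
  list(model = model,
       history = if (cfg$epochs > 0) do.call(rbind, hist) else
         data.frame(epoch = integer(), bce = numeric(), psi = numeric(),
                    colnorm_dev = numeric()))
}
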