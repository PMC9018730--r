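# Evaluation metrics: reconstruction BCE, Monte-Carlo marginal
# log-likelihood, masked MSE, classification error / linear probe, sparsity.

#' Binary cross-entropy (negative Bernoulli log-likelihood)
#'
#' `-(1/S) sum_s sum_d [ X log Xhat + (1 - X) log(1 - Xhat) ]`, in nats:
#' summed over dimensions, averaged over records. Predictions are clipped
#' into `[1e-6, 1 - 1e-6]` before the logs.
#'
#' @param X Binary matrix `D x S` (records as columns).
#' @param Xhat Predicted mean matrix, same shape.
#' @return Scalar BCE in nats.
#' @export
bce <- function(X, Xhat) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) stop("X and Xhat shapes differ",
                                      call. = FALSE)
  Xhat <- clip_prob(Xhat)
  -mean(colSums(X * log(Xhat) + (1 - X) * log(1 - Xhat)))
}

# Numerically stable log(mean(exp(v))) column-wise over a matrix.
log_mean_exp <- function(M) {
  mx <- apply(M, 2L, max)
  mx + log(colMeans(exp(sweep(M, 2L, mx, "-"))))
}

#' Monte-Carlo estimate of the marginal log-likelihood
#'
#' Draws `n_samples` ancestral mean images from the model under its mixture
#' prior; each test record's `log p(x)` is then the (max-shifted)
#' log-mean-exp of its Bernoulli log-likelihood under each sampled mean,
#' averaged over records. The reference protocol uses 5000 samples.
#'
#' @param model,prior Model and fitted `gmm_prior` (ignored when `samples`
#'   is supplied).
#' @param X Binary test matrix `D x S`.
#' @param n_samples Number of ancestral samples.
#' @param seed Optional seed for the draws.
#' @param samples Optional precomputed `D x n` matrix of mean images.
#' @return Scalar mean `log p(x)` in nats.
#' @export
mc_log_likelihood <- function(model, prior, X, n_samples = 5000L,
                              seed = NULL, samples = NULL) {
  if (is.null(samples)) {
    if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
    samples <- ancestral_sample(model, prior, n_samples, seed = seed)
  }
  X <- as.matrix(X)
  P <- clip_prob(as.matrix(samples))
  # ll[s, j] = log P(x_j | mean_s)
  ll <- t(log(P)) %*% X + t(log(1 - P)) %*% (1 - X)
  mean(log_mean_exp(ll))
}

#' Masked mean squared error
#'
#' `((Xhat - X) * (1 - M))' ((Xhat - X) * (1 - M))` per record -- the squared
#' error restricted to the masked-out entries -- averaged over records.
#'
#' @param X,Xhat Data and completed patterns, `D x S`.
#' @param M Binary mask matrix (1 = observed; masked-out entries score).
#' @return Scalar M-MSE.
#' @export
masked_mse <- function(X, Xhat, M) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat); M <- as.matrix(M)
  if (nrow(M) == nrow(X) && ncol(M) == 1L && ncol(X) > 1L)
    M <- matrix(M, nrow(X), ncol(X))
  if (!all(dim(X) == dim(Xhat)) || !all(dim(M) == dim(X)))
    stop("shape mismatch", call. = FALSE)
  r <- (Xhat - X) * (1 - M)
  mean(colSums(r^2))
}

#' Classification error from one-hot scores
#'
#' `100 * (1 - fraction of records whose predicted argmax matches the label
#' argmax)`.
#'
#' @param Y True one-hot label matrix `C x S`.
#' @param Yhat Predicted score matrix `C x S`.
#' @return Error percentage.
#' @export
classification_error <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat shapes differ",
                                      call. = FALSE)
  yd <- apply(Y, 2L, which.max)
  yh <- apply(Yhat, 2L, which.max)
  100 * (1 - mean(yh == yd))
}

# Accept labels as a factor/vector or a one-hot matrix (C x S).
.as_label_factor <- function(y) {
  if (is.matrix(y)) factor(apply(y, 2L, which.max)) else factor(y)
}

#' Log-linear probe on latent codes
#'
#' Fits a multinomial logistic (maximum-entropy) classifier on frozen latent
#' codes and reports the classification error on held-out codes. Used to
#' quantify how much label information the top-layer representation carries;
#' no labels enter training of the generative model itself.
#'
#' @param codes_train,codes_test `J x S` code matrices (records as columns).
#' @param y_train,y_test Labels: factors, integer vectors, or one-hot
#'   matrices.
#' @param maxit Optimizer iterations.
#' @return List with `fit` (the probe), `err` (test error percentage), and
#'   `pred` (test predictions).
#' @export
linear_probe <- function(codes_train, y_train, codes_test, y_test,
                         maxit = 200L) {
  ytr <- .as_label_factor(y_train)
  yte <- .as_label_factor(y_test)
  if (nlevels(droplevels(ytr)) < 2L)
    stop("probe needs at least two classes", call. = FALSE)
  dtr <- data.frame(t(codes_train))
  dte <- data.frame(t(codes_test))
  colnames(dte) <- colnames(dtr)
  dtr$.y <- ytr
  fit <- nnet::multinom(.y ~ ., data = dtr, trace = FALSE, maxit = maxit,
                        MaxNWts = 1e5)
  pred <- stats::predict(fit, newdata = dte)
  err <- 100 * mean(as.character(pred) != as.character(yte))
  list(fit = fit, err = err, pred = pred)
}

#' Fraction of active units per layer
#'
#' Settles the network on each record and reports, per hidden layer, the
#' mean fraction of units whose state exceeds `eps` (activity is measured on
#' the state `z` itself, before any nonlinearity).
#'
#' @param model A `gncn` model.
#' @param X Data matrix `D x S`.
#' @param eps Activity threshold (reference protocol: `1e-6`).
#' @param cfg Settle configuration.
#' @return Named vector `rho_1..rho_L`.
#' @export
layer_sparsity <- function(model, X, eps = 1e-6, cfg = model$settle) {
  st <- ngc_settle(model$spec, model$params, X, cfg, record = FALSE)$state
  rho <- vapply(seq_len(model$spec$L),
                function(l) mean(st$z[[l + 1L]] > eps), numeric(1))
  names(rho) <- paste0("rho_", seq_len(model$spec$L))
  rho
}
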