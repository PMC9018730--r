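# Top-layer mixture prior, ancestral sampling, and masked pattern completion.

#' Infer top-layer codes for a set of records
#'
#' Settles the network on each record (columns of `X`) and returns the final
#' topmost state vectors.
#'
#' @param model A `gncn` model.
#' @param X Data matrix `D x S`.
#' @param cfg Settle configuration; defaults to the model's.
#' @return `J_L x S` matrix of codes.
#' @export
ngc_codes <- function(model, X, cfg = model$settle) {
  st <- ngc_settle(model$spec, model$params, X, cfg, record = FALSE)$state
  st$z[[model$spec$L + 1L]]
}

#' Fit a Gaussian mixture prior over the top-layer codes
#'
#' Collects the settled topmost activities for every record and fits a
#' `n_components`-component Gaussian mixture by expectation-maximization
#' (the reference configuration uses 75 components; reduce for small runs).
#'
#' @param model A `gncn` model (trained).
#' @param X Training data matrix `D x S`.
#' @param n_components Number of mixture components `K`.
#' @param covariance `"full"` or `"diagonal"` component covariances.
#' @param cfg Settle configuration used to obtain the codes.
#' @param codes Optionally, precomputed `J_L x S` codes (skips settling).
#' @return A `gmm_prior` with mixing weights `pi`, means `mu` (`J_L x K`)
#'   and covariances `sigma` (`J_L x J_L x K`).
#' @importFrom mclust mclustBIC
#' @export
fit_prior <- function(model, X, n_components = 75L,
                      covariance = c("full", "diagonal"),
                      cfg = model$settle, codes = NULL) {
  covariance <- match.arg(covariance)
  if (is.null(codes)) codes <- ngc_codes(model, X, cfg)
  S <- ncol(codes)
  if (n_components > S)
    stop("n_components (", n_components, ") exceeds the number of records (",
         S, ")", call. = FALSE)
  fit <- mclust::Mclust(t(codes), G = n_components,
                        modelNames = if (covariance == "full") "VVV" else "VVI",
                        verbose = FALSE)
  if (is.null(fit))
    stop("EM fit of the mixture prior failed; try fewer components or ",
         "diagonal covariances", call. = FALSE)
  pr <- fit$parameters
  sigma <- pr$variance$sigma
  # guard against numerically singular components
  d <- nrow(codes)
  for (k in seq_len(n_components)) {
    ev <- eigen(sigma[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      sigma[, , k] <- sigma[, , k] + diag(1e-10 - min(ev, 0) + 1e-12, d)
  }
  structure(list(K = n_components, pi = as.numeric(pr$pro),
                 mu = matrix(pr$mean, nrow = d),
                 sigma = sigma, loglik = fit$loglik),
            class = "gmm_prior")
}

#' Assemble a Gaussian mixture prior by hand
#'
#' Mostly useful for tests and for loading externally fitted priors;
#' [fit_prior()] is the usual constructor.
#'
#' @param pi Mixing weights (must sum to 1 within 1e-9).
#' @param mu Component means, `d x K`.
#' @param sigma Component covariances, `d x d x K` (positive-definite).
#' @return A `gmm_prior`.
#' @export
gmm_prior <- function(pi, mu, sigma) {
  mu <- as.matrix(mu)
  K <- length(pi)
  if (abs(sum(pi) - 1) > 1e-9) stop("mixing weights must sum to 1",
                                    call. = FALSE)
  stopifnot(ncol(mu) == K, dim(sigma)[3L] == K)
  for (k in seq_len(K))
    if (min(eigen(sigma[, , k], symmetric = TRUE,
                  only.values = TRUE)$values) <= 0)
      stop("component ", k, " covariance is not positive-definite",
           call. = FALSE)
  structure(list(K = K, pi = pi, mu = mu, sigma = sigma, loglik = NA_real_),
            class = "gmm_prior")
}

#' Draw top-layer codes from a fitted mixture prior
#'
#' @param prior A `gmm_prior`.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return `J_L x n` matrix.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "gmm_prior"))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(prior$K, n, replace = TRUE, prob = prior$pi)
  d <- nrow(prior$mu)
  out <- matrix(0, d, n)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    out[, idx] <- t(MASS::mvrnorm(length(idx), prior$mu[, k],
                                  prior$sigma[, , k]))
  }
  out
}

#' Ancestral sampling from the generative model
#'
#' Draws `z_L` from the mixture prior and recursively propagates the means
#' down the hierarchy (including the skip path when present); no settling is
#' involved. The returned images are the output means `zbar_0`; optional
#' per-pixel Bernoulli draws are available behind `bernoulli = TRUE`.
#'
#' @param model A `gncn` model.
#' @param prior A fitted `gmm_prior`.
#' @param n Number of samples.
#' @param seed Optional seed.
#' @param bernoulli Also draw binary pixels from the means.
#' @return `D x n` matrix of sampled means (attribute `"bernoulli"` carries
#'   the binary draws when requested).
#' @export
ancestral_sample <- function(model, prior, n, seed = NULL, bernoulli = FALSE) {
  if (!inherits(prior, "gmm_prior"))
    stop("prior must be a fitted gmm_prior; see fit_prior()", call. = FALSE)
  spec <- model$spec
  params <- model$params
  if (!is.null(seed)) set.seed(seed)
  L <- spec$L
  z <- vector("list", L + 1L)
  z[[L + 1L]] <- sample_prior(prior, n)
  for (l in rev(seq_len(L))) {
    h <- params$W[[l]] %*% act_apply(spec$phi[l + 1L], z[[l + 1L]])
    if (spec$alpha_m == 1L && l + 1L <= L)
      h <- h + params$M[[l]] %*% act_apply(spec$phi[l + 2L], z[[l + 2L]])
    zb <- act_apply(spec$g[l], h)
    if (spec$g[l] == "sigmoid") zb <- clip_prob(zb)
    z[[l]] <- zb
  }
  out <- z[[1L]]
  if (bernoulli)
    attr(out, "bernoulli") <- matrix(stats::rbinom(length(out), 1L, out),
                                     nrow(out), ncol(out))
  out
}

#' Complete partially observed patterns
#'
#' Treats layer 0 as a partial latent state: observed entries (mask 1) stay
#' clamped to the data; missing entries are iteratively relaxed toward the
#' top-down prediction via the output error neurons,
#' `z0 <- x * m + (z0 - beta * e0) * (1 - m)`, interleaved with the ordinary
#' latent settling (latent update first, then output update, each step).
#'
#' @param model A `gncn` model.
#' @param x `D x B` matrix of (masked) patterns.
#' @param mask Binary mask like `x` (1 = observed), or a single `D`-vector
#'   recycled across records; see [make_half_mask()].
#' @param cfg Settle configuration (its `n_steps` sets the completion
#'   iterations; default matches settling).
#' @return List with `completed` (`D x B`), the final `state`, and the
#'   settling `trajectory`.
#' @export
complete_pattern <- function(model, x, mask, cfg = model$settle) {
  x <- as.matrix(x)
  mask <- as.matrix(mask)
  if (nrow(mask) == nrow(x) && ncol(mask) == 1L && ncol(x) > 1L)
    mask <- matrix(mask, nrow(x), ncol(x))
  if (!all(dim(mask) == dim(x)))
    stop("mask shape does not match x", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  res <- ngc_settle(model$spec, model$params, x, cfg, clamp = mask,
                    update_output = TRUE)
  list(completed = res$state$z[[1L]], state = res$state,
       trajectory = res$trajectory)
}
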