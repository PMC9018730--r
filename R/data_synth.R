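# Data preparation (binarization, masking, splits, IDX reading) and a
# synthetic ground-truth generator so every pipeline stage is testable
# without external downloads.

#' Binarize raw grayscale pixels
#'
#' Pixels in `[0, 255]` are scaled by 255 and thresholded strictly above 0.5
#' (no integer pixel value hits 0.5 exactly).
#'
#' @param images Numeric matrix/array of raw pixel values.
#' @return Binary object of the same shape.
#' @export
binarize <- function(images) {
  (images / 255 > 0.5) * 1
}

#' Half-image observation mask
#'
#' For square `sqrt(D) x sqrt(D)` images in row-major vector layout, marks
#' the left `sqrt(D)/2` pixel columns as observed (1) and the right half as
#' missing (0).
#'
#' @param D Pattern dimensionality; must be a perfect square.
#' @return Length-`D` binary vector.
#' @export
make_half_mask <- function(D) {
  s <- as.integer(round(sqrt(D)))
  if (s * s != D) stop("D must be a perfect square", call. = FALSE)
  col_of <- ((seq_len(D) - 1L) %% s) + 1L   # row-major: column index cycles fastest
  as.numeric(col_of <= s %/% 2L)
}

#' Generate data from a known hierarchical Gaussian-to-Bernoulli model
#'
#' Ground-truth generator emulating the model family under study: top latent
#' codes are drawn from a small Gaussian mixture (the mixture components act
#' as synthetic classes), propagated linearly through a random
#' column-normalized generative matrix, squashed by a tempered sigmoid, and
#' sampled as Bernoulli pixels. The temperature `noise` controls how
#' saturated the pixel means are: as `noise -> 0` the means approach {0, 1}
#' and records become deterministic given their latents.
#'
#' @param n Number of records.
#' @param D Pattern dimensionality.
#' @param J1 Latent dimensionality.
#' @param n_classes Mixture components (synthetic classes), uniform weights.
#' @param class_spread Standard deviation of the component means.
#' @param latent_sd Within-class latent standard deviation.
#' @param noise Sigmoid temperature in `(0, 1]`.
#' @param seed Optional seed.
#' @return List with `X` (`D x n` binary), `labels` (component per record),
#'   `means` (`D x n` true Bernoulli means), and `truth` (the generator:
#'   `W`, `mu`, `pi`, `latent_sd`, `noise`, `codes`).
#' @export
synth_generate <- function(n, D = 16L, J1 = 8L, n_classes = 4L,
                           class_spread = 1.0, latent_sd = 0.5,
                           noise = 0.4, seed = NULL) {
  stopifnot(n >= 1, noise > 0)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rnorm(D * J1), D, J1)
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  mu <- matrix(stats::rnorm(J1 * n_classes, sd = class_spread), J1, n_classes)
  labels <- sample.int(n_classes, n, replace = TRUE)
  codes <- mu[, labels, drop = FALSE] +
    matrix(stats::rnorm(J1 * n, sd = latent_sd), J1, n)
  means <- clip_prob(1 / (1 + exp(-(W %*% codes) / noise)))
  X <- matrix(stats::rbinom(D * n, 1L, means), D, n)
  list(X = X, labels = labels, means = means,
       truth = list(W = W, mu = mu, pi = rep(1 / n_classes, n_classes),
                    latent_sd = latent_sd, noise = noise, codes = codes))
}

#' Analytic pixel marginal means of the synthetic generator
#'
#' Each pixel's marginal mean is a mixture of 1-D Gaussian integrals of the
#' tempered sigmoid (the linear latent path reduces the integral to one
#' dimension per pixel and component); evaluated by Gauss-Hermite
#' quadrature.
#'
#' @param truth The `truth` element returned by [synth_generate()].
#' @param n_nodes Quadrature nodes.
#' @return Length-`D` vector of marginal pixel means.
#' @export
synth_marginal_means <- function(truth, n_nodes = 60L) {
  gh <- gauss_hermite(n_nodes)
  W <- truth$W
  D <- nrow(W)
  K <- ncol(truth$mu)
  rown2 <- rowSums(W^2)
  m <- numeric(D)
  for (k in seq_len(K)) {
    ctr <- as.numeric(W %*% truth$mu[, k])
    sd_d <- truth$latent_sd * sqrt(rown2)
    # E[sigmoid(a / noise)], a ~ N(ctr_d, sd_d^2), per pixel d
    for (d in seq_len(D)) {
      a <- ctr[d] + sqrt(2) * sd_d[d] * gh$nodes
      m[d] <- m[d] + truth$pi[k] *
        sum(gh$weights * (1 / (1 + exp(-a / truth$noise)))) / sqrt(pi)
    }
  }
  m
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigendecomposition of the
# Jacobi matrix (weight exp(-x^2), total weight sqrt(pi)).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  b <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- b
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

#' Seed-reproducible disjoint splits
#'
#' @param X Data matrix, records as columns.
#' @param fractions Non-negative weights for the splits (normalized to 1);
#'   named or in train/validation/test order.
#' @param seed Optional seed for the permutation.
#' @param labels Optional per-record labels split alongside.
#' @return List of splits, each a list with `X` (and `labels`); splits are
#'   disjoint and exhaustive.
#' @export
split_data <- function(X, fractions = c(train = 0.8, validation = 0.1,
                                        test = 0.1),
                       seed = NULL, labels = NULL) {
  X <- as.matrix(X)
  S <- ncol(X)
  stopifnot(all(fractions >= 0), sum(fractions) > 0)
  fr <- fractions / sum(fractions)
  if (is.null(names(fr)))
    names(fr) <- make.names(seq_along(fr))
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(S)
  counts <- floor(fr * S)
  counts[1L] <- counts[1L] + (S - sum(counts))  # remainder to the first split
  out <- list()
  at <- 0L
  for (i in seq_along(fr)) {
    idx <- if (counts[i] > 0) perm[(at + 1L):(at + counts[i])] else integer(0)
    at <- at + counts[i]
    out[[names(fr)[i]]] <- list(X = X[, idx, drop = FALSE],
                                labels = if (!is.null(labels)) labels[idx],
                                idx = idx)
  }
  out
}

#' Read an IDX-format array (MNIST dialect)
#'
#' Parses the magic number (type code, number of dimensions), the big-endian
#' 32-bit dimension sizes, and the payload. Unsigned-byte and 32-bit integer
#' payloads are supported.
#'
#' @param path File path.
#' @return Array with the dimensions declared in the header (images come as
#'   `n x rows x cols`).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (magic[1L] != 0L || magic[2L] != 0L)
    stop("not an IDX file: bad magic number", call. = FALSE)
  type <- magic[3L]
  ndim <- magic[4L]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(type),
                 "8"  = readBin(con, "integer", n = n, size = 1L,
                                signed = FALSE),
                 "12" = readBin(con, "integer", n = n, size = 4L,
                                endian = "big"),
                 "13" = readBin(con, "numeric", n = n, size = 4L,
                                endian = "big"),
                 stop("unsupported IDX type code: ", type, call. = FALSE))
  if (ndim == 1L) data else array(data, dim = rev(dims)) |>
    aperm(rev(seq_len(ndim)))
}
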