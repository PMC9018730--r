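# Activation registry. All functions are vectorized over matrices.

.ngc_acts <- list(
  identity = list(
    f  = function(v) v,
    df = function(v) array(1, dim = dim(as.matrix(v)))
  ),
  sigmoid = list(
    f  = function(v) 1 / (1 + exp(-v)),
    df = function(v) { s <- 1 / (1 + exp(-v)); s * (1 - s) }
  ),
  tanh = list(
    f  = function(v) tanh(v),
    df = function(v) 1 - tanh(v)^2
  ),
  relu = list(
    f  = function(v) pmax(v, 0),
    # subgradient at 0 taken as 1 so a zero-initialized state can move
    df = function(v) (v >= 0) * 1
  ),
  # signum is usable as a state nonlinearity in Type-2 models only (their
  # synaptic rules never require d phi / d z); df is the zero subgradient.
  signum = list(
    f  = function(v) sign(v),
    df = function(v) array(0, dim = dim(as.matrix(v)))
  )
)

ngc_act <- function(name) {
  a <- .ngc_acts[[name]]
  if (is.null(a)) stop("unknown activation: ", name, call. = FALSE)
  a
}

act_apply <- function(name, v) ngc_act(name)$f(v)
act_deriv <- function(name, v) ngc_act(name)$df(v)
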