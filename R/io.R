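# Checkpoints (named-matrix archives as JSON), flat config files, and
# delimited history/metric tables. Every artifact records the config and
# seed that produced it.

#' Save a model checkpoint
#'
#' Writes the spec, all synaptic matrices, the settle defaults and any
#' provenance metadata (config, seed) to a single JSON archive at full
#' numeric precision.
#'
#' @param model A `gncn` model.
#' @param path Output file.
#' @param meta Named list recorded under `$meta` (e.g. config and seed).
#' @export
ngc_save_model <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "gncn"))
  spec <- unclass(model$spec)
  obj <- list(format = "gncn-checkpoint-1",
              meta = meta,
              spec = spec,
              settle = unclass(model$settle),
              params = list(W = model$params$W, E = model$params$E,
                            M = model$params$M, V = model$params$V,
                            Prec = model$params$Prec,
                            prec_floor = model$params$prec_floor))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

# Rebuild a list of matrices from un-simplified JSON (arrays of rows).
.as_mat_list <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  lapply(x, function(m) {
    if (is.null(m) || length(m) == 0L) return(NULL)
    do.call(rbind, lapply(m, unlist))
  })
}

#' Load a model checkpoint
#'
#' Rebuilds the spec and parameters from a JSON archive written by
#' [ngc_save_model()]; shapes are re-validated and a mismatch between the
#' stored spec and matrices is refused with the offending shape named.
#'
#' @param path Checkpoint file.
#' @return A `gncn` model (metadata under `attr(, "meta")`).
#' @export
ngc_load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) ||
      !startsWith(unlist(obj$format), "gncn-checkpoint"))
    stop("not a gncn checkpoint: ", path, call. = FALSE)
  s <- lapply(obj$spec, unlist)
  spec <- ngc_spec(s$sizes,
                   g_out = s$g[1L],
                   phi = s$phi[-1L],
                   alpha_m = s$alpha_m,
                   error_type = s$error_type,
                   lateral_mode = s$lateral_mode,
                   group_size = s$group_size,
                   use_phi_derivative = s$use_phi_derivative,
                   precision_mode = s$precision_mode,
                   sigma2 = s$sigma2,
                   simplified_e0 = s$simplified_e0)
  V <- .as_mat_list(obj$params$V)
  if (is.null(V)) V <- vector("list", spec$L)
  Prec <- .as_mat_list(obj$params$Prec)
  params <- structure(list(W = .as_mat_list(obj$params$W),
                           E = .as_mat_list(obj$params$E),
                           M = .as_mat_list(obj$params$M),
                           V = V,
                           Prec = if (is.null(Prec)) list() else Prec,
                           prec_floor = unlist(obj$params$prec_floor) %||%
                             1e-4),
                      class = "ngc_params")
  st <- lapply(obj$settle, unlist)
  cfg <- settle_config(beta = st$beta, gamma = st$gamma,
                       lambda_prior = st$lambda_prior,
                       n_steps = st$n_steps, lateral_form = st$lateral_form)
  m <- gncn_model(spec, params, settle = cfg)
  attr(m, "meta") <- obj$meta
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key-value configuration file
#'
#' YAML with scalar values (and comma/sequence lists for `layer_sizes`).
#' Missing required keys are reported in one aggregated error.
#'
#' @param path Config file.
#' @param required Character vector of keys that must be present.
#' @return Named list.
#' @export
ngc_read_config <- function(path, required = character()) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config ", path, " is missing required keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$layer_sizes)) {
    ls <- cfg$layer_sizes
    if (is.character(ls) && length(ls) == 1L) ls <- strsplit(ls, ",")[[1L]]
    cfg$layer_sizes <- as.integer(unlist(ls))
  }
  cfg
}

# Delimited table with '#'-prefixed provenance header lines.
write_table_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, ": ",
                      paste(format(meta[[k]]), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_with_meta <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
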