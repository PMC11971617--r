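#' Serialize a fitted model to JSON and back
#'
#' Writes everything needed to re-instantiate a [gpcm_model()] (design,
#' configuration, parameters, reference pattern and support) as a compact JSON
#' file, so fits can be passed between command-line steps or sessions.
#'
#' @param x A [gpcm_model()] or [gpcm()] fit (the fit's log-likelihood travels
#'   along when present).
#' @param path Output file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a [gpcm_model()].
#' @export
write_model_json <- function(x, path) {
  model <- as_gpcm_model(x)
  obj <- list(
    type = model$type,
    m = model$design$m,
    v = model$spec$v, deg2 = model$spec$deg2,
    eps_fixed = c(model$spec$eps10, model$spec$eps20),
    beta = model$beta,
    alpha = model$alpha, eta = model$eta,
    eps_free = model$eps_free,
    y0 = pattern_string(model$y0),
    support = pattern_string(model$B),
    loglik = if (inherits(x, "gpcm_fit")) x$loglik
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- test_design(obj$m)
  spec <- cgf_spec(obj$v, obj$deg2, obj$eps_fixed)
  new_model(design, obj$beta,
            scal = if (identical(obj$type, "nominal")) obj$eta else obj$alpha,
            eps_free = if (length(obj$eps_free)) obj$eps_free else numeric(0),
            spec = spec, y0 = drop(parse_pattern(obj$y0)),
            B = parse_pattern(obj$support), type = obj$type)
}
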