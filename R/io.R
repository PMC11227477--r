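#' Read and write parameter sets
#'
#' Serializes [lv_params()], [scaling_constants()] and
#' [nondimensionalize()] objects to JSON or YAML and back, losslessly to
#' full double precision. Keys match the field names (snake_case, Greek
#' letters spelled out: `alpha`, `beta`, `gamma`, `delta`, `epsilon`); a
#' `type` key (`lv_params`, `lv_scaling` or `lv_params_hat`) records the
#' object class.
#'
#' @param x A parameter object of one of the three classes.
#' @param path File path; the format is chosen by extension
#'   (`.json`, `.yml`/`.yaml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`; default inferred from `path`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the reconstructed object.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_params(lv_fixture("case_I"), path)
#' read_params(path)
#' @export
write_params <- function(x, path, format = NULL) {
  type <- params_type(x)
  format <- format %||% format_from_path(path)
  fields <- drop_na_fields(unclass(x))
  payload <- c(list(type = type), fields)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  } else {
    writeLines(yaml::as.yaml(payload, precision = 17), path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, format = NULL) {
  format <- format %||% format_from_path(path)
  payload <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  type <- payload$type
  payload$type <- NULL
  payload <- purrr::map(payload, as.numeric)
  switch(
    type %||% "",
    lv_params = restore_params(payload),
    lv_scaling = rlang::exec(scaling_constants, !!!payload),
    lv_params_hat = restore_hat(payload),
    abort_invalid("file does not contain a recognised parameter type"))
}

params_type <- function(x) {
  if (inherits(x, "lv_params")) return("lv_params")
  if (inherits(x, "lv_scaling")) return("lv_scaling")
  if (inherits(x, "lv_params_hat")) return("lv_params_hat")
  abort_invalid("x must be an lv_params, lv_scaling or lv_params_hat object")
}

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yml", "yaml")) return("yaml")
  abort_invalid("cannot infer format from extension; pass format=")
}

drop_na_fields <- function(x) x[!vapply(x, function(v)
  is.numeric(v) && length(v) == 1 && is.na(v), logical(1))]

# The stored C0/H0 are passed through explicitly (exact round trip even
# when they were derived from epsilon); the recorded epsilon and m are
# then restored onto the object.
restore_params <- function(p) {
  obj <- lv_params(r1 = p$r1, r2 = p$r2, r3 = p$r3, K1 = p$K1,
                   K2 = p$K2, alpha = p$alpha, beta = p$beta,
                   gamma = p$gamma, delta = p$delta, I0 = p$I0,
                   T = p$T, C0 = p$C0, H0 = p$H0,
                   m = p$m %||% NA_real_)
  obj$epsilon <- p$epsilon %||% NA_real_
  obj
}

restore_hat <- function(p) {
  structure(p[c("r1_hat", "r2_hat", "r3_hat", "alpha_hat", "beta_hat",
                "gamma_hat", "delta_hat", "C0_tilde", "H0_tilde",
                "I0_tilde")],
            class = "lv_params_hat")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
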