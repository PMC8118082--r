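# Plain-text interfaces: delimited data / covariance input and a YAML model +
# prior configuration, shared by the command-line wrapper.

#' Read an indicator data matrix from delimited text
#'
#' Expects a header row of indicator names; the delimiter is sniffed from the
#' first line (comma, semicolon, tab, or whitespace).
#'
#' @param path File path.
#' @return Numeric matrix (observations x indicators).
#' @export
read_data_matrix <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else if (grepl(";", first)) ";" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep)
  as.matrix(df)
}

#' Read a covariance matrix from delimited text
#'
#' Accepts a square numeric table, with or without a header row of indicator
#' names.
#'
#' @param path File path.
#' @param n Sample size the matrix was computed from.
#' @return A [sample_moments()] object.
#' @export
read_cov_matrix <- function(path, n) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else if (grepl(";", first)) ";" else ""
  has_header <- !all(grepl("^[-0-9.eE+]+$",
                           strsplit(trimws(first),
                                    if (sep == "") "[[:space:]]+" else sep)[[1]]))
  m <- as.matrix(utils::read.table(path, header = has_header, sep = sep))
  sample_moments(unname(m), n = n)
}

#' Read a model and prior configuration from a YAML file
#'
#' The file has two top-level sections. `model` takes `loading_map` (integer
#' vector), and optionally `equal_loadings`, `fixed_sigma`, `epsilon`.
#' `priors` takes `mu_lambda`, `nu_lambda`, `mu_rho`, `nu_rho` (all optional;
#' defaults are the uniform priors).
#'
#' @param path File path.
#' @return List with `spec` ([cfa_model_spec()]) and `priors`
#'   ([prior_config()]).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("model:", "  loading_map: [1, 1, 1, 2, 2, 2]",
#'              "priors:", "  mu_rho: 0.3", "  nu_rho: 3"), cfg)
#' read_model_config(cfg)$priors
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$model
  if (is.null(m$loading_map)) stop("config must provide model$loading_map")
  spec <- cfa_model_spec(
    loading_map = m$loading_map,
    equal_loadings = isTRUE(m$equal_loadings),
    fixed_sigma = m$fixed_sigma,
    epsilon = if (is.null(m$epsilon)) 0.001 else m$epsilon
  )
  pr <- cfg$priors
  priors <- prior_config(
    spec,
    mu_lambda = if (is.null(pr$mu_lambda)) 0.5 else pr$mu_lambda,
    nu_lambda = if (is.null(pr$nu_lambda)) 0 else pr$nu_lambda,
    mu_rho = if (is.null(pr$mu_rho)) 0 else pr$mu_rho,
    nu_rho = if (is.null(pr$nu_rho)) 0 else pr$nu_rho
  )
  list(spec = spec, priors = priors)
}
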