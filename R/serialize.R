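#' Serialize a ZINB factor model to plain-text files
#'
#' Writes every parameter and design block of a model as a TSV file in
#' `dir`, plus a JSON manifest recording dimensions, covariate masks,
#' dispersion mode and penalty scale. For a [ZinbFit-class], the objective
#' trace and convergence diagnostics are stored alongside.
#' `readZinbModel` reconstructs the object.
#'
#' @param model a [ZinbModel-class] or [ZinbFit-class].
#' @param dir directory to create/read.
#' @return `writeZinbModel` returns `dir` invisibly; `readZinbModel` the
#'   reconstructed object.
#' @export
writeZinbModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(x, name) {
    utils::write.table(x, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  blocks <- c("X", "V", "O_mu", "O_pi", "W", "beta_mu", "beta_pi",
              "gamma_mu", "gamma_pi", "alpha_mu", "alpha_pi")
  for (b in blocks) wm(methods::slot(model, b), b)
  wm(matrix(model@zeta, nrow = 1), "zeta")
  manifest <- list(
    n = nSamples(model), J = nFeatures(model), K = nFactors(model),
    which_X_mu = model@which_X_mu, which_X_pi = model@which_X_pi,
    which_V_mu = model@which_V_mu, which_V_pi = model@which_V_pi,
    commonDispersion = model@commonDispersion, epsilon = model@epsilon)
  if (methods::is(model, "ZinbFit")) {
    manifest$converged <- model@converged
    manifest$iterations <- model@iterations
    wm(matrix(model@trace, nrow = 1), "trace")
    utils::write.table(model@traceDetail, file.path(dir, "trace_detail.tsv"),
                       sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeZinbModel
#' @export
readZinbModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(name) {
    f <- file.path(dir, paste0(name, ".tsv"))
    if (file.size(f) == 0) return(NULL)  # zero-column block (e.g. K = 0)
    as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
  }
  model <- zinbModel(
    n = man$n, J = man$J, K = man$K,
    X = rm_("X"), V = rm_("V"), O_mu = rm_("O_mu"), O_pi = rm_("O_pi"),
    which_X_mu = man$which_X_mu, which_X_pi = man$which_X_pi,
    which_V_mu = man$which_V_mu, which_V_pi = man$which_V_pi,
    W = rm_("W"), beta_mu = rm_("beta_mu"), beta_pi = rm_("beta_pi"),
    gamma_mu = rm_("gamma_mu"), gamma_pi = rm_("gamma_pi"),
    alpha_mu = rm_("alpha_mu"), alpha_pi = rm_("alpha_pi"),
    zeta = as.numeric(rm_("zeta")),
    commonDispersion = man$commonDispersion, epsilon = man$epsilon)
  if (!is.null(man$converged)) {
    model <- methods::new("ZinbFit", model,
      trace = as.numeric(rm_("trace")),
      traceDetail = utils::read.table(file.path(dir, "trace_detail.tsv"),
                                      sep = "\t", header = TRUE),
      converged = man$converged, iterations = as.integer(man$iterations))
  }
  model
}
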