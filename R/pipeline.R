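#' Analysis configuration
#'
#' Collects the tunable settings of the pipeline: the marginal-screen
#' significance level `alpha` (default 0.05), the EBIC weight `gamma`
#' (default 0.25), the neighborhood combination `rule`, the
#' Haldane–Anscombe `continuity` flag, the RNG `seed`, the age-balancing
#' `band_width` (years), the `age_split` defining the older band
#' (default 76, i.e. the 65–75 / 76+ dichotomy), and the exact-likelihood
#' `enumeration_limit`.
#'
#' @param alpha significance level in (0, 1).
#' @param gamma EBIC weight in `[0, 1]`.
#' @param rule `"AND"` or `"OR"`.
#' @param continuity logical.
#' @param seed integer RNG seed.
#' @param band_width age-band width in years (`>= 1`).
#' @param age_split first age (years) of the older band.
#' @param enumeration_limit maximum `p` for exact enumeration.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, gamma = 0.25,
                            rule = c("AND", "OR"), continuity = FALSE,
                            seed = 1L, band_width = 5, age_split = 76,
                            enumeration_limit = 20L) {
  rule <- match.arg(rule)
  if (alpha <= 0 || alpha >= 1) stop_morbnet("'alpha' must be in (0, 1)")
  if (gamma < 0 || gamma > 1) stop_morbnet("'gamma' must be in [0, 1]")
  if (band_width < 1) stop_morbnet("'band_width' must be >= 1")
  structure(list(alpha = alpha, gamma = gamma, rule = rule,
                 continuity = continuity, seed = as.integer(seed),
                 band_width = band_width, age_split = age_split,
                 enumeration_limit = as.integer(enumeration_limit)),
            class = c("analysis_config", "list"))
}

#' @rdname analysis_config
#' @param path file path for the YAML key-value serialization.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @param config an `analysis_config` (write) — for reading, settings in
#'   the file override the defaults.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y[intersect(names(y),
                                       names(formals(analysis_config)))])
}

#' Run the multimorbidity network pipeline
#'
#' End-to-end driver behind the command-line interface. Subcommands:
#' \describe{
#'   \item{`simulate`}{draw a cohort from the multimorbidity preset and
#'     write it to `<outdir>/cohort.csv`.}
#'   \item{`marginal`}{marginal odds-ratio screen with Holm correction.}
#'   \item{`fit`}{structure learning + joint Ising MLE + conditional OR
#'     matrix.}
#'   \item{`topology`}{`fit` plus the centrality table.}
#'   \item{`stratify`}{`fit` plus age-balanced stratified networks.}
#'   \item{`all`}{everything above.}
#' }
#' Every stochastic step is seeded from `config$seed`, so identical
#' (input, config) pairs reproduce byte-identical outputs.
#'
#' @param command one of `simulate`, `marginal`, `fit`, `topology`,
#'   `stratify`, `all`.
#' @param input path to a cohort CSV (ignored by `simulate`).
#' @param outdir output directory.
#' @param config an [analysis_config()].
#' @param n cohort size for `simulate` (default 20000).
#' @return The results list, invisibly (also written to `outdir`).
#' @export
run_pipeline <- function(command = c("all", "simulate", "marginal", "fit",
                                     "topology", "stratify"),
                         input = NULL, outdir, config = analysis_config(),
                         n = 20000L) {
  command <- match.arg(command)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  warn_log <- character(0)
  note <- function(...) warn_log <<- c(warn_log, paste0(...))

  results <- list(config = unclass(config))
  if (command == "simulate" || (command == "all" && is.null(input))) {
    spec <- make_multimorbidity_preset(n = n, seed = config$seed)
    cohort <- sample_cohort(spec)
    input <- file.path(outdir, "cohort.csv")
    write_cohort(cohort, input)
    results$cohort_path <- input
    if (command == "simulate") {
      export_results(results["config"], outdir)
      return(invisible(results))
    }
  }
  if (is.null(input)) stop_morbnet("'input' cohort path required")
  cohort <- read_cohort(input, age_split = config$age_split)
  results$n <- nrow(cohort)
  results$p <- length(cohort_variables(cohort))

  if (command %in% c("marginal", "all")) {
    results$marginal <- marginal_or_matrix(cohort, alpha = config$alpha,
                                           continuity = config$continuity)
  }
  if (command %in% c("fit", "topology", "stratify", "all")) {
    g <- withCallingHandlers(
      learn_structure(cohort, gamma = config$gamma, rule = config$rule),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    fit <- withCallingHandlers(
      fit_ising_mle(cohort, g, limit = config$enumeration_limit),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    results$structure <- g
    results$params <- fit
    results$conditional <- conditional_or_matrix(fit)
  }
  if (command %in% c("topology", "all")) {
    results$centrality <- centrality_table(results$structure)
  }
  if (command %in% c("stratify", "all")) {
    strat_cohort <- cohort
    if ("age_years" %in% names(cohort)) {
      strat_cohort <- age_balance(cohort, band_width = config$band_width,
                                  seed = config$seed)
    }
    results$stratified <- withCallingHandlers(
      stratified_networks(strat_cohort, gamma = config$gamma,
                          rule = config$rule),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
  }
  results$warnings <- warn_log
  export_results(results, outdir)
  invisible(results)
}
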