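#' Export analysis results to files
#'
#' Writes any combination of results to `outdir`:
#' \itemize{
#'   \item association matrices as CSV with blank cells for absent
#'     (conditionally independent) entries;
#'   \item fitted parameters as a tab-separated edge list
#'     (`from`, `to`, `lambda`, `or`, `q`, and Wald columns when
#'     available);
#'   \item graph structures as GraphML (via igraph), with Yule's Q as an
#'     edge attribute when fitted parameters are supplied;
#'   \item a structured plain-text run report echoing the configuration,
#'     densities, the centrality table, stratum summaries and warnings.
#' }
#'
#' @param results named list; recognized elements: `marginal`,
#'   `conditional` (association matrices), `structure`
#'   ([graph_structure()]), `params` ([ising_params()]), `centrality`
#'   ([centrality_table()] result), `stratified`
#'   ([stratified_networks()] result), `config` (a list), `warnings`
#'   (character).
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix (default `"morbnet"`).
#' @return Character vector of the files written, invisibly.
#' @export
export_results <- function(results, outdir, prefix = "morbnet") {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop_morbnet("cannot create output directory '", outdir, "'")
    }
  }
  files <- character(0)
  out <- function(name) file.path(outdir, paste0(prefix, "_", name))

  write_or_matrix <- function(am, path) {
    m <- am$or
    df <- as.data.frame(m)
    df[] <- lapply(df, function(x) ifelse(is.na(x), "", format(x, digits = 8)))
    utils::write.csv(cbind(node = rownames(m), df), path, row.names = FALSE,
                     quote = FALSE)
    path
  }
  for (kind in c("marginal", "conditional")) {
    if (!is.null(results[[kind]])) {
      files <- c(files, write_or_matrix(results[[kind]],
                                        out(paste0(kind, "_or.csv"))))
    }
  }
  if (!is.null(results$params)) {
    ew <- tryCatch(edge_wald(results$params), error = function(e) NULL)
    ek <- results$params$structure$edges
    el <- data.frame(from = ek[, 1L], to = ek[, 2L],
                     lambda = results$params$interactions[ek],
                     or = exp(results$params$interactions[ek]),
                     q = yules_q(exp(results$params$interactions[ek])))
    if (!is.null(ew) && nrow(ew) == nrow(el)) {
      el$se <- ew$se; el$z <- ew$z; el$p <- ew$p
    }
    f <- out("edges.tsv")
    utils::write.table(el, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(results$structure)) {
    g <- as_igraph(results$structure)
    if (!is.null(results$params)) {
      ek <- results$structure$edges
      if (nrow(ek)) {
        igraph::E(g)$q <- yules_q(exp(results$params$interactions[ek]))
      }
    }
    f <- out("graph.graphml")
    igraph::write_graph(g, f, format = "graphml")
    files <- c(files, f)
  }
  if (!is.null(results$centrality)) {
    f <- out("centrality.csv")
    utils::write.csv(as.data.frame(results$centrality), f,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  # structured run report
  rep_lines <- c("# morbnet run report", "", "[config]")
  cfg <- results$config
  if (!is.null(cfg)) {
    rep_lines <- c(rep_lines,
                   vapply(names(cfg), function(k) {
                     paste0(k, " = ", paste(format(cfg[[k]]), collapse = " "))
                   }, character(1)))
  }
  rep_lines <- c(rep_lines, "", "[summary]")
  if (!is.null(results$structure)) {
    rep_lines <- c(rep_lines,
                   paste0("nodes = ", length(results$structure$nodes)),
                   paste0("edges = ", nrow(results$structure$edges)),
                   paste0("density = ",
                          format(graph_density(results$structure))))
  }
  if (!is.null(results$centrality)) {
    tab <- as.data.frame(results$centrality)
    rep_lines <- c(rep_lines, "", "[centrality]",
                   paste(utils::capture.output(print(tab, row.names = FALSE)),
                         collapse = "\n"))
  }
  if (!is.null(results$stratified)) {
    rep_lines <- c(rep_lines, "", "[strata]")
    for (nm in names(results$stratified$strata)) {
      s <- results$stratified$strata[[nm]]
      rep_lines <- c(rep_lines, if (isTRUE(s$flagged)) {
        paste0(nm, ": flagged (", s$reason, ")")
      } else {
        paste0(nm, ": n = ", s$n, ", edges = ", nrow(s$structure$edges),
               ", density = ", format(s$density))
      })
    }
  }
  if (length(results$warnings %||% character(0))) {
    rep_lines <- c(rep_lines, "", "[warnings]", results$warnings)
  }
  f <- out("report.txt")
  writeLines(rep_lines, f)
  files <- c(files, f)
  invisible(files)
}
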