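# Report writers and run manifest --------------------------------------------

#' Run manifest
#'
#' Provenance record written alongside every output set: package version,
#' seed, life-table source, an MD5 hash of the serialized configuration and
#' a timestamp. A run is regenerable from its manifest (config + seed +
#' life-table source).
#'
#' @param p An `endocea_params` object.
#' @param seed Integer seed used (or `NA` for deterministic runs).
#' @param life_table_source Character description of the mortality input
#'   (file path or `"synthetic"`).
#' @return A named list.
#' @export
run_manifest <- function(p, seed = NA_integer_,
                         life_table_source = "synthetic") {
  stopifnot(inherits(p, "endocea_params"))
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(p, tmp)
  list(package = "endocea",
       version = as.character(utils::packageVersion("endocea")),
       seed = seed,
       life_table_source = life_table_source,
       config_md5 = unname(tools::md5sum(tmp)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write the base-case outcomes report
#'
#' Emits the lifetime outcomes of each strategy and the pairwise
#' incremental comparisons as a CSV table (strategies in columns: cost,
#' QALYs, life-years, progression-free life-years, cumulative event
#' probabilities, ICER rows) plus a JSON mirror and the run manifest.
#' Dominated or dominant comparisons render their label instead of a
#' number.
#'
#' @param outcomes Named list of `endocea_outcomes` (per strategy).
#' @param comparisons Named list of `endocea_comparison`.
#' @param dir Output directory (created if needed).
#' @param manifest Optional [run_manifest()] list.
#' @return Invisibly, the paths written.
#' @export
write_outcomes_report <- function(outcomes, comparisons, dir,
                                  manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_icer <- function(cmp)
    if (is.character(cmp$icer)) cmp$icer else sprintf("%.6g", cmp$icer)
  tab <- data.frame(
    quantity = c("discounted_cost_cny", "discounted_qalys",
                 "life_years", "pf_life_years",
                 "cum_recurrence", "cum_endometrial", "cum_fracture"),
    stringsAsFactors = FALSE)
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    tab[[nm]] <- c(o$discounted_cost, o$discounted_qalys, o$life_years,
                   o$pf_life_years, o$event_cumulatives[["recurrence"]],
                   o$event_cumulatives[["endometrial"]],
                   o$event_cumulatives[["fracture"]])
  }
  icer_rows <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    data.frame(comparison = nm, delta_cost = cmp$delta_cost,
               delta_qalys = cmp$delta_qalys, icer = fmt_icer(cmp),
               stringsAsFactors = FALSE)
  }))
  csv_out <- file.path(dir, "outcomes.csv")
  csv_icer <- file.path(dir, "icers.csv")
  json_out <- file.path(dir, "outcomes.json")
  utils::write.csv(tab, csv_out, row.names = FALSE)
  utils::write.csv(icer_rows, csv_icer, row.names = FALSE)
  payload <- list(
    outcomes = lapply(outcomes, function(o)
      list(discounted_cost = o$discounted_cost,
           discounted_qalys = o$discounted_qalys,
           life_years = o$life_years,
           pf_life_years = o$pf_life_years,
           event_cumulatives = as.list(o$event_cumulatives))),
    comparisons = lapply(comparisons, function(cmp)
      list(strategy = cmp$strategy, comparator = cmp$comparator,
           delta_cost = cmp$delta_cost, delta_qalys = cmp$delta_qalys,
           icer = cmp$icer)))
  if (!is.null(manifest)) payload$manifest <- manifest
  jsonlite::write_json(payload, json_out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(csv_out, csv_icer, json_out)
  if (!is.null(manifest)) {
    mf <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, mf)
  }
  invisible(paths)
}

#' Write a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
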