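.tool_version <- function()
  as.character(utils::packageVersion("hfssm"))

.write_manifest <- function(path, input, attempted, excluded, params,
                            seed = NULL, extra = list()) {
  manifest <- c(list(tool = "hfssm", version = .tool_version(),
                     input = input,
                     records_attempted = attempted,
                     records_excluded_missing = excluded,
                     records_analysed = attempted - excluded,
                     seed = seed),
                params, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}

#' Score a survey CSV and report prevalence
#'
#' Reads a respondent CSV, scores all four instruments, and writes the
#' prevalence table (`prevalence.csv` at full precision, `prevalence.txt`
#' pretty-printed to one decimal) plus a run manifest
#' (`manifest.json`: record accounting -- attempted, excluded for missing
#' instrument answers, analysed -- and parameters).
#'
#' @param input_csv Input CSV path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `prevalence` (the table) and `manifest`.
#' @export
run_score <- function(input_csv, out_dir = ".") {
  records <- read_records(input_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- prevalence_table(records)
  out <- cbind(measure = rownames(tab), as.data.frame(tab))
  utils::write.csv(out, file.path(out_dir, "prevalence.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(print(tab)),
             file.path(out_dir, "prevalence.txt"))
  manifest <- .write_manifest(
    file.path(out_dir, "manifest.json"), input = input_csv,
    attempted = attr(records, "attempted"),
    excluded = attr(records, "excluded"),
    params = list())
  invisible(list(prevalence = tab, manifest = manifest))
}

#' Evaluate brief screeners on a survey CSV
#'
#' Reads a respondent CSV, fits [brief_screener()], and writes the
#' pair-by-stratum diagnostics (`diagnostics.csv` at full precision, a
#' pretty-printed `diagnostics.txt`) and a manifest recording the
#' parameters and the recommended pair.  If the data contain no
#' reference-insecure records the report carries undefined (missing)
#' sensitivities and a warning is raised.
#'
#' @param input_csv Input CSV path.
#' @param out_dir Output directory.
#' @param candidate_items,reference_threshold,subgroups Passed to
#'   [brief_screener()].
#' @return Invisibly, the `brief_screener` fit.
#' @export
run_evaluate <- function(input_csv, out_dir = ".", candidate_items = 1:3,
                         reference_threshold = 3L,
                         subgroups = fs_subgroups()) {
  records <- read_records(input_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  any_insecure <- any(reference_status(affirmation_matrix(records),
                                       reference_threshold))
  fit <- NULL
  if (any_insecure) {
    fit <- brief_screener(records, candidate_items = candidate_items,
                          reference_threshold = reference_threshold,
                          subgroups = subgroups)
    report <- fit$report
    recommended <- paste(fit$recommended, collapse = "+")
  } else {
    report <- suppressWarnings(
      evaluate_pairs(records, candidate_items = candidate_items,
                     subgroups = subgroups,
                     reference_threshold = reference_threshold))
    recommended <- NULL
    warning("no reference-insecure records: sensitivity undefined, ",
            "no recommendation made", call. = FALSE)
  }
  utils::write.csv(as.data.frame(report),
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "diagnostics.txt"))
  .write_manifest(
    file.path(out_dir, "manifest.json"), input = input_csv,
    attempted = attr(records, "attempted"),
    excluded = attr(records, "excluded"),
    params = list(candidate_items = candidate_items,
                  reference_threshold = reference_threshold,
                  subgroups = unname(subgroups)),
    extra = list(recommended_items = recommended))
  if (!is.null(fit)) invisible(fit)
  else invisible(list(report = report, recommended = NULL))
}

#' Simulation recovery study
#'
#' Runs the full pipeline -- simulate, score, evaluate -- at several
#' sample sizes and compares the empirical sensitivity and specificity of
#' a screener with the exact population values from
#' [population_diagnostics()], writing a convergence table.
#'
#' @param cfg A `generator_config` (finite discrimination).
#' @param items Screener item ids, default `c(1, 3)`.
#' @param n_grid Sample sizes, default `c(1e3, 1e4, 2e5)`.
#' @param seed Base seed; run `k` of the grid uses `seed + k - 1`.
#' @param reference_threshold Reference cut-point.
#' @param out_dir Optional output directory for `convergence.csv` and a
#'   manifest.
#' @return Data frame with one row per `n`: empirical and population
#'   sensitivity/specificity and their absolute errors.
#' @export
run_simulation_study <- function(cfg, items = c(1, 3),
                                 n_grid = c(1e3, 1e4, 2e5), seed = 1L,
                                 reference_threshold = 3L, out_dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  pop <- population_diagnostics(cfg, items, reference_threshold)
  rows <- lapply(seq_along(n_grid), function(k) {
    sim <- simulate_respondents(cfg, n = n_grid[k], seed = seed + k - 1L)
    d <- diagnostics(cross_tabulate(sim, items, reference_threshold))
    data.frame(n = n_grid[k],
               sensitivity = d$sensitivity, specificity = d$specificity,
               sensitivity_pop = pop$sensitivity,
               specificity_pop = pop$specificity,
               abs_err_sensitivity = abs(d$sensitivity - pop$sensitivity),
               abs_err_specificity = abs(d$specificity - pop$specificity))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "convergence.csv"),
                     row.names = FALSE)
    .write_manifest(file.path(out_dir, "manifest.json"),
                    input = "simulated", attempted = sum(n_grid),
                    excluded = 0L,
                    params = list(items = items, n_grid = n_grid,
                                  reference_threshold = reference_threshold),
                    seed = seed)
  }
  out
}
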