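#' Configure the end-to-end simulation pipeline
#'
#' Validated configuration for [run_pipeline()]. Defaults reproduce the
#' published simulation experiment exactly: the full 4320-run factorial, the
#' 120-run propagule-stage factorial, and their sequential ANOVAs and figure
#' summaries. Unknown configuration keys are rejected before anything runs.
#'
#' @param out_dir Output directory (created if absent).
#' @param design A [factorial_design()].
#' @param propagule A [propagule_design()].
#' @param master_seed Integer master seed; every random draw in the pipeline
#'   descends from it.
#' @param ... Unknown keys: always an error.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = "clonalfx-output",
                            design = factorial_design(),
                            propagule = propagule_design(),
                            master_seed = 1, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            is.list(design), all(c("PN", "ON", "SR", "T", "replicates") %in% names(design)),
            is.list(propagule), all(c("PN", "SR", "replicates") %in% names(propagule)),
            is.numeric(master_seed), length(master_seed) == 1L)
  structure(list(out_dir = out_dir, design = design, propagule = propagule,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full simulation-and-analysis pipeline
#'
#' Runs both factorials, computes the ANOVA tables and the figure summaries,
#' and writes everything to \code{config$out_dir}: \code{runs.csv},
#' \code{propagule_runs.csv}, \code{anova_table2.csv},
#' \code{anova_table3.csv}, \code{fig_propagule_summary.csv},
#' \code{fig_offspring_summary.csv} and \code{provenance.json} (seed, design,
#' package version). Byte-identical outputs for a fixed master seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory path; the computed tables are
#'   attached as attribute \code{"results"}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "full factorial"
  res <- tryCatch({
    runs <- run_full_factorial(config$design, master_seed = config$master_seed)
    stage <- "propagule factorial"
    pruns <- run_propagule_factorial(config$propagule,
                                     master_seed = config$master_seed + 1L)
    stage <- "offspring ANOVA"
    t3 <- table3_anova(runs)
    stage <- "propagule ANOVA"
    t2 <- table2_anova(pruns)
    stage <- "figure summaries"
    figs <- summarize_figures(propagule_runs = pruns, full_runs = runs)
    list(runs = runs, propagule_runs = pruns, table2 = t2, table3 = t3,
         figures = figs)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })

  write_runs(res$runs, file.path(config$out_dir, "runs.csv"))
  utils::write.csv(res$propagule_runs,
                   file.path(config$out_dir, "propagule_runs.csv"),
                   row.names = FALSE)
  .write_anova_csv(res$table2, file.path(config$out_dir, "anova_table2.csv"))
  .write_anova_csv(res$table3, file.path(config$out_dir, "anova_table3.csv"))
  utils::write.csv(res$figures$propagule,
                   file.path(config$out_dir, "fig_propagule_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$figures$offspring,
                   file.path(config$out_dir, "fig_offspring_summary.csv"),
                   row.names = FALSE)
  prov <- list(
    master_seed = config$master_seed,
    design = config$design, propagule = config$propagule,
    package = "clonalfx",
    version = as.character(utils::packageVersion("clonalfx")))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}

.write_anova_csv <- function(tables, path) {
  rows <- do.call(rbind, lapply(names(tables), function(resp) {
    tb <- as.data.frame(tables[[resp]])
    cbind(response = resp, tb[c("term", "df_num", "df_den", "F", "p")])
  }))
  names(rows) <- c("response", "term", "df1", "df2", "F", "p")
  utils::write.csv(rows, path, row.names = FALSE)
}

.runs_columns <- c("PN", "ON", "SR", "T", "parent_mass", "n_propagules",
                   "n_survivors", "total_propagule_mass",
                   "mean_propagule_mass", "summed_offspring_mass",
                   "mean_offspring_mass", "replicate")

#' Read and write simulation run tables
#'
#' Tidy CSV round trip for the full-factorial run table (comma-separated, dot
#' decimal, header row, UTF-8). Reading validates the schema: the documented
#' columns must all be present and numeric; locale-style decimal commas are
#' rejected with the offending column named.
#'
#' @param runs Run table from [run_full_factorial()].
#' @param path CSV file path.
#' @return \code{read_runs}: the validated data.frame. \code{write_runs}:
#'   the path, invisibly.
#' @export
write_runs <- function(runs, path) {
  stopifnot(is.data.frame(runs))
  missing <- setdiff(.runs_columns, names(runs))
  if (length(missing)) stop("run table lacks column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.csv(runs[.runs_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.runs_columns, names(d))
  if (length(missing)) stop("run table lacks column(s): ",
                            paste(missing, collapse = ", "))
  extra <- setdiff(names(d), .runs_columns)
  if (length(extra)) stop("run table has unexpected column(s): ",
                          paste(extra, collapse = ", "))
  for (col in .runs_columns) {
    if (!is.numeric(d[[col]])) {
      stop("column '", col, "' is not numeric (decimal commas or stray text?)")
    }
  }
  d
}
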