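#' Convert an experiment to a serializable report
#'
#' Produces the plain-list structure written to `summary.json`: run metadata,
#' the error-summary cells (median / mean / 95% centiles per scenario,
#' strategy, product and error level) and the head-to-head win fractions.
#'
#' @param x A `strategy_experiment`.
#' @return A named list ready for [jsonlite::write_json()].
#' @export
as_report <- function(x) {
  stopifnot(inherits(x, "strategy_experiment"))
  list(
    meta = list(
      package = "hospsample",
      version = as.character(utils::packageVersion("hospsample")),
      seed = x$seed,
      n_reps = x$n_reps,
      n_batches = x$n_batches,
      population_size = x$population_size,
      holdout_only = x$holdout_only,
      strategies = as.list(x$strategies),
      products = as.list(x$products),
      scenarios = lapply(x$scenarios, function(s) as.list(unclass(s)))
    ),
    error_summary = x$summary,
    head_to_head = x$head_to_head
  )
}

#' Write the experiment artifacts to a directory
#'
#' Writes `replicates.csv` (tidy per-replicate errors), `summary.json` (the
#' [as_report()] structure) and `table.txt` (the human-readable comparison
#' table, rounded to whole percent).
#'
#' @param x A `strategy_experiment`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "strategy_experiment"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io("cannot create output directory: ", dir)
  }
  reps <- x$replicates[c("scenario", "strategy", "product", "replicate",
                         "batch", "hospital_error_pct", "national_error_pct")]
  utils::write.csv(reps, file.path(dir, "replicates.csv"), row.names = FALSE)
  jsonlite::write_json(as_report(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(x)), file.path(dir, "table.txt"))
  invisible(dir)
}

#' Validate a comparison report against the shipped schema
#'
#' Checks that a `summary.json` report (path or already-parsed list)
#' structurally conforms to the JSON schema shipped at
#' `system.file("schema", "compare-summary.schema.json", package = "hospsample")`:
#' required top-level blocks, required meta fields, the required columns of
#' every error-summary cell, and value ranges.
#'
#' @param report Path to a `summary.json` file, or the parsed list.
#' @return `TRUE` invisibly; otherwise a validation error saying what is
#'   missing.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    if (!file.exists(report)) stop_io("report file not found: ", report)
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  need <- function(ok, ...) if (!ok) stop_validation(...)
  need(all(c("meta", "error_summary", "head_to_head") %in% names(report)),
       "report must contain meta, error_summary and head_to_head blocks")
  meta_fields <- c("package", "version", "seed", "n_reps", "n_batches",
                   "population_size", "strategies", "products", "scenarios")
  miss <- setdiff(meta_fields, names(report$meta))
  need(!length(miss), "meta lacks field(s): ", paste(miss, collapse = ", "))
  es <- as.data.frame(report$error_summary)
  cols <- c("scenario", "strategy", "product", "metric", "median", "mean",
            "centile_2.5", "centile_97.5")
  miss <- setdiff(cols, names(es))
  need(!length(miss), "error_summary lacks column(s): ", paste(miss, collapse = ", "))
  need(all(es$strategy %in% STRATEGIES), "unknown strategy label in error_summary")
  need(all(es$product %in% PRODUCTS), "unknown product label in error_summary")
  need(all(es$metric %in% c("hospital", "national")), "unknown metric label")
  for (cl in c("median", "mean", "centile_2.5", "centile_97.5")) {
    need(all(is.finite(es[[cl]]) & es[[cl]] >= 0),
         "error_summary column '", cl, "' must be finite and nonnegative")
  }
  expected <- length(unique(es$scenario)) * length(unique(es$strategy)) *
    length(unique(es$product)) * 2L
  need(nrow(es) == expected, "error_summary has ", nrow(es),
       " cells, expected ", expected)
  if (!is.null(report$head_to_head)) {
    hh <- as.data.frame(report$head_to_head)
    need(all(c("random_strategy", "purposive_strategy", "pct_outperform") %in%
               names(hh)), "head_to_head lacks required columns")
    need(all(hh$pct_outperform >= 0 & hh$pct_outperform <= 100),
         "win fractions must lie in [0, 100]")
  }
  invisible(TRUE)
}
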