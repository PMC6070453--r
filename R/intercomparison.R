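#' Cross-protocol comparison report
#'
#' Collects the per-protocol quantification results on one comparison-source
#' geometry, compares them to the digital ground truth, and summarises them
#' the way multi-site exercises are reported: signed percent differences,
#' spread (range) and mean bias per compartment, the proportion of protocols
#' within 5/10/20/50/75/100\% of truth, and whether each reported
#' uncertainty range covers the true value.
#'
#' @name intercomparison
NULL

#' Signed percent difference from truth
#' @param measured measured value(s).
#' @param truth true value (> 0).
#' @return 100 * (measured - truth) / truth.
#' @export
percent_difference <- function(measured, truth) {
  if (any(truth <= 0)) {
    stop("percent difference undefined for zero truth", call. = FALSE)
  }
  100 * (measured - truth) / truth
}

#' Within-threshold tabulation
#'
#' For each threshold, the proportion of absolute differences not exceeding
#' it, formatted "k/n (p\%)".
#'
#' @param diffs percent differences.
#' @param thresholds ascending percent thresholds.
#' @return data.frame with \code{threshold}, \code{k}, \code{n},
#'   \code{proportion}, \code{label}.
#' @export
within_threshold_table <- function(diffs,
                                   thresholds = c(5, 10, 20, 50, 75, 100)) {
  if (length(diffs) == 0) stop("no differences to tabulate", call. = FALSE)
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  n <- length(diffs)
  k <- vapply(thresholds, function(t) sum(abs(diffs) <= t), integer(1))
  data.frame(threshold = thresholds, k = k, n = n, proportion = k / n,
             label = sprintf("%d/%d (%.0f%%)", k, n, 100 * k / n))
}

#' Compile the comparison report
#'
#' @param runs list of results from [run_protocol()].
#' @param truth optional truth list (defaults to the first run's, which is
#'   shared when all runs used the same phantom geometry).
#' @return object of class \code{comparison_report}: the results table with
#'   percent differences and coverage flags, per-compartment spread
#'   statistics and within-threshold tables.
#' @export
compile_report <- function(runs, truth = NULL) {
  stopifnot(length(runs) >= 1)
  if (is.null(truth)) truth <- runs[[1]]$truth
  res <- do.call(rbind, lapply(runs, function(r) r$results))
  res$true_volume_ml <- truth$volumes[res$compartment]
  res$true_activity_mbq <- truth$activities[res$compartment]
  res$diff_volume_pct <- percent_difference(res$volume_ml,
                                            res$true_volume_ml)
  res$diff_activity_pct <- percent_difference(res$activity_mbq,
                                              res$true_activity_mbq)
  res$covers_truth <- !is.na(res$sigma_mbq) &
    abs(res$activity_mbq - res$true_activity_mbq) <= res$sigma_mbq

  spread_stats <- function(d) {
    d <- d[is.finite(d)]
    c(min = min(d), max = max(d), range = max(d) - min(d), mean = mean(d))
  }
  compartments <- unique(res$compartment)
  spread <- lapply(stats::setNames(compartments, compartments), function(cc) {
    list(volume = spread_stats(res$diff_volume_pct[res$compartment == cc]),
         activity = spread_stats(res$diff_activity_pct[res$compartment == cc]))
  })
  tables <- lapply(stats::setNames(compartments, compartments), function(cc) {
    within_threshold_table(res$diff_activity_pct[res$compartment == cc])
  })
  structure(list(results = res, truth = truth, spread = spread,
                 within_threshold = tables),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Inter-comparison report\n=======================\n")
  for (cc in names(x$spread)) {
    s <- x$spread[[cc]]$activity
    cat(sprintf(
      "%s activity: spread %.0f%% (range %+.0f to %+.0f%%), mean %+.0f%%\n",
      cc, s["range"], s["min"], s["max"], s["mean"]))
  }
  cat("\nProportion of protocols within a given % of the true activity:\n")
  for (cc in names(x$within_threshold)) {
    t <- x$within_threshold[[cc]]
    cat(sprintf("  %-6s %s\n", cc,
                paste(sprintf("<=%d%%: %s", t$threshold, t$label),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Run several protocols on one comparison geometry and compile the report
#'
#' Each protocol gets its own seed offset (different sites received
#' different physical sources), its own calibration chain and its own noisy
#' comparison acquisition.
#'
#' @param protocols character vector of protocol ids.
#' @param seed base seed.
#' @param ... passed to [run_protocol()] (grid size, spacing, projections,
#'   noise).
#' @return a \code{comparison_report}.
#' @export
run_intercomparison <- function(protocols = paste0("H", 1:7), seed = 1,
                                ...) {
  runs <- lapply(seq_along(protocols), function(i) {
    run_protocol(protocols[i], seed = seed + 1000L * i, ...)
  })
  compile_report(runs)
}

#' Write a comparison report to disk
#'
#' Emits \code{results.csv}, \code{report.json} and a plain-text
#' \code{summary.txt}.
#'
#' @param report a \code{comparison_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("results.csv", "report.json", "summary.txt"))
  utils::write.csv(report$results, paths[1], row.names = FALSE)
  jsonlite::write_json(
    list(results = report$results, truth = report$truth,
         spread = report$spread,
         within_threshold = report$within_threshold),
    paths[2], auto_unbox = TRUE, digits = NA)
  con <- file(paths[3], "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(paths)
}
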