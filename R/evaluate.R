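# Evaluation against truth labels. Note the field-specific reading of the
# two headline metrics: sensitivity is the fraction of truly-clean
# sequence retained in the clean set, and specificity is the fraction of
# truly-contaminant sequence removed -- not the classical true-negative
# rate. Both come base-weighted (primary) and contig-weighted.

.confusion <- function(truth, label, weight) {
  tibble(truth = truth, label = label, w = weight) |>
    dplyr::group_by(.data$truth, .data$label) |>
    dplyr::summarise(bases = sum(.data$w), contigs = dplyr::n(),
                     .groups = "drop")
}

.metrics_from_counts <- function(cf, value_col) {
  v <- function(tr, lb) {
    x <- cf[[value_col]][cf$truth == tr & cf$label == lb]
    if (length(x)) sum(x) else 0
  }
  clean_tot <- v("clean", "CLEAN") + v("clean", "CONTAMINANT")
  con_tot <- v("contaminant", "CLEAN") + v("contaminant", "CONTAMINANT")
  tot <- clean_tot + con_tot
  flags <- character()
  sens <- if (clean_tot > 0) v("clean", "CLEAN") / clean_tot else {
    flags <- c(flags, "undefined-empty-class:clean"); 1.0
  }
  spec <- if (con_tot > 0) v("contaminant", "CONTAMINANT") / con_tot else {
    flags <- c(flags, "undefined-empty-class:contaminant"); 1.0
  }
  acc <- (v("clean", "CLEAN") + v("contaminant", "CONTAMINANT")) / tot
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       flags = flags)
}

#' Score a decontamination run against truth labels
#'
#' @param report A `prodege_report` (from [run_prodege()]) or a tibble
#'   with `contig_id`, `length` and final `label` columns.
#' @param truth Tibble with `contig_id` and `truth`
#'   (`"clean"`/`"contaminant"`), e.g. from [generate_mixture()]. Must
#'   cover every contig in the report.
#' @return A `prodege_eval` object: `metrics` (tibble with base- and
#'   contig-weighted sensitivity, specificity, accuracy), `counts`
#'   (truth x label table of bases and contigs), `flags`.
#' @export
score_run <- function(report, truth) {
  rows <- if (inherits(report, "prodege_report")) report$contigs else report
  miss <- setdiff(rows$contig_id, truth$contig_id)
  if (length(miss)) {
    abort(sprintf("Contig '%s' in the report is missing from the truth table.",
                  miss[1]))
  }
  d <- dplyr::left_join(
    dplyr::select(rows, "contig_id", "length", "label"),
    dplyr::select(truth, "contig_id", "truth"), by = "contig_id")
  cf <- .confusion(d$truth, d$label, d$length)
  mb <- .metrics_from_counts(cf, "bases")
  mc <- .metrics_from_counts(cf, "contigs")
  metrics <- tibble(
    metric = c("sensitivity", "specificity", "accuracy"),
    base_weighted = c(mb$sensitivity, mb$specificity, mb$accuracy),
    contig_weighted = c(mc$sensitivity, mc$specificity, mc$accuracy)
  )
  structure(list(metrics = metrics, counts = cf,
                 flags = unique(c(mb$flags, mc$flags))),
            class = "prodege_eval")
}

#' @export
print.prodege_eval <- function(x, ...) {
  cat("<prodege_eval>\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname score_run
#' @param x A `prodege_eval`.
#' @param ... Unused.
#' @export
tidy.prodege_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"metric", names_to = "weighting",
                      values_to = "value")
}

#' @rdname score_run
#' @export
glance.prodege_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    sensitivity = m$base_weighted[m$metric == "sensitivity"],
    specificity = m$base_weighted[m$metric == "specificity"],
    accuracy = m$base_weighted[m$metric == "accuracy"],
    n_flags = length(x$flags)
  )
}

#' Summarise evaluation results across runs
#'
#' @param results List of `prodege_eval` objects.
#' @return Tibble with per-metric, per-weighting median and mean.
#' @export
summarize_runs <- function(results) {
  if (!length(results)) abort("`results` must contain at least one run.")
  purrr::map_dfr(seq_along(results),
                 function(i) dplyr::mutate(tidy(results[[i]]), run = i)) |>
    dplyr::group_by(.data$metric, .data$weighting) |>
    dplyr::summarise(median = stats::median(.data$value),
                     mean = mean(.data$value), .groups = "drop")
}
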