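# Binary classification metrics and the coefficient of variation shared by
# the evaluation paths. Internal values keep full precision; rounding to
# one decimal place happens only at presentation.

#' Contingency table of a binary classifier against a manual reference
#'
#' @param tp,fn,fp,tn nonnegative integer counts (rows: algorithm;
#'   columns: manual reference).
#' @return a `contingency_table` list.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)),
            sum(counts) > 0)
  structure(as.list(counts), class = "contingency_table")
}

#' Classification metrics from a contingency table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`, each as a percentage at full precision.
#' A metric with a zero denominator is reported as `NA` (undefined), never
#' as 0.
#'
#' @param t a [contingency_table()].
#' @return named numeric vector (percent): `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv`.
#' @export
classification_metrics <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  q <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  total <- t$tp + t$fn + t$fp + t$tn
  c(sensitivity = q(t$tp, t$tp + t$fn),
    specificity = q(t$tn, t$tn + t$fp),
    accuracy = q(t$tp + t$tn, total),
    ppv = q(t$tp, t$tp + t$fp),
    npv = q(t$tn, t$tn + t$fn))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- classification_metrics(x)
  cat(sprintf("          reference+  reference-\n"))
  cat(sprintf("test+     %9d  %9d\n", x$tp, x$fp))
  cat(sprintf("test-     %9d  %9d\n", x$fn, x$tn))
  cat(paste(sprintf("%s %.1f%%", names(m), m), collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, as a percentage.
#'
#' @param values numeric vector (>= 2 values, nonzero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  100 * stats::sd(values) / m
}

#' Write a metrics report
#'
#' JSON or CSV report of a contingency table and its metrics.
#'
#' @param t a [contingency_table()].
#' @param path output path; format from the extension (`.json` / `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(t, path) {
  m <- classification_metrics(t)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(c(t[c("tp", "fn", "fp", "tn")], as.list(m)),
                         path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    utils::write.csv(data.frame(metric = names(m), percent = as.numeric(m)),
                     path, row.names = FALSE)
  }
  invisible(path)
}
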