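#' Evaluate predicted against true labels
#'
#' Accuracy is the percentage of correct predictions; the false
#' negative rate (FNR) is reported as `100 - accuracy`, the convention
#' used throughout multimodal tumor-type benchmarking. The confusion
#' matrix has true classes in rows and predicted classes in columns.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes optional class order; defaults to the sorted union of
#'   levels found in `truth`. A predicted label outside the class set
#'   is an error.
#' @return list with `accuracy` (%), `fnr` (%), `confusion` (integer
#'   count matrix), and `confusion_pct` (row-normalized percentages).
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  conf <- table(truth = tf, predicted = pf)
  conf <- matrix(as.integer(conf), nrow = length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  acc <- 100 * sum(diag(conf)) / length(truth)
  rs <- rowSums(conf)
  pct <- 100 * conf / ifelse(rs == 0, 1, rs)
  list(accuracy = acc, fnr = 100 - acc, confusion = conf, confusion_pct = pct)
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance-of-indicators generalization of MCC computed from a
#' confusion count matrix: with `c` the trace, `s` the total count,
#' `t_k` the row (true-class) sums and `p_k` the column (predicted)
#' sums,
#' `MCC = (c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))`.
#' Returns 0 when the denominator vanishes.
#'
#' @param conf square confusion count matrix (rows = truth).
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(conf) {
  conf <- as.matrix(conf)
  if (nrow(conf) != ncol(conf)) stop("confusion matrix must be square")
  if (sum(conf) == 0) stop("empty confusion matrix")
  s <- sum(conf); cc <- sum(diag(conf))
  t_k <- rowSums(conf); p_k <- colSums(conf)
  num <- cc * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Summarize repeated-run accuracies
#'
#' Computes min/avg/max, variance, standard deviation, and the standard
#' error of the mean over repeated evaluation runs. The published run
#' summaries this mirrors use the population (divide-by-n) variance;
#' `var_type = "sample"` gives the n-1 denominator instead. In both
#' cases `sem = sd / sqrt(n_runs)`.
#'
#' @param accuracies numeric vector of per-run accuracies (%), length
#'   at least 2.
#' @param var_type `"population"` (default) or `"sample"`.
#' @return list of class `run_summary` with `min`, `avg`, `max`,
#'   `variance`, `sd`, `sem`, `n_runs`.
#' @export
summarize_runs <- function(accuracies, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  n <- length(accuracies)
  if (n < 2) stop("need at least 2 runs")
  m <- mean(accuracies)
  ss <- sum((accuracies - m)^2)
  v <- ss / if (var_type == "population") n else (n - 1)
  s <- sqrt(v)
  structure(list(min = min(accuracies), avg = m, max = max(accuracies),
                 variance = v, sd = s, sem = s / sqrt(n), n_runs = n),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> n=%d  min %.3f  avg %.3f  max %.3f  var %.4f  sd %.4f  sem %.4f\n",
              x$n_runs, x$min, x$avg, x$max, x$variance, x$sd, x$sem))
  invisible(x)
}

#' Normal-theory confidence-interval margin
#'
#' `margin = z * sem` with `z` the standard-normal quantile at
#' `(1 + level/100) / 2` (1.96 at the 95% level). Presentation rounding
#' of published margins is half-away-from-zero to 3 decimals; apply
#' [round_half_up()] if that formatting is wanted.
#'
#' @param sem non-negative standard error of the mean.
#' @param level confidence level in percent, in `(0, 100)`.
#' @return the margin of error.
#' @export
ci_margin <- function(sem, level = 95) {
  if (sem < 0) stop("sem must be non-negative")
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)")
  stats::qnorm((1 + level / 100) / 2) * sem
}

#' Published per-method run summaries
#'
#' The reported accuracy summaries (three repeated runs per method) for
#' the three BraTS benchmark editions, as shipped in
#' `extdata/reported_run_stats.csv`: per method the minimum, average,
#' and maximum accuracy (%) and the reported standard deviation. These
#' serve as reference inputs for reproducing the derived statistics
#' (variance, SEM, confidence margins).
#'
#' @return data frame with columns `dataset`, `method`, `min`, `avg`,
#'   `max`, `sigma`.
#' @export
reported_run_stats <- function() {
  utils::read.csv(system.file("extdata", "reported_run_stats.csv",
                              package = "mrimodal"))
}
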