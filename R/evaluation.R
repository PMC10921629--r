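# Model evaluation: prediction error summaries per algorithm and
# train/test partition.

#' Evaluate a fitted model on one partition
#'
#' Computes the mean error and its spread on the chosen partition, on
#' unit-scaled labels (percent / 100). The mean error is the mean absolute
#' prediction error by default; `metric = "signed"` reports the signed
#' mean instead. The spread is the population (divisor N) standard
#' deviation of the error.
#'
#' @param fr A `fit_result` (weights on unit-scaled labels).
#' @param ts A split `training_set`.
#' @param partition `"train"` or `"test"`.
#' @param metric `"absolute"` (default) or `"signed"`.
#' @return List with `mean_error`, `std_error` and `n`.
#' @export
evaluate_model <- function(fr, ts, partition = c("train", "test"),
                           metric = c("absolute", "signed")) {
  partition <- match.arg(partition)
  metric <- match.arg(metric)
  part <- training_partition(ts, partition)
  b <- build_basis(part$d_e)
  y <- part$d_tr / 100
  e <- prediction_error(y, predict_risk(fr$w, b))$e
  me <- if (metric == "absolute") mean(abs(e)) else mean(e)
  list(mean_error = me,
       std_error = sqrt(mean((e - mean(e))^2)),
       n = length(e))
}

#' Compare the four learners on a training set
#'
#' Fits BLS, INN, LSLC and SCE on the training partition and evaluates
#' each on both partitions, producing the 4 x 2 report of mean error and
#' error standard deviation. A failing fitter yields `NA` cells for its
#' rows; the other algorithms are still reported.
#'
#' @param ts A split `training_set`.
#' @param configs Named list of per-algorithm argument lists, e.g.
#'   `list(INN = list(eta = 0.05, epochs = 1))`.
#' @param seed Integer seed forwarded to the stochastic fitter (SCE).
#' @param metric Passed to [evaluate_model()].
#' @return List with `report` (`data.frame`:
#'   `algorithm,partition,mean_error,std_error,n`) and `fits` (named list
#'   of `fit_result`s or `NULL` for failures).
#' @export
compare_algorithms <- function(ts, configs = list(), seed = 1L,
                               metric = "absolute") {
  algos <- c("BLS", "INN", "LSLC", "SCE")
  fits <- list()
  rows <- list()
  n_test <- sum(ts$split == "test")
  for (alg in algos) {
    extra <- configs[[alg]]
    if (is.null(extra)) extra <- list()
    fr <- tryCatch(
      do.call(fit, c(list(algorithm = alg, ts = ts, seed = seed), extra)),
      error = function(e) {
        warning("fit failed for ", alg, ": ", conditionMessage(e))
        NULL
      })
    fits[[alg]] <- fr
    for (part in c("train", "test")) {
      if (part == "test" && n_test == 0L) next
      if (is.null(fr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, partition = part,
          mean_error = NA_real_, std_error = NA_real_, n = NA_integer_)
      } else {
        ev <- evaluate_model(fr, ts, part, metric = metric)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, partition = part,
          mean_error = ev$mean_error, std_error = ev$std_error, n = ev$n)
      }
    }
  }
  list(report = do.call(rbind, rows), fits = fits)
}

#' Mean absolute error over a label range
#'
#' Helper for inspecting how prediction quality varies along the risk
#' scale, e.g. abundant negative intervals versus scarce positive ones.
#'
#' @inheritParams evaluate_model
#' @param label_range `c(low, high)` in percent; rows of the partition
#'   whose label falls in this closed range are evaluated.
#' @return Mean absolute error on unit-scaled labels, or `NA` if no row
#'   falls in the range.
#' @export
mean_error_in_range <- function(fr, ts, partition, label_range) {
  part <- training_partition(ts, partition)
  sel <- part$d_tr >= label_range[1L] & part$d_tr <= label_range[2L]
  if (!any(sel)) return(NA_real_)
  b <- build_basis(part$d_e[sel, , drop = FALSE])
  y <- part$d_tr[sel] / 100
  mean(abs(prediction_error(y, predict_risk(fr$w, b))$e))
}
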