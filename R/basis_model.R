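# Norm-power basis expansion and the shared error/gradient primitives of
# the linear-in-parameters risk prediction model.

#' Exponents of the basis maps
#'
#' The seven scalar maps applied elementwise to each analyte: a bias term
#' and the powers 1/2, 1, 1.2, 2, 3 and 4 of the absolute value. With five
#' analytes this yields the 35-column basis.
#'
#' @format Numeric vector of length 7; `0` denotes the bias map.
#' @export
BASIS_EXPONENTS <- c(0, 0.5, 1, 1.2, 2, 3, 4)

#' Build the 35-column basis matrix
#'
#' Expands an M x 5 matrix of normalized analyte values into the M x 35
#' regression basis: for each analyte (analyte-major order) the seven maps
#' `1, |x|^0.5, |x|, |x|^1.2, |x|^2, |x|^3, |x|^4`. Absolute values keep
#' the fractional powers real for held-out values that fall below 0 on the
#' training scale. Column names encode analyte and exponent
#' (`htc_bias`, `htc_pow0.5`, ..., `mpv_pow4`).
#'
#' @param d_e Numeric M x 5 matrix (column order HTC, HGB, WBC, PLT, MPV).
#' @return M x 35 numeric matrix.
#' @export
build_basis <- function(d_e) {
  d_e <- as.matrix(d_e)
  if (ncol(d_e) != 5L) stop("expected a 5-column analyte matrix")
  if (any(!is.finite(d_e))) stop("basis input must be finite")
  m <- nrow(d_e)
  cols <- vector("list", 5L * length(BASIS_EXPONENTS))
  nm <- character(length(cols))
  k <- 0L
  for (j in seq_len(5L)) {
    x <- abs(d_e[, j])
    for (p in BASIS_EXPONENTS) {
      k <- k + 1L
      cols[[k]] <- if (p == 0) rep(1, m) else x^p
      nm[k] <- if (p == 0) paste0(PANEL_ANALYTES[j], "_bias") else
        paste0(PANEL_ANALYTES[j], "_pow", p)
    }
  }
  b <- do.call(cbind, cols)
  colnames(b) <- nm
  b
}

#' Predict risk from a weight vector and basis matrix
#'
#' @param w Numeric weight vector, length `ncol(b)`.
#' @param b Basis matrix from [build_basis()].
#' @return Numeric vector of predictions, one per row of `b`.
#' @export
predict_risk <- function(w, b) {
  if (length(w) != ncol(b)) {
    stop("weight vector length ", length(w),
         " does not match basis column count ", ncol(b))
  }
  drop(b %*% w)
}

#' Prediction error and its squared norm
#'
#' @param y Observed labels.
#' @param y_hat Predictions of equal length.
#' @return List with `e = y - y_hat` and `sq = sum(e^2)`.
#' @export
prediction_error <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  e <- y - y_hat
  list(e = e, sq = sum(e^2))
}

#' Gradient of the squared prediction error
#'
#' Returns `-2 * t(b) %*% y + 2 * t(b) %*% b %*% w`, the gradient of
#' `sum((y - b w)^2)` with respect to `w`.
#'
#' @inheritParams predict_risk
#' @param y Observed labels, length `nrow(b)`.
#' @return Numeric vector of length `ncol(b)`.
#' @export
squared_error_gradient <- function(b, y, w) {
  if (length(y) != nrow(b)) stop("label length does not match basis rows")
  if (length(w) != ncol(b)) stop("weight length does not match basis columns")
  drop(-2 * crossprod(b, y) + 2 * crossprod(b, b %*% w))
}
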