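# Parameter-learning algorithms for the linear-in-parameters risk model:
# batch least squares, iterative per-sample descent, norm-constrained
# per-sample least squares, and shuffled complex evolution.

new_fit_result <- function(w, error_trace, algorithm, converged = TRUE,
                           seed_used = NULL, extra = list()) {
  structure(c(list(w = w, error_trace = error_trace, algorithm = algorithm,
                   converged = converged, seed_used = seed_used), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: %d parameters, final objective %.6g%s\n",
              x$algorithm, length(x$w),
              x$error_trace[length(x$error_trace)],
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Batch least squares fit
#'
#' Minimizes the squared prediction error over all rows at once. The basis
#' matrix carries five identical bias columns, so the normal-equation
#' matrix is rank deficient; the fit therefore uses minimum-norm
#' pseudo-inverse semantics (SVD with small singular values dropped), which
#' returns the least-squares solution of smallest Euclidean norm.
#'
#' @param b Basis matrix (M x P).
#' @param y Label vector, length M, on the unit scale.
#' @return A `fit_result` with the weight vector and a length-1 error trace.
#' @export
fit_bls <- function(b, y) {
  if (nrow(b) < 1L) stop("empty data")
  if (length(y) != nrow(b)) stop("label length does not match basis rows")
  sv <- svd(b)
  tol <- max(dim(b)) * .Machine$double.eps * sv$d[1L]
  pos <- sv$d > tol
  w <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  w <- drop(w)
  names(w) <- colnames(b)
  new_fit_result(w, prediction_error(y, predict_risk(w, b))$sq, "BLS")
}

#' Iterative per-sample gradient descent fit
#'
#' Updates the weights one sample at a time by the descent step
#' `w <- w + eta * e_k * b_k`, starting from zero. By default samples are
#' visited in label-ascending order (worst-case low first), which makes the
#' characteristic recency effect of the rule observable: late near-normal
#' samples overwrite what was learned from early extreme ones.
#'
#' @inheritParams fit_bls
#' @param eta Learning rate (> 0, default 0.05).
#' @param epochs Number of passes over the data (default 1).
#' @param sample_order `"label-ascending"` or `"given"`.
#' @return A `fit_result`; `error_trace` holds the full-data squared error
#'   after each epoch. If the weight norm exceeds 1e6 the fit stops and is
#'   flagged non-converged.
#' @export
fit_inn <- function(b, y, eta = 0.05, epochs = 1L,
                    sample_order = c("label-ascending", "given")) {
  sample_order <- match.arg(sample_order)
  if (nrow(b) < 1L) stop("empty data")
  if (length(y) != nrow(b)) stop("label length does not match basis rows")
  if (!is.numeric(eta) || eta < 0) stop("eta must be non-negative")
  ord <- if (sample_order == "label-ascending") order(y) else seq_along(y)
  w <- numeric(ncol(b))
  trace <- numeric(0)
  converged <- TRUE
  for (ep in seq_len(epochs)) {
    for (k in ord) {
      bk <- b[k, ]
      ek <- y[k] - sum(w * bk)
      w <- w + eta * ek * bk
      if (sqrt(sum(w^2)) > 1e6) {
        converged <- FALSE
        break
      }
    }
    trace <- c(trace, prediction_error(y, predict_risk(w, b))$sq)
    if (!converged) break
  }
  names(w) <- colnames(b)
  new_fit_result(w, trace, "INN", converged = converged,
                 extra = list(eta = eta, epochs = epochs,
                              sample_order = sample_order))
}

#' Norm-constrained per-sample least squares fit
#'
#' Per-sample update `w <- w + eta_c * b_k / (b_k . b_k + lambda_k) * y_k`
#' with the Lagrange multiplier solved in closed form per sample,
#' `lambda_k = max(0, ||b_k y_k|| / (p ||alpha||) - b_k . b_k)`, followed
#' by projection of `w` onto the feasible ball `||w||_2 <= p ||alpha||_2`.
#' The projection makes the norm constraint hold at every iteration, which
#' the raw update alone does not guarantee.
#'
#' @inheritParams fit_inn
#' @param eta_c Learning rate (> 0, default 0.05).
#' @param alpha Constraint vector (default all ones, length `ncol(b)`).
#' @param p Bound multiplier (> 0, default 10); the feasible radius is
#'   `p * ||alpha||_2`.
#' @param epochs Number of passes over the data (default 1).
#' @return A `fit_result`; the returned weights satisfy the norm bound.
#' @export
fit_lslc <- function(b, y, eta_c = 0.05, alpha = NULL, p = 10, epochs = 1L) {
  if (nrow(b) < 1L) stop("empty data")
  if (length(y) != nrow(b)) stop("label length does not match basis rows")
  if (is.null(alpha)) alpha <- rep(1, ncol(b))
  if (length(alpha) != ncol(b)) stop("alpha length must match basis columns")
  radius <- p * sqrt(sum(alpha^2))
  if (!is.finite(radius) || radius <= 0) {
    stop("p * ||alpha|| must be positive")
  }
  w <- numeric(ncol(b))
  trace <- numeric(0)
  w_norm_trace <- numeric(epochs * nrow(b))
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (k in seq_len(nrow(b))) {
      bk <- b[k, ]
      bb <- sum(bk^2)
      lambda <- max(0, sqrt(sum((bk * y[k])^2)) / radius - bb)
      w <- w + eta_c * bk / (bb + lambda) * y[k]
      nw <- sqrt(sum(w^2))
      if (nw > radius) w <- w * (radius / nw)
      step <- step + 1L
      w_norm_trace[step] <- min(nw, radius)
    }
    trace <- c(trace, prediction_error(y, predict_risk(w, b))$sq)
  }
  names(w) <- colnames(b)
  new_fit_result(w, trace, "LSLC",
                 extra = list(eta_c = eta_c, p = p, radius = radius,
                              w_norm_trace = w_norm_trace))
}

#' Default configuration of the shuffled complex evolution optimizer
#'
#' @param n Points per complex (default 10).
#' @param A Number of complexes (default 4).
#' @param q Sub-complex size (default 5).
#' @param alpha_sce Evolution steps per sub-complex (default 3).
#' @param beta_sce Sub-complex draws per complex per shuffling round
#'   (default 5).
#' @param Omega Maximum shuffling iterations (default 100).
#' @param f_q Objective value at which the search stops early (default 0).
#' @return List of settings for [fit_sce()].
#' @export
sce_config <- function(n = 10L, A = 4L, q = 5L, alpha_sce = 3L,
                       beta_sce = 5L, Omega = 100L, f_q = 0) {
  if (q < 2L || q > n) stop("sub-complex size q must satisfy 2 <= q <= n")
  if (A < 1L || Omega < 1L) stop("A and Omega must be >= 1")
  list(n = n, A = A, q = q, alpha_sce = alpha_sce, beta_sce = beta_sce,
       Omega = Omega, f_q = f_q)
}

#' Shuffled complex evolution fit
#'
#' Gradient-free global minimization of an objective over a box. The
#' population of `n * A` points is sampled uniformly in the bounds, ranked,
#' and partitioned into `A` complexes by rank striping. Each complex
#' evolves through `beta_sce` rounds: a `q`-point sub-complex is drawn with
#' triangular rank weighting and improved `alpha_sce` times by a simplex
#' step (reflection of the worst point through the centroid, else
#' contraction halfway to the centroid, else a fresh uniform point). The
#' complexes are then merged, re-ranked and re-partitioned (shuffled) for
#' up to `Omega` iterations, or until the best objective reaches `f_q`.
#'
#' @param objective Function mapping a length-D numeric vector to a scalar.
#' @param bounds 2 x D matrix (rows `low`, `high`) of box bounds.
#' @param config Settings from [sce_config()].
#' @param seed Integer seed; the search is deterministic given it.
#' @return A `fit_result` with the best point as `w`, the best objective
#'   per shuffling iteration as `error_trace`, and `iterations` used.
#' @export
fit_sce <- function(objective, bounds, config = sce_config(), seed = 1L) {
  if (!is.matrix(bounds) || nrow(bounds) != 2L) {
    stop("bounds must be a 2 x D matrix (rows: low, high)")
  }
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("bounds must be finite with low < high in every dimension")
  }
  D <- length(lo)
  n_eval <- 0L
  eval_safe <- function(x) {
    n_eval <<- n_eval + 1L
    f <- objective(x)
    if (!is.finite(f)) NA_real_ else f
  }
  res <- with_seed(seed, {
    npop <- config$n * config$A
    pop <- matrix(stats::runif(npop * D, rep(lo, each = npop),
                               rep(hi, each = npop)), nrow = npop)
    f <- apply(pop, 1L, eval_safe)
    # points with non-finite objective are resampled within the bounds
    while (any(is.na(f))) {
      bad <- which(is.na(f))
      pop[bad, ] <- matrix(stats::runif(length(bad) * D,
                                        rep(lo, each = length(bad)),
                                        rep(hi, each = length(bad))),
                           nrow = length(bad))
      f[bad] <- apply(pop[bad, , drop = FALSE], 1L, eval_safe)
    }
    ord <- order(f)
    pop <- pop[ord, , drop = FALSE]; f <- f[ord]
    trace <- f[1L]
    iters <- 0L
    # triangular selection weights over ranks within a complex
    psel <- (2 * (config$n + 1 - seq_len(config$n))) /
      (config$n * (config$n + 1))
    for (it in if (f[1L] <= config$f_q) integer(0) else
               seq_len(config$Omega)) {
      iters <- it
      for (a in seq_len(config$A)) {
        cidx <- seq(a, npop, by = config$A)  # rank striping
        cpop <- pop[cidx, , drop = FALSE]
        cf <- f[cidx]
        for (bstep in seq_len(config$beta_sce)) {
          ord_c <- order(cf)
          cpop <- cpop[ord_c, , drop = FALSE]; cf <- cf[ord_c]
          sub <- sort(sample.int(config$n, config$q, prob = psel))
          for (astep in seq_len(config$alpha_sce)) {
            worst_in_sub <- sub[which.max(cf[sub])]
            others <- setdiff(sub, worst_in_sub)
            centroid <- colMeans(cpop[others, , drop = FALSE])
            cand <- 2 * centroid - cpop[worst_in_sub, ]
            fcand <- if (all(cand >= lo & cand <= hi)) eval_safe(cand)
                     else NA_real_
            if (is.na(fcand) || fcand >= cf[worst_in_sub]) {
              cand <- (centroid + cpop[worst_in_sub, ]) / 2
              fcand <- eval_safe(cand)
            }
            if (is.na(fcand) || fcand >= cf[worst_in_sub]) {
              repeat {
                cand <- stats::runif(D, lo, hi)
                fcand <- eval_safe(cand)
                if (!is.na(fcand)) break
              }
            }
            if (fcand < cf[worst_in_sub]) {
              cpop[worst_in_sub, ] <- cand
              cf[worst_in_sub] <- fcand
            }
          }
        }
        pop[cidx, ] <- cpop
        f[cidx] <- cf
      }
      ord <- order(f)
      pop <- pop[ord, , drop = FALSE]; f <- f[ord]
      trace <- c(trace, f[1L])
      if (f[1L] <= config$f_q) break
    }
    list(w = pop[1L, ], trace = trace, iters = iters)
  })
  new_fit_result(res$w, res$trace, "SCE",
                 converged = res$trace[length(res$trace)] <= config$f_q ||
                   res$iters == config$Omega,
                 seed_used = as.integer(seed),
                 extra = list(iterations = res$iters, n_eval = n_eval,
                              config = config, bounds = bounds))
}

#' Fit the risk model to a training set with a chosen learner
#'
#' Uniform entry point: builds the 35-column basis from the training
#' partition, rescales the percent labels to the unit interval (divide by
#' 100), and dispatches to [fit_bls()], [fit_inn()], [fit_lslc()] or
#' [fit_sce()]. For SCE the objective is the squared prediction error on
#' the training partition and each of the 35 weights is searched in
#' `sce_bounds` (default \[-10, 10\]).
#'
#' @param algorithm One of `"BLS"`, `"INN"`, `"LSLC"`, `"SCE"`
#'   (case-insensitive).
#' @param ts A split `training_set` (see [split_train_test()]).
#' @param ... Passed to the selected fitter (`eta`, `epochs`, `eta_c`,
#'   `alpha`, `p`, `config`).
#' @param seed Integer seed, used by SCE.
#' @param sce_bounds Per-parameter search interval for SCE, `c(low, high)`.
#' @return A `fit_result` whose weights act on unit-scaled labels.
#' @export
fit <- function(algorithm, ts, ..., seed = 1L, sce_bounds = c(-10, 10)) {
  algorithm <- toupper(algorithm)
  tr <- training_partition(ts, "train")
  b <- build_basis(tr$d_e)
  y <- tr$d_tr / 100  # percent -> unit scale for conditioning
  switch(algorithm,
    BLS = fit_bls(b, y),
    INN = fit_inn(b, y, ...),
    LSLC = fit_lslc(b, y, ...),
    SCE = {
      obj <- function(w) prediction_error(y, predict_risk(w, b))$sq
      bounds <- matrix(rep(sce_bounds, ncol(b)), nrow = 2L)
      fit_sce(obj, bounds, seed = seed, ...)
    },
    stop("unknown algorithm tag '", algorithm,
         "'; expected BLS, INN, LSLC or SCE")
  )
}
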