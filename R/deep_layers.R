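# Preprocessing stack: band-based record elimination, self-feature
# weighting onto the -100..+100 percent risk scale, and interval-balanced
# selection of training records.

#' Eliminate records whose analytes are all within the normal band
#'
#' A record is considered normal, and eliminated, when every one of its
#' five analytes lies inside the band `mean +/- a_fe * std` of its analyte
#' (inclusive). If even one analyte falls outside its band the whole record
#' is kept: abnormality in any dimension makes the subject informative.
#' `a_fe` is the adaptive feature-elimination multiplier; widening it
#' eliminates more records.
#'
#' @param m Normalized `panel_matrix`.
#' @param s Statistics from [analyte_stats()] computed on `m`.
#' @param a_fe Non-negative band half-width in units of the per-analyte
#'   standard deviation (default 1).
#' @return An `elimination_result`: `keep_mask` (logical, length N),
#'   `n_eliminated`, `n_retained`, per-analyte `bounds` and `a_fe`.
#' @export
eliminate_normal_records <- function(m, s, a_fe = 1) {
  stopifnot(inherits(m, "panel_matrix"), m$normalized)
  check_stats(m, s)
  if (!is.numeric(a_fe) || length(a_fe) != 1L || is.na(a_fe) || a_fe < 0) {
    stop("a_fe must be a single non-negative number")
  }
  lower <- s$mean - a_fe * s$std
  upper <- s$mean + a_fe * s$std
  v <- m$values
  inside <- sweep(v, 2L, lower, ">=") & sweep(v, 2L, upper, "<=")
  keep <- !apply(inside, 1L, all)
  structure(list(
    keep_mask = keep,
    n_eliminated = sum(!keep),
    n_retained = sum(keep),
    bounds = data.frame(lower = lower, upper = upper,
                        row.names = PANEL_ANALYTES),
    a_fe = a_fe
  ), class = "elimination_result")
}

#' @export
print.elimination_result <- function(x, ...) {
  cat(sprintf("elimination (a_fe = %g): %d eliminated, %d retained of %d\n",
              x$a_fe, x$n_eliminated, x$n_retained,
              x$n_eliminated + x$n_retained))
  invisible(x)
}

check_stats <- function(m, s) {
  if (!identical(rownames(s), PANEL_ANALYTES)) {
    stop("analyte statistics do not match the panel analytes")
  }
  if (s$n[1L] != nrow(m$values)) {
    stop("analyte statistics were computed on a different number of records")
  }
  invisible(s)
}

#' Sweep the elimination multiplier
#'
#' Runs [eliminate_normal_records()] at each value of `a_fe_values` and
#' tabulates the eliminated count, reproducing the band-width sweep used to
#' calibrate the elimination stage. Counts are weakly increasing in `a_fe`.
#'
#' @inheritParams eliminate_normal_records
#' @param a_fe_values Non-empty vector of non-negative multipliers.
#' @return `data.frame` with columns `a_fe`, `n_eliminated`, `n_retained`.
#' @export
elimination_sweep <- function(m, s, a_fe_values) {
  if (length(a_fe_values) == 0L) stop("a_fe_values must be non-empty")
  if (any(a_fe_values < 0)) stop("a_fe values must be non-negative")
  rows <- lapply(a_fe_values, function(a) {
    r <- eliminate_normal_records(m, s, a)
    data.frame(a_fe = a, n_eliminated = r$n_eliminated,
               n_retained = r$n_retained)
  })
  do.call(rbind, rows)
}

#' Self-weight retained records onto the percent risk scale
#'
#' Maps each analyte of each retained record to a signed percentage in
#' \[-100, 100\]. Inside the normal band the weight is 0. Outside, the
#' excess deviation beyond the band is scaled linearly so that the most
#' extreme observed value on that side of the mean maps to exactly -100
#' (worst-case low) or +100 (worst-case high):
#' `w = 100 * sign(x - mean) * (|x - mean| - beta) / (D_side - beta)`
#' with `beta = a_fe * std` and `D_side` the distance from the mean to the
#' observed column minimum or maximum. Each record's scalar risk label is
#' then the analyte weight of maximal magnitude (see
#' [assign_record_label()]).
#'
#' @param m Normalized `panel_matrix`.
#' @param s Statistics from [analyte_stats()] computed on `m`.
#' @param keep `elimination_result` computed from `(m, s)`.
#' @return A `weighted_panel`: `analyte_weights` (N_r x 5), `record_label`
#'   (length N_r, percent), `values` (the retained normalized rows) and
#'   `source_rows` (indices into `m`).
#' @export
self_weight <- function(m, s, keep) {
  stopifnot(inherits(m, "panel_matrix"), inherits(keep, "elimination_result"))
  check_stats(m, s)
  if (length(keep$keep_mask) != nrow(m$values)) {
    stop("elimination result does not match the panel matrix")
  }
  idx <- which(keep$keep_mask)
  v <- m$values[idx, , drop = FALSE]
  beta <- keep$a_fe * s$std
  d_hi <- s$max - s$mean
  d_lo <- s$mean - s$min
  w <- matrix(0, nrow = nrow(v), ncol = 5L,
              dimnames = list(rownames(v), PANEL_ANALYTES))
  for (j in seq_len(5L)) {
    dev <- v[, j] - s$mean[j]
    out <- abs(dev) > beta[j]
    if (!any(out)) next
    side_scale <- ifelse(dev[out] > 0, d_hi[j], d_lo[j]) - beta[j]
    if (any(side_scale <= 0)) {
      stop("degenerate deviation scale for analyte '", PANEL_ANALYTES[j],
           "': the band reaches the observed extreme on a side that has ",
           "out-of-band values")
    }
    w[out, j] <- 100 * sign(dev[out]) * (abs(dev[out]) - beta[j]) / side_scale
  }
  # values beyond the training extremes (held-out data normalized with
  # training ranges) would exceed the scale; saturate at the scale ends
  w <- pmin(pmax(w, -100), 100)
  labels <- apply(w, 1L, assign_record_label)
  structure(list(analyte_weights = w, record_label = labels,
                 values = v, source_rows = idx),
            class = "weighted_panel")
}

#' @export
print.weighted_panel <- function(x, ...) {
  cat(sprintf("weighted_panel: %d retained records, labels in [%.1f, %.1f]%%\n",
              nrow(x$analyte_weights), min(x$record_label),
              max(x$record_label)))
  invisible(x)
}

#' Reduce five analyte weights to one record label
#'
#' A record's risk label is the analyte weight of largest magnitude — risk
#' is driven by the most abnormal analyte. Magnitude ties are broken by the
#' fixed analyte priority HTC > HGB > WBC > PLT > MPV.
#'
#' @param weights Numeric vector of 5 analyte weights in \[-100, 100\], at
#'   least one nonzero.
#' @return Scalar label in \[-100, 100\].
#' @export
assign_record_label <- function(weights) {
  if (length(weights) != 5L) stop("expected 5 analyte weights")
  if (all(weights == 0)) {
    stop("all analyte weights are zero; the record lies inside every band ",
         "and should have been eliminated")
  }
  weights[which.max(abs(weights))]  # which.max takes the first on ties
}

#' Select a balanced training set by risk interval
#'
#' Bins record labels into signed 10-percent intervals — `(k-10, k]` for
#' positive labels, `[-k, -k+10)` for negative — and keeps at most `i_t`
#' records per bin and sign, ranked by label magnitude (most extreme first,
#' ties by source row index). Bins with fewer than `i_t` records keep all
#' they have. This caps the over-represented near-normal intervals while
#' retaining every scarce extreme record.
#'
#' @param wp A `weighted_panel` from [self_weight()].
#' @param i_t Required records per interval and sign (default 300).
#' @param interval_width Bin width in percent; must divide 100 (default 10).
#' @return List with `training_set` (a `training_set` object: `d_e` M x 5
#'   matrix of selected normalized rows, `d_tr` percent labels, `interval`,
#'   `source_rows`, `split` placeholder) and `summary` (per-interval
#'   existing/selected counts for both signs).
#' @export
select_by_interval <- function(wp, i_t = 300, interval_width = 10) {
  stopifnot(inherits(wp, "weighted_panel"))
  if (i_t < 1L) stop("i_t must be a positive integer")
  if (interval_width <= 0 || 100 %% interval_width != 0) {
    stop("interval_width must be a positive divisor of 100")
  }
  if (length(wp$record_label) == 0L) stop("weighted panel is empty")
  lab <- wp$record_label
  edges <- seq(interval_width, 100, by = interval_width)
  # signed bin index: positive labels in (k-w, k], negative in [-k, -k+w)
  bin_of <- function(x) {
    s <- sign(x)
    s * pmin(ceiling(abs(x) / interval_width), length(edges))
  }
  bins <- bin_of(lab)
  sel_rows <- integer(0)
  sel_bins <- integer(0)
  summary <- data.frame(interval = edges,
                        existing_pos = 0L, selected_pos = 0L,
                        existing_neg = 0L, selected_neg = 0L)
  for (k in seq_along(edges)) {
    for (sgn in c(1L, -1L)) {
      in_bin <- which(bins == sgn * k)
      existing <- length(in_bin)
      ord <- in_bin[order(-abs(lab[in_bin]), wp$source_rows[in_bin])]
      take <- ord[seq_len(min(existing, i_t))]
      if (sgn == 1L) {
        summary$existing_pos[k] <- existing
        summary$selected_pos[k] <- length(take)
      } else {
        summary$existing_neg[k] <- existing
        summary$selected_neg[k] <- length(take)
      }
      sel_rows <- c(sel_rows, take)
      sel_bins <- c(sel_bins, rep(sgn * k, length(take)))
    }
  }
  ts <- structure(list(
    d_e = wp$values[sel_rows, , drop = FALSE],
    d_tr = lab[sel_rows],
    interval = sel_bins,
    source_rows = wp$source_rows[sel_rows],
    split = rep(NA_character_, length(sel_rows))
  ), class = "training_set")
  list(training_set = ts, summary = summary)
}

#' @export
print.training_set <- function(x, ...) {
  n <- length(x$d_tr)
  cat(sprintf("training_set: %d selected records", n))
  if (!all(is.na(x$split))) {
    cat(sprintf(" (%d train / %d test)",
                sum(x$split == "train"), sum(x$split == "test")))
  }
  cat("\n")
  invisible(x)
}

#' Stratified train/test split of a training set
#'
#' Splits within each signed risk interval so both partitions cover the
#' whole label range, assigning `round(fraction * n_bin)` records of each
#' bin to training. Deterministic for a fixed seed.
#'
#' @param ts A `training_set` from [select_by_interval()].
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return The training set with its `split` field filled with
#'   `"train"`/`"test"`.
#' @export
split_train_test <- function(ts, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  n <- length(ts$d_tr)
  if (n == 0L) stop("training set is empty")
  split <- rep("test", n)
  with_seed(seed, {
    for (b in unique(ts$interval)) {
      rows <- which(ts$interval == b)
      n_train <- round(fraction * length(rows))
      if (n_train > 0L) {
        split[rows[sample.int(length(rows), n_train)]] <- "train"
      }
    }
  })
  ts$split <- split
  ts
}

#' Extract one partition of a split training set
#'
#' @param ts A split `training_set`.
#' @param partition `"train"` or `"test"`.
#' @return List with `d_e` (matrix) and `d_tr` (percent labels).
#' @export
training_partition <- function(ts, partition = c("train", "test")) {
  partition <- match.arg(partition)
  if (all(is.na(ts$split))) stop("training set has not been split")
  rows <- which(ts$split == partition)
  if (length(rows) == 0L) stop("partition '", partition, "' is empty")
  list(d_e = ts$d_e[rows, , drop = FALSE], d_tr = ts$d_tr[rows])
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
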