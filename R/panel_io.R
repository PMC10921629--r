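# Reading, validating and normalizing complete-blood-count panel tables.

#' Analyte names of the five-dimensional blood panel
#'
#' Fixed column order used throughout the package: hematocrit (HTC),
#' hemoglobin (HGB), white blood cell count (WBC), platelet count (PLT) and
#' mean platelet volume (MPV).
#'
#' @format Character vector of length 5.
#' @export
PANEL_ANALYTES <- c("htc", "hgb", "wbc", "plt", "mpv")

panel_columns <- function() c("subject_id", "age", "gender", PANEL_ANALYTES)

#' Read a blood-panel CSV table
#'
#' Reads a CSV with the header `subject_id,age,gender,htc,hgb,wbc,plt,mpv`
#' (columns matched by name, any order). Gender is coded -1 for female and
#' +1 for male; age is a positive number of years; the five analytes are
#' non-negative lab-unit values.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with one row per subject and the eight canonical
#'   columns in canonical order.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(panel_columns(), names(df))
  if (length(missing) > 0L) {
    stop("panel CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, panel_columns()]
  for (col in c("age", "gender", PANEL_ANALYTES)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric value in column '", col, "' at data row ",
           if (length(bad)) bad[1L] else "?")
    }
  }
  validate_panel(df)
  df
}

#' Write a blood-panel table to CSV
#'
#' @param records Panel `data.frame` as returned by [read_panel_csv()] or
#'   [generate_panels()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(records, path) {
  validate_panel(records)
  utils::write.csv(records[, panel_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

validate_panel <- function(df) {
  bad_gender <- which(!(df$gender %in% c(-1, 1)))
  if (length(bad_gender) > 0L) {
    stop("gender must be -1 (female) or +1 (male); offending data row ",
         bad_gender[1L])
  }
  if (any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("age must be a finite positive number of years")
  }
  av <- as.matrix(df[, PANEL_ANALYTES])
  if (any(!is.finite(av))) stop("analyte values must be finite")
  if (any(av < 0)) stop("analyte values must be non-negative")
  invisible(df)
}

#' Build a panel matrix from panel records
#'
#' Extracts the N x 5 analyte matrix (column order HTC, HGB, WBC, PLT, MPV)
#' from a panel data frame.
#'
#' @param records Panel `data.frame`.
#' @return A `panel_matrix` object: numeric matrix plus a `normalized` flag
#'   and the subject ids as rownames.
#' @export
panel_matrix <- function(records) {
  validate_panel(records)
  m <- as.matrix(records[, PANEL_ANALYTES])
  rownames(m) <- as.character(records$subject_id)
  structure(list(values = m, normalized = FALSE, ranges = NULL),
            class = "panel_matrix")
}

new_panel_matrix <- function(values, normalized, ranges = NULL) {
  stopifnot(is.matrix(values), ncol(values) == 5L)
  colnames(values) <- PANEL_ANALYTES
  structure(list(values = values, normalized = normalized, ranges = ranges),
            class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat(sprintf("panel_matrix: %d records x 5 analytes (%s)\n",
              nrow(x$values),
              if (x$normalized) "normalized" else "raw lab units"))
  invisible(x)
}

#' @export
dim.panel_matrix <- function(x) dim(x$values)

#' Min-max normalize a panel matrix
#'
#' Maps each analyte column onto \[0, 1\] by `(x - min) / (max - min)`. The
#' per-analyte `(min, max)` pairs are stored on the result so they can be
#' reused to place held-out data on the training scale; values outside the
#' training range then fall outside \[0, 1\] and are deliberately not
#' clipped, preserving how far they deviate.
#'
#' @param m A raw `panel_matrix`.
#' @param ranges Optional 2 x 5 matrix (rows `min`, `max`) of training
#'   ranges to reuse; by default ranges are computed from `m` itself.
#' @return A normalized `panel_matrix` carrying its `ranges`.
#' @export
min_max_normalize <- function(m, ranges = NULL) {
  stopifnot(inherits(m, "panel_matrix"))
  if (m$normalized) stop("panel matrix is already normalized")
  v <- m$values
  if (is.null(ranges)) {
    ranges <- rbind(min = apply(v, 2L, min), max = apply(v, 2L, max))
    colnames(ranges) <- PANEL_ANALYTES
  }
  span <- ranges["max", ] - ranges["min", ]
  if (any(span <= 0)) {
    stop("constant analyte column(s): ",
         paste(PANEL_ANALYTES[span <= 0], collapse = ", "),
         " (zero range, cannot normalize)")
  }
  out <- sweep(sweep(v, 2L, ranges["min", ], "-"), 2L, span, "/")
  rownames(out) <- rownames(v)
  new_panel_matrix(out, normalized = TRUE, ranges = ranges)
}

#' Per-analyte summary statistics of a normalized panel
#'
#' Computes, for each analyte column of a normalized panel, the minimum,
#' maximum, mean and standard deviation. The standard deviation uses the
#' population convention (divisor N, not N - 1); these statistics define
#' the normal band used by [eliminate_normal_records()] and the deviation
#' scale used by [self_weight()].
#'
#' @param m A normalized `panel_matrix` with at least one row.
#' @return A `data.frame` with rownames `htc,...,mpv` and columns
#'   `min`, `max`, `mean`, `std`, `n`.
#' @export
analyte_stats <- function(m) {
  stopifnot(inherits(m, "panel_matrix"))
  if (!m$normalized) stop("analyte_stats expects a normalized panel matrix")
  v <- m$values
  n <- nrow(v)
  if (n < 1L) stop("empty panel matrix")
  mu <- colMeans(v)
  # population std: sqrt(sum((x - mean)^2)) / sqrt(N)
  sd_pop <- sqrt(colMeans(sweep(v, 2L, mu, "-")^2))
  data.frame(min = apply(v, 2L, min), max = apply(v, 2L, max),
             mean = mu, std = sd_pop, n = n,
             row.names = PANEL_ANALYTES)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation between two equal-length numeric vectors,
#' with explicit validation (length >= 2, both non-constant).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("correlation requires at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant input")
  }
  stats::cor(x, y)
}

#' Pairwise analyte correlations by subject group
#'
#' Splits panel records by gender (-1 female / +1 male) or by age bin and
#' returns, per group, the 5 x 5 matrix of pairwise Pearson correlations
#' among the analytes. Groups with fewer than two records (or with a
#' constant analyte) are flagged unavailable rather than raising an error.
#'
#' @param records Panel `data.frame`.
#' @param grouping `"gender"` or `"age"`.
#' @param age_bins List of `c(low, high)` inclusive year ranges used when
#'   `grouping = "age"`; defaults to 18-37 and 38-64.
#' @return Named list, one element per group, each a list with `available`
#'   (logical), `n` and `table` (5 x 5 matrix or `NULL`).
#' @export
correlation_by_group <- function(records, grouping = c("gender", "age"),
                                 age_bins = list(c(18, 37), c(38, 64))) {
  grouping <- match.arg(grouping)
  validate_panel(records)
  groups <- if (grouping == "gender") {
    list(female = records[records$gender == -1, , drop = FALSE],
         male   = records[records$gender == 1, , drop = FALSE])
  } else {
    out <- lapply(age_bins, function(b) {
      records[records$age >= b[1L] & records$age <= b[2L], , drop = FALSE]
    })
    names(out) <- vapply(age_bins, function(b) paste0(b[1L], "-", b[2L]), "")
    out
  }
  lapply(groups, function(g) {
    v <- as.matrix(g[, PANEL_ANALYTES])
    constant <- nrow(v) >= 2L && any(apply(v, 2L, stats::sd) == 0)
    if (nrow(v) < 2L || constant) {
      return(list(available = FALSE, n = nrow(v), table = NULL))
    }
    tab <- stats::cor(v)
    dimnames(tab) <- list(PANEL_ANALYTES, PANEL_ANALYTES)
    list(available = TRUE, n = nrow(v), table = tab)
  })
}
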