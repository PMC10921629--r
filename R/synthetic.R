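# Synthetic blood-panel generator: mostly-normal analyte values with
# sparse abnormal tails, a male-dominated cohort, and a platelet column on
# a much larger magnitude scale than the other analytes.

#' Default per-analyte generator parameters
#'
#' Normal-component mean and standard deviation per analyte in typical
#' adult lab units (HTC percent, HGB g/dL, WBC 10^9/L, PLT 10^9/L, MPV
#' fL), plus the low- and high-side tail shifts (in the same units) used
#' for abnormal draws. PLT sits an order of magnitude above the other four
#' analytes, so magnitude normalization is a meaningful test.
#'
#' @return `data.frame` with rownames `htc,...,mpv` and columns
#'   `mean`, `sd`, `low_shift`, `high_shift`.
#' @export
default_analyte_params <- function() {
  p <- data.frame(
    mean = c(42, 14, 7, 250, 10),
    sd   = c(4, 1.3, 1.8, 60, 0.9),
    row.names = PANEL_ANALYTES)
  p$low_shift <- 4 * p$sd
  p$high_shift <- 4 * p$sd
  p
}

#' Generate synthetic blood-panel records
#'
#' Each record draws gender from a Bernoulli female fraction (female -1,
#' male +1), an age from weighted year bins, and its five analytes from
#' the per-analyte normal component. A fraction of records is abnormal:
#' one or two of their analytes are drawn instead from a tail component
#' shifted down (low side) or up (high side) by the configured shift,
#' with the high side deliberately scarce. Analyte abnormalities are
#' independent across analytes; values are truncated at zero. Fully
#' deterministic for a fixed seed.
#'
#' @param n Number of records.
#' @param female_fraction Probability of a female record (default 0.086,
#'   a heavily male cohort).
#' @param abnormal_fraction Fraction of records given 1-2 abnormal
#'   analytes (default 0.45).
#' @param high_side_share Probability that an abnormal analyte deviates on
#'   the high side (default 0.15; high-side abnormalities are scarce).
#' @param analyte_params Per-analyte parameters as in
#'   [default_analyte_params()].
#' @param age_bins List of `c(low, high)` year ranges.
#' @param age_weights Sampling weights over `age_bins`.
#' @param seed Integer seed.
#' @return Panel `data.frame` (see [read_panel_csv()] for the schema).
#' @export
generate_panels <- function(n,
                            female_fraction = 0.086,
                            abnormal_fraction = 0.45,
                            high_side_share = 0.15,
                            analyte_params = default_analyte_params(),
                            age_bins = list(c(18, 40), c(41, 50),
                                            c(51, 64), c(65, 90)),
                            age_weights = c(38595, 13944, 5949, 19894),
                            seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  for (f in c(female_fraction, abnormal_fraction, high_side_share)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      stop("fractions must lie in [0, 1]")
    }
  }
  if (!identical(rownames(analyte_params), PANEL_ANALYTES) ||
      any(analyte_params$sd <= 0)) {
    stop("analyte_params must cover the five analytes with positive sd")
  }
  if (length(age_bins) != length(age_weights)) {
    stop("age_bins and age_weights must have equal length")
  }
  with_seed(seed, {
    gender <- ifelse(stats::runif(n) < female_fraction, -1, 1)
    bin <- sample.int(length(age_bins), n, replace = TRUE,
                      prob = age_weights / sum(age_weights))
    lo <- vapply(age_bins, `[`, 0, 1L)[bin]
    hi <- vapply(age_bins, `[`, 0, 2L)[bin]
    age <- floor(stats::runif(n, lo, hi + 1))
    values <- matrix(stats::rnorm(n * 5L,
                                  rep(analyte_params$mean, each = n),
                                  rep(analyte_params$sd, each = n)),
                     nrow = n, dimnames = list(NULL, PANEL_ANALYTES))
    abnormal <- stats::runif(n) < abnormal_fraction
    for (i in which(abnormal)) {
      k <- sample.int(2L, 1L)              # 1 or 2 abnormal analytes
      which_analytes <- sample.int(5L, k)
      for (j in which_analytes) {
        high <- stats::runif(1) < high_side_share
        shift <- if (high) analyte_params$high_shift[j] else
          -analyte_params$low_shift[j]
        values[i, j] <- stats::rnorm(1, analyte_params$mean[j] + shift,
                                     analyte_params$sd[j])
      }
    }
    values[values < 0] <- 0
    data.frame(subject_id = sprintf("S%06d", seq_len(n)),
               age = as.integer(age), gender = gender,
               as.data.frame(values))
  })
}

#' Write a seeded fixture panel plus its downstream-count manifest
#'
#' Generates a panel with a frozen seed, writes it as CSV, runs the
#' preprocessing stages once (normalize, statistics, elimination at
#' `a_fe = 1`, self-weighting, interval selection) and writes the
#' resulting counts to a JSON manifest for regression testing:
#' regenerating the fixture must reproduce the manifest exactly.
#'
#' @param size `"small"` (500 records, seed 101) or `"medium"`
#'   (5000 records, seed 202).
#' @param dir Output directory (default a temporary one).
#' @return List with `panel_path`, `manifest_path` and the `manifest`
#'   itself (`n`, `n_eliminated`, `n_retained`, per-interval existing
#'   counts).
#' @export
make_fixture <- function(size = c("small", "medium"), dir = tempdir()) {
  size <- match.arg(size)
  n <- switch(size, small = 500L, medium = 5000L)
  fixture_seed <- switch(size, small = 101L, medium = 202L)
  records <- generate_panels(n, seed = fixture_seed)
  panel_path <- file.path(dir, paste0("panel_", size, ".csv"))
  write_panel_csv(records, panel_path)
  norm <- min_max_normalize(panel_matrix(records))
  s <- analyte_stats(norm)
  elim <- eliminate_normal_records(norm, s, a_fe = 1)
  wp <- self_weight(norm, s, elim)
  sel <- select_by_interval(wp, i_t = 300)
  manifest <- list(size = size, n = n, seed = fixture_seed,
                   n_eliminated = elim$n_eliminated,
                   n_retained = elim$n_retained,
                   n_selected = length(sel$training_set$d_tr),
                   existing_pos = sel$summary$existing_pos,
                   existing_neg = sel$summary$existing_neg)
  manifest_path <- file.path(dir, paste0("panel_", size, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  list(panel_path = panel_path, manifest_path = manifest_path,
       manifest = manifest)
}
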