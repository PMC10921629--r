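# End-to-end pipeline driver: normalize -> statistics -> eliminate ->
# self-weight -> select -> split -> fit (x4) -> evaluate, with CSV/JSON
# artifacts and a run manifest.

#' Write a split training set to CSV
#'
#' Columns `htc_n,hgb_n,wbc_n,plt_n,mpv_n,label,split` (normalized
#' analytes, percent label, partition tag).
#'
#' @param ts A `training_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_training_set_csv <- function(ts, path) {
  df <- as.data.frame(ts$d_e)
  names(df) <- paste0(PANEL_ANALYTES, "_n")
  df$label <- ts$d_tr
  df$split <- ts$split
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a training set written by [write_training_set_csv()]
#'
#' @param path CSV file path.
#' @return A `training_set` (without source-row provenance).
#' @export
read_training_set_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c(paste0(PANEL_ANALYTES, "_n"), "label", "split")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("training-set CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  d_e <- as.matrix(df[, paste0(PANEL_ANALYTES, "_n")])
  colnames(d_e) <- PANEL_ANALYTES
  structure(list(d_e = d_e, d_tr = df$label,
                 interval = sign(df$label) * ceiling(abs(df$label) / 10),
                 source_rows = seq_len(nrow(df)),
                 split = as.character(df$split)),
            class = "training_set")
}

#' Write a fit result to JSON
#'
#' @param fr A `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_result_json <- function(fr, path) {
  jsonlite::write_json(list(
    algorithm = fr$algorithm,
    w = unname(fr$w),
    error_trace = fr$error_trace,
    converged = fr$converged,
    seed_used = fr$seed_used
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Executes every stage on an input panel (read from CSV, passed directly,
#' or simulated): min-max normalization, analyte statistics, band
#' elimination, self-weighting, interval selection, stratified split, the
#' four learners, and evaluation on both partitions. Artifacts
#' (`training_set.csv`, `selection_summary.csv`, `fit_<alg>.json`,
#' `evaluation.csv`, `manifest.json`) are written to `output_dir` when one
#' is given; on a stage failure, partial artifacts are removed. Each
#' stochastic stage gets a sub-seed derived from `seed`, recorded in the
#' manifest.
#'
#' @param input Panel `data.frame`, or path to a panel CSV, or `NULL` to
#'   simulate.
#' @param simulate_n Number of synthetic records when `input` is `NULL`
#'   (default 5000).
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param a_fe Elimination band multiplier (default 1).
#' @param i_t Required records per risk interval (default 300).
#' @param interval_width Risk interval width in percent (default 10).
#' @param fraction Training fraction (default 0.75).
#' @param configs Per-algorithm settings, as in [compare_algorithms()].
#' @param algorithms Learners to run (default all four).
#' @param seed Master integer seed.
#' @return List with `report`, `fits`, `training_set`, `summary`, `stats`,
#'   `elimination` and `manifest`.
#' @export
run_pipeline <- function(input = NULL, simulate_n = 5000L,
                         output_dir = NULL,
                         a_fe = 1, i_t = 300, interval_width = 10,
                         fraction = 0.75, configs = list(),
                         algorithms = c("BLS", "INN", "LSLC", "SCE"),
                         seed = 1L) {
  seed <- as.integer(seed)
  gen_seed <- seed
  split_seed <- seed + 1000L
  fit_seed <- seed + 2000L
  written <- character(0)
  on_fail_cleanup <- function() {
    if (length(written) > 0L) unlink(written)
  }
  result <- tryCatch({
    records <- if (is.null(input)) {
      generate_panels(simulate_n, seed = gen_seed)
    } else if (is.character(input)) {
      read_panel_csv(input)
    } else {
      validate_panel(input)
    }
    norm <- min_max_normalize(panel_matrix(records))
    s <- analyte_stats(norm)
    elim <- eliminate_normal_records(norm, s, a_fe = a_fe)
    wp <- self_weight(norm, s, elim)
    sel <- select_by_interval(wp, i_t = i_t, interval_width = interval_width)
    ts <- split_train_test(sel$training_set, fraction = fraction,
                           seed = split_seed)
    cmp <- compare_algorithms(ts, configs = configs, seed = fit_seed)
    cmp$report <- cmp$report[cmp$report$algorithm %in% algorithms, ,
                             drop = FALSE]
    manifest <- list(
      config = list(a_fe = a_fe, i_t = i_t,
                    interval_width = interval_width, fraction = fraction,
                    algorithms = algorithms, simulated = is.null(input),
                    simulate_n = if (is.null(input)) simulate_n else NULL),
      seeds = list(master = seed, generate = gen_seed,
                   split = split_seed, fit = fit_seed),
      counts = list(total = nrow(records),
                    eliminated = elim$n_eliminated,
                    retained = elim$n_retained,
                    selected = length(ts$d_tr),
                    train = sum(ts$split == "train"),
                    test = sum(ts$split == "test"))
    )
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(output_dir, c(
        "training_set.csv", "selection_summary.csv", "evaluation.csv",
        "manifest.json",
        paste0("fit_", tolower(algorithms), ".json")))
      written <- paths
      write_training_set_csv(ts, paths[1L])
      utils::write.csv(sel$summary, paths[2L], row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(cmp$report, paths[3L], row.names = FALSE,
                       quote = FALSE)
      jsonlite::write_json(manifest, paths[4L], auto_unbox = TRUE,
                           digits = NA, null = "null")
      for (alg in algorithms) {
        if (!is.null(cmp$fits[[alg]])) {
          write_fit_result_json(
            cmp$fits[[alg]],
            file.path(output_dir, paste0("fit_", tolower(alg), ".json")))
        }
      }
    }
    list(report = cmp$report, fits = cmp$fits[algorithms],
         training_set = ts, summary = sel$summary, stats = s,
         elimination = elim, manifest = manifest)
  }, error = function(e) {
    on_fail_cleanup()
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  result
}
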