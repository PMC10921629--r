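# Elimination band, self-weighting and interval selection.

# A 6-record normalized matrix engineered around known column statistics:
# each column holds 0 and 1 so the observed extremes are the scale ends.
weighting_fixture <- function() {
  base <- c(0, 1, 0.5, 0.5, 0.5, 0.5)
  v <- matrix(rep(base, 5), ncol = 5)
  known_norm_matrix(v)
}

test_that("a record is eliminated iff every analyte sits inside its band", {
  m <- weighting_fixture()
  s <- analyte_stats(m)
  r <- eliminate_normal_records(m, s, a_fe = 1)

  # all-at-mean record is inside every band, hence eliminated
  expect_equal(s$mean, rep(0.5, 5))
  expect_false(r$keep_mask[3])
  # rows holding the extremes are retained
  expect_true(r$keep_mask[1])
  expect_true(r$keep_mask[2])
  expect_equal(r$n_eliminated + r$n_retained, nrow(m$values))

  # one analyte two stds out keeps the whole record
  v <- matrix(0.5, nrow = 8, ncol = 5)
  v[1, ] <- 0; v[2, ] <- 1          # anchor extremes
  v[5, 3] <- 0.5 + 2 * analyte_stats(known_norm_matrix(v))$std[3]
  m2 <- known_norm_matrix(v)
  s2 <- analyte_stats(m2)
  r2 <- eliminate_normal_records(m2, s2, a_fe = 1)
  expect_true(r2$keep_mask[5])
  expect_false(r2$keep_mask[6])

  # band wide enough to cover [0, 1] eliminates everything
  r3 <- eliminate_normal_records(m, s, a_fe = 100)
  expect_equal(r3$n_eliminated, nrow(m$values))
})

test_that("the elimination sweep is monotone and matches per-value calls", {
  rec <- generate_panels(800, seed = 6)
  m <- min_max_normalize(panel_matrix(rec))
  s <- analyte_stats(m)
  sweep_values <- c(0.1, 0.5, 1, 2, 3)
  tab <- elimination_sweep(m, s, sweep_values)
  expect_equal(tab$a_fe, sweep_values)
  # weakly increasing eliminated counts as the band widens
  expect_true(all(diff(tab$n_eliminated) >= 0))
  # oracle: one eliminate_normal_records call per value
  for (i in seq_along(sweep_values)) {
    expect_equal(tab$n_eliminated[i],
                 eliminate_normal_records(m, s, sweep_values[i])$n_eliminated)
  }
  # a_fe = 0: only records with every analyte exactly at its mean go
  tab0 <- elimination_sweep(m, s, 0)
  at_mean <- sum(apply(m$values, 1, function(x) all(x == s$mean)))
  expect_equal(tab0$n_eliminated, at_mean)
  expect_error(elimination_sweep(m, s, c(1, -1)), "non-negative")
})

test_that("eliminated sets are nested as the band widens", {
  for (seed in 1:8) {
    rec <- generate_panels(400, seed = seed)
    m <- min_max_normalize(panel_matrix(rec))
    s <- analyte_stats(m)
    grid <- c(0.25, 0.5, 1, 1.5, 2.5)
    masks <- lapply(grid, function(a) !eliminate_normal_records(m, s, a)$keep_mask)
    for (i in seq_len(length(grid) - 1)) {
      expect_true(all(masks[[i + 1]][masks[[i]]]),
                  label = sprintf("seed %d: eliminated(a=%g) subset of a=%g",
                                  seed, grid[i], grid[i + 1]))
    }
  }
})

test_that("self-weights span the band to the observed extremes", {
  m <- weighting_fixture()
  s <- analyte_stats(m)
  r <- eliminate_normal_records(m, s, a_fe = 1)
  wp <- self_weight(m, s, r)

  row_of <- function(src) which(wp$source_rows == src)
  # global minimum -> worst-case low, global maximum -> worst-case high
  expect_equal(unname(wp$analyte_weights[row_of(1), ]), rep(-100, 5))
  expect_equal(unname(wp$analyte_weights[row_of(2), ]), rep(100, 5))
  expect_equal(wp$record_label[row_of(1)], -100)
  expect_equal(wp$record_label[row_of(2)], 100)

  # a value exactly at mean + beta carries zero weight: with column
  # values (0, 1, 0.5 + d, 0.5 - d) the mean is 0.5 and the band edge
  # d = a * std solves d^2 = a^2 (0.5 + 2 d^2) / 4 in closed form
  a_fe <- 0.8
  d <- sqrt(0.5 * a_fe^2 / (4 - 2 * a_fe^2))
  v <- cbind(c(0, 1, 0.5 + d, 0.5 - d),   # record 3 exactly at the edge
             c(0, 1, 0.9, 0.1),           # record 3 clearly out of band
             c(0, 1, 0.5, 0.5),
             c(0, 1, 0.5, 0.5),
             c(0, 1, 0.5, 0.5))
  m3 <- known_norm_matrix(v)
  s3 <- analyte_stats(m3)
  expect_equal(a_fe * s3$std[1], d, tolerance = 1e-12)
  r3 <- eliminate_normal_records(m3, s3, a_fe = a_fe)
  expect_true(r3$keep_mask[3])            # retained through analyte 2
  wp3 <- self_weight(m3, s3, r3)
  i3 <- which(wp3$source_rows == 3)
  expect_equal(unname(wp3$analyte_weights[i3, 1]), 0)
  expect_gt(wp3$analyte_weights[i3, 2], 0)
})

test_that("weights are zero exactly inside the band and monotone outside", {
  rec <- generate_panels(600, seed = 12)
  m <- min_max_normalize(panel_matrix(rec))
  s <- analyte_stats(m)
  r <- eliminate_normal_records(m, s, 1)
  wp <- self_weight(m, s, r)
  expect_true(all(abs(wp$analyte_weights) <= 100))
  expect_true(all(abs(wp$record_label) <= 100))
  # every retained record has at least one nonzero weight
  expect_true(all(rowSums(wp$analyte_weights != 0) >= 1))
  v <- wp$values
  for (j in 1:5) {
    dev <- v[, j] - s$mean[j]
    inside <- abs(dev) <= s$std[j]
    expect_true(all(wp$analyte_weights[inside, j] == 0))
    out <- !inside
    expect_true(all(sign(wp$analyte_weights[out, j]) == sign(dev[out])))
    # |weight| strictly increasing in |deviation| beyond the band, per side
    for (sgn in c(-1, 1)) {
      side <- out & sign(dev) == sgn
      if (sum(side) > 2) {
        o <- order(abs(dev[side]))
        expect_true(all(diff(abs(wp$analyte_weights[side, j][o])) >= 0))
      }
    }
  }
})

test_that("record labels take the dominant analyte weight with fixed tie order", {
  expect_equal(assign_record_label(c(0, 0, -40, 0, 0)), -40)
  expect_equal(assign_record_label(c(30, -50, 0, 0, 0)), -50)
  # magnitude tie: HTC outranks HGB
  expect_equal(assign_record_label(c(50, -50, 0, 0, 0)), 50)
  expect_error(assign_record_label(rep(0, 5)), "eliminated")
})

test_that("interval selection caps each signed bin at i_t", {
  rec <- generate_panels(4000, seed = 20)
  m <- min_max_normalize(panel_matrix(rec))
  s <- analyte_stats(m)
  wp <- self_weight(m, s, eliminate_normal_records(m, s, 1))
  sel <- select_by_interval(wp, i_t = 300)
  sm <- sel$summary
  expect_equal(sm$selected_pos, pmin(sm$existing_pos, 300L))
  expect_equal(sm$selected_neg, pmin(sm$existing_neg, 300L))
  # every labelled record falls in exactly one bin
  expect_equal(sum(sm$existing_pos) + sum(sm$existing_neg),
               length(wp$record_label))
  expect_equal(length(sel$training_set$d_tr),
               sum(sm$selected_pos) + sum(sm$selected_neg))
  # fixture is rich enough that the cap actually binds somewhere
  expect_true(any(sm$existing_pos > 300 | sm$existing_neg > 300))

  # small i_t: under-filled bins keep everything they have
  sel2 <- select_by_interval(wp, i_t = 10)
  expect_true(all(sel2$summary$selected_pos <= 10))
  expect_equal(sel2$summary$selected_pos,
               pmin(sel2$summary$existing_pos, 10L))

  # empty bins report zero existing and selected without error
  extreme_only <- abs(wp$record_label) > 55
  few <- structure(list(
    analyte_weights = wp$analyte_weights[extreme_only, , drop = FALSE],
    record_label = wp$record_label[extreme_only],
    values = wp$values[extreme_only, , drop = FALSE],
    source_rows = wp$source_rows[extreme_only]), class = "weighted_panel")
  sel3 <- select_by_interval(few, i_t = 300)
  mid <- sel3$summary$interval <= 50
  expect_true(all(sel3$summary$existing_pos[mid] == 0))
  expect_true(all(sel3$summary$selected_pos[mid] == 0))
})

test_that("within-bin selection ranks by label magnitude", {
  rec <- generate_panels(2000, seed = 33)
  m <- min_max_normalize(panel_matrix(rec))
  s <- analyte_stats(m)
  wp <- self_weight(m, s, eliminate_normal_records(m, s, 1))
  i_t <- 50
  sel <- select_by_interval(wp, i_t = i_t)
  ts <- sel$training_set
  bins <- sign(wp$record_label) * ceiling(abs(wp$record_label) / 10)
  for (b in unique(ts$interval)) {
    chosen <- ts$d_tr[ts$interval == b]
    pool <- wp$record_label[bins == b]
    if (length(pool) > i_t) {
      # the i_t largest magnitudes were taken
      expect_equal(sort(abs(chosen), decreasing = TRUE),
                   sort(abs(pool), decreasing = TRUE)[seq_len(i_t)])
    }
  }
})

test_that("train/test split is stratified, seeded and a partition", {
  ts <- imbalanced_training_set(1)
  out <- split_train_test(ts, 0.75, seed = 99)
  expect_setequal(unique(out$split), c("train", "test"))
  # per-bin rounding: a 4-record bin yields 3 train, 1 test
  for (b in unique(out$interval)) {
    nb <- sum(out$interval == b)
    expect_equal(sum(out$split == "train" & out$interval == b),
                 round(0.75 * nb))
  }
  # determinism and partition
  out2 <- split_train_test(ts, 0.75, seed = 99)
  expect_identical(out$split, out2$split)
  expect_equal(sum(out$split == "train") + sum(out$split == "test"),
               length(out$d_tr))
  expect_error(split_train_test(ts, 1.2, 1), "between 0 and 1")
})
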