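# Shared fixtures built in code.

# A tiny handwritten panel table.
tiny_panel <- function() {
  data.frame(subject_id = c("a", "b", "c", "d"),
             age = c(25L, 40L, 63L, 70L),
             gender = c(1, -1, 1, 1),
             htc = c(40, 42, 45, 38),
             hgb = c(13.5, 14.2, 15.0, 12.8),
             wbc = c(6.2, 7.5, 9.9, 5.4),
             plt = c(240, 260, 310, 180),
             mpv = c(9.8, 10.1, 10.9, 9.2))
}

# Write a panel data frame to a temporary CSV, optionally permuting columns.
write_tmp_panel <- function(df, permute = FALSE) {
  path <- tempfile(fileext = ".csv")
  if (permute) df <- df[, rev(names(df))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A normalized panel matrix with exactly known column structure, built
# through the package constructor so elimination/weighting tests can place
# values precisely. Values must include 0 and 1 per column.
known_norm_matrix <- function(values) {
  colnames(values) <- PANEL_ANALYTES
  bloodrisk:::new_panel_matrix(values, normalized = TRUE)
}

# An imbalance fixture: abundant negative-label rows, scarce positive,
# with a label map (tanh + sine) outside the span of the power basis, so
# a global least-squares fit trades accuracy toward the dense region.
imbalanced_training_set <- function(seed, n_neg = 950, n_pos = 50) {
  set.seed(seed)
  x_neg <- matrix(stats::runif(n_neg * 5, 0, 0.5), ncol = 5)
  x_pos <- matrix(stats::runif(n_pos * 5, 0.5, 1), ncol = 5)
  d <- rbind(x_neg, x_pos)
  colnames(d) <- PANEL_ANALYTES
  lab <- 100 * tanh(4 * (d[, 1] - 0.5)) + 10 * sin(6 * d[, 2])
  lab <- pmax(pmin(lab, 100), -100)
  lab[seq_len(n_neg)] <- pmin(lab[seq_len(n_neg)], -1)
  lab[(n_neg + 1):(n_neg + n_pos)] <-
    pmax(lab[(n_neg + 1):(n_neg + n_pos)], 1)
  structure(list(d_e = d, d_tr = lab,
                 interval = sign(lab) * ceiling(abs(lab) / 10),
                 source_rows = seq_along(lab),
                 split = rep(NA_character_, length(lab))),
            class = "training_set")
}

# Well-conditioned consistent regression instance: orthonormal columns
# scaled by 2, labels exactly in the column span.
consistent_instance <- function(seed, m = 20L, p = 6L) {
  set.seed(seed)
  b <- qr.Q(qr(matrix(stats::rnorm(m * p), m, p))) * 2
  w_star <- stats::rnorm(p)
  list(b = b, w_star = w_star, y = drop(b %*% w_star))
}
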