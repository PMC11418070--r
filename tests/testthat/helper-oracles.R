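# Independent, deliberately naive re-implementations used as oracles.
# They follow the verbal recipes with explicit loops and never call the
# package's own scoring/ANOVA code paths.

# risk rating: per topic, substitute zeros, sum ratings, divide by the
# maximum possible for the rated count, scale by TRR, add topics up
naive_risk_rating <- function(ratings, instrument) {
  total <- 0
  for (i in seq_len(nrow(instrument$topics))) {
    tid <- instrument$topics$id[i]
    trr <- instrument$topics$trr[i]
    fids <- instrument$factors$id[instrument$factors$topic_id == tid]
    vals <- c()
    for (f in fids) {
      v <- if (f %in% names(ratings)) ratings[[f]] else NA
      if (!is.na(v)) {
        if (v == 0) v <- instrument$zero_substitute
        vals <- c(vals, v)
      }
    }
    if (length(vals) > 0) {
      frac <- sum(vals) / (instrument$rating_scale_max * length(vals))
      total <- total + trr * frac
    }
  }
  total
}

# MOC, subtraction form: unrated count times factor value, taken off each TRR
naive_moc_subtraction <- function(ratings, instrument) {
  total <- 0
  for (i in seq_len(nrow(instrument$topics))) {
    tid <- instrument$topics$id[i]
    fids <- instrument$factors$id[instrument$factors$topic_id == tid]
    m <- 0
    for (f in fids) {
      v <- if (f %in% names(ratings)) ratings[[f]] else NA
      if (is.na(v)) m <- m + 1
    }
    fv <- instrument$topics$trr[i] / length(fids)
    total <- total + (instrument$topics$trr[i] - m * fv)
  }
  total
}

# MOC, additive form: rated count times factor value
naive_moc_additive <- function(ratings, instrument) {
  total <- 0
  for (i in seq_len(nrow(instrument$topics))) {
    tid <- instrument$topics$id[i]
    fids <- instrument$factors$id[instrument$factors$topic_id == tid]
    r <- 0
    for (f in fids) {
      v <- if (f %in% names(ratings)) ratings[[f]] else NA
      if (!is.na(v)) r <- r + 1
    }
    total <- total + r * instrument$topics$trr[i] / length(fids)
  }
  total
}

# brute-force two-way ANOVA sums of squares by direct summation
naive_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_rows <- 0; ss_cols <- 0; ss_total <- 0; ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_total <- ss_total + (m[i, j] - g)^2
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + g)^2
  }
  for (i in 1:n) ss_rows <- ss_rows + k * (mean(m[i, ]) - g)^2
  for (j in 1:k) ss_cols <- ss_cols + n * (mean(m[, j]) - g)^2
  list(ms_rows = ss_rows / (n - 1), ms_cols = ss_cols / (k - 1),
       ms_error = ss_err / ((n - 1) * (k - 1)),
       ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_err,
       ss_total = ss_total)
}

# closed-form simple OLS via the normal equations
naive_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# random instrument generator for property tests
random_instrument <- function() {
  n_topics <- sample(2:5, 1)
  w <- stats::runif(n_topics, 0.5, 3)
  trr <- 100 * w / sum(w)
  ids <- paste0("t", seq_len(n_topics))
  nf <- sample(1:6, n_topics, replace = TRUE)
  topics <- data.frame(id = ids, name = ids, trr = trr)
  factors <- do.call(rbind, lapply(seq_len(n_topics), function(i)
    data.frame(id = paste0(ids[i], "_f", seq_len(nf[i])),
               label = "x", topic_id = ids[i])))
  new_instrument(topics, factors)
}

# random ratings vector over an instrument, with missingness
random_ratings <- function(instrument, p_missing = 0.3,
                           ensure_one = TRUE) {
  fids <- instrument$factors$id
  v <- stats::runif(length(fids), 0, 100)
  v[sample(c(TRUE, FALSE), length(fids), replace = TRUE,
           prob = c(p_missing, 1 - p_missing))] <- NA
  # zeros with some probability, to exercise the substitution rule
  zer <- !is.na(v) & stats::runif(length(fids)) < 0.1
  v[zer] <- 0
  if (ensure_one && all(is.na(v))) v[sample(length(fids), 1)] <- 50
  stats::setNames(v, fids)
}

full_ratings <- function(instrument, value = 50) {
  stats::setNames(rep(value, nrow(instrument$factors)),
                  instrument$factors$id)
}
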