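#' Read observation-study responses from CSV
#'
#' Columns: \code{observer_code, session, item_id, rating}, optionally
#' \code{timestamp} (ISO-8601 date). Ratings are 0-100 visual-analogue
#' values; empty cells are missing.
#'
#' @param path CSV file path.
#' @return data.frame of responses.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_code", "session", "item_id", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation CSV missing column(s): ", paste(miss, collapse = ", "))
  df$session <- as.integer(df$session)
  df$rating <- as.numeric(df$rating)
  if ("timestamp" %in% names(df)) df$timestamp <- as.Date(df$timestamp)
  bad <- !is.na(df$rating) & (df$rating < 0 | df$rating > 100)
  if (any(bad)) stop("rating out of [0, 100] at row(s): ",
                     paste(which(bad), collapse = ", "))
  df
}

#' Pair repeat test sessions per observer
#'
#' Builds, for each observer who completed both sessions, an items x 2
#' matrix of ratings for test-retest analysis. Items missing in either
#' session are dropped for that observer. Observers with a single session
#' are routed to the inter-observer pool unchanged. When both sessions
#' carry timestamps, pairs closer together than \code{min_gap_days} are
#' rejected; without timestamps the session labels are trusted.
#'
#' @param responses data.frame as from [read_observations()].
#' @param min_gap_days minimum days between the two sessions (default 10).
#' @return list with \code{paired} (named list of n x 2 matrices, one per
#'   observer), \code{unpaired} (observer codes with one session only) and
#'   \code{rejected_gap} (codes whose sessions were too close together).
#' @export
pair_sessions <- function(responses, min_gap_days = 10) {
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  paired <- list()
  unpaired <- character()
  rejected <- character()
  for (obs in unique(responses$observer_code)) {
    sub <- responses[responses$observer_code == obs, , drop = FALSE]
    sess <- sort(unique(sub$session))
    if (length(sess) > 2)
      stop("observer '", obs, "' has more than two sessions: ",
           paste(sess, collapse = ", "))
    if (length(sess) < 2) {
      unpaired <- c(unpaired, obs)
      next
    }
    if ("timestamp" %in% names(sub) && !all(is.na(sub$timestamp))) {
      d1 <- unique(sub$timestamp[sub$session == sess[1]])
      d2 <- unique(sub$timestamp[sub$session == sess[2]])
      if (length(d1) == 1 && length(d2) == 1 &&
          !is.na(d1) && !is.na(d2) &&
          abs(as.numeric(d2 - d1)) < min_gap_days) {
        rejected <- c(rejected, obs)
        next
      }
    }
    s1 <- sub[sub$session == sess[1], c("item_id", "rating")]
    s2 <- sub[sub$session == sess[2], c("item_id", "rating")]
    items <- intersect(s1$item_id, s2$item_id)
    m <- cbind(s1$rating[match(items, s1$item_id)],
               s2$rating[match(items, s2$item_id)])
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- items[keep]
    colnames(m) <- paste0("session", sess)
    paired[[obs]] <- m
  }
  list(paired = paired, unpaired = unpaired, rejected_gap = rejected)
}

#' Two-way ANOVA decomposition of a complete rating matrix
#'
#' Partitions the variation of an n x k grid (items in rows, raters or
#' sessions in columns, one observation per cell) into between-item,
#' between-rater and residual sums of squares, and returns the mean squares
#' needed by the intraclass correlation formulas. The layout is balanced,
#' so the sums of squares are computed directly from row, column and grand
#' means; df are n-1, k-1 and (n-1)(k-1).
#'
#' @param m numeric matrix with no missing cells, n >= 2 rows, k >= 2 cols.
#' @return object of class \code{awrat_anova}: list with \code{ms_rows},
#'   \code{ms_cols}, \code{ms_error}, \code{ss_rows}, \code{ss_cols},
#'   \code{ss_error}, \code{ss_total}, \code{n}, \code{k}.
#' @export
anova_decompose <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("rating matrix has missing cells; complete cases only")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 raters, got ",
                           n, " x ", k)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ss_error <- max(ss_error, 0)  # guard tiny negative from rounding
  structure(
    list(ms_rows = ss_rows / (n - 1),
         ms_cols = ss_cols / (k - 1),
         ms_error = ss_error / ((n - 1) * (k - 1)),
         ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
         ss_total = ss_total, n = n, k = k),
    class = "awrat_anova")
}

#' Intraclass correlation coefficient from ANOVA mean squares
#'
#' Single-rater ICC computed from a two-way decomposition. The default,
#' ICC(2,1), treats raters as a random sample and measures absolute
#' agreement — the right notion when assessors must be interchangeable:
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)}}
#' ICC(3,1) (consistency, raters fixed) and ICC(1,1) (one-way random) are
#' available. Values are reported as computed — negative estimates are not
#' truncated — so small-sample estimator behaviour stays visible.
#'
#' @param decomp an \code{awrat_anova}, or a complete rating matrix which
#'   is decomposed first.
#' @param form one of \code{"ICC2_1"} (default), \code{"ICC3_1"},
#'   \code{"ICC1_1"}.
#' @return the coefficient (theoretical range [-1, 1] for k = 2; not
#'   clamped).
#' @export
icc <- function(decomp, form = c("ICC2_1", "ICC3_1", "ICC1_1")) {
  form <- match.arg(form)
  if (is.matrix(decomp) || is.data.frame(decomp))
    decomp <- anova_decompose(decomp)
  stopifnot(inherits(decomp, "awrat_anova"))
  msr <- decomp$ms_rows; msc <- decomp$ms_cols; mse <- decomp$ms_error
  n <- decomp$n; k <- decomp$k
  val <- switch(form,
    ICC2_1 = {
      den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
      if (abs(den) < .Machine$double.eps * 100)
        stop("degenerate data: zero ICC(2,1) denominator")
      (msr - mse) / den
    },
    ICC3_1 = {
      den <- msr + (k - 1) * mse
      if (abs(den) < .Machine$double.eps * 100)
        stop("degenerate data: zero ICC(3,1) denominator")
      (msr - mse) / den
    },
    ICC1_1 = {
      # one-way layout: rater and residual variation pool into MS within
      msw <- (decomp$ss_cols + decomp$ss_error) / (n * (k - 1))
      den <- msr + (k - 1) * msw
      if (abs(den) < .Machine$double.eps * 100)
        stop("degenerate data: zero ICC(1,1) denominator")
      (msr - msw) / den
    })
  val
}

#' Intra-observer (test-retest) reliability report
#'
#' Computes one ICC per observer over their items x 2 sessions matrix and
#' summarises how many observers reach a reliability threshold.
#'
#' @param paired named list of n x 2 matrices, as from
#'   [pair_sessions()]\code{$paired}.
#' @param form ICC variant, see [icc()].
#' @param threshold reliability threshold for the summary (default 0.8).
#' @return list with \code{table} (data.frame: observer, n_items, icc,
#'   at_threshold), \code{n_observers}, \code{n_ge_threshold},
#'   \code{prop_ge_threshold}, \code{icc_range} (min, max).
#' @export
intra_observer_report <- function(paired, form = "ICC2_1", threshold = 0.8) {
  if (!length(paired)) stop("no paired observers to report on")
  rows <- lapply(names(paired), function(obs) {
    m <- paired[[obs]]
    val <- tryCatch(icc(m, form), error = function(e) NA_real_)
    data.frame(observer = obs, n_items = nrow(m), icc = val,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$at_threshold <- !is.na(tab$icc) & tab$icc >= threshold
  ok <- tab$icc[!is.na(tab$icc)]
  list(table = tab,
       n_observers = nrow(tab),
       n_ge_threshold = sum(tab$at_threshold),
       prop_ge_threshold = mean(tab$at_threshold),
       icc_range = if (length(ok)) range(ok) else c(NA_real_, NA_real_),
       threshold = threshold, form = form)
}

#' Inter-observer reliability
#'
#' Agreement across observers: each observer contributes their first (or
#' only) session; observers with any missing rating over the item set are
#' removed before analysis, leaving a complete items x observers matrix
#' from which a single ICC is computed.
#'
#' @param responses data.frame as from [read_observations()].
#' @param form ICC variant, see [icc()].
#' @return list with \code{icc}, \code{n_items}, \code{n_observers},
#'   \code{observers_used}, \code{observers_dropped}.
#' @export
inter_observer_icc <- function(responses, form = "ICC2_1") {
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  items <- sort(unique(responses$item_id))
  cols <- list()
  dropped <- character()
  for (obs in unique(responses$observer_code)) {
    sub <- responses[responses$observer_code == obs, , drop = FALSE]
    first <- min(sub$session)
    sub <- sub[sub$session == first, , drop = FALSE]
    v <- sub$rating[match(items, sub$item_id)]
    if (anyNA(v)) dropped <- c(dropped, obs) else cols[[obs]] <- v
  }
  if (length(cols) < 2)
    stop("insufficient data: fewer than 2 observers with complete tests")
  m <- do.call(cbind, cols)
  rownames(m) <- items
  list(icc = icc(m, form), n_items = nrow(m), n_observers = ncol(m),
       observers_used = colnames(m), observers_dropped = dropped,
       form = form)
}

#' Full observation-study reliability analysis
#'
#' Convenience wrapper: pairs sessions, computes the per-observer
#' test-retest ICC table and the pooled inter-observer ICC.
#'
#' @inheritParams inter_observer_icc
#' @inheritParams intra_observer_report
#' @param min_gap_days minimum days between paired sessions.
#' @return list with \code{intra} (see [intra_observer_report()]),
#'   \code{inter} (see [inter_observer_icc()]; NULL with a message if
#'   fewer than two complete observers), and \code{pairing}.
#' @export
reliability_report <- function(responses, form = "ICC2_1", threshold = 0.8,
                               min_gap_days = 10) {
  pairing <- pair_sessions(responses, min_gap_days)
  intra <- if (length(pairing$paired))
    intra_observer_report(pairing$paired, form, threshold) else NULL
  inter <- tryCatch(inter_observer_icc(responses, form),
                    error = function(e) conditionMessage(e))
  list(intra = intra, inter = inter, pairing = pairing)
}
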