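#' Clean raw assessment records for analysis
#'
#' Applies the trial's exclusion rules, in order: records with no factor
#' ratings at all; records with no overall welfare rating (WR); records
#' for non-key livestock species; records entered more than
#' \code{recency_days} days after the farm visit (retrospective entries
#' are unreliable); and same-day duplicates, keeping one assessment per
#' farm per record date (the last-entered, i.e. latest file order).
#'
#' @param records assessment data.frame (see [read_assessments()]).
#' @param instrument an \code{awrat_instrument} (identifies factor columns).
#' @param recency_days maximum days between visit and data entry
#'   (default 31, a fixed testable bound for "within one month").
#' @param key_species species retained (default cattle, sheep, goats).
#' @return list with \code{records} (the retained rows) and \code{report},
#'   a \code{CleaningReport} data.frame of per-rule removal counts whose
#'   total plus \code{n_retained} equals \code{n_input}.
#' @export
clean_records <- function(records, instrument, recency_days = 31,
                          key_species = c("cattle", "sheep", "goats")) {
  stopifnot(inherits(instrument, "awrat_instrument"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n_input <- nrow(records)
  fids <- intersect(instrument$factors$id, names(records))
  if (!length(fids)) stop("records carry no instrument factor columns")

  # rule 1: no factor values at all
  has_value <- rowSums(!is.na(records[, fids, drop = FALSE])) > 0
  n_no_values <- sum(!has_value)
  records <- records[has_value, , drop = FALSE]

  # rule 2: no WR
  has_wr <- !is.na(records$wr)
  n_no_wr <- sum(!has_wr)
  records <- records[has_wr, , drop = FALSE]

  # rule 3: non-key livestock
  keep_sp <- records$species %in% key_species
  n_species <- sum(!keep_sp)
  records <- records[keep_sp, , drop = FALSE]

  # rule 4: stale entry (recorded too long after the visit)
  vd <- as.Date(records$visit_date)
  rd <- as.Date(records$record_date)
  bad_date <- is.na(vd) | is.na(rd)
  n_bad_dates <- sum(bad_date)
  lag <- as.numeric(rd - vd)
  fresh <- !bad_date & lag <= recency_days
  n_stale <- sum(!fresh & !bad_date)
  records <- records[fresh, , drop = FALSE]

  # rule 5: one assessment per farm per record date; keep the last entered
  if (nrow(records)) {
    key <- paste(records$farm_code, as.Date(records$record_date))
    keep <- !duplicated(key, fromLast = TRUE)
  } else keep <- logical(0)
  n_dupes <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL

  report <- data.frame(
    n_input = n_input,
    n_removed_no_values = n_no_values,
    n_removed_no_wr = n_no_wr,
    n_removed_species = n_species,
    n_removed_bad_dates = n_bad_dates,
    n_removed_stale = n_stale,
    n_removed_same_day_dupes = n_dupes,
    n_retained = nrow(records))
  stopifnot(report$n_input == report$n_retained +
              n_no_values + n_no_wr + n_species + n_bad_dates +
              n_stale + n_dupes)
  list(records = records, report = report)
}

#' Parse a compact MOC stratum specification
#'
#' Tokens: \code{all}, \code{geNN} (MOC >= NN) and \code{eqNN} (MOC = NN),
#' comma separated. The default \code{"all,ge70,ge80,ge90,eq100"} mirrors
#' the strata used to study how completeness affects validity.
#'
#' @param spec specification string.
#' @return data.frame with columns \code{stratum} (label), \code{op}
#'   (\code{all}, \code{ge} or \code{eq}) and \code{cut} (numeric, NA for
#'   \code{all}).
#' @export
parse_strata <- function(spec = "all,ge70,ge80,ge90,eq100") {
  toks <- trimws(strsplit(spec, ",")[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty strata specification")
  rows <- lapply(toks, function(tk) {
    if (tk == "all")
      return(data.frame(stratum = "all", op = "all", cut = NA_real_))
    m <- regmatches(tk, regexec("^(ge|eq)([0-9]+(\\.[0-9]+)?)$", tk))[[1]]
    if (!length(m)) stop("bad stratum token: '", tk,
                         "' (expected all, geNN or eqNN)")
    data.frame(stratum = ifelse(m[2] == "ge",
                                paste0("MOC>=", m[3]),
                                paste0("MOC=", m[3])),
               op = m[2], cut = as.numeric(m[3]))
  })
  do.call(rbind, rows)
}

#' MOC-stratified linear regression of WR on the risk rating
#'
#' For each MOC stratum, fits ordinary least squares with the overall
#' welfare rating (WR) as response and the AWRAT risk rating as the single
#' predictor, and reports slope, intercept, adjusted R-squared and the
#' two-sided slope p-value. Higher adjusted R-squared in high-MOC strata
#' indicates the composite tracks the holistic judgement better when more
#' factors were rated.
#'
#' @param scored data.frame holding \code{wr}, \code{risk_rating} and
#'   \code{moc} columns, e.g. the output of [score_batch()].
#' @param strata stratum table from [parse_strata()], or a spec string.
#' @return \code{RegressionReport} data.frame: one row per stratum with
#'   \code{stratum, n, slope, intercept, r2, adjusted_r2, p_value, note}.
#'   Strata with n < 3 or a constant predictor are reported with NA
#'   statistics and an explanatory note rather than aborting.
#' @export
stratified_regression <- function(scored, strata = parse_strata()) {
  if (is.character(strata)) strata <- parse_strata(strata)
  scored <- as.data.frame(scored, stringsAsFactors = FALSE)
  need <- c("wr", "risk_rating", "moc")
  miss <- setdiff(need, names(scored))
  if (length(miss)) stop("scored records missing column(s): ",
                         paste(miss, collapse = ", "))
  usable <- scored[!is.na(scored$wr) & !is.na(scored$risk_rating) &
                     !is.na(scored$moc), , drop = FALSE]

  out <- lapply(seq_len(nrow(strata)), function(i) {
    op <- strata$op[i]; cut <- strata$cut[i]
    sub <- switch(op,
                  all = usable,
                  ge = usable[usable$moc >= cut - 1e-9, , drop = FALSE],
                  eq = usable[abs(usable$moc - cut) <= 1e-9, , drop = FALSE])
    n <- nrow(sub)
    row <- data.frame(stratum = strata$stratum[i], n = n,
                      slope = NA_real_, intercept = NA_real_,
                      r2 = NA_real_, adjusted_r2 = NA_real_,
                      p_value = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (n < 3) { row$note <- "undefined: n < 3"; return(row) }
    if (stats::var(sub$risk_rating) == 0) {
      row$note <- "degenerate: constant predictor"; return(row)
    }
    fit <- stats::lm(wr ~ risk_rating, data = sub)
    # exact-linear data (e.g. noise-free cohorts) are legal: the perfect-fit
    # warning from summary.lm is expected there, not actionable
    sm <- suppressWarnings(summary(fit))
    row$slope <- unname(stats::coef(fit)[2])
    row$intercept <- unname(stats::coef(fit)[1])
    row$r2 <- sm$r.squared
    row$adjusted_r2 <- 1 - (1 - sm$r.squared) * (n - 1) / (n - 2)
    row$p_value <- sm$coefficients["risk_rating", "Pr(>|t|)"]
    row
  })
  do.call(rbind, out)
}

#' End-to-end trial analysis: clean, score, stratified regression
#'
#' Runs [clean_records()], [score_batch()] and [stratified_regression()]
#' and bundles the pieces. Output is deterministic given the input.
#'
#' @inheritParams clean_records
#' @param strata stratum table or spec string (see [parse_strata()]).
#' @param moc_threshold validity MOC threshold passed to [score_batch()].
#' @return list of class \code{awrat_trial_report}: \code{cleaning}
#'   (the CleaningReport), \code{scored} (scored retained records) and
#'   \code{regression} (the per-stratum RegressionReport).
#' @export
trial_report <- function(records, instrument, strata = parse_strata(),
                         recency_days = 31,
                         key_species = c("cattle", "sheep", "goats"),
                         moc_threshold = 70) {
  if (!nrow(as.data.frame(records))) stop("empty input: no records")
  cleaned <- clean_records(records, instrument, recency_days, key_species)
  if (!nrow(cleaned$records))
    stop("no records survive cleaning; see the cleaning report")
  scored <- score_batch(cleaned$records, instrument, moc_threshold)
  reg <- stratified_regression(scored, strata)
  structure(list(cleaning = cleaned$report, scored = scored,
                 regression = reg),
            class = "awrat_trial_report")
}

#' @export
print.awrat_trial_report <- function(x, ...) {
  cat("Cleaning:\n")
  print(x$cleaning, row.names = FALSE)
  cat("\nMOC-stratified regression of WR on AWRAT-RR:\n")
  print(x$regression, row.names = FALSE, digits = 4)
  invisible(x)
}
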