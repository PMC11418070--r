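#' Measure of Completeness (MOC)
#'
#' Missing factor ratings reduce the reliability of a risk assessment
#' unevenly: a skipped factor in a heavily weighted topic matters more.
#' The MOC weights each unrated factor by its factor value (TRR of its
#' topic divided by the topic's factor count) and subtracts the total from
#' the 100-point budget: \deqn{MOC = \sum_t (TRR_t - m_t \cdot v_t)} where
#' \eqn{m_t} is the number of unrated factors in topic \eqn{t} and
#' \eqn{v_t} its factor value. Equivalently the sum of
#' \eqn{r_t \cdot v_t} over rated counts \eqn{r_t}. MOC is 100 when every
#' factor is rated and 0 when none is.
#'
#' @param ratings named numeric vector of factor ratings on the instrument's
#'   scale; \code{NA} marks an unrated factor. Names are factor ids; factors
#'   absent from the vector count as unrated.
#' @param instrument an \code{awrat_instrument}.
#' @return the MOC, a number in [0, 100].
#' @examples
#' inst <- default_instrument()
#' full <- stats::setNames(rep(50, nrow(inst$factors)), inst$factors$id)
#' compute_moc(full, inst)  # 100
#' @export
compute_moc <- function(ratings, instrument) {
  stopifnot(inherits(instrument, "awrat_instrument"))
  ratings <- check_ratings(ratings, instrument)
  topics <- instrument$topics
  moc <- 0
  for (i in seq_len(nrow(topics))) {
    fids <- instrument$factors$id[instrument$factors$topic_id == topics$id[i]]
    m_unrated <- sum(is.na(ratings[fids]))
    moc <- moc + (topics$trr[i] - m_unrated * topics$factor_value[i])
  }
  moc
}

#' AWRAT risk rating for one assessment
#'
#' Produces the AWRAT-RR, a number on (0, 100] where 0 means an extremely
#' high risk of poor welfare and 100 an extremely low risk. Within each
#' topic area only rated factors are used: ratings of exactly 0 are first
#' replaced by \code{zero_substitute} (so a zero still counts as a value),
#' the substituted ratings are summed and divided by the maximum possible
#' rating for that many factors, and the fraction is scaled by the topic's
#' TRR. Topic contributions add up to the risk rating. A topic with no
#' rated factors contributes 0 and invalidates the result; validity also
#' requires MOC at or above \code{moc_threshold}.
#'
#' @inheritParams compute_moc
#' @param moc_threshold minimum MOC for a valid assessment (default 70).
#' @return object of class \code{awrat_risk}: list with \code{risk_rating},
#'   \code{moc}, \code{topic_contributions} (named), \code{topic_rated_counts}
#'   (named), \code{valid}, \code{validity_reasons}.
#' @examples
#' inst <- default_instrument()
#' r <- stats::setNames(rep(100, nrow(inst$factors)), inst$factors$id)
#' compute_risk_rating(r, inst)$risk_rating  # 100
#' @export
compute_risk_rating <- function(ratings, instrument, moc_threshold = 70) {
  stopifnot(inherits(instrument, "awrat_instrument"))
  ratings <- check_ratings(ratings, instrument)
  if (all(is.na(ratings)))
    stop("empty assessment: no factor carries a rating")

  topics <- instrument$topics
  contrib <- rated <- stats::setNames(numeric(nrow(topics)), topics$id)
  for (i in seq_len(nrow(topics))) {
    fids <- instrument$factors$id[instrument$factors$topic_id == topics$id[i]]
    vals <- ratings[fids]
    vals <- vals[!is.na(vals)]
    rated[i] <- length(vals)
    if (length(vals)) {
      vals[vals == 0] <- instrument$zero_substitute
      contrib[i] <- topics$trr[i] *
        sum(vals) / (instrument$rating_scale_max * length(vals))
    }
  }
  moc <- compute_moc(ratings, instrument)

  reasons <- character()
  if (any(rated == 0))
    reasons <- c(reasons, paste0("topic without ratings: ",
                                 paste(topics$id[rated == 0], collapse = ",")))
  if (moc < moc_threshold)
    reasons <- c(reasons, sprintf("MOC %.6g below threshold %g",
                                  moc, moc_threshold))

  structure(
    list(risk_rating = sum(contrib), moc = moc,
         topic_contributions = contrib,
         topic_rated_counts = rated,
         valid = length(reasons) == 0L,
         validity_reasons = reasons),
    class = "awrat_risk")
}

#' @export
print.awrat_risk <- function(x, ...) {
  cat(sprintf("AWRAT-RR %.4g  MOC %.4g  valid: %s\n",
              x$risk_rating, x$moc, x$valid))
  if (length(x$validity_reasons))
    cat("  ", paste(x$validity_reasons, collapse = "; "), "\n")
  invisible(x)
}

# validate a ratings vector against the instrument; returns the vector
# re-indexed over all instrument factors (missing names become NA)
check_ratings <- function(ratings, instrument) {
  if (is.null(names(ratings)) && length(ratings))
    stop("ratings must be a named vector keyed by factor id")
  unknown <- setdiff(names(ratings), instrument$factors$id)
  if (length(unknown))
    stop("ratings reference unknown factor id: ",
         paste(unknown, collapse = ", "))
  bad <- names(ratings)[!is.na(ratings) &
                        (ratings < 0 | ratings > instrument$rating_scale_max)]
  if (length(bad))
    stop("rating out of [0, ", instrument$rating_scale_max, "] for factor: ",
         paste(bad, collapse = ", "))
  full <- stats::setNames(rep(NA_real_, nrow(instrument$factors)),
                          instrument$factors$id)
  full[names(ratings)] <- as.numeric(ratings)
  full
}

#' Score a batch of assessment records
#'
#' Applies [compute_risk_rating()] row by row to an assessment table.
#' Records that cannot be scored (for example, no factor rated at all) are
#' kept in the output with \code{scored = FALSE} and the error message in
#' \code{validity_reasons}, so a single bad record never aborts a batch.
#'
#' @param records assessment data.frame: metadata columns plus one column
#'   per instrument factor id (NA = unrated). See [read_assessments()].
#' @inheritParams compute_risk_rating
#' @return the input data.frame with appended columns \code{risk_rating},
#'   \code{moc}, \code{valid}, \code{scored}, \code{validity_reasons} and
#'   one \code{contrib_<topic>} column per topic area.
#' @export
score_batch <- function(records, instrument, moc_threshold = 70) {
  stopifnot(inherits(instrument, "awrat_instrument"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records)) stop("empty batch: no assessment records")
  fids <- instrument$factors$id
  missing_cols <- setdiff(fids, names(records))
  if (length(missing_cols))  # absent column = factor never rated
    records[missing_cols] <- NA_real_

  n <- nrow(records)
  out <- records
  out$risk_rating <- NA_real_
  out$moc <- NA_real_
  out$valid <- NA
  out$scored <- FALSE
  out$validity_reasons <- ""
  for (t in instrument$topics$id) out[[paste0("contrib_", t)]] <- NA_real_

  for (i in seq_len(n)) {
    ratings <- unlist(records[i, fids, drop = FALSE])
    names(ratings) <- fids
    res <- tryCatch(compute_risk_rating(ratings, instrument, moc_threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$validity_reasons[i] <- conditionMessage(res)
      out$valid[i] <- FALSE
      next
    }
    out$risk_rating[i] <- res$risk_rating
    out$moc[i] <- res$moc
    out$valid[i] <- res$valid
    out$scored[i] <- TRUE
    out$validity_reasons[i] <- paste(res$validity_reasons, collapse = "; ")
    for (t in names(res$topic_contributions))
      out[[paste0("contrib_", t)]][i] <- res$topic_contributions[[t]]
  }
  out
}

#' Read assessment records from CSV
#'
#' Expected columns: \code{farm_code, participant_code, visit_date,
#' record_date, visit_reason, prior_offences, species, wr}, then one column
#' per factor id; empty cells mark unrated factors. Dates are ISO-8601.
#'
#' @param path CSV file path.
#' @param instrument optional \code{awrat_instrument}; when given, factor
#'   columns are checked against it and unknown extra columns rejected.
#' @return data.frame with parsed \code{Date} columns and numeric ratings.
#' @export
read_assessments <- function(path, instrument = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("farm_code", "participant_code", "visit_date", "record_date",
            "visit_reason", "prior_offences", "species", "wr")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stop("assessment CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(instrument)) {
    extra <- setdiff(names(df), c(meta, instrument$factors$id))
    if (length(extra))
      stop("unknown factor column(s) in assessment CSV: ",
           paste(extra, collapse = ", "))
  }
  df$visit_date <- as.Date(df$visit_date)
  df$record_date <- as.Date(df$record_date)
  df$prior_offences <- as.logical(df$prior_offences)
  df$wr <- as.numeric(df$wr)
  rate_cols <- setdiff(names(df), meta)
  for (cc in rate_cols) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write assessment or scored-assessment records to CSV
#'
#' @param records data.frame as produced by [simulate_assessments()] or
#'   [score_batch()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_assessments <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
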