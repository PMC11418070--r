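clamp01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

#' Simulate a cohort of farm assessments with a shared latent welfare state
#'
#' Each farm draws a latent welfare quality \eqn{q} on [0, 100]
#' (default \eqn{100 \cdot Beta(2, 2)}, a mild central tendency). The
#' overall welfare rating is \eqn{WR = q + N(0, \sigma_{wr})}; each topic
#' area draws a shared offset \eqn{d_t \sim N(0, \sigma_{topic})} (some
#' aspects of a farm are systematically better than others); each factor
#' rating is \eqn{q + d_t + N(0, \sigma_{factor})}. All values are clamped
#' to [0, 100], mirroring the hard stops of a visual-analogue slider.
#' Factors go unrated independently with probability \code{p_missing}
#' (missing completely at random); \code{missing_by_quality = TRUE}
#' makes poorer farms harder to assess by scaling the missingness
#' probability with \eqn{(100 - q)/100 \cdot 2}.
#'
#' @param n_farms number of farms (one assessment each).
#' @param instrument an \code{awrat_instrument}.
#' @param sigma_wr SD (rating points) of WR noise around q; default 10.
#' @param sigma_topic SD of the per-farm, per-topic offset; default 5.
#' @param sigma_factor SD of per-factor noise; default 10.
#' @param p_missing per-factor missingness probability in [0, 1];
#'   default 0.15.
#' @param latent_shape1,latent_shape2 Beta parameters of q/100; default 2, 2.
#' @param wr_coupling 1 (default) couples WR to the latent state; 0 draws
#'   WR from an independent latent of the same distribution, giving a null
#'   cohort in which WR carries no information about the factor ratings.
#' @param missing_by_quality logical; see above. Default FALSE.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return assessment data.frame in the [read_assessments()] layout, plus
#'   a hidden column \code{latent_q} with the true state for diagnostics.
#' @export
simulate_assessments <- function(n_farms, instrument,
                                 sigma_wr = 10, sigma_topic = 5,
                                 sigma_factor = 10, p_missing = 0.15,
                                 latent_shape1 = 2, latent_shape2 = 2,
                                 wr_coupling = 1,
                                 missing_by_quality = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(instrument, "awrat_instrument"),
            n_farms >= 1, sigma_wr >= 0, sigma_topic >= 0,
            sigma_factor >= 0, p_missing >= 0, p_missing <= 1,
            wr_coupling %in% c(0, 1))
  if (!is.null(seed)) set.seed(as.integer(seed))

  topics <- instrument$topics
  fids <- instrument$factors$id
  topic_of <- instrument$factors$topic_id

  q <- 100 * stats::rbeta(n_farms, latent_shape1, latent_shape2)
  q_wr <- if (wr_coupling == 1) q
          else 100 * stats::rbeta(n_farms, latent_shape1, latent_shape2)
  wr <- clamp01(q_wr + stats::rnorm(n_farms, 0, sigma_wr))

  ratings <- matrix(NA_real_, n_farms, length(fids),
                    dimnames = list(NULL, fids))
  for (i in seq_len(n_farms)) {
    d <- stats::setNames(stats::rnorm(nrow(topics), 0, sigma_topic),
                         topics$id)
    vals <- clamp01(q[i] + d[topic_of] +
                      stats::rnorm(length(fids), 0, sigma_factor))
    pm <- if (missing_by_quality)
      clamp01(p_missing * 2 * (100 - q[i]) / 100, 0, 1) else p_missing
    vals[stats::runif(length(fids)) < pm] <- NA_real_
    ratings[i, ] <- vals
  }

  base <- as.Date("2023-01-01")
  visit <- base + sample.int(120, n_farms, replace = TRUE)
  df <- data.frame(
    farm_code = sprintf("F%04d", seq_len(n_farms)),
    participant_code = sprintf("P%02d", sample.int(max(2, n_farms %/% 3),
                                                   n_farms, replace = TRUE)),
    visit_date = visit,
    record_date = visit + sample.int(5, n_farms, replace = TRUE) - 1L,
    visit_reason = sample(c("welfare", "non-welfare", "revisit"), n_farms,
                          replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    prior_offences = stats::runif(n_farms) < 0.25,
    species = sample(c("cattle", "sheep", "goats"), n_farms, replace = TRUE),
    wr = wr,
    stringsAsFactors = FALSE)
  cbind(df, as.data.frame(ratings), latent_q = q)
}

#' Simulate observation-study ratings with known variance components
#'
#' Generates the two-session photograph-rating table underlying the ICC
#' analysis from an additive variance-component model:
#' \deqn{rating_{ios} = \mu_i + b_o + e_{ios}}
#' with item true scores \eqn{\mu_i \sim N(item\_mean, \sigma_{item})},
#' rater bias \eqn{b_o \sim N(0, \sigma_{observer})}, and residual
#' \eqn{e} combining retest noise \eqn{N(0, \sigma_{session})} and
#' measurement error \eqn{N(0, \sigma_{error})}; ratings are clamped to
#' [0, 100]. Under this model the population single-rater absolute
#' agreement ICC is
#' \eqn{\sigma^2_{item} / (\sigma^2_{item} + \sigma^2_{observer} +
#' \sigma^2_{session} + \sigma^2_{error})} (before clamping effects).
#'
#' @param n_items number of photographs/statements; default 20.
#' @param n_observers number of raters; default 30.
#' @param sigma_item SD of item true scores; default 20.
#' @param sigma_observer SD of rater bias; default 5.
#' @param sigma_session SD of within-observer retest noise; default 5.
#' @param sigma_error residual SD; default 5.
#' @param item_mean centre of the item true-score distribution; default 50.
#' @param p_missing per-response missingness probability; default 0.
#' @param p_second_session probability an observer completes the retest;
#'   default 1.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{observer_code, session, item_id,
#'   rating} (NA where missing), matching [read_observations()].
#' @export
simulate_observations <- function(n_items = 20, n_observers = 30,
                                  sigma_item = 20, sigma_observer = 5,
                                  sigma_session = 5, sigma_error = 5,
                                  item_mean = 50, p_missing = 0,
                                  p_second_session = 1, seed = NULL) {
  stopifnot(n_items >= 2, n_observers >= 2,
            sigma_item >= 0, sigma_observer >= 0, sigma_session >= 0,
            sigma_error >= 0, p_missing >= 0, p_missing <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  mu <- stats::rnorm(n_items, item_mean, sigma_item)
  bias <- stats::rnorm(n_observers, 0, sigma_observer)
  does_retest <- stats::runif(n_observers) < p_second_session

  rows <- list()
  for (o in seq_len(n_observers)) {
    for (s in if (does_retest[o]) 1:2 else 1L) {
      e <- stats::rnorm(n_items, 0, sigma_session) +
        stats::rnorm(n_items, 0, sigma_error)
      val <- clamp01(mu + bias[o] + e)
      val[stats::runif(n_items) < p_missing] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        observer_code = sprintf("OBS%03d", o),
        session = s,
        item_id = sprintf("item%03d", seq_len(n_items)),
        rating = val, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
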