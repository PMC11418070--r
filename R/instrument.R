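#' Construct an AWRAT instrument definition
#'
#' An instrument groups observational risk factors into topic areas, each
#' carrying a topic-risk rating (TRR). TRRs are weights on a 100-point
#' budget: they must sum exactly to 100. The per-factor weight used by the
#' Measure of Completeness, the \emph{factor value}, is derived as
#' TRR / (number of factors in the topic).
#'
#' @param topics data.frame with columns \code{id}, \code{name}, \code{trr}.
#' @param factors data.frame with columns \code{id}, \code{label},
#'   \code{topic_id}.
#' @param rating_scale_max maximum of the visual-analogue rating scale
#'   (default 100).
#' @param zero_substitute value substituted for ratings of exactly zero when
#'   computing the risk rating, so that a zero rating still contributes a
#'   (tiny) value rather than vanishing (default 0.01).
#' @return object of class \code{awrat_instrument}: a list with elements
#'   \code{topics} (with derived \code{n_factors} and \code{factor_value}
#'   columns), \code{factors}, \code{rating_scale_max}, \code{zero_substitute}.
#' @examples
#' inst <- default_instrument()
#' inst$topics
#' @export
new_instrument <- function(topics, factors, rating_scale_max = 100,
                           zero_substitute = 0.01) {
  topics <- as.data.frame(topics, stringsAsFactors = FALSE)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  need_t <- c("id", "name", "trr")
  need_f <- c("id", "label", "topic_id")
  if (!all(need_t %in% names(topics)))
    stop("instrument topics need columns: ", paste(need_t, collapse = ", "))
  if (!all(need_f %in% names(factors)))
    stop("instrument factors need columns: ", paste(need_f, collapse = ", "))

  if (anyDuplicated(topics$id))
    stop("duplicate topic id: ",
         paste(unique(topics$id[duplicated(topics$id)]), collapse = ", "))
  if (anyDuplicated(factors$id))
    stop("duplicate factor id: ",
         paste(unique(factors$id[duplicated(factors$id)]), collapse = ", "))
  orphan <- setdiff(factors$topic_id, topics$id)
  if (length(orphan))
    stop("factor references unknown topic id: ", paste(orphan, collapse = ", "))

  topics$trr <- as.numeric(topics$trr)
  if (any(topics$trr <= 0)) stop("every TRR must be > 0")
  trr_sum <- sum(topics$trr)
  if (abs(trr_sum - 100) > 1e-9)
    stop(sprintf("TRR weights must sum to 100, got %g", trr_sum))

  counts <- table(factor(factors$topic_id, levels = topics$id))
  topics$n_factors <- as.integer(counts[topics$id])
  if (any(topics$n_factors < 1))
    stop("every topic area needs at least one factor; empty: ",
         paste(topics$id[topics$n_factors < 1], collapse = ", "))
  topics$factor_value <- topics$trr / topics$n_factors

  if (!is.numeric(rating_scale_max) || rating_scale_max <= 0)
    stop("rating_scale_max must be a positive number")
  if (!is.numeric(zero_substitute) || zero_substitute < 0)
    stop("zero_substitute must be a non-negative number")

  structure(
    list(topics = topics, factors = factors,
         rating_scale_max = as.numeric(rating_scale_max),
         zero_substitute = as.numeric(zero_substitute)),
    class = "awrat_instrument"
  )
}

#' The default 4-topic, 18-factor AWRAT instrument
#'
#' Topic-risk ratings default to farm 30, animals 30, treatment 20,
#' nutrition 20. The published factor statements live in the tool's
#' standard operating procedure; the shipped configuration uses placeholder
#' labels with a per-topic allocation of 5/5/4/4 factors (18 total), which
#' is all the scoring arithmetic depends on. Supply your own configuration
#' via [load_instrument()] to use the real wording or a different split.
#'
#' @param trr named numeric vector of topic weights, summing to 100.
#' @param n_factors named integer vector, factors per topic (same names).
#' @inheritParams new_instrument
#' @return an \code{awrat_instrument}.
#' @export
default_instrument <- function(trr = c(farm = 30, animals = 30,
                                       treatment = 20, nutrition = 20),
                               n_factors = c(farm = 5, animals = 5,
                                             treatment = 4, nutrition = 4),
                               rating_scale_max = 100,
                               zero_substitute = 0.01) {
  if (!identical(sort(names(trr)), sort(names(n_factors))))
    stop("trr and n_factors must cover the same topic names")
  ids <- names(trr)
  topics <- data.frame(id = ids, name = ids, trr = as.numeric(trr),
                       stringsAsFactors = FALSE)
  factors <- do.call(rbind, lapply(ids, function(t) {
    k <- n_factors[[t]]
    data.frame(
      id = sprintf("%s_%02d", t, seq_len(k)),
      label = sprintf("Placeholder statement %d for topic '%s'", seq_len(k), t),
      topic_id = t, stringsAsFactors = FALSE)
  }))
  new_instrument(topics, factors, rating_scale_max, zero_substitute)
}

#' Load an instrument configuration from a YAML file
#'
#' The file is a human-editable description of the instrument:
#' top-level keys \code{rating_scale_max}, \code{zero_substitute} and
#' \code{topics}, a list of \code{{id, name, trr, factors: [{id, label}]}}.
#' The shipped default lives at
#' \code{system.file("extdata", "awrat_default.yaml", package = "awrat")}.
#'
#' @param path path to the YAML configuration.
#' @return a validated \code{awrat_instrument}.
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) stop("instrument config not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("instrument config parse failure in ",
                                           path, ": ", conditionMessage(e)))
  if (is.null(cfg$topics)) stop("instrument config missing key 'topics'")
  topics <- do.call(rbind, lapply(cfg$topics, function(t) {
    for (k in c("id", "trr")) if (is.null(t[[k]]))
      stop("topic entry missing key '", k, "'")
    data.frame(id = t$id, name = if (is.null(t$name)) t$id else t$name,
               trr = as.numeric(t$trr), stringsAsFactors = FALSE)
  }))
  factors <- do.call(rbind, lapply(cfg$topics, function(t) {
    if (is.null(t$factors) || !length(t$factors))
      stop("topic '", t$id, "' missing key 'factors'")
    do.call(rbind, lapply(t$factors, function(f) {
      if (is.null(f$id)) stop("factor entry under topic '", t$id,
                              "' missing key 'id'")
      data.frame(id = f$id, label = if (is.null(f$label)) f$id else f$label,
                 topic_id = t$id, stringsAsFactors = FALSE)
    }))
  }))
  new_instrument(
    topics, factors,
    rating_scale_max = if (is.null(cfg$rating_scale_max)) 100
                       else cfg$rating_scale_max,
    zero_substitute = if (is.null(cfg$zero_substitute)) 0.01
                      else cfg$zero_substitute)
}

#' Serialize an instrument back to YAML
#'
#' Round-trips with [load_instrument()]: loading the written file yields an
#' instrument equal to the input.
#'
#' @param instrument an \code{awrat_instrument}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "awrat_instrument"))
  cfg <- list(
    rating_scale_max = instrument$rating_scale_max,
    zero_substitute = instrument$zero_substitute,
    topics = lapply(seq_len(nrow(instrument$topics)), function(i) {
      t <- instrument$topics[i, ]
      fs <- instrument$factors[instrument$factors$topic_id == t$id, ,
                               drop = FALSE]
      list(id = t$id, name = t$name, trr = t$trr,
           factors = lapply(seq_len(nrow(fs)), function(j)
             list(id = fs$id[j], label = fs$label[j])))
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Per-factor weight of a topic area
#'
#' The factor value is the topic's TRR divided by its number of factors;
#' it is the weight a single rated (or unrated) factor carries in the
#' Measure of Completeness.
#'
#' @param trr topic-risk rating (weight out of 100).
#' @param n_factors number of factors in the topic; must be >= 1.
#' @return \code{trr / n_factors}.
#' @examples
#' factor_value(20, 4)  # 5
#' @export
factor_value <- function(trr, n_factors) {
  if (any(n_factors < 1)) stop("degenerate topic: n_factors must be >= 1")
  trr / n_factors
}

#' Equal-impact topic weight
#'
#' The TRR each topic would receive if all topics had equal impact on
#' welfare outcomes: 100 / n_topics.
#'
#' @param n_topics number of topic areas; must be >= 1.
#' @return the equal weight.
#' @examples
#' equal_weight_trr(4)  # 25
#' @export
equal_weight_trr <- function(n_topics) {
  if (any(n_topics < 1)) stop("n_topics must be >= 1")
  100 / n_topics
}

#' @export
print.awrat_instrument <- function(x, ...) {
  cat("AWRAT instrument:", nrow(x$topics), "topic areas,",
      nrow(x$factors), "factors\n")
  print(x$topics[, c("id", "trr", "n_factors", "factor_value")],
        row.names = FALSE)
  cat("rating scale 0-", x$rating_scale_max,
      ", zero substitute ", x$zero_substitute, "\n", sep = "")
  invisible(x)
}
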