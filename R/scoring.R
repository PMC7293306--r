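#' Scoring configuration
#'
#' Parameters of the ranking and aggregation step: the severity threshold
#' an ADR must reach to count as clinically relevant, the length of the
#' ranked list, and the number of top System Organ Classes reported.
#'
#' @param severity_threshold severity score at or above which an ADR enters
#'   the ranked list and the aggregate scores; inclusive comparison.
#'   Default 0.7.
#' @param top_k maximum length of the ranked ADR list. Default 20.
#' @param n_top_socs number of top SOC groupings reported. Default 5.
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(severity_threshold = 0.7, top_k = 20L,
                           n_top_socs = 5L) {
  stopifnot(is.numeric(severity_threshold), length(severity_threshold) == 1,
            severity_threshold > 0, severity_threshold <= 1,
            top_k >= 1, n_top_socs >= 1)
  structure(list(severity_threshold = severity_threshold,
                 top_k = as.integer(top_k),
                 n_top_socs = as.integer(n_top_socs)),
            class = "scoring_config")
}

check_prob <- function(x, what) {
  if (length(x) && (anyNA(x) || any(x < 0 | x > 1))) {
    stop(what, " must lie in [0,1]")
  }
  invisible(x)
}

#' ADR frequency score for a drug combination
#'
#' Probability that at least one of the queried drugs elicits the ADR,
#' treating each drug's listed frequency as an independent Bernoulli
#' probability: the complement of the Poisson-binomial mass at zero events,
#' `1 - prod(1 - f_i)`. An empty contribution list scores 0.
#'
#' @param freqs numeric vector of per-drug frequencies in \[0,1\].
#' @return probability in \[0,1\]; non-decreasing in each frequency and
#'   under list extension.
#' @examples
#' frequency_score(c(0.1, 0.2, 0.5))  # 0.64
#' @export
frequency_score <- function(freqs) {
  check_prob(freqs, "frequencies")
  if (length(freqs) == 0L) return(0)
  1 - prod(1 - freqs)
}

#' ADR severity score
#'
#' Probability that the ADR, if it appears, leads to a severe event:
#' hospitalization or death/life threat, combined by inclusion-exclusion
#' under independence, `1 - (1 - pr_hosp) * (1 - pr_mort)`.
#'
#' @param pr_hosp predicted hospitalization probability.
#' @param pr_mort predicted mortality (death or life threat) probability.
#' @return probability; at least `max(pr_hosp, pr_mort)`; symmetric.
#' @examples
#' severity_score(0.3, 0.2)  # 0.44
#' @export
severity_score <- function(pr_hosp, pr_mort) {
  check_prob(pr_hosp, "pr_hosp"); check_prob(pr_mort, "pr_mort")
  1 - (1 - pr_hosp) * (1 - pr_mort)
}

#' Combined per-ADR score
#'
#' Product of frequency and severity scores: the probability that the ADR
#' both appears and leads to a serious event.
#'
#' @param frequency_score,severity_score probabilities in \[0,1\].
#' @return their product.
#' @export
combined_adr_score <- function(frequency_score, severity_score) {
  check_prob(frequency_score, "frequency_score")
  check_prob(severity_score, "severity_score")
  frequency_score * severity_score
}

passing_idx <- function(scored, config) {
  which(scored$severity_score >= config$severity_threshold)
}

# complement-product aggregation, summed smallest-first for stability on
# long score lists
complement_product_risk <- function(scores) {
  if (length(scores) == 0L) return(0)
  1 - prod(1 - sort(scores))
}

#' Total patient risk score
#'
#' Probability of at least one severe-ADR event, aggregated over the ADRs
#' whose severity score meets the threshold:
#' `1 - prod over passing j of (1 - score_j)`. Zero when no ADR passes;
#' never decreased by adding an ADR.
#'
#' @param scored data.frame with columns `severity_score` and `score` (the
#'   combined frequency x severity score), one row per candidate ADR.
#' @param config a [scoring_config()].
#' @return probability in \[0,1\].
#' @export
total_score <- function(scored, config = scoring_config()) {
  check_prob(scored$score, "scores")
  check_prob(scored$severity_score, "severity scores")
  complement_product_risk(scored$score[passing_idx(scored, config)])
}

#' Per-System-Organ-Class risk scores
#'
#' The total-score aggregation restricted to each SOC grouping of the
#' passing ADRs. SOCs with no passing ADR score 0. Because every passing
#' ADR belongs to exactly one SOC, the scores satisfy the partition law
#' `prod(1 - soc_score) == 1 - total_score`.
#'
#' @param scored data.frame with columns `soc`, `severity_score`, `score`.
#' @param config a [scoring_config()].
#' @return named numeric vector, one entry per SOC present in `scored`,
#'   sorted in decreasing score order.
#' @export
soc_scores <- function(scored, config = scoring_config()) {
  check_prob(scored$score, "scores")
  if (nrow(scored) && (anyNA(scored$soc) || any(!nzchar(scored$soc)))) {
    stop("every scored ADR must carry a SOC annotation")
  }
  socs <- unique(scored$soc)
  pass <- scored[passing_idx(scored, config), , drop = FALSE]
  out <- vapply(socs, function(s) {
    complement_product_risk(pass$score[pass$soc == s])
  }, numeric(1))
  sort(out, decreasing = TRUE)
}

#' Cumulative hospitalization or mortality risk
#'
#' Outcome-specific analogue of the total score: the probability of at
#' least one passing ADR both appearing and leading to the given outcome,
#' `1 - prod over passing j of (1 - frequency_score_j * pr_outcome_j)`.
#' Each term's outcome probability is bounded by the ADR's severity score,
#' so the result never exceeds the total score of the same passing set.
#'
#' @param scored data.frame with columns `severity_score`,
#'   `frequency_score`, `pr_hosp`, `pr_mort`.
#' @param config a [scoring_config()].
#' @param outcome `"hospitalization"` or `"mortality"`.
#' @return probability in \[0,1\].
#' @export
cumulative_outcome_risk <- function(scored, config = scoring_config(),
                                    outcome = c("hospitalization",
                                                "mortality")) {
  outcome <- match.arg(outcome)
  pr <- if (outcome == "hospitalization") scored$pr_hosp else scored$pr_mort
  check_prob(pr, "outcome probabilities")
  check_prob(scored$frequency_score, "frequency scores")
  idx <- passing_idx(scored, config)
  complement_product_risk(scored$frequency_score[idx] * pr[idx])
}

#' Rank clinically relevant ADRs
#'
#' Keeps the ADRs whose severity score meets the threshold, sorts them in
#' decreasing combined-score order (ties broken lexicographically by PT),
#' truncates to `top_k`, and assigns consecutive ranks 1, 2, ...
#'
#' @param scored data.frame with columns `pt`, `severity_score`, `score`
#'   (other columns are carried through).
#' @param config a [scoring_config()].
#' @return the passing rows, ordered, with a `rank` column prepended.
#' @export
rank_adrs <- function(scored, config = scoring_config()) {
  check_prob(scored$score, "scores")
  pass <- scored[passing_idx(scored, config), , drop = FALSE]
  ord <- order(-pass$score, pass$pt)
  pass <- pass[ord, , drop = FALSE]
  pass <- utils::head(pass, config$top_k)
  out <- cbind(rank = seq_len(nrow(pass)), pass)
  rownames(out) <- NULL
  out
}
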