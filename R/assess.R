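#' Patient query
#'
#' The input to a patient assessment: age, gender, the drug regimen, and
#' any of the six canonical comorbidities.
#'
#' @param age years, non-negative.
#' @param gender `"male"` or `"female"`.
#' @param drugs non-empty character vector of drug names.
#' @param pathologies character vector drawn from
#'   [canonical_pathologies()] (matched case-insensitively).
#' @return object of class `patient_query`.
#' @export
patient_query <- function(age, gender, drugs, pathologies = character()) {
  stopifnot(length(age) == 1, is.numeric(age), age >= 0)
  if (!gender %in% c("male", "female")) {
    stop("gender must be 'male' or 'female'")
  }
  drugs <- unique(canonical_drug(drugs))
  drugs <- drugs[nzchar(drugs)]
  if (length(drugs) == 0L) stop("drugs must be non-empty")
  pathologies <- unique(canonical_pt(pathologies))
  unknown <- setdiff(pathologies, canonical_pathologies())
  if (length(unknown)) {
    warning("ignoring unknown pathology(ies): ",
            paste(unknown, collapse = ", "))
    pathologies <- intersect(pathologies, canonical_pathologies())
  }
  structure(list(age = age, gender = gender, drugs = drugs,
                 pathologies = pathologies),
            class = "patient_query")
}

#' Assess a patient's ADR risk profile
#'
#' The end-to-end pipeline. For every Preferred Term listed for at least
#' one queried drug: the frequency score (at-least-one-drug
#' Poisson-binomial complement), the severity model's hospitalization and
#' mortality probabilities for the patient with that single candidate ADR,
#' the severity score and the combined score. ADRs at or above the
#' severity threshold are ranked and aggregated into the Total Score, the
#' per-SOC scores and the cumulative hospitalization and mortality risks.
#' The result is deterministic given (kb, model, query).
#'
#' @param query a [patient_query()].
#' @param kb an `adr_kb`; unknown queried drugs warn and are skipped.
#' @param model a fitted [fit_severity_model()] object (or a stub
#'   implementing [predict_outcome_probability()]).
#' @param config a [scoring_config()].
#' @return object of class `risk_profile`: `total_score`,
#'   `hospitalization_risk`, `mortality_risk`, `soc_scores` (all SOCs,
#'   decreasing), `top_socs`, `ranked` (top-k ranked ADR data.frame) and
#'   `scored` (all candidate ADRs).
#' @examples
#' kb <- simulate_knowledge_base(5, 10, 3, seed = 7)
#' stub <- constant_severity_model(0.8, 0.5)
#' q <- patient_query(70, "female", unique(kb$records$drug)[1:2])
#' assess_patient(q, kb, stub)
#' @export
assess_patient <- function(query, kb, model, config = scoring_config()) {
  stopifnot(inherits(query, "patient_query"), inherits(kb, "adr_kb"))
  resolvable <- intersect(query$drugs, unique(kb$records$drug))
  if (length(resolvable) == 0L) {
    stop("none of the queried drugs are in the knowledge base")
  }
  profile <- candidate_adr_profile(query$drugs, kb)
  scored <- score_candidates(query, profile, model)
  build_risk_profile(scored, config)
}

score_candidates <- function(query, profile, model) {
  if (length(profile) == 0L) {
    return(data.frame(pt = character(), soc = character(),
                      frequency_score = numeric(), pr_hosp = numeric(),
                      pr_mort = numeric(), severity_score = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  vocab <- model$vocabulary
  rows <- lapply(profile, function(entry) {
    fs <- frequency_score(entry$contributions$frequency)
    if (!is.null(vocab)) {
      x <- encode_instance(query$age, query$gender,
                           intersect(query$drugs, vocab$drugs),
                           query$pathologies, entry$pt, vocab)
    } else {
      x <- numeric(0)
    }
    ph <- predict_outcome_probability(model, x, "hospitalization")
    pm <- predict_outcome_probability(model, x, "mortality")
    sev <- severity_score(ph, pm)
    data.frame(pt = entry$pt, soc = entry$soc, frequency_score = fs,
               pr_hosp = ph, pr_mort = pm, severity_score = sev,
               score = combined_adr_score(fs, sev),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_risk_profile <- function(scored, config) {
  socs <- soc_scores(scored, config)
  structure(list(total_score = total_score(scored, config),
                 hospitalization_risk =
                   cumulative_outcome_risk(scored, config, "hospitalization"),
                 mortality_risk =
                   cumulative_outcome_risk(scored, config, "mortality"),
                 soc_scores = socs,
                 top_socs = utils::head(socs, config$n_top_socs),
                 ranked = rank_adrs(scored, config),
                 scored = scored,
                 config = config),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(render_profile(x, "text"))
  invisible(x)
}

#' Render a risk profile
#'
#' Serializes a [assess_patient()] result. The text format prints the
#' Total Score and the cumulative hospitalization / mortality risks as
#' percentages to 2 decimals, the top SOC scores, and the ranked ADR
#' table. The JSON format round-trips losslessly; TSV emits the ranked
#' table.
#'
#' @param profile a `risk_profile`.
#' @param format `"text"`, `"json"` or `"tsv"`.
#' @return a single character string.
#' @export
render_profile <- function(profile, format = c("text", "json", "tsv")) {
  stopifnot(inherits(profile, "risk_profile"))
  format <- match.arg(format)
  switch(format,
         text = render_profile_text(profile),
         json = render_profile_json(profile),
         tsv = render_profile_tsv(profile))
}

render_profile_text <- function(p) {
  pc <- function(v) sprintf("%.2f%%", 100 * v)
  lines <- c("ADR risk profile",
             paste0("  Total Score:          ", pc(p$total_score)),
             paste0("  Hospitalization Risk: ", pc(p$hospitalization_risk)),
             paste0("  Mortality Risk:       ", pc(p$mortality_risk)),
             "", "Top SOC groupings:")
  if (length(p$top_socs)) {
    lines <- c(lines, sprintf("  %-45s %s", names(p$top_socs),
                              pc(p$top_socs)))
  } else {
    lines <- c(lines, "  (none)")
  }
  lines <- c(lines, "", sprintf("Ranked ADRs (severity >= %g, top %d):",
                                p$config$severity_threshold, p$config$top_k))
  if (nrow(p$ranked)) {
    lines <- c(lines,
               sprintf("  %2d. %-35s %-40s %s", p$ranked$rank, p$ranked$pt,
                       p$ranked$soc, pc(p$ranked$score)))
  } else {
    lines <- c(lines, "  (none)")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

profile_as_list <- function(p) {
  list(total_score = p$total_score,
       hospitalization_risk = p$hospitalization_risk,
       mortality_risk = p$mortality_risk,
       soc_scores = as.list(p$soc_scores),
       top_socs = as.list(p$top_socs),
       ranked = p$ranked,
       scored = p$scored,
       config = unclass(p$config))
}

render_profile_json <- function(p) {
  as.character(jsonlite::toJSON(profile_as_list(p), auto_unbox = TRUE,
                                digits = NA, dataframe = "columns"))
}

#' Parse a JSON-rendered risk profile
#'
#' Inverse of `render_profile(..., format = "json")`: reconstructs the
#' `risk_profile` so that serialize-parse-serialize is a fixed point.
#'
#' @param txt JSON string from [render_profile()].
#' @return a `risk_profile`.
#' @export
parse_profile_json <- function(txt) {
  raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  as_df <- function(x, template_cols) {
    df <- as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      df <- do.call(data.frame,
                    c(stats::setNames(rep(list(numeric(0)),
                                          length(template_cols)),
                                      template_cols),
                      list(stringsAsFactors = FALSE)))
    }
    df
  }
  cfg <- scoring_config(raw$config$severity_threshold, raw$config$top_k,
                        raw$config$n_top_socs)
  structure(list(total_score = raw$total_score,
                 hospitalization_risk = raw$hospitalization_risk,
                 mortality_risk = raw$mortality_risk,
                 soc_scores = unlist(raw$soc_scores) %||%
                   stats::setNames(numeric(0), character(0)),
                 top_socs = unlist(raw$top_socs) %||%
                   stats::setNames(numeric(0), character(0)),
                 ranked = as_df(raw$ranked,
                                c("rank", "pt", "soc", "frequency_score",
                                  "pr_hosp", "pr_mort", "severity_score",
                                  "score")),
                 scored = as_df(raw$scored,
                                c("pt", "soc", "frequency_score", "pr_hosp",
                                  "pr_mort", "severity_score", "score")),
                 config = cfg),
            class = "risk_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

render_profile_tsv <- function(p) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(p$ranked, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Train, validate and persist a severity model
#'
#' The training pipeline behind the CLI `train` subcommand: loads a corpus
#' and knowledge base, splits off a hold-out test set, fits the two
#' ensembles on the training portion (mortality with oversampling), runs
#' the hold-out validation for both outcomes, logs every metric to
#' standard error and saves the model.
#'
#' @param corpus_path path to a report corpus (see
#'   [read_report_corpus()]).
#' @param kb_path path to a drug-ADR table; `soc_path` to the PT-SOC map.
#' @param soc_path see above.
#' @param model_path output path for the serialized model.
#' @param config an [ensemble_config()].
#' @param test_fraction hold-out fraction (default 0.2).
#' @param split_seed seed of the hold-out shuffle.
#' @param report_path optional path for the JSON validation report.
#' @return invisibly, a list with the fitted `model` and the
#'   `hospitalization` / `mortality` validation reports.
#' @export
train_severity_pipeline <- function(corpus_path, kb_path, soc_path,
                                    model_path,
                                    config = ensemble_config(),
                                    test_fraction = 0.2, split_seed = 1L,
                                    report_path = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  corpus <- read_report_corpus(corpus_path)
  kb <- knowledge_base(read_drug_adr_table(kb_path), read_soc_map(soc_path))
  split <- holdout_split(corpus, test_fraction, split_seed)
  message("Training on ", nrow(split$train), " reports; holding out ",
          nrow(split$test))
  model <- fit_severity_model(split$train, kb, config)
  mats <- build_training_matrices(split$test, model$vocabulary)
  reports <- list(
    hospitalization = validation_report(
      mats$y_hosp, predict_outcome_probability(model, mats$x,
                                               "hospitalization"),
      threshold = config$classification_threshold),
    mortality = validation_report(
      mats$y_mort, predict_outcome_probability(model, mats$x, "mortality"),
      threshold = config$classification_threshold))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    message(sprintf(
      "%s: accuracy %.4f precision %.4f recall %.4f F1 %.4f Brier %.4f AUC %.4f",
      nm, r$accuracy, r$precision, r$recall, r$f1, r$brier, r$roc_auc))
  }
  if (!is.null(report_path)) {
    jsonlite::write_json(
      lapply(reports, function(r) jsonlite::fromJSON(
        validation_report_json(r))),
      report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  save_severity_model(model, model_path)
  message("Model written to ", model_path)
  invisible(list(model = model, reports = reports))
}
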