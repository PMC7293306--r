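#' Feature vocabulary for report encoding
#'
#' Fixes the ordered entity lists behind the indicator encoding: drugs and
#' Preferred Terms from the knowledge base (lexicographic order), the six
#' canonical pathologies, and the age scaling constant. The vocabulary is
#' stored with any trained model so encodings stay stable.
#'
#' @param corpus a report corpus data.frame (non-empty); every drug it
#'   mentions must be present in `kb`.
#' @param kb an `adr_kb`.
#' @return object of class `adr_vocabulary`: list with `drugs`,
#'   `pathologies`, `adrs`, `age_scale`.
#' @export
build_vocabulary <- function(corpus, kb) {
  stopifnot(inherits(kb, "adr_kb"))
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    stop("corpus must be a non-empty data.frame")
  }
  kb_drugs <- sort(unique(kb$records$drug))
  corpus_drugs <- unique(unlist(split_multi(corpus$drugs)))
  unknown <- setdiff(corpus_drugs, kb_drugs)
  if (length(unknown)) {
    stop("corpus drug(s) absent from the knowledge base: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(drugs = kb_drugs,
                 pathologies = canonical_pathologies(),
                 adrs = sort(unique(kb$records$pt)),
                 age_scale = 100),
            class = "adr_vocabulary")
}

#' Encode one instance as a feature vector
#'
#' Encoding: scaled age (`age / age_scale`), gender indicator (male = 1,
#' female = 0), then binary indicators over the vocabulary's drugs,
#' pathologies and ADR terms. At scoring time `adrs` is a single candidate
#' Preferred Term; at training time it is the report's full ADR set.
#'
#' @param age years (non-negative).
#' @param gender `"male"` or `"female"`.
#' @param drugs,pathologies,adrs character vectors of entities, all known
#'   to the vocabulary.
#' @param vocab an `adr_vocabulary`.
#' @return named numeric feature vector of length
#'   `2 + n_drugs + 6 + n_adrs`.
#' @export
encode_instance <- function(age, gender, drugs, pathologies, adrs, vocab) {
  stopifnot(inherits(vocab, "adr_vocabulary"), length(age) == 1, age >= 0)
  if (!gender %in% c("male", "female")) {
    stop("gender must be 'male' or 'female'")
  }
  ind <- function(x, universe, what) {
    unknown <- setdiff(x, universe)
    if (length(unknown)) {
      stop("unknown ", what, ": ", paste(unknown, collapse = ", "))
    }
    as.numeric(universe %in% x)
  }
  c(age_scaled = age / vocab$age_scale,
    gender_male = as.numeric(gender == "male"),
    stats::setNames(ind(drugs, vocab$drugs, "drug(s)"),
                    paste0("drug:", vocab$drugs)),
    stats::setNames(ind(pathologies, vocab$pathologies, "pathology(ies)"),
                    paste0("path:", vocab$pathologies)),
    stats::setNames(ind(adrs, vocab$adrs, "ADR term(s)"),
                    paste0("adr:", vocab$adrs)))
}

#' Build training matrices from a corpus
#'
#' One training instance per report, with the report's full ADR set
#' multi-hot encoded; the labels are the hospitalization and the
#' death/life-threat outcome flags.
#'
#' @param corpus a report corpus data.frame.
#' @param vocab an `adr_vocabulary`.
#' @return list with `x` (numeric matrix, one row per report), `y_hosp`
#'   and `y_mort` (0/1 integer vectors).
#' @export
build_training_matrices <- function(corpus, vocab) {
  stopifnot(inherits(vocab, "adr_vocabulary"), nrow(corpus) > 0L)
  drugs <- split_multi(corpus$drugs)
  paths <- split_multi(corpus$pathologies)
  adrs <- split_multi(corpus$adrs)
  x <- t(vapply(seq_len(nrow(corpus)), function(i) {
    encode_instance(corpus$age[i], corpus$gender[i], drugs[[i]],
                    paths[[i]], adrs[[i]], vocab)
  }, numeric(2L + length(vocab$drugs) + length(vocab$pathologies) +
               length(vocab$adrs))))
  list(x = x, y_hosp = as.integer(corpus$hospitalized),
       y_mort = as.integer(corpus$fatal_or_life_threat))
}

#' Randomly oversample to target class counts
#'
#' Repetitive random oversampling: rows are added by sampling with
#' replacement from the existing rows of each class until the class counts
#' exactly equal the configured targets (every added row duplicates an
#' observed row). Used on the mortality training set to rebalance the rare
#' fatal/life-threat class.
#'
#' @param x feature matrix.
#' @param y 0/1 label vector (both classes present).
#' @param target_counts named vector/list with elements `"0"` and `"1"`;
#'   each target must be at least the observed class count.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with oversampled `x` and `y` (original rows first, in
#'   order, then the sampled duplicates).
#' @export
oversample_minority <- function(x, y, target_counts, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  tc <- c("0" = as.integer(target_counts[["0"]]),
          "1" = as.integer(target_counts[["1"]]))
  obs <- c("0" = sum(y == 0L), "1" = sum(y == 1L))
  if (any(tc < obs)) {
    stop("target counts (", paste(tc, collapse = "/"),
         ") below observed counts (", paste(obs, collapse = "/"), ")")
  }
  with_seed(seed, {
    extra <- unlist(lapply(c("0", "1"), function(cl) {
      n_add <- tc[[cl]] - obs[[cl]]
      if (n_add == 0L) return(integer(0))
      sample(which(y == as.integer(cl)), n_add, replace = TRUE)
    }))
    idx <- c(seq_along(y), extra)
    list(x = x[idx, , drop = FALSE], y = y[idx])
  })
}

#' Ensemble configuration
#'
#' Hyperparameters of the severity classifier ensemble: five
#' single-hidden-layer perceptrons with logistic activation, hidden layer
#' size 40, at most 500 optimizer iterations and fit tolerance 0.1,
#' differing only by random seed. `oversample_targets`, when set, gives
#' the mortality-model class targets (named `"0"`/`"1"`); the default
#' `"balance"` oversamples the minority class up to the majority count.
#'
#' @param n_members number of ensemble members (default 5).
#' @param hidden_layer_size hidden units per member (default 40).
#' @param max_iterations optimizer iteration cap (default 500).
#' @param tolerance absolute fit tolerance passed to the optimizer
#'   (default 0.1).
#' @param member_seeds integer vector of length `n_members`; defaults to
#'   `seed_base + 1:n_members`.
#' @param seed_base base for default member seeds and the oversampling
#'   seed.
#' @param oversample_targets `"balance"`, `NULL` (no oversampling), or a
#'   named vector of per-class target counts.
#' @param classification_threshold probability cut for class prediction
#'   (default 0.5).
#' @param bootstrap if `TRUE`, each member additionally trains on a
#'   bootstrap resample of the training set (off by default; members then
#'   differ only by seed).
#' @param weight_decay per-instance L2 penalty on the network weights
#'   (default 1e-3); the optimizer's total penalty is
#'   `weight_decay * n_train`, keeping the regularization strength
#'   independent of training-set size. The default keeps the ensemble's
#'   held-out probabilities calibrated (reliability slope near 1) at the
#'   corpus sizes the package targets.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 5L, hidden_layer_size = 40L,
                            max_iterations = 500L, tolerance = 0.1,
                            member_seeds = NULL, seed_base = 100L,
                            oversample_targets = "balance",
                            classification_threshold = 0.5,
                            bootstrap = FALSE, weight_decay = 1e-3) {
  stopifnot(n_members >= 1, hidden_layer_size >= 1, max_iterations >= 1,
            tolerance > 0, classification_threshold > 0,
            classification_threshold < 1, weight_decay >= 0)
  if (is.null(member_seeds)) {
    member_seeds <- as.integer(seed_base) + seq_len(n_members)
  }
  stopifnot(length(member_seeds) == n_members)
  structure(list(n_members = as.integer(n_members),
                 hidden_layer_size = as.integer(hidden_layer_size),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 member_seeds = as.integer(member_seeds),
                 seed_base = as.integer(seed_base),
                 oversample_targets = oversample_targets,
                 classification_threshold = classification_threshold,
                 bootstrap = isTRUE(bootstrap),
                 weight_decay = weight_decay),
            class = "ensemble_config")
}

#' Train one outcome's classifier ensemble
#'
#' Fits `n_members` single-hidden-layer perceptrons ([nnet::nnet] with
#' logistic hidden activation and entropy loss) under identical
#' hyperparameters and distinct member seeds (seeding the weight
#' initialization, and the bootstrap resample if enabled). Training is
#' deterministic given the seeds.
#'
#' @param x feature matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param config an [ensemble_config()].
#' @return object of class `severity_ensemble` (list of fitted members +
#'   config).
#' @export
train_severity_ensemble <- function(x, y, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"), is.matrix(x),
            nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class")
  }
  members <- lapply(config$member_seeds, function(s) {
    with_seed(s, {
      idx <- if (config$bootstrap) {
        sample.int(nrow(x), nrow(x), replace = TRUE)
      } else seq_len(nrow(x))
      nnet::nnet(x[idx, , drop = FALSE], y[idx],
                 size = config$hidden_layer_size,
                 maxit = config$max_iterations,
                 abstol = config$tolerance,
                 decay = config$weight_decay * length(idx),
                 entropy = TRUE, trace = FALSE,
                 MaxNWts = (ncol(x) + 2L) * config$hidden_layer_size + 1L)
    })
  })
  structure(list(members = members, config = config),
            class = "severity_ensemble")
}

#' @export
predict.severity_ensemble <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  preds <- vapply(object$members,
                  function(m) as.numeric(stats::predict(m, newdata)),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  pmin(pmax(rowMeans(preds), 0), 1)
}

#' Fit the patient-tailored severity model
#'
#' The central fitting function: trains the hospitalization and the
#' mortality classifier ensembles on a spontaneous-report corpus. Each
#' instance is one report (full ADR set multi-hot encoded) labelled by its
#' hospitalization and death/life-threat flags. The mortality training set
#' is rebalanced by random minority oversampling (per
#' `config$oversample_targets`); the hospitalization set, typically far
#' less imbalanced, is used as observed. Predictions are the unweighted
#' mean of the five members' positive-class probabilities.
#'
#' @param corpus a report corpus data.frame (see
#'   [simulate_report_corpus()] / [read_report_corpus()]).
#' @param kb the `adr_kb` the corpus is paired with.
#' @param config an [ensemble_config()].
#' @param vocab optional pre-built `adr_vocabulary`; defaults to
#'   `build_vocabulary(corpus, kb)`.
#' @return an object of class `severity_model` with components
#'   `hospitalization` and `mortality` (fitted `severity_ensemble`s),
#'   `vocabulary` and `config`.
#' @seealso [predict.severity_model()], [assess_patient()],
#'   [save_severity_model()]
#' @export
fit_severity_model <- function(corpus, kb, config = ensemble_config(),
                               vocab = NULL) {
  if (is.null(vocab)) vocab <- build_vocabulary(corpus, kb)
  mats <- build_training_matrices(corpus, vocab)
  hosp <- train_severity_ensemble(mats$x, mats$y_hosp, config)
  targets <- config$oversample_targets
  if (identical(targets, "balance")) {
    n_max <- max(sum(mats$y_mort == 0L), sum(mats$y_mort == 1L))
    targets <- c("0" = n_max, "1" = n_max)
  }
  if (is.null(targets)) {
    xm <- mats$x; ym <- mats$y_mort
  } else {
    os <- oversample_minority(mats$x, mats$y_mort, targets,
                              seed = config$seed_base)
    xm <- os$x; ym <- os$y
  }
  mort <- train_severity_ensemble(xm, ym, config)
  structure(list(hospitalization = hosp, mortality = mort,
                 vocabulary = vocab, config = config),
            class = "severity_model")
}

#' Predicted outcome probability
#'
#' Mean positive-class probability across the ensemble members for the
#' requested outcome. Generic so that stub models (see
#' [constant_severity_model()]) can stand in for a trained model in tests
#' and closed-form pipeline checks.
#'
#' @param model a `severity_model` (or stub).
#' @param x a feature vector from [encode_instance()] or a feature matrix
#'   (one row per instance).
#' @param outcome `"hospitalization"` or `"mortality"`.
#' @return probability vector in \[0, 1\].
#' @export
predict_outcome_probability <- function(model, x,
                                        outcome = c("hospitalization",
                                                    "mortality")) {
  UseMethod("predict_outcome_probability")
}

#' @export
predict_outcome_probability.severity_model <- function(model, x,
    outcome = c("hospitalization", "mortality")) {
  outcome <- match.arg(outcome)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  expected <- 2L + length(model$vocabulary$drugs) +
    length(model$vocabulary$pathologies) + length(model$vocabulary$adrs)
  if (ncol(x) != expected) {
    stop("feature dimension ", ncol(x), " does not match the model's ",
         "vocabulary (", expected, ")")
  }
  ens <- if (outcome == "hospitalization") model$hospitalization else
    model$mortality
  predict(ens, x)
}

#' Predict outcome probabilities for reports or feature rows
#'
#' @param object a `severity_model`.
#' @param newdata either a report corpus data.frame (encoded with the
#'   model's vocabulary) or an already-encoded feature matrix/vector.
#' @param outcome `"hospitalization"` or `"mortality"`.
#' @param ... unused.
#' @return probability vector.
#' @export
predict.severity_model <- function(object, newdata,
                                   outcome = c("hospitalization",
                                               "mortality"), ...) {
  outcome <- match.arg(outcome)
  x <- if (is.data.frame(newdata)) {
    build_training_matrices(newdata, object$vocabulary)$x
  } else newdata
  predict_outcome_probability(object, x, outcome)
}

#' Constant-probability stub severity model
#'
#' Returns fixed hospitalization and mortality probabilities regardless of
#' the input — used to exercise the scoring pipeline against closed-form
#' hand computations.
#'
#' @param pr_hosp,pr_mort constants in \[0, 1\].
#' @param vocabulary optional `adr_vocabulary` for encoding queries.
#' @return an object of classes `constant_severity_model`.
#' @export
constant_severity_model <- function(pr_hosp, pr_mort, vocabulary = NULL) {
  check_prob(pr_hosp, "pr_hosp"); check_prob(pr_mort, "pr_mort")
  structure(list(pr_hosp = pr_hosp, pr_mort = pr_mort,
                 vocabulary = vocabulary),
            class = "constant_severity_model")
}

#' @export
predict_outcome_probability.constant_severity_model <- function(model, x,
    outcome = c("hospitalization", "mortality")) {
  outcome <- match.arg(outcome)
  n <- if (is.matrix(x)) nrow(x) else 1L
  rep(if (outcome == "hospitalization") model$pr_hosp else model$pr_mort, n)
}

#' @export
print.severity_model <- function(x, ...) {
  cat("Severity model (ensemble of", x$config$n_members,
      "logistic-activation MLPs per outcome)\n")
  cat("  hidden units:", x$config$hidden_layer_size,
      " max iterations:", x$config$max_iterations,
      " tolerance:", x$config$tolerance, "\n")
  cat("  vocabulary:", length(x$vocabulary$drugs), "drugs,",
      length(x$vocabulary$adrs), "ADR terms,",
      length(x$vocabulary$pathologies), "pathologies\n")
  invisible(x)
}

#' @export
summary.severity_model <- function(object, ...) {
  cat("Severity model\n")
  print(object)
  for (nm in c("hospitalization", "mortality")) {
    ens <- object[[nm]]
    val <- vapply(ens$members, function(m) m$value, numeric(1))
    cat(sprintf("  %s ensemble: final fit criterion %s\n", nm,
                paste(signif(val, 4), collapse = ", ")))
  }
  invisible(object)
}

#' Save / load a trained severity model
#'
#' Serializes the full model (member weights, vocabulary, config including
#' seeds) so that reloading reproduces predictions bit-exactly on the same
#' machine.
#'
#' @param model a `severity_model`.
#' @param path file path (RDS).
#' @return `load_severity_model` returns the model.
#' @export
save_severity_model <- function(model, path) {
  stopifnot(inherits(model, "severity_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_severity_model
#' @export
load_severity_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "severity_model")) {
    stop("file does not contain a severity model")
  }
  model
}
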