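# Small shared fixtures: a 6-drug knowledge base and a 60-report corpus.
small_kb <- function() simulate_knowledge_base(6, 10, 3, seed = 41)
small_corpus <- function(kb = small_kb(), n = 60) {
  simulate_report_corpus(kb, random_generative_spec(kb, seed = 42,
                                                    drugs_range = c(1, 4)),
                         n)
}

test_that("vocabularies cover the knowledge base deterministically", {
  kb <- small_kb()
  corpus <- small_corpus(kb)
  v1 <- build_vocabulary(corpus, kb)
  v2 <- build_vocabulary(corpus, kb)
  expect_identical(v1, v2)
  expect_equal(v1$drugs, sort(unique(kb$records$drug)))
  expect_equal(v1$adrs, sort(unique(kb$records$pt)))
  expect_length(v1$pathologies, 6L)
  expect_false(is.unsorted(v1$drugs))

  expect_error(build_vocabulary(corpus[0, ], kb), "non-empty")
  bad <- corpus
  bad$drugs[1] <- "rogueDrug"
  expect_error(build_vocabulary(bad, kb), "roguedrug|rogueDrug")
})

test_that("instances encode per the documented scheme", {
  kb <- toy_kb()
  corpus <- data.frame(age = 40L, gender = "female", drugs = "druga",
                       pathologies = "", adrs = "Nausea",
                       hospitalized = 0L, fatal_or_life_threat = 0L,
                       stringsAsFactors = FALSE)
  vocab <- build_vocabulary(corpus, kb)
  x <- encode_instance(85, "male", "druga", "Cardiac failure", "Nausea",
                       vocab)
  expect_equal(unname(x["age_scaled"]), 0.85)
  expect_equal(unname(x["gender_male"]), 1)
  expect_equal(unname(x["drug:druga"]), 1)
  expect_equal(unname(x["drug:drugb"]), 0)
  expect_equal(unname(x["path:Cardiac failure"]), 1)
  expect_equal(sum(x[grepl("^path:", names(x))]), 1)
  expect_equal(unname(x["adr:Nausea"]), 1)
  expect_equal(unname(x["adr:Rash"]), 0)

  zero <- encode_instance(0, "female", character(), character(), "Nausea",
                          vocab)
  expect_equal(sum(zero), 1)  # only the nausea bit

  expect_error(encode_instance(40, "male", "druga", character(),
                               "Unheard-of term", vocab), "Unheard-of")
  expect_error(encode_instance(40, "other", "druga", character(), "Nausea",
                               vocab), "gender")
})

test_that("training matrices are one row per report with multi-hot ADRs", {
  kb <- small_kb()
  corpus <- small_corpus(kb)
  vocab <- build_vocabulary(corpus, kb)
  mats <- build_training_matrices(corpus, vocab)
  expect_equal(nrow(mats$x), nrow(corpus))
  expect_equal(length(mats$y_hosp), nrow(corpus))
  expect_equal(mats$y_hosp, corpus$hospitalized)
  expect_equal(mats$y_mort, corpus$fatal_or_life_threat)

  # indicator encoding is a bijection back to the entity sets
  adr_cols <- grepl("^adr:", colnames(mats$x))
  drug_cols <- grepl("^drug:", colnames(mats$x))
  for (i in seq_len(10)) {
    expect_setequal(sub("^adr:", "", colnames(mats$x)[adr_cols][
      mats$x[i, adr_cols] == 1]),
      strsplit(corpus$adrs[i], ";")[[1]])
    expect_setequal(sub("^drug:", "", colnames(mats$x)[drug_cols][
      mats$x[i, drug_cols] == 1]),
      strsplit(corpus$drugs[i], ";")[[1]])
    expect_equal(sum(mats$x[i, adr_cols]),
                 length(strsplit(corpus$adrs[i], ";")[[1]]))
  }
})

test_that("oversampling hits the targets exactly with duplicated rows", {
  set.seed(43)
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- c(rep(0L, 8), rep(1L, 2))
  os <- oversample_minority(x, y, c("0" = 8, "1" = 8), seed = 1)
  expect_equal(sum(os$y == 0), 8L)
  expect_equal(sum(os$y == 1), 8L)
  expect_equal(nrow(os$x), 16L)
  # every added row duplicates an observed minority row
  added <- os$x[11:16, , drop = FALSE]
  pool <- x[9:10, , drop = FALSE]
  for (i in seq_len(nrow(added))) {
    expect_true(any(apply(pool, 1, function(r) all(r == added[i, ]))))
  }
  # identity when targets equal the observed counts
  same <- oversample_minority(x, y, c("0" = 8, "1" = 2), seed = 1)
  expect_identical(same$x, x)
  expect_identical(same$y, y)
  # determinism
  expect_identical(oversample_minority(x, y, c("0" = 8, "1" = 8), seed = 5),
                   oversample_minority(x, y, c("0" = 8, "1" = 8), seed = 5))
  expect_error(oversample_minority(x, y, c("0" = 4, "1" = 8)), "below")
  expect_error(oversample_minority(x, rep(0L, 10), c("0" = 10, "1" = 1)),
               "both classes")
})

test_that("the ensemble fits separable data and is seed-deterministic", {
  set.seed(44)
  n <- 20
  x <- cbind(f1 = c(rnorm(10, -3), rnorm(10, 3)), f2 = rnorm(n))
  y <- rep(c(0L, 1L), each = 10)
  cfg <- ensemble_config(weight_decay = 1e-6)
  ens <- train_severity_ensemble(x, y, cfg)
  expect_length(ens$members, 5L)
  for (m in ens$members) {
    acc <- mean((as.numeric(predict(m, x)) >= 0.5) == y)
    expect_equal(acc, 1)
  }
  p1 <- predict(ens, x)
  p2 <- predict(train_severity_ensemble(x, y, cfg), x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(train_severity_ensemble(x, rep(1L, n), cfg), "single class")
})

test_that("ensemble averaging never leaves the members' range", {
  set.seed(45)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0L, 1L)
  ens <- train_severity_ensemble(x, y, ensemble_config(
    hidden_layer_size = 5, max_iterations = 50))
  xt <- matrix(rnorm(20 * 4), 20, 4)
  member_preds <- sapply(ens$members,
                         function(m) as.numeric(predict(m, xt)))
  avg <- predict(ens, xt)
  expect_true(all(avg >= apply(member_preds, 1, min) - 1e-12))
  expect_true(all(avg <= apply(member_preds, 1, max) + 1e-12))
})

test_that("stubbed member averaging is the arithmetic mean", {
  # constant stub members exercise the combination rule in isolation
  stub_ensemble <- structure(
    list(members = lapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
      structure(list(p = p), class = "stub_member")
    })),
    class = "severity_ensemble")
  # predict method for the stub member class, visible for S3 dispatch
  assign("predict.stub_member",
         function(object, newdata, ...) rep(object$p, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.stub_member", envir = globalenv()), add = TRUE)
  xt <- matrix(0, 2, 3)
  expect_equal(predict(stub_ensemble, xt), c(0.5, 0.5))
})

test_that("fit_severity_model trains both outcomes and round-trips", {
  kb <- small_kb()
  corpus <- small_corpus(kb, n = 80)
  cfg <- ensemble_config(n_members = 2, hidden_layer_size = 4,
                         max_iterations = 60)
  model <- fit_severity_model(corpus, kb, cfg)
  expect_s3_class(model, "severity_model")
  mats <- build_training_matrices(corpus, model$vocabulary)
  ph <- predict_outcome_probability(model, mats$x, "hospitalization")
  pm <- predict_outcome_probability(model, mats$x, "mortality")
  expect_true(all(ph >= 0 & ph <= 1))
  expect_true(all(pm >= 0 & pm <= 1))

  # persistence round-trips predictions bit-exactly
  path <- tempfile(fileext = ".rds")
  save_severity_model(model, path)
  back <- load_severity_model(path)
  expect_identical(predict_outcome_probability(back, mats$x, "mortality"),
                   pm)

  # dimension mismatches are caught
  expect_error(predict_outcome_probability(model, mats$x[, 1:3],
                                           "hospitalization"), "dimension")
})

test_that("single-row prediction matches the matrix path", {
  kb <- small_kb()
  corpus <- small_corpus(kb, n = 40)
  cfg <- ensemble_config(n_members = 2, hidden_layer_size = 3,
                         max_iterations = 40)
  model <- fit_severity_model(corpus, kb, cfg)
  mats <- build_training_matrices(corpus, model$vocabulary)
  p_all <- predict_outcome_probability(model, mats$x, "hospitalization")
  p_one <- predict_outcome_probability(model, mats$x[3, ],
                                       "hospitalization")
  expect_equal(p_one, p_all[3], tolerance = 1e-12)
})
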