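# Closed-form oracle for the stub-model pipeline on the 3-row toy
# knowledge base, computed outside the package's pipeline functions.
closed_form_profile <- function(pr_hosp, pr_mort, threshold = 0.7) {
  sev <- 1 - (1 - pr_hosp) * (1 - pr_mort)
  f_nausea <- 1 - (1 - 0.10) * (1 - 0.25)   # 0.325
  f_rash <- 0.02
  s_nausea <- f_nausea * sev
  s_rash <- f_rash * sev
  pass <- sev >= threshold
  list(
    sev = sev,
    nausea = s_nausea, rash = s_rash,
    total = if (pass) 1 - (1 - s_nausea) * (1 - s_rash) else 0,
    hosp = if (pass) 1 - (1 - f_nausea * pr_hosp) * (1 - f_rash * pr_hosp)
           else 0,
    mort = if (pass) 1 - (1 - f_nausea * pr_mort) * (1 - f_rash * pr_mort)
           else 0,
    soc_gi = if (pass) s_nausea else 0,
    soc_skin = if (pass) s_rash else 0)
}

test_that("assess_patient matches the closed-form stub computation", {
  kb <- toy_kb()
  stub <- constant_severity_model(0.8, 0.5)
  q <- patient_query(70, "female", c("drugA", "drugB"))
  prof <- assess_patient(q, kb, stub)
  oracle <- closed_form_profile(0.8, 0.5)

  expect_equal(oracle$sev, 0.9, tolerance = 1e-15)
  expect_equal(prof$total_score, oracle$total, tolerance = 1e-12)
  expect_equal(prof$hospitalization_risk, oracle$hosp, tolerance = 1e-12)
  expect_equal(prof$mortality_risk, oracle$mort, tolerance = 1e-12)
  expect_equal(unname(prof$soc_scores["Gastrointestinal disorders"]),
               oracle$soc_gi, tolerance = 1e-12)
  expect_equal(unname(prof$soc_scores["Skin disorders"]),
               oracle$soc_skin, tolerance = 1e-12)
  expect_equal(prof$ranked$pt, c("Nausea", "Rash"))
  expect_equal(prof$ranked$rank, 1:2)
  expect_equal(prof$ranked$score, c(oracle$nausea, oracle$rash),
               tolerance = 1e-12)
})

test_that("sub-threshold severities empty the profile", {
  kb <- toy_kb()
  stub <- constant_severity_model(0.3, 0.2)  # severity 0.44 < 0.7
  q <- patient_query(70, "female", c("drugA", "drugB"))
  prof <- assess_patient(q, kb, stub)
  expect_equal(prof$total_score, 0)
  expect_equal(prof$hospitalization_risk, 0)
  expect_equal(prof$mortality_risk, 0)
  expect_equal(nrow(prof$ranked), 0L)
  expect_true(all(prof$soc_scores == 0))
})

test_that("unknown drugs warn; fully unknown queries error", {
  kb <- toy_kb()
  stub <- constant_severity_model(0.8, 0.5)
  q <- suppressWarnings(patient_query(50, "male", c("drugA", "drugZZ")))
  expect_warning(prof <- assess_patient(q, kb, stub), "drugzz")
  # the resolvable part still scores
  expect_gt(prof$total_score, 0)
  q2 <- patient_query(50, "male", "drugZZ")
  expect_error(suppressWarnings(assess_patient(q2, kb, stub)),
               "none of the queried drugs")
})

test_that("assessment is deterministic for a fixed trained model", {
  kb <- simulate_knowledge_base(6, 10, 3, seed = 51)
  spec <- random_generative_spec(kb, seed = 51, drugs_range = c(1, 4))
  corpus <- simulate_report_corpus(kb, spec, 80)
  model <- fit_severity_model(corpus, kb, ensemble_config(
    n_members = 2, hidden_layer_size = 4, max_iterations = 60))
  q <- patient_query(72, "male", unique(kb$records$drug)[1:3],
                     "Cardiac failure")
  p1 <- assess_patient(q, kb, model)
  p2 <- assess_patient(q, kb, model)
  expect_identical(p1, p2)
  expect_true(p1$total_score >= 0 && p1$total_score <= 1)
})

test_that("text rendering reports percentages that re-parse to 2 decimals", {
  kb <- toy_kb()
  stub <- constant_severity_model(0.8, 0.5)
  prof <- assess_patient(patient_query(70, "female", c("drugA", "drugB")),
                         kb, stub)
  txt <- render_profile(prof, "text")
  nums <- as.numeric(regmatches(txt,
                                gregexpr("[0-9]+\\.[0-9]{2}(?=%)", txt,
                                         perl = TRUE))[[1]]) / 100
  expect_equal(nums[1], prof$total_score, tolerance = 0.005)
  expect_equal(nums[2], prof$hospitalization_risk, tolerance = 0.005)
  expect_equal(nums[3], prof$mortality_risk, tolerance = 0.005)
  # ranks listed in order
  expect_match(txt, "1\\. Nausea")
  expect_match(txt, "2\\. Rash")
})

test_that("json rendering is a serialize-parse-serialize fixed point", {
  kb <- toy_kb()
  stub <- constant_severity_model(0.8, 0.5)
  prof <- assess_patient(patient_query(70, "female", c("drugA", "drugB")),
                         kb, stub)
  j1 <- render_profile(prof, "json")
  j2 <- render_profile(parse_profile_json(j1), "json")
  expect_identical(j1, j2)

  # empty profile renders and round-trips too
  low <- assess_patient(patient_query(70, "female", c("drugA", "drugB")),
                        kb, constant_severity_model(0.1, 0.1))
  je <- render_profile(low, "json")
  expect_identical(render_profile(parse_profile_json(je), "json"), je)
  expect_match(render_profile(low, "text"), "0\\.00%")
  expect_error(render_profile(prof, "xml"))
})

test_that("the training pipeline runs end to end from files", {
  kb <- simulate_knowledge_base(5, 8, 3, seed = 61)
  spec <- random_generative_spec(kb, seed = 61, drugs_range = c(1, 3))
  corpus <- simulate_report_corpus(kb, spec, 150)
  kb_path <- tempfile(fileext = ".tsv")
  soc_path <- tempfile(fileext = ".tsv")
  corpus_path <- tempfile(fileext = ".tsv")
  model_path <- tempfile(fileext = ".rds")
  report_path <- tempfile(fileext = ".json")
  write_drug_adr_table(kb$records, kb_path)
  write.table(data.frame(pt = names(kb$soc_map),
                         soc = unname(kb$soc_map)),
              soc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_report_corpus(corpus, corpus_path)

  res <- suppressMessages(train_severity_pipeline(
    corpus_path, kb_path, soc_path, model_path,
    config = ensemble_config(n_members = 2, hidden_layer_size = 3,
                             max_iterations = 40),
    report_path = report_path))
  expect_true(file.exists(model_path))
  expect_s3_class(res$reports$hospitalization, "validation_report")
  expect_true(file.exists(report_path))

  # the persisted model reproduces the in-memory predictions
  model <- load_severity_model(model_path)
  mats <- build_training_matrices(corpus, model$vocabulary)
  expect_identical(
    predict_outcome_probability(model, mats$x, "hospitalization"),
    predict_outcome_probability(res$model, mats$x, "hospitalization"))
})
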