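# Shared in-code fixtures.

# The 3-row toy knowledge base used across the knowledge-base and pipeline
# tests: drugA {nausea 0.10, rash 0.02}, drugB {nausea 0.25}.
toy_kb_records <- function() {
  data.frame(drug = c("druga", "druga", "drugb"),
             pt = c("Nausea", "Rash", "Nausea"),
             frequency = c(0.10, 0.02, 0.25),
             stringsAsFactors = FALSE)
}

toy_soc_map <- function() {
  c(Nausea = "Gastrointestinal disorders", Rash = "Skin disorders")
}

toy_kb <- function() knowledge_base(toy_kb_records(), toy_soc_map())

write_toy_kb_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("drug\tpt\tfrequency",
               "drugA\tnausea\t0.10",
               "drugA\trash\t0.02",
               "drugB\tnausea\t0.25"), path)
  path
}

# Random scored-ADR table for scoring property tests.
random_scored <- function(n, n_socs = 3) {
  fs <- runif(n)
  sev <- runif(n)
  data.frame(pt = sprintf("Pt%03d", sample.int(999, n)),
             soc = sprintf("Soc %d", sample.int(n_socs, n, replace = TRUE)),
             frequency_score = fs,
             pr_hosp = runif(n), pr_mort = runif(n),
             severity_score = sev,
             score = fs * sev,
             stringsAsFactors = FALSE)
}
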