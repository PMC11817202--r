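# Shared fixtures, built once per test run and cached. All cohorts are
# generated in code at test time; sizes are kept small so the suite
# stays fast while preserving the statistical structure under test.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

frontal_set <- function() c("F3", "F4", "Fz", "Fp2")

# Cohort with the default frontal beta/gamma amplitude effect (x1.5 in
# patients), scaled down to 6+6 subjects x 12 epochs.
effect_table <- function() fixture("effect_table", {
  cohort <- generate_cohort(
    simulation_config(n_per_group = 6, epochs_per_subject = 12, seed = 42))
  cohort_features(cohort)
})

# Exchangeable cohort (no group effect), 5+5 subjects x 10 epochs.
null_table <- function() fixture("null_table", {
  cohort <- generate_cohort(
    simulation_config(n_per_group = 5, epochs_per_subject = 10,
                      effect = NULL, seed = 43))
  cohort_features(cohort)
})

# Linear-SVM LOSO evaluation of the effect cohort on beta+gamma activity
# features, with fold models kept for explanation.
effect_report <- function() fixture("effect_report", {
  tab <- subset_features(effect_table(), bands = c("beta", "gamma"),
                         parameters = "activity")
  run_loso(tab, classifier_spec("linear_svm"), selection_config(k = 12),
           keep_models = TRUE)
})

effect_explanations <- function() fixture("effect_explanations", {
  tab <- subset_features(effect_table(), bands = c("beta", "gamma"),
                         parameters = "activity")
  explain_evaluation(tab, effect_report(), lime_config(n_samples = 500),
                     max_per_fold = 2)
})

# A small feature table with perfectly separated classes on one feature.
separable_table <- function(n_subj = 6, n_epochs = 5, seed = 5) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = n_epochs)
  grp <- rep(rep(c("patient", "control"), length.out = n_subj),
             each = n_epochs)
  n <- length(subj)
  data.frame(subject_id = subj, group = grp,
             beta.activity.F3 = ifelse(grp == "patient", 10, 0) +
               rnorm(n, sd = 0.1),
             beta.activity.O1 = rnorm(n),
             stringsAsFactors = FALSE)
}
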