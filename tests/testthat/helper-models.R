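# Trained models are expensive; build them once per test run and share
# them across test files.  The desk-scale study protocol: default synthetic
# cohort (n = 600, p = 32, T = 200), stratified 80:20 split, 15 epochs of
# Adam at lr 2e-3, batch 16.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- fn()
  .fit_cache[[key]]
}

study_epochs <- function(task) if (task == "classification") 25L else 15L
study_lr <- 1e-3

study_cohort <- function(seed) cached(paste0("cohort", seed), function() {
  cohort <- generate_cohort(sim_config(), seed = seed)
  x <- cohort_sfc(cohort)
  split <- stratified_split(cohort$manifest, seed = seed)
  list(cohort = cohort, x = x,
       tr = match(split$train_ids, cohort$manifest$subject_id),
       te = match(split$test_ids, cohort$manifest$subject_id))
})

study_fit <- function(seed, task = "classification",
                      architecture = "resnet5", attention = TRUE) {
  key <- paste(task, architecture, attention, seed, sep = "_")
  cached(key, function() {
    d <- study_cohort(seed)
    man <- d$cohort$manifest
    y <- if (task == "classification") man$group else man$age
    fit <- ayu_net(d$x[, , d$tr], y[d$tr], architecture = architecture,
                   attention = attention, epochs = study_epochs(task),
                   lr = study_lr, seed = seed)
    pred <- predict(fit, d$x[, , d$te])
    metrics <- if (task == "classification")
      evaluate_classification(pred, y[d$te])
    else evaluate_regression(pred, y[d$te])
    list(fit = fit, metrics = metrics)
  })
}

# group-level attribution of a seed's classifier, shared by the
# localization and trajectory checks
study_attribution <- function(seed, mode = "masked_fc") {
  key <- paste("attr", seed, mode, sep = "_")
  cached(key, function() {
    d <- study_cohort(seed)
    fit <- study_fit(seed)$fit
    group_attribution_analysis(fit, d$x, d$cohort$manifest$group,
                               steps = 50, mode = mode,
                               completeness_tol = Inf)
  })
}

# a small trained network for attribution-completeness checks
toy_fit <- function() cached("toy", function() {
  cohort <- generate_cohort(sim_config(n_subjects = 120L, p = 16L,
                                       n_timepoints = 150L), seed = 71)
  x <- cohort_sfc(cohort)
  fit <- ayu_net(x, cohort$manifest$group, architecture = "vgg5",
                 epochs = 6, lr = 2e-3, seed = 71)
  list(cohort = cohort, x = x, fit = fit)
})

planted_roi_labels <- function(cohort) {
  gt <- cohort$ground_truth
  atlas <- cohort$atlas
  list(dec = unique(atlas$roi_label[unlist(gt[gt$class == "dec",
                                             c("roi1", "roi2")])]),
       invU = unique(atlas$roi_label[unlist(gt[gt$class == "invU",
                                               c("roi1", "roi2")])]))
}
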