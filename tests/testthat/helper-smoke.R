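# End-to-end smoke training on the easy cohort, cached so the learning and
# robustness checks share one set of fits. Three training seeds on a common
# cohort; early stopping once validation accuracy clears 0.85.

smoke_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- easy_cohort(seed = 2024)
    ds <- prepare_dataset(co)
    # one fixed subject-disjoint split: the three seeds vary initialization
    # and shuffling, not the data partition
    split <- subject_split(ds, 0.25, seed = 2024)
    fits <- lapply(c(11L, 22L, 33L), function(sd) {
      mdl <- init_model(model_config("tiny"), seed = sd)
      tcfg <- train_config("desk", epochs = 30, batch = 4, lr = 0.01,
                           seed = sd, early_stop_acc = 0.85)
      train(ds, mdl, tcfg, split = split)
    })
    cache <<- list(cohort = co, ds = ds, fits = fits,
                   best_acc = vapply(fits, function(f)
                     max(f$log$val_accuracy, na.rm = TRUE), 0))
    cache
  }
})
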