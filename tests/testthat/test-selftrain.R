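test_that("selftrain_config validates its fields", {
  expect_error(selftrain_config(confidence_threshold = 0.4), "0.5")
  expect_error(selftrain_config(default_k = 123L), "default_k")
  cfg <- selftrain_config()
  expect_equal(cfg$confidence_threshold, 0.9)
  expect_equal(cfg$default_k, 5000L)
  expect_equal(cfg$candidate_added_sizes,
               c(1000L, 2000L, 3000L, 5000L, 10000L))
})

fake_predictions <- function(p1) {
  data.frame(prob0 = 1 - p1, prob1 = p1,
             predicted_class = as.integer(p1 > 0.5), confidence = p1)
}

test_that("select_pseudolabels thresholds, samples quotas, and handles
           shortfall", {
  cfg <- selftrain_config(class_ratio_policy = "natural", seed = 2L)
  pp <- fake_predictions(c(0.99, 0.95, 0.60))
  sel <- select_pseudolabels(pp, 2L, cfg)
  expect_setequal(sel$index, c(1L, 2L))
  expect_equal(sel$pseudo_label, c(1L, 1L))
  expect_true(all(sel$confidence >= 0.9))

  # class quotas under preserve_labeled_ratio: 1:1 labeled ratio, k=4
  cfg2 <- selftrain_config(seed = 3L)
  pp2 <- fake_predictions(c(0.99, 0.97, 0.96, 0.02, 0.03, 0.01))
  sel2 <- select_pseudolabels(pp2, 4L, cfg2,
                              labeled_labels = c(0L, 1L, 0L, 1L))
  expect_equal(sum(sel2$pseudo_label == 1L), 2L)
  expect_equal(sum(sel2$pseudo_label == 0L), 2L)

  # shortfall: take all candidates of the short class, no backfill
  pp3 <- fake_predictions(c(0.99, 0.98, 0.97, 0.96, 0.01))
  expect_warning(
    sel3 <- select_pseudolabels(pp3, 4L, cfg2,
                                labeled_labels = c(0L, 1L, 0L, 1L)),
    "taking all")
  expect_equal(sum(sel3$pseudo_label == 0L), 1L)
  expect_equal(sum(sel3$pseudo_label == 1L), 2L)

  # k=10 with only 3 candidates (natural policy)
  expect_warning(sel4 <- select_pseudolabels(
    fake_predictions(c(0.95, 0.93, 0.99, 0.6, 0.5)), 10L, cfg), "taking all")
  expect_equal(nrow(sel4), 3L)

  # degenerate inputs
  expect_error(select_pseudolabels(pp, -1L, cfg), "non-negative")
  expect_warning(s0 <- select_pseudolabels(fake_predictions(c(0.6, 0.55)),
                                           2L, cfg), "threshold")
  expect_equal(nrow(s0), 0L)

  # threshold applies to the *predicted-class* probability: a confident
  # negative (prob1 = 0.05) is a candidate too
  sel5 <- select_pseudolabels(fake_predictions(c(0.05, 0.5)), 1L, cfg)
  expect_equal(sel5$index, 1L)
  expect_equal(sel5$pseudo_label, 0L)
})

test_that("selection respects the threshold on randomized pools", {
  cfg <- selftrain_config(class_ratio_policy = "natural", seed = 11L)
  set.seed(11)
  for (rep in 1:20) {
    pp <- fake_predictions(runif(50))
    # shortfall warnings are expected on uniform pools
    sel <- suppressWarnings(select_pseudolabels(pp, 10L, cfg))
    expect_true(all(sel$confidence >= cfg$confidence_threshold))
    expect_lte(nrow(sel), 10L)
  }
})

test_that("run_pipeline with k=0 is bit-identical to a supervised-only fit
           and bookkeeping is exact", {
  w <- encoded_world(synth_config(n_labeled = 80L, n_unlabeled = 300L,
                                  n_test = 60L, seed = 51L))
  sp <- stratified_split(w$ds$labeled, split_config(seed = 51L))
  keys <- comention_keys(w$ds$labeled)
  trn <- encoded_subset(w$train, keys %in% comention_keys(sp$train))
  val <- encoded_subset(w$train, keys %in% comention_keys(sp$validation))
  tc <- small_train_config(seed = 5L, epochs = 2L)
  cfg <- selftrain_config(seed = 5L)

  res0 <- run_pipeline(trn, val, w$pool, k = 0L, cfg = cfg, tcfg = tc,
                       ensemble_kinds = c("cnn", "rnn"))
  # supervised-only arm: train the same members directly, same derived seeds
  no_selection <- data.frame(index = integer(), pseudo_label = integer(),
                             confidence = numeric())
  sup <- comention:::fit_expanded_ensemble(trn, w$pool, no_selection,
                                           c("cnn", "rnn"), tc, cfg$seed)
  p0 <- ensemble_predict(res0$ensemble, w$test)
  ps <- ensemble_predict(sup$ensemble, w$test)
  expect_identical(p0$prob1, ps$prob1)

  expect_equal(res0$report$k, 0L)
  expect_equal(res0$report$n_expanded, res0$report$n_train)

  # k > 0: exact size and class-count bookkeeping
  res2 <- run_pipeline(trn, val, w$pool, k = 50L, cfg = cfg, tcfg = tc,
                       ensemble_kinds = "lightweight")
  rep2 <- res2$report
  expect_equal(rep2$n_expanded, rep2$n_train + rep2$n_selected)
  expect_equal(rep2$expanded_class_counts$`1`,
               rep2$train_class_counts$`1` + rep2$selected_class_counts$`1`)
  expect_equal(rep2$expanded_class_counts$`0`,
               rep2$train_class_counts$`0` + rep2$selected_class_counts$`0`)
})

test_that("validation/test leakage is rejected by disjointness checks", {
  w <- encoded_world(synth_config(n_labeled = 40L, n_unlabeled = 50L,
                                  n_test = 0L, seed = 53L))
  trn <- encoded_subset(w$train, 1:30)
  val_overlap <- encoded_subset(w$train, 25:40)
  expect_error(run_pipeline(trn, val_overlap, w$pool, k = 0L,
                            cfg = selftrain_config(),
                            tcfg = small_train_config(epochs = 1L),
                            ensemble_kinds = "lightweight"),
               "overlaps")
  # pool must not contain labeled records either
  bad_pool <- encoded_rbind(w$pool, encoded_subset(trn, 1:2))
  expect_error(run_pipeline(trn, encoded_subset(w$train, 31:40), bad_pool,
                            k = 0L, cfg = selftrain_config(),
                            tcfg = small_train_config(epochs = 1L),
                            ensemble_kinds = "lightweight"),
               "overlaps")
})

test_that("choose_added_size prefers a helpful k and breaks ties toward
           the smallest", {
  # empty candidate list -> 0
  cfg0 <- selftrain_config()
  cfg0$candidate_added_sizes <- integer()
  expect_equal(choose_added_size(NULL, NULL,
                                 structure(list(key = "a"),
                                           class = "encoded_set"),
                                 structure(list(key = "b"),
                                           class = "encoded_set"),
                                 cfg0), 0L)

  # unlabeled data demonstrably helps: tiny labeled set, generous pool
  w <- encoded_world(synth_config(n_labeled = 60L, n_unlabeled = 1500L,
                                  n_test = 0L, seed = 57L))
  sp <- stratified_split(w$ds$labeled, split_config(seed = 57L))
  keys <- comention_keys(w$ds$labeled)
  trn <- encoded_subset(w$train, keys %in% comention_keys(sp$train))
  val <- encoded_subset(w$train,
                        keys %in% comention_keys(sp$validation) |
                          keys %in% comention_keys(sp$test))
  cfg <- selftrain_config(seed = 57L)
  cfg$candidate_added_sizes <- c(800L)
  base <- train_classifier(trn, "lightweight", small_train_config())
  # a mild per-class candidate shortfall is expected and warned about
  k_star <- suppressWarnings(
    choose_added_size(base, w$pool, trn, val, cfg, small_train_config(),
                      ensemble_kinds = "lightweight", n_repeats = 5L))
  expect_equal(k_star, 800L)
})
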