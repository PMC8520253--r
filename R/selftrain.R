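## selftrain: fit a base classifier on the small labeled set, pseudo-label
## the unlabeled pool, select a validation-tuned number of high-confidence
## predictions, expand the training set, and train the CNN+RNN ensemble.

#' Self-training configuration
#'
#' "Top predictions" is operationalized as threshold-then-random-sample:
#' the confidence threshold defines which pool predictions count as top,
#' and a seeded uniform sample selects among them.
#'
#' @param confidence_threshold tau in (0.5, 1]: minimum predicted-class
#'   probability for a pool example to become a pseudo-label candidate
#'   (default 0.9).
#' @param candidate_added_sizes candidate numbers of added instances
#'   explored by [choose_added_size()] (default 1000, 2000, 3000, 5000,
#'   10000).
#' @param default_k default added size (default 5000; must be one of the
#'   candidate sizes or 0).
#' @param class_ratio_policy `"preserve_labeled_ratio"` (default): per-class
#'   selection quotas proportional to the labeled training set's class
#'   ratio; `"natural"`: sample candidates regardless of class.
#' @param seed integer seed for candidate sampling.
#' @return object of class `selftrain_config`.
#' @export
selftrain_config <- function(confidence_threshold = 0.9,
                             candidate_added_sizes = c(1000L, 2000L, 3000L,
                                                       5000L, 10000L),
                             default_k = 5000L,
                             class_ratio_policy = c("preserve_labeled_ratio",
                                                    "natural"),
                             seed = 1L) {
  class_ratio_policy <- match.arg(class_ratio_policy)
  stopifnot(confidence_threshold > 0.5, confidence_threshold <= 1,
            all(candidate_added_sizes > 0L))
  if (!(default_k %in% c(candidate_added_sizes, 0L))) {
    stop_("default_k must be 0 or one of candidate_added_sizes")
  }
  structure(list(confidence_threshold = confidence_threshold,
                 candidate_added_sizes = as.integer(candidate_added_sizes),
                 default_k = as.integer(default_k),
                 class_ratio_policy = class_ratio_policy,
                 seed = as.integer(seed)),
            class = "selftrain_config")
}

#' Select pseudo-labeled examples from scored pool predictions
#'
#' Candidates are pool members whose predicted-class probability (the max of
#' the two class probabilities) is at least tau. `k` members are sampled
#' uniformly at random (seeded) from the candidates. Under the
#' preserve_labeled_ratio policy, per-class quotas follow the labeled
#' training set's class ratio (round half up for the positive class); a
#' class whose candidate count falls short of its quota contributes all its
#' candidates with a warning, without backfilling from the other class.
#'
#' @param pool_predictions data.frame from [ensemble_predict()] (or any
#'   frame with `prob0`, `prob1`, `predicted_class`) over the unlabeled
#'   pool.
#' @param k number of examples to add.
#' @param cfg a [selftrain_config()].
#' @param labeled_labels labels of the training set; required for the
#'   preserve_labeled_ratio policy.
#' @return data.frame with `index` (row in the pool), `pseudo_label`,
#'   `confidence` (predicted-class probability), sorted by index.
#' @export
select_pseudolabels <- function(pool_predictions, k, cfg = selftrain_config(),
                                labeled_labels = NULL) {
  if (k < 0L) stop_("k must be non-negative")
  pc_prob <- pmax(pool_predictions$prob0, pool_predictions$prob1)
  cand <- which(pc_prob >= cfg$confidence_threshold)
  empty <- data.frame(index = integer(), pseudo_label = integer(),
                      confidence = numeric())
  if (k == 0L) return(empty)
  if (length(cand) == 0L) {
    warn_("no pool predictions reach the confidence threshold %.3f",
          cfg$confidence_threshold)
    return(empty)
  }
  cls <- pool_predictions$predicted_class[cand]
  take <- integer()
  with_seed(cfg$seed, {
    if (cfg$class_ratio_policy == "natural") {
      if (length(cand) <= k) {
        if (length(cand) < k) {
          warn_("only %d candidates for k=%d; taking all", length(cand), k)
        }
        take <- cand
      } else {
        take <- cand[sample.int(length(cand), k)]
      }
    } else {
      if (is.null(labeled_labels)) {
        stop_("preserve_labeled_ratio policy requires labeled_labels")
      }
      ratio_pos <- mean(labeled_labels == 1L)
      quota_pos <- as.integer(round_half_up(k * ratio_pos))
      quota <- c(`0` = k - quota_pos, `1` = quota_pos)
      for (cl in c(0L, 1L)) {
        pool_cl <- cand[cls == cl]
        q <- quota[[as.character(cl)]]
        if (length(pool_cl) <= q) {
          if (length(pool_cl) < q) {
            warn_("class %d: %d candidates for quota %d; taking all",
                  cl, length(pool_cl), q)
          }
          take <- c(take, pool_cl)
        } else {
          take <- c(take, pool_cl[sample.int(length(pool_cl), q)])
        }
      }
    }
  })
  take <- sort(take)
  data.frame(index = take,
             pseudo_label = pool_predictions$predicted_class[take],
             confidence = pc_prob[take])
}

## Expand a training set with pseudo-labeled pool examples and fit the
## downstream ensemble. Member seeds are derived per kind from `seed`.
fit_expanded_ensemble <- function(train, pool, selection, ensemble_kinds,
                                  tcfg, seed) {
  expanded <- train
  if (nrow(selection) > 0L) {
    add <- encoded_subset(pool, selection$index)
    add$label <- as.integer(selection$pseudo_label)
    expanded <- encoded_rbind(train, add)
  }
  members <- lapply(seq_along(ensemble_kinds), function(i) {
    kind <- ensemble_kinds[[i]]
    mcfg <- tcfg
    mcfg$seed <- derive_seed(seed, paste0("member_", i, "_", kind))
    train_classifier(expanded, kind, mcfg)
  })
  list(ensemble = ensemble_model(members), expanded = expanded)
}

#' Choose the added-size k by validation F1
#'
#' For each candidate k (plus the k = 0 supervised baseline), expands the
#' training set with k pseudo-labels and trains the downstream ensemble,
#' scoring F1 on the validation set; the mean over `n_repeats` differently
#' seeded repeats decides. Ties go to the smallest k.
#'
#' @param base a fitted base classifier.
#' @param pool unlabeled `encoded_set`.
#' @param train,validation labeled `encoded_set`s (disjoint).
#' @param cfg a [selftrain_config()].
#' @param tcfg a [train_config()] for the ensemble members.
#' @param ensemble_kinds classifier kinds of the downstream ensemble.
#' @param n_repeats seeded repeats per candidate (default 3).
#' @return the selected k (integer). Empty candidate list returns 0.
#' @export
choose_added_size <- function(base, pool, train, validation,
                              cfg = selftrain_config(), tcfg = train_config(),
                              ensemble_kinds = c("cnn", "rnn"),
                              n_repeats = 3L) {
  if (length(cfg$candidate_added_sizes) == 0L) return(0L)
  if (length(intersect(train$key, validation$key)) > 0L) {
    stop_("validation set overlaps the training set")
  }
  pool_pred <- as_prediction_frame(predict_proba(base, pool))
  ks <- sort(unique(c(0L, cfg$candidate_added_sizes)))
  mean_f1 <- vapply(ks, function(k) {
    f1s <- vapply(seq_len(n_repeats), function(r) {
      rseed <- derive_seed(cfg$seed, sprintf("choose_k_%d_rep_%d", k, r))
      scfg <- cfg
      scfg$seed <- derive_seed(rseed, "select")
      sel <- select_pseudolabels(pool_pred, k, scfg, train$label)
      fit <- fit_expanded_ensemble(train, pool, sel, ensemble_kinds, tcfg,
                                   rseed)
      pred <- ensemble_predict(fit$ensemble, validation)
      compute_metrics(validation$label, pred$predicted_class)$f1
    }, 0)
    mean(f1s)
  }, 0)
  best <- ks[mean_f1 >= max(mean_f1) - 1e-12]
  min(best)
}

as_prediction_frame <- function(probs) {
  data.frame(prob0 = probs[, 1L], prob1 = probs[, 2L],
             predicted_class = as.integer(probs[, 2L] > probs[, 1L]),
             confidence = probs[, 2L])
}

#' Run the full self-training pipeline
#'
#' Stages: (1) fit the base classifier on the labeled training set; (2)
#' score the unlabeled pool; (3) select k pseudo-labels; (4) expand the
#' training set; (5) fit the ensemble members on the expanded set. With
#' k = 0, stages 2-3 are skipped and the result equals a supervised-only
#' run with the same seed. Validation and test sets are never pseudo-labeled
#' or added to training.
#'
#' @param train,validation labeled `encoded_set`s.
#' @param pool unlabeled `encoded_set` sharing the training vocabulary.
#' @param k number of pseudo-labeled instances to add, or `"auto"` to run
#'   [choose_added_size()].
#' @param cfg a [selftrain_config()].
#' @param tcfg a [train_config()].
#' @param base_kind classifier kind of the base model; default
#'   `"lightweight"` so the pipeline runs without a pretrained model
#'   plug-in (supply `tcfg$base_factory` and `base_kind = "base"` to use
#'   one).
#' @param ensemble_kinds downstream ensemble member kinds (default one CNN
#'   and one RNN).
#' @return list with `ensemble` (a `comention_ensemble`) and `report`
#'   (sizes, class counts, seeds, base and ensemble validation metrics, the
#'   k used).
#' @export
run_pipeline <- function(train, validation, pool, k = NULL,
                         cfg = selftrain_config(), tcfg = train_config(),
                         base_kind = "lightweight",
                         ensemble_kinds = c("cnn", "rnn")) {
  stopifnot(inherits(train, "encoded_set"), inherits(pool, "encoded_set"))
  if (length(intersect(train$key, validation$key)) > 0L) {
    stop_("validation set overlaps the training set")
  }
  if (length(intersect(pool$key, c(train$key, validation$key))) > 0L) {
    stop_("unlabeled pool overlaps the labeled splits")
  }
  bcfg <- tcfg
  bcfg$seed <- derive_seed(cfg$seed, "base_fit")
  base <- train_classifier(train, base_kind, bcfg)
  base_val <- as_prediction_frame(predict_proba(base, validation))
  base_f1 <- compute_metrics(validation$label, base_val$predicted_class)$f1

  if (identical(k, "auto")) {
    k <- choose_added_size(base, pool, train, validation, cfg, tcfg,
                           ensemble_kinds)
  }
  k <- as.integer(k %||% cfg$default_k)
  if (k < 0L) stop_("k must be non-negative")

  selection <- if (k == 0L) {
    data.frame(index = integer(), pseudo_label = integer(),
               confidence = numeric())
  } else {
    scfg <- cfg
    scfg$seed <- derive_seed(cfg$seed, "select")
    select_pseudolabels(as_prediction_frame(predict_proba(base, pool)),
                        k, scfg, train$label)
  }
  fit <- fit_expanded_ensemble(train, pool, selection, ensemble_kinds, tcfg,
                               cfg$seed)
  ens_val <- ensemble_predict(fit$ensemble, validation)
  val_metrics <- compute_metrics(validation$label, ens_val$predicted_class)

  report <- list(
    k = k,
    n_train = length(train$label),
    n_selected = nrow(selection),
    n_expanded = length(fit$expanded$label),
    train_class_counts = as.list(table(factor(train$label, c(0L, 1L)))),
    selected_class_counts =
      as.list(table(factor(selection$pseudo_label, c(0L, 1L)))),
    expanded_class_counts =
      as.list(table(factor(fit$expanded$label, c(0L, 1L)))),
    seed = cfg$seed,
    base_kind = base_kind,
    ensemble_kinds = ensemble_kinds,
    base_validation_f1 = base_f1,
    validation = val_metrics[c("precision", "recall", "f1")]
  )
  list(ensemble = fit$ensemble, report = report)
}
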