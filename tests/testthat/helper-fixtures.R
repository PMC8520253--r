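# Shared fixtures. All synthetic data is generated in code at test time;
# model/test sizes are scaled down from package defaults so the suite runs
# in minutes on one CPU (the generator's *world* parameters -- signal 0.9,
# noise 0.05, positive fraction 0.5 -- are never changed here).

tiny_proteins <- function() {
  lexicon(list(P1 = "BRCA1", P2 = c("TP53", "tumor protein p53")),
          kind = "protein")
}

tiny_phenotypes <- function() {
  lexicon(list(H1 = "breast cancer", H2 = "cancer"), kind = "phenotype")
}

# small, fast model configuration used throughout the suite
small_train_config <- function(seed = 1L, epochs = 6L) {
  train_config(epochs_cnn_rnn = epochs, embedding_dim = 16L,
               cnn_filters_per_width = 16L, cnn_filter_widths = c(3L, 4L, 5L),
               rnn_hidden_size = 16L, batch_size = 32L, seed = seed)
}

small_pre_config <- function(max_len = 24L) preprocess_config(max_len = max_len)

# generate a dataset and encode its parts on the labeled split's vocabulary
encoded_world <- function(cfg, pre = small_pre_config()) {
  ds <- generate_dataset(cfg)
  tr <- encode_records(ds$labeled, ds$proteins, ds$phenotypes, cfg = pre)
  out <- list(ds = ds, train = tr)
  if (!is.null(ds$unlabeled) && nrow(ds$unlabeled) > 0L) {
    out$pool <- encode_records(ds$unlabeled, ds$proteins, ds$phenotypes,
                               vocab = tr$vocab, cfg = pre)
  }
  if (!is.null(ds$test) && nrow(ds$test) > 0L) {
    out$test <- encode_records(ds$test, ds$proteins, ds$phenotypes,
                               vocab = tr$vocab, cfg = pre)
  }
  out
}

predicted_class_of <- function(probs) as.integer(probs[, 2L] > probs[, 1L])

# constant-output classifier honouring the contract, for ensemble algebra
# tests (probabilities fixed at construction)
make_const_classifier <- function(p1, L = 8L, V = 10L) {
  structure(list(p1 = p1, L = L, V = V),
            class = c("comention_const", "comention_classifier"))
}
predict_proba.comention_const <- function(model, examples) {
  ids <- if (inherits(examples, "encoded_set")) examples$ids else examples
  p1 <- rep_len(model$p1, nrow(ids))
  cbind(p0 = 1 - p1, p1 = p1)
}
registerS3method("predict_proba", "comention_const",
                 predict_proba.comention_const,
                 envir = asNamespace("comention"))

# --- independent oracles (kept deliberately naive) ------------------------

# positional leftmost-longest scan over every (id, name) pair of one or two
# lexicons; boundary rule re-stated from scratch
oracle_scan <- function(sentence, lexicons) {
  pairs <- do.call(rbind, lapply(lexicons, function(lex) {
    data.frame(id = rep(names(lex$entries), lengths(lex$entries)),
               name = unlist(lex$entries, use.names = FALSE),
               kind = lex$kind, stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(-nchar(pairs$name),
                       match(pairs$kind, c("protein", "phenotype")),
                       pairs$id), ]
  low <- tolower(sentence)
  n <- nchar(low)
  alnum <- function(i) i >= 1 && i <= n && grepl("[[:alnum:]]",
                                                 substr(low, i, i))
  out <- NULL
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (r in seq_len(nrow(pairs))) {
      nm <- tolower(pairs$name[[r]])
      len <- nchar(nm)
      if (i + len - 1L > n) next
      if (substr(low, i, i + len - 1L) != nm) next
      if (alnum(i - 1L) || alnum(i + len)) next
      hit <- data.frame(entity_id = pairs$id[[r]], start = i - 1L,
                        end = i - 1L + len, kind = pairs$kind[[r]],
                        stringsAsFactors = FALSE)
      break
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      out <- rbind(out, hit)
      i <- hit$end + 1L
    }
  }
  if (is.null(out)) {
    out <- data.frame(entity_id = character(), start = integer(),
                      end = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

# all-pairs AUROC, ties at 1/2
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force confusion counts
oracle_confusion <- function(labels, predicted) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && predicted[i] == 1) tp <- tp + 1L
    else if (labels[i] == 0 && predicted[i] == 1) fp <- fp + 1L
    else if (labels[i] == 1 && predicted[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

record_identity_cols <- function(df) {
  df[c("doc_id", "sentence_index", "protein_id", "protein_start",
       "protein_end", "phenotype_id", "phenotype_start", "phenotype_end")]
}
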