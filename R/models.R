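## models: the classifier contract, CNN / RNN / lightweight implementations,
## the optional pretrained-model plug-in, and the probability-averaging
## ensemble.

#' Training configuration
#'
#' Defaults follow conventional text-classification practice: CNN with
#' parallel convolution widths 3/4/5 and 100 feature maps each over a
#' 100-dimensional embedding trained from scratch; bidirectional tanh RNN
#' with hidden size 128 and final-state concatenation; 20 epochs of Adam on
#' binary cross-entropy, batch size 32, learning rate 1e-3. A pluggable
#' pretrained base model (kind `"base"`) fine-tunes for `epochs_base`
#' epochs.
#'
#' @param epochs_cnn_rnn training epochs for the CNN and RNN (default 20).
#' @param epochs_base fine-tuning epochs for a plugged-in base model
#'   (default 4).
#' @param seed integer seed governing initialization and batch shuffling.
#' @param embedding_dim embedding dimension (default 100).
#' @param cnn_filter_widths convolution widths (default c(3, 4, 5)).
#' @param cnn_filters_per_width feature maps per width (default 100).
#' @param rnn_hidden_size per-direction hidden size (default 128).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param grad_clip global gradient-norm clip (default 5).
#' @param base_factory optional `function(train, cfg)` returning a fitted
#'   classifier honouring the contract; how a pretrained transformer is
#'   plugged in.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs_cnn_rnn = 20L, epochs_base = 4L, seed = 1L,
                         embedding_dim = 100L,
                         cnn_filter_widths = c(3L, 4L, 5L),
                         cnn_filters_per_width = 100L,
                         rnn_hidden_size = 128L, batch_size = 32L,
                         learning_rate = 1e-3, grad_clip = 5,
                         base_factory = NULL) {
  stopifnot(epochs_cnn_rnn >= 1L, epochs_base >= 1L, batch_size >= 1L,
            embedding_dim >= 1L, all(cnn_filter_widths >= 1L),
            cnn_filters_per_width >= 1L, rnn_hidden_size >= 1L,
            learning_rate > 0)
  structure(list(epochs_cnn_rnn = as.integer(epochs_cnn_rnn),
                 epochs_base = as.integer(epochs_base),
                 seed = as.integer(seed),
                 embedding_dim = as.integer(embedding_dim),
                 cnn_filter_widths = as.integer(cnn_filter_widths),
                 cnn_filters_per_width = as.integer(cnn_filters_per_width),
                 rnn_hidden_size = as.integer(rnn_hidden_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 grad_clip = grad_clip,
                 base_factory = base_factory),
            class = "train_config")
}

check_trainable <- function(train) {
  stopifnot(inherits(train, "encoded_set"))
  y <- train$label
  if (any(is.na(y))) stop_("training set contains unlabeled examples")
  if (length(unique(y)) < 2L) {
    stop_("training set must contain both classes")
  }
}

#' Train a co-mention classifier
#'
#' All classifiers honour the same contract: they are fitted on encoded
#' examples and emit per-example 2-vectors of class probabilities via
#' [predict_proba()]. Kinds:
#' \describe{
#'   \item{cnn}{parallel-width convolutional network, global max-pool.}
#'   \item{rnn}{bidirectional recurrent network, final-state concatenation.}
#'   \item{lightweight}{ridge-penalized logistic regression over token
#'     counts; trains in seconds and exists so the whole pipeline is
#'     testable at desk scale. A test fixture, not a scientific claim.}
#'   \item{base}{a pluggable pretrained model supplied via
#'     `cfg$base_factory`; errors when none is configured.}
#' }
#' Fitting is deterministic given `cfg$seed`; prediction is deterministic
#' after fitting.
#'
#' @param train an `encoded_set` with labels (both classes present).
#' @param kind one of `"cnn"`, `"rnn"`, `"lightweight"`, `"base"`.
#' @param cfg a [train_config()].
#' @return a fitted object of class `comention_classifier`.
#' @export
train_classifier <- function(train, kind = c("cnn", "rnn", "lightweight",
                                             "base"),
                             cfg = train_config()) {
  kind <- match.arg(kind)
  check_trainable(train)
  V <- length(train$vocab)
  L <- ncol(train$ids)
  y <- train$label
  model <- switch(
    kind,
    lightweight = {
      X <- token_count_matrix(train$ids, V)
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = c(1, 0.1, 0.01, 0.001),
                            standardize = FALSE)
      list(fit = fit, lambda = 0.001)
    },
    cnn = with_seed(cfg$seed, {
      params <- cnn_init(V, cfg$embedding_dim, cfg$cnn_filter_widths,
                         cfg$cnn_filters_per_width)
      list(params = nn_fit(params, cnn_forward, cnn_backward, train$ids, y,
                           cfg$epochs_cnn_rnn, cfg$batch_size,
                           cfg$learning_rate, cfg$grad_clip))
    }),
    rnn = with_seed(cfg$seed, {
      params <- rnn_init(V, cfg$embedding_dim, cfg$rnn_hidden_size)
      list(params = nn_fit(params, rnn_forward, rnn_backward, train$ids, y,
                           cfg$epochs_cnn_rnn, cfg$batch_size,
                           cfg$learning_rate, cfg$grad_clip))
    }),
    base = {
      if (!is.function(cfg$base_factory)) {
        stop_(paste("kind='base' requires a pretrained model plug-in:",
                    "supply train_config(base_factory = ...)",
                    "or use kind='lightweight'"))
      }
      return(cfg$base_factory(train, cfg))
    }
  )
  structure(c(model, list(kind = kind, V = V, L = L, cfg = cfg)),
            class = c(paste0("comention_", kind), "comention_classifier"))
}

token_count_matrix <- function(ids, V) {
  ## counts of ids 1..V-1 (pad id 0 dropped); n x (V - 1) sparse matrix
  n <- nrow(ids)
  ii <- rep(seq_len(n), ncol(ids))
  jj <- as.vector(ids)
  keep <- jj > 0L
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                       dims = c(n, V - 1L))
}

#' Per-class probabilities from a fitted classifier
#'
#' @param model a fitted `comention_classifier`.
#' @param examples an `encoded_set` or an integer id matrix with the
#'   classifier's sequence length.
#' @return numeric matrix n x 2; column 1 is P(class 0), column 2 is
#'   P(class 1); rows sum to 1.
#' @export
predict_proba <- function(model, examples) {
  UseMethod("predict_proba")
}

example_ids <- function(model, examples) {
  ids <- if (inherits(examples, "encoded_set")) examples$ids else examples
  if (!is.matrix(ids)) stop_("examples must be an encoded_set or id matrix")
  if (ncol(ids) != model$L) {
    stop_("example length %d does not match model length %d",
          ncol(ids), model$L)
  }
  ids
}

as_proba <- function(p1) {
  p1 <- pmin(pmax(as.numeric(p1), 0), 1)
  cbind(p0 = 1 - p1, p1 = p1)
}

#' @export
predict_proba.comention_lightweight <- function(model, examples) {
  ids <- example_ids(model, examples)
  X <- token_count_matrix(ids, model$V)
  p1 <- stats::predict(model$fit, newx = X, s = model$lambda,
                       type = "response")[, 1L]
  as_proba(p1)
}

#' @export
predict_proba.comention_cnn <- function(model, examples) {
  ids <- example_ids(model, examples)
  probs <- cnn_forward(model$params, ids)$probs
  colnames(probs) <- c("p0", "p1")
  probs
}

#' @export
predict_proba.comention_rnn <- function(model, examples) {
  ids <- example_ids(model, examples)
  probs <- rnn_forward(model$params, ids)$probs
  colnames(probs) <- c("p0", "p1")
  probs
}

#' Build an ensemble of fitted classifiers
#'
#' @param members list of fitted `comention_classifier`s sharing the same
#'   vocabulary size and sequence length (default composition downstream of
#'   self-training: one CNN and one RNN).
#' @return object of class `comention_ensemble`.
#' @export
ensemble_model <- function(members) {
  if (length(members) < 1L) stop_("ensemble needs at least one member")
  ok <- vapply(members, inherits, TRUE, "comention_classifier")
  if (!all(ok)) stop_("all ensemble members must be comention_classifiers")
  L <- unique(vapply(members, `[[`, 0L, "L"))
  V <- unique(vapply(members, `[[`, 0L, "V"))
  if (length(L) != 1L || length(V) != 1L) {
    stop_("ensemble members must share vocabulary and sequence length")
  }
  structure(list(members = members, L = L, V = V),
            class = "comention_ensemble")
}

#' Ensemble predictions by probability averaging
#'
#' The ensemble probability vector is the unweighted arithmetic mean of the
#' member probability vectors; the confidence score of an example is the
#' ensemble-averaged positive-class probability. The predicted class is the
#' argmax, with exact ties resolved to class 0 (a tie does not assert a
#' relation).
#'
#' @param ensemble a [ensemble_model()].
#' @param examples an `encoded_set` or id matrix.
#' @return data.frame with columns `prob0`, `prob1`, `predicted_class`,
#'   `confidence` (= `prob1`).
#' @export
ensemble_predict <- function(ensemble, examples) {
  stopifnot(inherits(ensemble, "comention_ensemble"))
  probs <- lapply(ensemble$members, predict_proba, examples = examples)
  avg <- Reduce(`+`, probs) / length(probs)
  data.frame(prob0 = avg[, 1L], prob1 = avg[, 2L],
             predicted_class = as.integer(avg[, 2L] > avg[, 1L]),
             confidence = avg[, 2L])
}
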