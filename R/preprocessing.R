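## preprocessing: entity masking, tokenization, vocabulary, fixed-length
## integer encoding, and the stratified train/validation/test split.

#' Preprocessing configuration
#'
#' @param protein_token sentinel replacing every protein name (default
#'   `"PROT"`).
#' @param phenotype_token sentinel replacing every phenotype name (default
#'   `"PHENO"`).
#' @param max_len fixed sequence length L; longer token sequences are
#'   truncated, shorter ones right-padded (default 128).
#' @param lowercase lowercase all non-sentinel tokens (default TRUE).
#' @param min_token_freq minimum training-split frequency for a token to
#'   enter the vocabulary (default 1).
#' @return object of class `preprocess_config`. `pad_id` is 0 and `unk_id`
#'   is 1, by construction.
#' @export
preprocess_config <- function(protein_token = "PROT",
                              phenotype_token = "PHENO",
                              max_len = 128L, lowercase = TRUE,
                              min_token_freq = 1L) {
  stopifnot(nzchar(protein_token), nzchar(phenotype_token),
            protein_token != phenotype_token,
            max_len >= 4L, min_token_freq >= 1L)
  structure(list(protein_token = protein_token,
                 phenotype_token = phenotype_token,
                 max_len = as.integer(max_len),
                 lowercase = isTRUE(lowercase),
                 min_token_freq = as.integer(min_token_freq),
                 pad_id = 0L, unk_id = 1L),
            class = "preprocess_config")
}

#' Mask all entity names in a sentence
#'
#' Every lexicon protein-name match becomes the protein sentinel and every
#' phenotype-name match the phenotype sentinel -- all entities, not only the
#' record's focal pair. Matching follows the extraction rules
#' (case-insensitive, token-boundary, leftmost-longest). Idempotent.
#'
#' @param sentence a single string.
#' @param proteins,phenotypes lexicons.
#' @param cfg a [preprocess_config()].
#' @return the masked sentence.
#' @export
mask_sentence <- function(sentence, proteins, phenotypes,
                          cfg = preprocess_config()) {
  men <- match_both(sentence, proteins, phenotypes)
  if (nrow(men) == 0L) return(sentence)
  men <- men[order(-men$start), , drop = FALSE]  # right-to-left replacement
  for (i in seq_len(nrow(men))) {
    tok <- if (men$kind[[i]] == "protein") cfg$protein_token
           else cfg$phenotype_token
    sentence <- paste0(substr(sentence, 1L, men$start[[i]]), tok,
                       substr(sentence, men$end[[i]] + 1L, nchar(sentence)))
  }
  sentence
}

#' Mask the sentence of a co-mention record
#'
#' @param record one co-mention row.
#' @inheritParams mask_sentence
#' @export
mask_entities <- function(record, proteins, phenotypes,
                          cfg = preprocess_config()) {
  mask_sentence(record$sentence, proteins, phenotypes, cfg)
}

#' Tokenize a masked sentence
#'
#' Splits on runs of non-alphanumeric characters (so hyphenated names split)
#' and discards empty tokens. Sentinel tokens are preserved verbatim; all
#' other tokens are lowercased when `cfg$lowercase`.
#'
#' @param masked_sentence a string (typically from [mask_sentence()]).
#' @param cfg a [preprocess_config()].
#' @return character vector of tokens.
#' @export
tokenize <- function(masked_sentence, cfg = preprocess_config()) {
  toks <- strsplit(masked_sentence, "[^[:alnum:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character())
  sentinel <- toks == cfg$protein_token | toks == cfg$phenotype_token
  if (cfg$lowercase) {
    toks[!sentinel] <- stringi::stri_trans_tolower(toks[!sentinel])
  }
  toks
}

#' Build a vocabulary from training-split token sequences
#'
#' Reserved ids: 0 = pad, 1 = unknown, 2 = protein sentinel, 3 = phenotype
#' sentinel. Remaining tokens with training frequency >= `min_token_freq`
#' follow, ordered by descending frequency then lexicographically (C
#' locale), so two builds on the same input are identical. Build the
#' vocabulary from the training split only, to avoid leakage.
#'
#' @param token_sequences list of character vectors.
#' @param cfg a [preprocess_config()].
#' @return named integer vector token -> id, class `comention_vocab`.
#' @export
build_vocab <- function(token_sequences, cfg = preprocess_config()) {
  reserved <- c("<pad>", "<unk>", cfg$protein_token, cfg$phenotype_token)
  toks <- unlist(token_sequences, use.names = FALSE)
  toks <- toks[!toks %in% reserved]
  extra <- character()
  if (length(toks)) {
    tab <- table(toks)
    tab <- tab[tab >= cfg$min_token_freq]
    if (length(tab)) {
      nm <- names(tab)
      ord <- order(-as.integer(tab), nm, method = "radix")
      extra <- nm[ord]
    }
  }
  all_tokens <- c(reserved, extra)
  structure(stats::setNames(seq_along(all_tokens) - 1L, all_tokens),
            class = "comention_vocab", cfg = cfg)
}

#' Encode tokens as a fixed-length id sequence
#'
#' Unknown tokens map to the unk id; sequences longer than L keep their
#' first L tokens; shorter ones are right-padded with the pad id.
#'
#' @param tokens character vector.
#' @param vocab a [build_vocab()] result.
#' @param cfg a [preprocess_config()].
#' @return integer vector of length exactly `cfg$max_len`.
#' @export
encode_pad <- function(tokens, vocab, cfg = preprocess_config()) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- cfg$unk_id
  n <- length(ids)
  L <- cfg$max_len
  if (n >= L) ids[seq_len(L)] else c(ids, rep(cfg$pad_id, L - n))
}

#' Encode a co-mention table into model-ready examples
#'
#' Runs mask -> tokenize -> encode for every record. When `vocab` is `NULL`
#' a vocabulary is built from these records (do this only on the training
#' split).
#'
#' @param records co-mention data.frame.
#' @param proteins,phenotypes lexicons.
#' @param vocab optional existing vocabulary.
#' @param cfg a [preprocess_config()].
#' @return object of class `encoded_set`: list with `ids` (integer matrix
#'   n x L), `label` (integer, `NA` when unlabeled), `key` (record identity
#'   strings), `vocab`, `cfg`.
#' @export
encode_records <- function(records, proteins, phenotypes, vocab = NULL,
                           cfg = preprocess_config()) {
  toks <- lapply(seq_len(nrow(records)), function(i) {
    tokenize(mask_sentence(records$sentence[[i]], proteins, phenotypes, cfg),
             cfg)
  })
  if (is.null(vocab)) vocab <- build_vocab(toks, cfg)
  ids <- matrix(cfg$pad_id, nrow = nrow(records), ncol = cfg$max_len)
  for (i in seq_along(toks)) ids[i, ] <- encode_pad(toks[[i]], vocab, cfg)
  structure(list(ids = ids,
                 label = as.integer(records$label),
                 key = comention_keys(records),
                 vocab = vocab, cfg = cfg),
            class = "encoded_set")
}

#' Record identity keys
#'
#' A co-mention is identified by (doc_id, sentence_index, protein_id,
#' phenotype_id); used for split-disjointness assertions.
#' @param records co-mention data.frame.
#' @export
comention_keys <- function(records) {
  paste(records$doc_id, records$sentence_index, records$protein_id,
        records$phenotype_id, sep = "\r")
}

#' Subset an encoded set
#' @param es an `encoded_set`.
#' @param idx integer or logical index.
#' @export
encoded_subset <- function(es, idx) {
  structure(list(ids = es$ids[idx, , drop = FALSE],
                 label = es$label[idx], key = es$key[idx],
                 vocab = es$vocab, cfg = es$cfg),
            class = "encoded_set")
}

#' Concatenate encoded sets (same vocabulary and length)
#' @param a,b `encoded_set`s.
#' @export
encoded_rbind <- function(a, b) {
  stopifnot(identical(unclass(a$vocab), unclass(b$vocab)),
            ncol(a$ids) == ncol(b$ids))
  structure(list(ids = rbind(a$ids, b$ids),
                 label = c(a$label, b$label),
                 key = c(a$key, b$key),
                 vocab = a$vocab, cfg = a$cfg),
            class = "encoded_set")
}

#' @export
print.encoded_set <- function(x, ...) {
  cat(sprintf("<encoded_set: %d examples, L=%d, |V|=%d, %d labeled>\n",
              nrow(x$ids), ncol(x$ids), length(x$vocab),
              sum(!is.na(x$label))))
  invisible(x)
}

#' Split configuration
#'
#' @param fractions train/validation/test fractions (default 0.60/0.20/0.20,
#'   must sum to 1).
#' @param seed integer seed for the per-class shuffle.
#' @export
split_config <- function(fractions = c(train = 0.6, validation = 0.2,
                                       test = 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_config")
}

#' Stratified train/validation/test split
#'
#' Per class: test gets round(f_test * n_c) records (round half up),
#' validation gets round(f_val * n_c), train the remainder. Partitions are
#' disjoint, exhaustive, and deterministic given the seed.
#'
#' @param records labeled co-mention data.frame (no `NA` labels).
#' @param cfg a [split_config()].
#' @return list of data.frames: `train`, `validation`, `test`.
#' @export
stratified_split <- function(records, cfg = split_config()) {
  if (any(is.na(records$label))) stop_("stratified_split requires labels")
  classes <- sort(unique(records$label))
  idx_tr <- idx_va <- idx_te <- integer()
  with_seed(cfg$seed, {
    for (cl in classes) {
      idx <- which(records$label == cl)
      n_c <- length(idx)
      if (n_c < 3L) stop_("class %d has %d record(s); need >= 3", cl, n_c)
      n_te <- as.integer(round_half_up(cfg$fractions[[3L]] * n_c))
      n_va <- as.integer(round_half_up(cfg$fractions[[2L]] * n_c))
      if (n_te + n_va >= n_c) stop_("class %d too small for fractions", cl)
      idx <- sample(idx)
      idx_te <- c(idx_te, idx[seq_len(n_te)])
      idx_va <- c(idx_va, idx[n_te + seq_len(n_va)])
      idx_tr <- c(idx_tr, idx[(n_te + n_va + 1L):n_c])
    }
  })
  list(train = records[sort(idx_tr), , drop = FALSE],
       validation = records[sort(idx_va), , drop = FALSE],
       test = records[sort(idx_te), , drop = FALSE])
}
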