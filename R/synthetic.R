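## synthetic: template-based generator of lexicons, corpora and
## labeled/unlabeled co-mention datasets with controllable signal, so every
## pipeline stage is testable against a known ground truth without any
## download. The Bayes-optimal rule is known by construction: relational
## template phrases appear only in true-positive sentences (with
## probability = signal strength); the remaining positives and all
## negatives draw from a shared co-occurrence-only template set.

## Relational phrases: their presence marks a valid relationship.
POS_TEMPLATES <- c(
  "mutations in {P} cause {H}",
  "{P} is associated with {H}",
  "loss of {P} results in {H}",
  "{P} deficiency leads to {H}",
  "variants of {P} confer susceptibility to {H}",
  "knockdown of {P} induces {H}"
)

## Co-occurrence-only phrases: enumerations and adjacent mentions without a
## relational verb; used by all negatives and by positives that miss the
## signal (ambiguous cases).
NEG_TEMPLATES <- c(
  "{P} and {H} were examined",
  "both {P} and {H} have been studied extensively",
  "the panel included {P} as well as {H}",
  "{P} was measured and {H} was recorded",
  "samples were screened for {P} and for {H}",
  "{P} appears in the list together with {H}"
)

#' Synthetic-world configuration
#'
#' @param n_proteins,n_phenotypes lexicon sizes (defaults 20/20).
#' @param max_name_words entity names have 1..max_name_words pseudowords
#'   (default 3).
#' @param n_labeled,n_unlabeled,n_test dataset sizes (defaults 100, 5000,
#'   500 -- a small gold set against a large pool).
#' @param positive_fraction fraction of true positives per subset (default
#'   0.5; counts are exact, round half up).
#' @param signal_strength probability that a true-positive sentence carries
#'   a relational template phrase (default 0.9).
#' @param label_noise probability that an observed label is flipped
#'   (default 0.05).
#' @param filler_vocab_size size of the shared filler-word pool (default
#'   200).
#' @param sentence_len_range target sentence lengths in words (default
#'   8..18).
#' @param seed integer master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 20L, n_phenotypes = 20L,
                         max_name_words = 3L, n_labeled = 100L,
                         n_unlabeled = 5000L, n_test = 500L,
                         positive_fraction = 0.5, signal_strength = 0.9,
                         label_noise = 0.05, filler_vocab_size = 200L,
                         sentence_len_range = c(8L, 18L), seed = 1L) {
  stopifnot(n_proteins >= 1L, n_phenotypes >= 1L, max_name_words >= 1L,
            n_labeled >= 0L, n_unlabeled >= 0L, n_test >= 0L,
            positive_fraction >= 0, positive_fraction <= 1,
            signal_strength >= 0, signal_strength <= 1,
            label_noise >= 0, label_noise <= 1,
            filler_vocab_size >= 10L, length(sentence_len_range) == 2L,
            sentence_len_range[[1L]] <= sentence_len_range[[2L]])
  structure(list(n_proteins = as.integer(n_proteins),
                 n_phenotypes = as.integer(n_phenotypes),
                 max_name_words = as.integer(max_name_words),
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_test = as.integer(n_test),
                 positive_fraction = positive_fraction,
                 signal_strength = signal_strength,
                 label_noise = label_noise,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 sentence_len_range = as.integer(sentence_len_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

## Unique 6-character CVCVCV pseudowords. Equal length guarantees no word is
## a substring of another; the strict consonant-vowel pattern guarantees no
## collision with template English or the PROT/PHENO sentinels.
pseudowords <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  n_syll <- length(cons) * length(vow)
  total <- n_syll^3
  if (n > total) stop_("too many pseudowords requested")
  idx <- sample.int(total, n) - 1L
  syll <- function(k) paste0(cons[k %/% length(vow) + 1L],
                             vow[k %% length(vow) + 1L])
  vapply(idx, function(i) {
    paste0(syll(i %/% n_syll^2), syll((i %/% n_syll) %% n_syll),
           syll(i %% n_syll))
  }, "")
}

#' Generate synthetic protein and phenotype lexicons
#'
#' Ids are `SP0001...` / `SH0001...`; each entity gets one multi-token name
#' of 1..max_name_words pseudowords. Every pseudoword is globally unique
#' and of equal length, so no name is a substring of another and the
#' dictionary-matching oracle is unambiguous. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `proteins` and `phenotypes` lexicons and the reserved
#'   `filler` word pool.
#' @export
generate_lexicons <- function(cfg = synth_config()) {
  with_seed(derive_seed(cfg$seed, "lexicons"), {
    n_ent <- cfg$n_proteins + cfg$n_phenotypes
    n_words <- sample(seq_len(cfg$max_name_words), n_ent, replace = TRUE)
    words <- pseudowords(sum(n_words) + cfg$filler_vocab_size)
    name_words <- words[seq_len(sum(n_words))]
    filler <- words[sum(n_words) + seq_len(cfg$filler_vocab_size)]
    names_all <- character(n_ent)
    off <- 0L
    for (i in seq_len(n_ent)) {
      names_all[[i]] <- paste(name_words[off + seq_len(n_words[[i]])],
                              collapse = " ")
      off <- off + n_words[[i]]
    }
    prot <- as.list(names_all[seq_len(cfg$n_proteins)])
    names(prot) <- sprintf("SP%04d", seq_len(cfg$n_proteins))
    phen <- as.list(names_all[cfg$n_proteins + seq_len(cfg$n_phenotypes)])
    names(phen) <- sprintf("SH%04d", seq_len(cfg$n_phenotypes))
    list(proteins = lexicon(prot, "protein"),
         phenotypes = lexicon(phen, "phenotype"),
         filler = filler)
  })
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

## Build one sentence from a template; returns the sentence plus 0-based
## half-open spans of the two entity names.
build_sentence <- function(template, pname, hname, filler, len_range) {
  tpl_words <- strsplit(template, " ", fixed = TRUE)[[1L]]
  n_prefix <- sample(0:3, 1L)
  target <- sample(seq(len_range[[1L]], len_range[[2L]]), 1L)
  n_suffix <- max(0L, target - length(tpl_words) - n_prefix)
  words <- c(if (n_prefix > 0L) sample(filler, n_prefix, replace = TRUE),
             tpl_words,
             if (n_suffix > 0L) sample(filler, n_suffix, replace = TRUE))
  words[words == "{P}"] <- pname
  words[words == "{H}"] <- hname
  p_at <- which(c(rep(FALSE, n_prefix), tpl_words == "{P}",
                  rep(FALSE, n_suffix)))
  h_at <- which(c(rep(FALSE, n_prefix), tpl_words == "{H}",
                  rep(FALSE, n_suffix)))
  starts <- c(0L, cumsum(nchar(words) + 1L))  # 0-based word starts
  sent <- paste0(capitalize(paste(words, collapse = " ")), ".")
  list(sentence = sent,
       protein_span = c(starts[[p_at]], starts[[p_at]] + nchar(pname)),
       phenotype_span = c(starts[[h_at]], starts[[h_at]] + nchar(hname)))
}

#' Generate a complete synthetic dataset
#'
#' Emits labeled, unlabeled and test co-mention records plus the document
#' corpus containing every sentence (documents hold 1-3 co-mention
#' sentences and occasionally a filler-only sentence). Each sentence embeds
#' exactly one protein and one phenotype name. True positives carry a
#' relational template phrase with probability `signal_strength`, otherwise
#' an ambiguous co-occurrence template; negatives always use co-occurrence
#' templates. Observed labels are the true labels flipped with probability
#' `label_noise`; per-subset positive counts are exact. True generative
#' labels are returned in a separate `truth` side channel for test oracles
#' only -- pipeline code must never read it.
#'
#' @param cfg a [synth_config()].
#' @param lexicons optional result of [generate_lexicons()] (generated when
#'   `NULL`).
#' @return list with `labeled`, `unlabeled`, `test` (co-mention
#'   data.frames), `corpus` (documents), `truth` (subset, index,
#'   true_label, observed_label), `proteins`, `phenotypes`.
#' @export
generate_dataset <- function(cfg = synth_config(), lexicons = NULL) {
  if (is.null(lexicons)) lexicons <- generate_lexicons(cfg)
  prot_ids <- names(lexicons$proteins$entries)
  phen_ids <- names(lexicons$phenotypes$entries)
  sizes <- c(labeled = cfg$n_labeled, unlabeled = cfg$n_unlabeled,
             test = cfg$n_test)
  with_seed(derive_seed(cfg$seed, "dataset"), {
    subsets <- list()
    truth <- list()
    doc_counter <- 0L
    for (sub in names(sizes)) {
      n <- sizes[[sub]]
      if (n == 0L) {
        subsets[[sub]] <- NULL
        next
      }
      n_pos <- as.integer(round_half_up(cfg$positive_fraction * n))
      true_lab <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
      observed <- ifelse(stats::runif(n) < cfg$label_noise,
                         1L - true_lab, true_lab)
      pid <- sample(prot_ids, n, replace = TRUE)
      hid <- sample(phen_ids, n, replace = TRUE)
      has_signal <- true_lab == 1L & stats::runif(n) < cfg$signal_strength
      tpl <- ifelse(has_signal,
                    sample(POS_TEMPLATES, n, replace = TRUE),
                    sample(NEG_TEMPLATES, n, replace = TRUE))
      sentence <- character(n)
      p_span <- matrix(0L, n, 2L)
      h_span <- matrix(0L, n, 2L)
      for (i in seq_len(n)) {
        bs <- build_sentence(tpl[[i]], lexicons$proteins$entries[[pid[[i]]]],
                             lexicons$phenotypes$entries[[hid[[i]]]],
                             lexicons$filler, cfg$sentence_len_range)
        sentence[[i]] <- bs$sentence
        p_span[i, ] <- bs$protein_span
        h_span[i, ] <- bs$phenotype_span
      }
      recs <- data.frame(
        doc_id = NA_character_, sentence_index = NA_integer_,
        sentence = sentence,
        protein_id = pid, protein_start = p_span[, 1L],
        protein_end = p_span[, 2L],
        phenotype_id = hid, phenotype_start = h_span[, 1L],
        phenotype_end = h_span[, 2L],
        year = sample(1990:2024, n, replace = TRUE),
        label = if (sub == "unlabeled") NA_integer_ else observed,
        confidence = NA_real_, stringsAsFactors = FALSE
      )
      subsets[[sub]] <- recs
      truth[[sub]] <- data.frame(subset = sub, index = seq_len(n),
                                 true_label = true_lab,
                                 observed_label = observed,
                                 stringsAsFactors = FALSE)
    }

    ## pack sentences into documents: 1-3 co-mention sentences per document,
    ## with a filler-only sentence inserted with probability 0.3
    docs <- list()
    for (sub in names(subsets)) {
      recs <- subsets[[sub]]
      if (is.null(recs)) next
      i <- 1L
      n <- nrow(recs)
      while (i <= n) {
        take <- min(sample(1:3, 1L), n - i + 1L)
        doc_counter <- doc_counter + 1L
        doc_id <- sprintf("SD%06d", doc_counter)
        sents <- recs$sentence[i:(i + take - 1L)]
        s_idx <- seq_along(sents) - 1L
        if (stats::runif(1L) < 0.3) {
          fill_sent <- paste0(capitalize(paste(
            sample(lexicons$filler, sample(5:10, 1L), replace = TRUE),
            collapse = " ")), ".")
          at <- sample(0:length(sents), 1L)  # insertion point
          sents <- append(sents, fill_sent, after = at)
          s_idx <- setdiff(seq_along(sents), at + 1L) - 1L
        }
        recs$doc_id[i:(i + take - 1L)] <- doc_id
        recs$sentence_index[i:(i + take - 1L)] <- s_idx
        recs$year[i:(i + take - 1L)] <- recs$year[[i]]  # one year per doc
        docs[[doc_counter]] <- data.frame(
          doc_id = doc_id, year = recs$year[[i]],
          text = paste(sents, collapse = " "), stringsAsFactors = FALSE)
        i <- i + take
      }
      subsets[[sub]] <- recs
    }

    out <- lapply(subsets, comention_records)
    list(labeled = out$labeled, unlabeled = out$unlabeled, test = out$test,
         corpus = do.call(rbind, docs),
         truth = do.call(rbind, truth),
         proteins = lexicons$proteins, phenotypes = lexicons$phenotypes)
  })
}
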