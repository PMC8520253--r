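## extraction: sentence segmentation, dictionary-based entity matching, and
## emission of one co-mention record per (sentence, protein, phenotype) pair.

## Tokens that end with "." but do not terminate a sentence.
ABBREVIATIONS <- c("e.g.", "i.e.", "etc.", "cf.", "vs.", "ca.", "approx.",
                   "Fig.", "Figs.", "Tab.", "Eq.", "Ref.", "al.", "Dr.",
                   "St.", "No.", "resp.")

#' Split text into sentences
#'
#' Rule-based segmenter: a sentence ends at a run of `.?!` followed by
#' whitespace and an uppercase letter or digit, unless the preceding token
#' is a known abbreviation (e.g. "e.g.", "Fig.", "et al.") or a single
#' capital-letter initial. The segmenter is deliberately simple and
#' pluggable; see [extract_comentions()].
#'
#' @param text a single string (may be empty).
#' @return data.frame with columns `sentence` (character) and `start`
#'   (integer, 0-based offset of the sentence within `text`). Sentences are
#'   non-overlapping, in order, and cover all non-whitespace text.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(sentence = character(), start = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  text <- norm_text(text)
  m <- gregexpr("[.?!]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1L]]
  breaks <- integer()
  if (m[[1L]] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last punct
    for (e in ends) {
      ## token immediately preceding and including the punctuation
      head_txt <- substr(text, 1L, e)
      tok <- sub(".*[\\s(]", "", head_txt, perl = TRUE)
      if (tok %in% ABBREVIATIONS) next
      if (grepl("^[A-Z]\\.$", tok)) next  # initials like "J."
      breaks <- c(breaks, e)
    }
  }
  starts1 <- c(1L, breaks + 1L)
  ends1 <- c(breaks, nchar(text))
  out <- lapply(seq_along(starts1), function(i) {
    raw <- substr(text, starts1[[i]], ends1[[i]])
    lead <- nchar(sub("^\\s*", "", raw))
    s0 <- starts1[[i]] + (nchar(raw) - lead)  # 1-based start after whitespace
    sent <- trimws(raw)
    if (!nzchar(sent)) return(NULL)
    data.frame(sentence = sent, start = s0 - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

## Collect every candidate dictionary match of the (id, name) pairs in
## `sentence`: case-insensitive, token-boundary anchored. Returns a
## data.frame of candidates (entity_id, start, end, kind) with 0-based
## half-open spans, unresolved for overlap. Vectorized over names and hits.
candidate_matches <- function(sentence, ids, names, kinds) {
  empty <- data.frame(entity_id = character(), start = integer(),
                      end = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  low <- stringi::stri_trans_tolower(sentence)
  loc <- stringi::stri_locate_all_fixed(low, stringi::stri_trans_tolower(names))
  n_hits <- vapply(loc, function(m) if (is.na(m[1L, 1L])) 0L else nrow(m), 0L)
  if (sum(n_hits) == 0L) return(empty)
  which_name <- rep.int(seq_along(names), n_hits)
  s1 <- unlist(lapply(loc[n_hits > 0L], function(m) m[, 1L]),
               use.names = FALSE)
  e1 <- unlist(lapply(loc[n_hits > 0L], function(m) m[, 2L]),
               use.names = FALSE)
  nlen <- stringi::stri_length(low)
  is_alnum <- function(ch) stringi::stri_detect_regex(ch, "^[[:alnum:]]$")
  before_ok <- s1 == 1L | !is_alnum(stringi::stri_sub(low, s1 - 1L, s1 - 1L))
  after_ok <- e1 == nlen | !is_alnum(stringi::stri_sub(low, e1 + 1L, e1 + 1L))
  keep <- before_ok & after_ok
  if (!any(keep)) return(empty)
  data.frame(entity_id = ids[which_name[keep]],
             start = as.integer(s1[keep] - 1L),
             end = as.integer(e1[keep]),
             kind = kinds[which_name[keep]],
             stringsAsFactors = FALSE)
}

## Leftmost-longest non-overlapping resolution of candidate matches.
## Ties at identical (start, length): protein before phenotype, then id.
resolve_matches <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(cand$start, -(cand$end - cand$start),
               match(cand$kind, c("protein", "phenotype")), cand$entity_id,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  taken_end <- -1L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[[i]] >= taken_end) {
      keep[[i]] <- TRUE
      taken_end <- cand$end[[i]]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find lexicon mentions in a sentence
#'
#' Dictionary matching: case-insensitive, anchored at token boundaries
#' (transitions between alphanumeric and non-alphanumeric characters, so
#' "AML" never matches inside "AML1"), leftmost-longest, non-overlapping.
#'
#' @param sentence a single string.
#' @param lexicon a [lexicon()].
#' @return data.frame with columns `entity_id`, `start`, `end` (0-based
#'   half-open span) and `matched_text`, in span order.
#' @export
match_entities <- function(sentence, lexicon) {
  stopifnot(inherits(lexicon, "comention_lexicon"))
  ids <- rep(names(lexicon$entries), lengths(lexicon$entries))
  nms <- unlist(lexicon$entries, use.names = FALSE)
  cand <- candidate_matches(sentence, ids, nms, rep(lexicon$kind, length(ids)))
  res <- resolve_matches(cand)
  res$matched_text <- substr(rep(sentence, nrow(res)), res$start + 1L, res$end)
  res[c("entity_id", "start", "end", "matched_text")]
}

## Joint matching over both lexicons so that overlapping protein/phenotype
## name matches are resolved by the same leftmost-longest rule (the shorter
## match is dropped).
match_both <- function(sentence, proteins, phenotypes) {
  pids <- rep(names(proteins$entries), lengths(proteins$entries))
  pnms <- unlist(proteins$entries, use.names = FALSE)
  hids <- rep(names(phenotypes$entries), lengths(phenotypes$entries))
  hnms <- unlist(phenotypes$entries, use.names = FALSE)
  cand <- candidate_matches(
    sentence,
    c(pids, hids), c(pnms, hnms),
    c(rep("protein", length(pids)), rep("phenotype", length(hids)))
  )
  resolve_matches(cand)
}

#' Extract co-mentions from a document
#'
#' Splits the document into sentences, matches both lexicons, and emits one
#' co-mention record per (sentence, distinct protein id, distinct phenotype
#' id) pair: a sentence with m distinct proteins and n distinct phenotypes
#' yields m*n records, with spans pointing at the first mention of each id.
#' Sentences lacking either entity kind yield nothing.
#'
#' @param doc one row of a document data.frame (or a list with `doc_id`,
#'   `year`, `text`).
#' @param proteins,phenotypes lexicons of matching kinds.
#' @param segmenter sentence-splitting function with the contract of
#'   [split_sentences()]; swap in a statistical segmenter if desired.
#' @return co-mention data.frame (see [comention_records()]).
#' @export
extract_comentions <- function(doc, proteins, phenotypes,
                               segmenter = split_sentences) {
  stopifnot(proteins$kind == "protein", phenotypes$kind == "phenotype")
  sents <- segmenter(doc$text)
  out <- vector("list", nrow(sents))
  for (si in seq_len(nrow(sents))) {
    sent <- sents$sentence[[si]]
    men <- match_both(sent, proteins, phenotypes)
    if (nrow(men) == 0L) next
    prot <- men[men$kind == "protein", , drop = FALSE]
    phen <- men[men$kind == "phenotype", , drop = FALSE]
    if (nrow(prot) == 0L || nrow(phen) == 0L) next
    ## first mention of each distinct id, in order of first appearance
    prot <- prot[!duplicated(prot$entity_id), , drop = FALSE]
    phen <- phen[!duplicated(phen$entity_id), , drop = FALSE]
    grid <- expand.grid(p = seq_len(nrow(prot)), h = seq_len(nrow(phen)),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$p, grid$h), , drop = FALSE]
    out[[si]] <- data.frame(
      doc_id = doc$doc_id,
      sentence_index = si - 1L,
      sentence = sent,
      protein_id = prot$entity_id[grid$p],
      protein_start = prot$start[grid$p],
      protein_end = prot$end[grid$p],
      phenotype_id = phen$entity_id[grid$h],
      phenotype_start = phen$start[grid$h],
      phenotype_end = phen$end[grid$h],
      year = if (is.null(doc$year)) NA_integer_ else as.integer(doc$year),
      label = NA_integer_,
      confidence = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    df <- data.frame(matrix(character(), 0L, length(COMENTION_COLS)),
                     stringsAsFactors = FALSE)
    names(df) <- COMENTION_COLS
    return(comention_records(df))
  }
  comention_records(out)
}

#' Extract co-mentions from a whole corpus
#'
#' @param docs document data.frame from [read_documents()].
#' @inheritParams extract_comentions
#' @export
extract_corpus <- function(docs, proteins, phenotypes,
                           segmenter = split_sentences) {
  parts <- lapply(seq_len(nrow(docs)), function(i)
    extract_comentions(docs[i, ], proteins, phenotypes, segmenter))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
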