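## ranking: the curation-assistant engine. Score stored co-mentions with a
## fitted ensemble and answer protein / phenotype / pair queries with the
## top-k sentences by descending confidence.

#' Score a co-mention store with a fitted ensemble
#'
#' Each record's confidence becomes the ensemble-averaged positive-class
#' probability of its (masked, encoded) sentence. Records that fail to
#' encode are skipped with a warning.
#'
#' @param records co-mention data.frame.
#' @param ensemble a fitted `comention_ensemble`.
#' @param proteins,phenotypes lexicons used for masking.
#' @param vocab the training vocabulary.
#' @param cfg the [preprocess_config()] used at training time.
#' @return object of class `scored_store`: the scored records plus
#'   protein/phenotype/pair indexes.
#' @export
score_store <- function(records, ensemble, proteins, phenotypes, vocab,
                        cfg = preprocess_config()) {
  keep <- rep(TRUE, nrow(records))
  enc <- tryCatch(
    encode_records(records, proteins, phenotypes, vocab, cfg),
    error = function(e) NULL
  )
  if (is.null(enc)) {
    ## fall back to per-record encoding so one bad record is skipped, not all
    rows <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      rows[[i]] <- tryCatch(
        encode_records(records[i, ], proteins, phenotypes, vocab, cfg)$ids,
        error = function(e) {
          warn_("skipping record %d: %s", i, conditionMessage(e))
          NULL
        }
      )
      keep[[i]] <- !is.null(rows[[i]])
    }
    ids <- do.call(rbind, rows[keep])
  } else {
    ids <- enc$ids
  }
  records <- records[keep, , drop = FALSE]
  pred <- ensemble_predict(ensemble, ids)
  records$confidence <- pred$confidence
  rownames(records) <- NULL
  structure(list(
    records = records,
    idx_protein = split(seq_len(nrow(records)), records$protein_id),
    idx_phenotype = split(seq_len(nrow(records)), records$phenotype_id),
    idx_pair = split(seq_len(nrow(records)),
                     paste(records$protein_id, records$phenotype_id,
                           sep = "\r"))
  ), class = "scored_store")
}

#' @export
print.scored_store <- function(x, ...) {
  cat(sprintf("<scored_store: %d records, %d proteins, %d phenotypes>\n",
              nrow(x$records), length(x$idx_protein),
              length(x$idx_phenotype)))
  invisible(x)
}

#' Query a scored store
#'
#' Returns records matching all supplied ids, sorted by confidence
#' descending with ties broken by doc_id then sentence_index ascending (a
#' deterministic total order), cut at `top_k`. Each returned record exposes
#' the sentence, its PubMed id, year and confidence.
#'
#' @param store a [score_store()].
#' @param protein_id,phenotype_id at least one must be given.
#' @param top_k maximum records returned (>= 1).
#' @return co-mention data.frame (possibly empty) with a leading `rank`
#'   column.
#' @export
query_rank <- function(store, protein_id = NULL, phenotype_id = NULL,
                       top_k = 10L) {
  stopifnot(inherits(store, "scored_store"))
  if (is.null(protein_id) && is.null(phenotype_id)) {
    stop_("supply a protein id, a phenotype id, or both")
  }
  if (top_k < 1L) stop_("top_k must be >= 1")
  idx <- seq_len(nrow(store$records))
  if (!is.null(protein_id) && !is.null(phenotype_id)) {
    idx <- store$idx_pair[[paste(protein_id, phenotype_id, sep = "\r")]]
  } else if (!is.null(protein_id)) {
    idx <- store$idx_protein[[protein_id]]
  } else {
    idx <- store$idx_phenotype[[phenotype_id]]
  }
  if (is.null(idx) || length(idx) == 0L) {
    out <- store$records[0L, , drop = FALSE]
    out$rank <- integer()
    return(out[c("rank", setdiff(names(out), "rank"))])
  }
  hits <- store$records[idx, , drop = FALSE]
  ord <- order(-hits$confidence, hits$doc_id, hits$sentence_index,
               method = "radix")
  hits <- hits[ord[seq_len(min(top_k, length(ord)))], , drop = FALSE]
  rownames(hits) <- NULL
  hits <- cbind(rank = seq_len(nrow(hits)), hits)
  hits
}

#' Resolve an entity name or id against a lexicon
#'
#' Exact case-insensitive match on surface names; an input that already is a
#' lexicon id resolves to itself. A name shared by several ids is an error
#' listing the candidates (no fuzzy matching).
#'
#' @param query name or id string.
#' @param lexicon a [lexicon()].
#' @return the entity id.
#' @export
resolve_entity <- function(query, lexicon) {
  stopifnot(inherits(lexicon, "comention_lexicon"))
  if (query %in% names(lexicon$entries)) return(query)
  q <- stringi::stri_trans_tolower(squish(norm_text(query)))
  hits <- names(lexicon$entries)[vapply(lexicon$entries, function(nms)
    q %in% stringi::stri_trans_tolower(nms), TRUE)]
  if (length(hits) == 0L) stop_("no %s matches '%s'", lexicon$kind, query)
  if (length(hits) > 1L) {
    stop_("'%s' is ambiguous between: %s", query,
          paste(hits, collapse = ", "))
  }
  hits
}
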