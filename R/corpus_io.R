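## corpus_io: readers/writers for documents, lexicons and co-mention tables.
## All downstream modules consume only the data frames defined here.

COMENTION_COLS <- c(
  "doc_id", "sentence_index", "sentence",
  "protein_id", "protein_start", "protein_end",
  "phenotype_id", "phenotype_start", "phenotype_end",
  "year", "label", "confidence"
)

#' Read a document corpus
#'
#' Documents are one record per biomedical document (e.g. a Medline
#' abstract): a document identifier such as a PMID, an optional publication
#' year, and the text. Two on-disk formats are accepted: JSON-lines with
#' keys `doc_id`, `year` (optional) and `text`, or plain text with one
#' document per line (ids are generated as `doc1`, `doc2`, ...).
#'
#' @param path path to a UTF-8 file.
#' @param format `"jsonl"` (default) or `"text"`.
#' @return a data.frame with columns `doc_id` (character), `year` (integer,
#'   `NA` when absent) and `text` (character), in file order.
#' @export
read_documents <- function(path, format = c("jsonl", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("document file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(doc_id = character(), year = integer(),
                      text = character(), stringsAsFactors = FALSE))
  }
  if (format == "jsonl") {
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$doc_id) || is.null(rec$text)) {
        stop_("malformed document record at line %d of %s", i, path)
      }
      list(doc_id = as.character(rec$doc_id),
           year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
           text = norm_text(as.character(rec$text)))
    })
    docs <- data.frame(
      doc_id = vapply(recs, `[[`, "", "doc_id"),
      year = vapply(recs, `[[`, NA_integer_, "year"),
      text = vapply(recs, `[[`, "", "text"),
      stringsAsFactors = FALSE
    )
  } else {
    docs <- data.frame(
      doc_id = paste0("doc", seq_along(lines)),
      year = NA_integer_,
      text = norm_text(lines),
      stringsAsFactors = FALSE
    )
  }
  if (any(docs$doc_id == "")) stop_("empty doc_id in %s", path)
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup)) stop_("duplicate doc_id in %s: %s", path, dup[[1L]])
  docs
}

#' Construct an entity lexicon
#'
#' A lexicon maps entity identifiers (UniProt accessions for proteins, HPO
#' ids for phenotypes) to an ordered set of surface names used for
#' dictionary matching.
#'
#' @param entries named list: `entity_id -> character vector of names`.
#' @param kind `"protein"` or `"phenotype"`.
#' @param validate_ids when `TRUE`, phenotype ids must match `HP:` followed
#'   by 7 digits (disable for synthetic lexicons). Default: validate iff
#'   `kind == "phenotype"` and ids look HPO-style is left to the caller.
#' @return an object of class `comention_lexicon`.
#' @export
lexicon <- function(entries, kind = c("protein", "phenotype"),
                    validate_ids = FALSE) {
  kind <- match.arg(kind)
  ids <- names(entries)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    stop_("lexicon entries must be uniquely named by entity id")
  }
  entries <- lapply(entries, function(nm) {
    nm <- squish(norm_text(as.character(nm)))
    if (any(nm == "")) stop_("empty surface name in lexicon")
    nm
  })
  if (validate_ids && kind == "phenotype" &&
      !all(grepl("^HP:[0-9]{7}$", ids))) {
    bad <- ids[!grepl("^HP:[0-9]{7}$", ids)][[1L]]
    stop_("phenotype id does not match HP:<7 digits>: %s", bad)
  }
  structure(list(kind = kind, entries = entries),
            class = "comention_lexicon")
}

#' @export
print.comention_lexicon <- function(x, ...) {
  cat(sprintf("<%s lexicon: %d ids, %d names>\n", x$kind,
              length(x$entries), sum(lengths(x$entries))))
  invisible(x)
}

#' Read an entity lexicon from TSV
#'
#' Expects a headerless TSV with at least two columns, `id` and `name`, one
#' row per (id, name) pair. Names are grouped by id in file order and
#' whitespace-normalized.
#'
#' @inheritParams lexicon
#' @param path TSV path.
#' @export
read_lexicon <- function(path, kind = c("protein", "phenotype"),
                         validate_ids = (match.arg(kind) == "phenotype")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_("lexicon file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           colClasses = "character", encoding = "UTF-8")
  if (ncol(tab) < 2L) stop_("lexicon TSV needs >= 2 columns (id, name)")
  ids <- tab[[1L]]
  nms <- squish(norm_text(tab[[2L]]))
  if (any(nms == "")) {
    stop_("empty surface name at line %d of %s", which(nms == "")[[1L]], path)
  }
  entries <- split(nms, factor(ids, levels = unique(ids)))
  lexicon(as.list(entries), kind = kind, validate_ids = validate_ids)
}

#' Construct a co-mention table
#'
#' One row per sentence-level co-occurrence of a protein and a phenotype.
#' Character spans are 0-based half-open intervals over the sentence string.
#' `label` is 1 for a "good" (valid relationship) co-mention, 0 for "bad";
#' absent fields are `NA`.
#'
#' @param ... column vectors in the order of `COMENTION_COLS`, or a
#'   data.frame with those columns.
#' @return a validated data.frame with the canonical columns.
#' @export
comention_records <- function(...) {
  args <- list(...)
  df <- if (length(args) == 1L && is.data.frame(args[[1L]])) args[[1L]]
        else data.frame(..., stringsAsFactors = FALSE)
  missing_cols <- setdiff(COMENTION_COLS, names(df))
  if (length(missing_cols)) {
    stop_("missing co-mention columns: %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[COMENTION_COLS]
  df$doc_id <- as.character(df$doc_id)
  df$sentence <- as.character(df$sentence)
  df$protein_id <- as.character(df$protein_id)
  df$phenotype_id <- as.character(df$phenotype_id)
  for (col in c("sentence_index", "protein_start", "protein_end",
                "phenotype_start", "phenotype_end", "year", "label")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$confidence <- as.numeric(df$confidence)
  validate_comentions(df)
  df
}

#' Validate co-mention invariants
#'
#' Checks span bounds and non-overlap; when lexicons are supplied, also
#' checks that each span's substring equals (case-insensitively) a surface
#' name of the recorded entity id.
#'
#' @param records co-mention data.frame.
#' @param proteins,phenotypes optional lexicons.
#' @return `records`, invisibly; errors on violation.
#' @export
validate_comentions <- function(records, proteins = NULL, phenotypes = NULL) {
  if (nrow(records) == 0L) return(invisible(records))
  n <- nchar(records$sentence)
  ok <- records$protein_start >= 0L & records$protein_end <= n &
    records$protein_start < records$protein_end &
    records$phenotype_start >= 0L & records$phenotype_end <= n &
    records$phenotype_start < records$phenotype_end
  if (any(!ok)) stop_("span out of bounds in co-mention row %d", which(!ok)[[1L]])
  overlap <- pmax(records$protein_start, records$phenotype_start) <
    pmin(records$protein_end, records$phenotype_end)
  if (any(overlap)) {
    stop_("overlapping protein/phenotype spans in row %d", which(overlap)[[1L]])
  }
  check_lex <- function(lex, id_col, s_col, e_col, what) {
    if (is.null(lex)) return()
    sub <- substr(records$sentence, records[[s_col]] + 1L, records[[e_col]])
    for (i in seq_len(nrow(records))) {
      names_i <- lex$entries[[records[[id_col]][i]]]
      if (is.null(names_i) || !(tolower(sub[i]) %in% tolower(names_i))) {
        stop_("%s span text '%s' not a lexicon name of %s (row %d)",
              what, sub[i], records[[id_col]][i], i)
      }
    }
  }
  check_lex(proteins, "protein_id", "protein_start", "protein_end", "protein")
  check_lex(phenotypes, "phenotype_id", "phenotype_start", "phenotype_end",
            "phenotype")
  invisible(records)
}

#' Write co-mentions to TSV
#'
#' Fixed column order (see `COMENTION_COLS`), header row, absent values as
#' empty strings, confidences with 9 decimal digits. Sentences must not
#' contain tab or newline characters (they never do when produced by the
#' sentence splitter).
#'
#' @param records co-mention data.frame.
#' @param path output path.
#' @export
write_comentions <- function(records, path) {
  if (any(grepl("[\t\n\r]", records$sentence))) {
    stop_("sentence contains tab/newline; cannot serialize as TSV")
  }
  fmt <- records
  fmt$confidence <- ifelse(is.na(records$confidence), "",
                           sprintf("%.9f", records$confidence))
  for (col in names(fmt)) {
    v <- fmt[[col]]
    fmt[[col]] <- ifelse(is.na(v), "", as.character(v))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(COMENTION_COLS, collapse = "\t"),
               do.call(paste, c(unname(fmt), sep = "\t"))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read co-mentions from TSV
#'
#' Inverse of [write_comentions()]; validates span bounds on read.
#' @param path TSV path.
#' @export
read_comentions <- function(path) {
  if (!file.exists(path)) stop_("co-mention file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, COMENTION_COLS)) {
    stop_("unexpected co-mention header in %s", path)
  }
  body <- lines[-1L]
  if (length(body) == 0L) {
    df <- data.frame(matrix(character(), 0L, length(COMENTION_COLS)),
                     stringsAsFactors = FALSE)
    names(df) <- COMENTION_COLS
    return(comention_records(df))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  ## trailing empty fields are dropped by strsplit; restore them
  parts <- lapply(parts, function(p) c(p, rep("", 12L - length(p))))
  if (any(nf > 12L)) stop_("too many fields at line %d", which(nf > 12L)[[1L]] + 1L)
  col <- function(j) vapply(parts, `[[`, "", j)
  df <- data.frame(
    doc_id = col(1L), sentence_index = col(2L), sentence = col(3L),
    protein_id = col(4L), protein_start = col(5L), protein_end = col(6L),
    phenotype_id = col(7L), phenotype_start = col(8L), phenotype_end = col(9L),
    year = col(10L), label = col(11L), confidence = col(12L),
    stringsAsFactors = FALSE
  )
  for (c2 in c("sentence_index", "protein_start", "protein_end",
               "phenotype_start", "phenotype_end", "year", "label")) {
    df[[c2]] <- ifelse(df[[c2]] == "", NA_integer_, df[[c2]])
  }
  df$confidence <- ifelse(df$confidence == "", NA_character_, df$confidence)
  comention_records(df)
}
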