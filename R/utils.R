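#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never perturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from one global seed
#'
#' One global `--seed` fans out to reproducible per-stage seeds keyed by the
#' stage name, so stages can be rerun independently yet deterministically.
#' Result is always in `[0, 2^31 - 2]`.
#' @param seed integer global seed.
#' @param stage character stage name (e.g. "base_fit", "member_cnn").
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000003
  as.integer((abs(seed) %% 2097152 * 1000003 + h) %% 2147483647)
}

#' Normalize text to NFC and squish whitespace
#' @noRd
norm_text <- function(x) stringi::stri_trans_nfc(enc2utf8(x))

#' @noRd
squish <- function(x) gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))

#' Round half away from zero (commercial rounding)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
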