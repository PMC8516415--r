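#' Stage-vocabulary dialects
#'
#' Hypnogram files in the wild use heterogeneous stage vocabularies. A
#' dialect is a named character vector mapping every raw token to one of the
#' canonical stages `W, N1, N2, N3, R` or to `"UNS"` (unscored). Two
#' built-ins are provided:
#'
#' * `dialect_aasm()` — identity mapping for AASM labels, plus common
#'   aliases (`"REM"`, `"WAKE"`, `"Sleep stage W"`-style tokens are *not*
#'   included; supply your own dialect for annotation-style files).
#' * `dialect_rk()` — numeric Rechtschaffen & Kales tokens as used by many
#'   legacy cohorts: `0` = W, `1` = N1, `2` = N2, `3` and `4` = N3 (the two
#'   R&K slow-wave-sleep stages are merged under AASM rules), `5` = R,
#'   `9` = unscored, `"MOVEMENT"`/`"UNKNOWN"` = unscored.
#'
#' @return Named character vector (names = raw tokens, values = canonical).
#' @export
dialect_aasm <- function() {
  c(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", R = "R",
    UNS = "UNS", MOVEMENT = "UNS", UNKNOWN = "UNS")
}

#' @rdname dialect_aasm
#' @export
dialect_rk <- function() {
  c(`0` = "W", `1` = "N1", `2` = "N2", `3` = "N3", `4` = "N3", `5` = "R",
    `9` = "UNS", MOVEMENT = "UNS", UNKNOWN = "UNS")
}

#' Read a hypnogram file
#'
#' Reads a plain-text or CSV hypnogram (one stage label per 30-s epoch) and
#' maps the raw stage vocabulary onto the canonical 5-stage alphabet. Plain
#' text files carry one token per line; CSV files must have a `stage` column
#' (the layout written by [write_hypnogram()]).
#'
#' @param path File path.
#' @param dialect Named character vector mapping every raw token to a
#'   canonical stage or `"UNS"`; see [dialect_aasm()].
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = dialect_aasm(), epoch_len_s = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first) && grepl("stage", first, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"stage" %in% names(df)) stop("CSV hypnogram must have a `stage` column")
    tokens <- as.character(df$stage)
  } else {
    tokens <- trimws(readLines(path))
    tokens <- tokens[nzchar(tokens)]
  }
  mapped <- unname(dialect[tokens])
  if (anyNA(mapped)) {
    i <- which(is.na(mapped))[1L]
    stop(sprintf("unmapped stage token '%s' at line/row %d", tokens[i], i))
  }
  hypnogram(mapped, epoch_len_s = epoch_len_s)
}

#' Write a hypnogram (and optional stage probabilities) to CSV
#'
#' Writes one data row per epoch with columns `epoch_index` (0-based) and
#' `stage`; when per-epoch stage probabilities are supplied, five columns
#' `p_W, p_N1, p_N2, p_N3, p_R` plus `confidence` (the row maximum) are
#' appended. [read_hypnogram()] inverts the `stage` column.
#'
#' @param hyp A [hypnogram()].
#' @param path Output file path.
#' @param probs Optional [stage_probs()] with one row per epoch.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path, probs = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp$stages) - 1L,
                   stage = hyp$stages, stringsAsFactors = FALSE)
  if (!is.null(probs)) {
    stopifnot(inherits(probs, "stage_probs"))
    if (nrow(probs$probs) != length(hyp$stages)) {
      stop("probability rows (", nrow(probs$probs), ") do not match epochs (",
           length(hyp$stages), ")")
    }
    pm <- probs$probs
    colnames(pm) <- paste0("p_", stages())
    df <- cbind(df, as.data.frame(pm), confidence = probs$confidence)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
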