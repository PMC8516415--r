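#' Canonical sleep-stage alphabet
#'
#' The five AASM sleep stages in the canonical order used throughout the
#' package for probability matrices, confusion matrices and argmax
#' tie-breaking: Wake, N1, N2, N3 (light to deep non-REM) and REM.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "R")`.
#' @export
stages <- function() c("W", "N1", "N2", "N3", "R")

# sentinel used for epochs without a valid human score
UNSCORED <- "UNS"

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of sleep-stage labels across a night, one
#' label per scoring epoch (30 s by default). Epochs without a valid score
#' (movement time, unscorable signal) carry the sentinel `"UNS"` and are
#' flagged in `scored`; they are excluded from model training and from all
#' agreement metrics but preserved in outputs so epoch indexing is stable.
#'
#' @param stages_seq Character vector over `c(stages(), "UNS")`.
#' @param scored Optional logical vector, same length; defaults to
#'   `stages_seq != "UNS"`.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return An object of class `"hypnogram"`: a list with elements `stages`,
#'   `scored` and `epoch_len_s`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2", "N3"))
#' n_epochs(h)
#' @export
hypnogram <- function(stages_seq, scored = NULL, epoch_len_s = 30) {
  stages_seq <- as.character(stages_seq)
  bad <- !(stages_seq %in% c(stages(), UNSCORED))
  if (any(bad)) {
    stop("invalid stage label(s): ", paste(unique(stages_seq[bad]), collapse = ", "),
         " (expected ", paste(c(stages(), UNSCORED), collapse = ", "), ")")
  }
  if (is.null(scored)) scored <- stages_seq != UNSCORED
  if (length(scored) != length(stages_seq)) {
    stop("`scored` and `stages_seq` must have equal length")
  }
  if (any(!scored)) stages_seq[!scored] <- UNSCORED
  if (!is.numeric(epoch_len_s) || length(epoch_len_s) != 1L || epoch_len_s <= 0) {
    stop("`epoch_len_s` must be a positive scalar")
  }
  structure(
    list(stages = stages_seq, scored = as.logical(scored), epoch_len_s = epoch_len_s),
    class = "hypnogram"
  )
}

#' Number of epochs in a hypnogram
#' @param h A `hypnogram`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  length(h$stages)
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = c(stages(), UNSCORED)))
  cat(sprintf("<hypnogram> %d epochs x %gs (%.1f h)\n",
              length(x$stages), x$epoch_len_s,
              length(x$stages) * x$epoch_len_s / 3600))
  print(tab)
  invisible(x)
}

#' @export
`==.hypnogram` <- function(e1, e2) {
  e1$stages == e2$stages
}

# internal: stages as an integer code 1..5 (NA for unscored)
stage_codes <- function(h) {
  match(h$stages, stages())
}
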