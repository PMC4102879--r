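# AP right-boundary classification. A target noun counts as phrased in
# its own Accentual Phrase (TWO_AP) only when both acoustic cues are
# present: the f0 rise (pitch accent) and pre-boundary lengthening.

#' Pitch-accent criterion
#'
#' A pitch accent is considered present when the f0 maximum associated
#' with the noun's last syllable is at least 10% higher than the
#' preceding early L minimum. Ratios are taken on raw Hz; the threshold
#' is inclusive, so a ratio of exactly 1.10 counts as accented.
#'
#' @param f0_h f0 of the H maximum, Hz (> 0).
#' @param f0_l f0 of the early L minimum, Hz (> 0).
#' @param threshold Minimum proportional rise (default 0.10).
#' @return Logical vector: `TRUE` where `f0_h >= (1 + threshold) * f0_l`.
#' @export
pitch_accent_present <- function(f0_h, f0_l, threshold = 0.10) {
  check_positive(f0_h, "f0_h"); check_positive(f0_l, "f0_l")
  at_least_ratio(f0_h, f0_l, 1 + threshold)
}

# Inclusive ratio comparison with a 1e-12 relative tolerance, so that
# decimal-entered values sitting exactly at the threshold (e.g. 198 Hz
# vs 180 Hz at 10%) count as criterion-met despite binary rounding.
at_least_ratio <- function(num, den, ratio) {
  num >= ratio * den * (1 - 1e-12)
}

#' Pre-boundary lengthening criterion
#'
#' The noun's last full syllable (S2) counts as lengthened when its
#' duration is at least 10% longer than that of the first full
#' syllable (S1). The threshold is inclusive.
#'
#' @param dur_s2 Duration of S2, seconds (> 0).
#' @param dur_s1 Duration of S1, seconds (> 0).
#' @param threshold Minimum proportional lengthening (default 0.10).
#' @return Logical vector: `TRUE` where `dur_s2 >= (1 + threshold) * dur_s1`.
#' @export
lengthening_present <- function(dur_s2, dur_s1, threshold = 0.10) {
  check_positive(dur_s2, "dur_s2"); check_positive(dur_s1, "dur_s1")
  at_least_ratio(dur_s2, dur_s1, 1 + threshold)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop(name, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

#' Classify tokens as one- or two-AP phrasings
#'
#' Applies both boundary criteria to each token and labels it `TWO_AP`
#' (noun phrased separately from the adjective) if and only if both the
#' pitch-accent and the lengthening criterion are met; otherwise
#' `ONE_AP`.
#'
#' @param tokens A [pp_dataset()] or a token data.frame with at least
#'   `token_id`, `dur_s1`, `dur_s2`, `f0_l`, `f0_h`.
#' @param pitch_threshold,length_threshold Proportional thresholds for
#'   the two criteria (defaults 0.10, supporting sensitivity analyses).
#' @return A data.frame of class `pp_phrasing` with columns `token_id`,
#'   `pitch_criterion_met`, `lengthening_criterion_met`, `f0_ratio`,
#'   `dur_ratio`, `label`.
#' @export
classify_phrasing <- function(tokens, pitch_threshold = 0.10,
                              length_threshold = 0.10) {
  if (inherits(tokens, "pp_dataset")) tokens <- tokens$tokens
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  for (col in c("token_id", "dur_s1", "dur_s2", "f0_l", "f0_h")) {
    if (!col %in% names(tokens)) {
      stop("classify_phrasing: missing column ", col, call. = FALSE)
    }
  }
  for (col in c("dur_s1", "dur_s2", "f0_l", "f0_h")) {
    v <- tokens[[col]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop("non-positive or non-finite ", col, " for token(s): ",
           paste(tokens$token_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  pitch <- pitch_accent_present(tokens$f0_h, tokens$f0_l, pitch_threshold)
  leng <- lengthening_present(tokens$dur_s2, tokens$dur_s1, length_threshold)
  out <- data.frame(
    token_id = tokens$token_id,
    pitch_criterion_met = pitch,
    lengthening_criterion_met = leng,
    f0_ratio = tokens$f0_h / tokens$f0_l,
    dur_ratio = tokens$dur_s2 / tokens$dur_s1,
    label = ifelse(pitch & leng, "TWO_AP", "ONE_AP"),
    stringsAsFactors = FALSE)
  class(out) <- c("pp_phrasing", "data.frame")
  out
}

#' Drop disfluent and mislabelled tokens
#'
#' Retains only noun-adjective pairs containing neither
#' disfluencies/hesitations nor object appellation errors, and accounts
#' for every input token in the returned report.
#'
#' @param dataset A [pp_dataset()].
#' @return A list with `dataset` (the retained tokens, same class) and
#'   `report`, a one-row data.frame with `n_input`, `n_retained`,
#'   `n_removed_disfluent`, `n_removed_error`, `retained_pct`.
#'   A token that is both disfluent and mislabelled is counted once,
#'   under disfluency.
#' @export
filter_tokens <- function(dataset) {
  validate_dataset(dataset)
  tk <- dataset$tokens
  removed_disfluent <- tk$disfluent
  removed_error <- !tk$disfluent & tk$labeling_error
  keep <- !removed_disfluent & !removed_error
  n_input <- nrow(tk)
  report <- data.frame(
    n_input = n_input,
    n_retained = sum(keep),
    n_removed_disfluent = sum(removed_disfluent),
    n_removed_error = sum(removed_error),
    retained_pct = if (n_input > 0) 100 * sum(keep) / n_input else NA_real_)
  out <- dataset
  out$tokens <- tk[keep, , drop = FALSE]
  rownames(out$tokens) <- NULL
  out$provenance <- c(out$provenance,
                      sprintf("filter_tokens: retained %d/%d (%.2f%%)",
                              report$n_retained, n_input,
                              report$retained_pct))
  list(dataset = out, report = report)
}
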