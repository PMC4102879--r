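# The prosodic phrasing score compares the phrasing a participant
# produced with the phrasing the discourse context calls for: one AP
# (noun grouped with the adjective) when the noun is given, two APs
# (noun in its own AP) when it is contrastive. Agreement is pooled over
# both conditions and scaled to 0-20 for comparability with the
# hinting task.

#' Per-participant prosodic phrasing score
#'
#' Given one participant's analyzable tokens, counts how often the
#' produced phrasing matches the condition-expected phrasing (ONE_AP
#' under given, TWO_AP under contrastive) and scales the pooled match
#' proportion to 0--20. A participant with 3/9 matches in the given
#' condition and 6/9 in the contrastive condition scores
#' 20 x 9/18 = 10.
#'
#' @param condition Character vector, `"given"`/`"contrastive"`, one
#'   entry per token.
#' @param label Character vector, `"ONE_AP"`/`"TWO_AP"`, same length.
#' @return A one-row data.frame with `n_given`, `n_given_one_ap`,
#'   `n_contrastive`, `n_contrastive_two_ap`, `phrasing_score`.
#'   Scores are kept at full precision; the 0--20 scale is not rounded.
#' @export
phrasing_score <- function(condition, label) {
  if (length(condition) != length(label)) {
    stop("condition and label must have the same length", call. = FALSE)
  }
  if (length(condition) == 0L) {
    stop("phrasing score is undefined for zero analyzable tokens",
         call. = FALSE)
  }
  if (!all(condition %in% CONDITION_LEVELS)) {
    stop("condition must be 'given' or 'contrastive'", call. = FALSE)
  }
  if (!all(label %in% c("ONE_AP", "TWO_AP"))) {
    stop("label must be 'ONE_AP' or 'TWO_AP'", call. = FALSE)
  }
  given <- condition == "given"
  match <- (given & label == "ONE_AP") | (!given & label == "TWO_AP")
  data.frame(
    n_given = sum(given),
    n_given_one_ap = sum(given & label == "ONE_AP"),
    n_contrastive = sum(!given),
    n_contrastive_two_ap = sum(!given & label == "TWO_AP"),
    phrasing_score = 20 * sum(match) / length(condition))
}

#' Participant score table
#'
#' Joins phrasing classifications back to the dataset and computes one
#' phrasing score per participant with any analyzable tokens, alongside
#' the participant's hinting-task score. Participants whose tokens were
#' all filtered out are omitted (with a message), since their score is
#' undefined.
#'
#' @param dataset A [pp_dataset()] (typically the retained dataset from
#'   [filter_tokens()]).
#' @param results A `pp_phrasing` data.frame from [classify_phrasing()]
#'   covering the dataset's tokens.
#' @return A data.frame with one row per scored participant:
#'   `participant_id`, `group`, the four per-condition counts,
#'   `phrasing_score`, `hinting_score`.
#' @export
score_table <- function(dataset, results) {
  validate_dataset(dataset)
  tk <- dataset$tokens
  if (nrow(tk) == 0L || nrow(results) == 0L) {
    out <- data.frame(participant_id = character(), group = character(),
                      n_given = integer(), n_given_one_ap = integer(),
                      n_contrastive = integer(),
                      n_contrastive_two_ap = integer(),
                      phrasing_score = numeric(),
                      hinting_score = numeric())
    return(out)
  }
  idx <- match(tk$token_id, results$token_id)
  if (anyNA(idx)) {
    stop("no phrasing result for token(s): ",
         paste(tk$token_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tk$label <- results$label[idx]
  no_meta <- setdiff(unique(tk$participant_id),
                     dataset$participants$participant_id)
  if (length(no_meta) > 0L) {
    stop("participant(s) with tokens but no metadata: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  }
  skipped <- setdiff(dataset$participants$participant_id,
                     unique(tk$participant_id))
  if (length(skipped) > 0L) {
    message("score_table: no analyzable tokens for participant(s) ",
            paste(skipped, collapse = ", "), "; omitted")
  }
  rows <- lapply(split(tk, tk$participant_id), function(d) {
    cbind(data.frame(participant_id = d$participant_id[1L],
                     group = d$group[1L], stringsAsFactors = FALSE),
          phrasing_score(d$condition, d$label))
  })
  out <- do.call(rbind, rows)
  pm <- dataset$participants
  out$hinting_score <- pm$hinting_score[match(out$participant_id,
                                              pm$participant_id)]
  # keep first-appearance order of participants in the token table
  out <- out[match(unique(tk$participant_id), out$participant_id), ]
  rownames(out) <- NULL
  out
}
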