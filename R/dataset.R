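# Canonical column sets shared by the readers, writers and validators.
TOKEN_COLUMNS <- c("token_id", "participant_id", "group", "item_id",
                   "condition", "dur_s1", "dur_s2", "f0_l", "f0_h",
                   "disfluent", "labeling_error")
PARTICIPANT_COLUMNS <- c("participant_id", "group", "hinting_score",
                         "total_time", "speaking_turns")
GROUP_LEVELS <- c("HC", "SZ")
CONDITION_LEVELS <- c("given", "contrastive")

#' Construct a token-level prosodic annotation dataset
#'
#' Bundles per-token acoustic annotations with per-participant metadata.
#' Each token row describes one noun produced in the map task: the
#' durations of its first (`dur_s1`) and last (`dur_s2`) full syllables
#' in seconds, the f0 of the "early L" minimum (`f0_l`) and of the
#' S2-region maximum H (`f0_h`) in Hz, the discourse condition under
#' which it was elicited, and flags for disfluent or mislabelled
#' productions that exclude the token from analysis.
#'
#' @param tokens data.frame with columns `token_id`, `participant_id`,
#'   `group` (`"HC"`/`"SZ"`), `item_id`, `condition`
#'   (`"given"`/`"contrastive"`), `dur_s1`, `dur_s2`, `f0_l`, `f0_h`,
#'   `disfluent`, `labeling_error`.
#' @param participants data.frame with columns `participant_id`,
#'   `group`, `hinting_score` (integer 0--20), and optionally
#'   `total_time` (seconds) and `speaking_turns`.
#' @param provenance character vector recording source files and
#'   filters applied; free text.
#'
#' @return An object of class `pp_dataset`.
#' @export
pp_dataset <- function(tokens, participants, provenance = character()) {
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  for (col in setdiff(PARTICIPANT_COLUMNS, names(participants))) {
    if (col %in% c("total_time", "speaking_turns")) participants[[col]] <- NA_real_
  }
  out <- structure(
    list(tokens = tokens, participants = participants,
         provenance = as.character(provenance)),
    class = "pp_dataset")
  validate_dataset(out)
  out
}

#' Validate a `pp_dataset`
#'
#' Checks the invariants of the data model: positive finite durations
#' and f0 values, legal group/condition levels, unique
#' (participant, item) pairs, hinting scores within 0--20, and that
#' every token's participant resolves to exactly one metadata row.
#'
#' @param x A `pp_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown
#'   naming the offending column or token.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "pp_dataset"))
  validate_tokens(x$tokens)
  validate_participants(x$participants)
  orphan <- setdiff(unique(x$tokens$participant_id),
                    x$participants$participant_id)
  if (length(orphan) > 0L) {
    stop("tokens reference participants with no metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$participants$participant_id)) {
    stop("duplicated participant_id in participant metadata", call. = FALSE)
  }
  invisible(x)
}

validate_tokens <- function(tokens) {
  missing_cols <- setdiff(TOKEN_COLUMNS, names(tokens))
  if (length(missing_cols) > 0L) {
    stop("missing required token column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tokens) == 0L) return(invisible(tokens))
  bad_group <- !tokens$group %in% GROUP_LEVELS
  if (any(bad_group)) {
    stop("invalid group value(s) for token(s): ",
         paste(tokens$token_id[bad_group], collapse = ", "), call. = FALSE)
  }
  bad_cond <- !tokens$condition %in% CONDITION_LEVELS
  if (any(bad_cond)) {
    stop("invalid condition value(s) for token(s): ",
         paste(tokens$token_id[bad_cond], collapse = ", "), call. = FALSE)
  }
  for (col in c("dur_s1", "dur_s2", "f0_l", "f0_h")) {
    v <- tokens[[col]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop("non-positive or non-finite ", col, " for token(s): ",
           paste(tokens$token_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("disfluent", "labeling_error")) {
    if (!is.logical(tokens[[col]]) || anyNA(tokens[[col]])) {
      stop(col, " must be TRUE/FALSE with no missing values", call. = FALSE)
    }
  }
  key <- paste(tokens$participant_id, tokens$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicated (participant_id, item_id) pair: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }
  invisible(tokens)
}

validate_participants <- function(participants) {
  missing_cols <- setdiff(c("participant_id", "group", "hinting_score"),
                          names(participants))
  if (length(missing_cols) > 0L) {
    stop("missing required participant column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(participants) == 0L) return(invisible(participants))
  if (!all(participants$group %in% GROUP_LEVELS)) {
    stop("participant group must be one of: ",
         paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
  }
  hs <- participants$hinting_score
  bad <- !is.na(hs) & (hs < 0 | hs > 20 | hs != round(hs))
  if (any(bad)) {
    stop("hinting_score must be an integer in [0, 20]; offending participant(s): ",
         paste(participants$participant_id[bad], collapse = ", "),
         call. = FALSE)
  }
  for (col in c("total_time", "speaking_turns")) {
    if (col %in% names(participants)) {
      v <- participants[[col]]
      if (any(!is.na(v) & v < 0)) {
        stop(col, " must be non-negative", call. = FALSE)
      }
    }
  }
  invisible(participants)
}

#' @export
print.pp_dataset <- function(x, ...) {
  cat("<pp_dataset>\n")
  cat("  tokens      :", nrow(x$tokens), "rows,",
      length(unique(x$tokens$participant_id)), "participants,",
      length(unique(x$tokens$item_id)), "items\n")
  tab <- table(factor(x$tokens$group, GROUP_LEVELS),
               factor(x$tokens$condition, CONDITION_LEVELS))
  for (g in rownames(tab)) {
    cat("    ", g, ": ", paste(sprintf("%s=%d", colnames(tab), tab[g, ]),
                               collapse = ", "), "\n", sep = "")
  }
  cat("  participants:", nrow(x$participants), "rows\n")
  if (length(x$provenance)) {
    cat("  provenance  :", paste(x$provenance, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @method all.equal pp_dataset
#' @export
all.equal.pp_dataset <- function(target, current, ...) {
  all.equal(unclass(target)[c("tokens", "participants")],
            unclass(current)[c("tokens", "participants")], ...)
}
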