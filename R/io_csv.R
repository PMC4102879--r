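#' Read token annotations and participant metadata from CSV
#'
#' Reads the canonical flat interchange format: one row per noun token
#' with identifiers, acoustic measurements and validity flags, plus a
#' companion participant-metadata table (either a separate CSV or
#' hinting-score columns carried on the token file).
#'
#' @param path Path to the token CSV. Required columns are
#'   `token_id, participant_id, group, item_id, condition, dur_s1,
#'   dur_s2, f0_l, f0_h, disfluent, labeling_error`; booleans are
#'   `true`/`false`, durations in seconds, f0 in Hz. Unknown columns
#'   are retained and noted in the dataset provenance.
#' @param participants_path Optional path to a participant CSV with
#'   columns `participant_id, group, hinting_score` and optionally
#'   `total_time`, `speaking_turns`. If omitted, a `hinting_score`
#'   column on the token file is used; participants then inherit group
#'   from their tokens.
#'
#' @return A [pp_dataset()] whose tokens preserve file order.
#' @export
read_tokens_csv <- function(path, participants_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TOKEN_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("token CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tokens <- raw[TOKEN_COLUMNS]
  for (col in c("token_id", "participant_id", "group", "item_id", "condition")) {
    tokens[[col]] <- as.character(tokens[[col]])
  }
  for (col in c("dur_s1", "dur_s2", "f0_l", "f0_h")) {
    tokens[[col]] <- as.numeric(tokens[[col]])
  }
  for (col in c("disfluent", "labeling_error")) {
    tokens[[col]] <- parse_bool(tokens[[col]], col)
  }
  extra <- setdiff(names(raw), c(TOKEN_COLUMNS, "hinting_score"))
  provenance <- c(
    paste0("read_tokens_csv: ", path, " (", nrow(tokens), " tokens)"),
    if (length(extra)) paste0("unknown columns preserved in source: ",
                              paste(extra, collapse = ", ")))

  if (!is.null(participants_path)) {
    participants <- read_participants_csv(participants_path)
    provenance <- c(provenance,
                    paste0("participants: ", participants_path))
  } else if ("hinting_score" %in% names(raw)) {
    first <- !duplicated(tokens$participant_id)
    participants <- data.frame(
      participant_id = tokens$participant_id[first],
      group = tokens$group[first],
      hinting_score = as.numeric(raw$hinting_score[first]),
      total_time = NA_real_, speaking_turns = NA_real_,
      stringsAsFactors = FALSE)
    provenance <- c(provenance, "participants: derived from token file")
  } else {
    stop("no participant metadata: supply participants_path or a ",
         "hinting_score column", call. = FALSE)
  }
  pp_dataset(tokens, participants, provenance)
}

#' Read a participant metadata CSV
#'
#' @param path Path to a CSV with columns `participant_id, group,
#'   hinting_score` and optionally `total_time` (seconds) and
#'   `speaking_turns`. Optional fields absent from the file are
#'   recorded as missing (`NA`), never as zero.
#' @return A data.frame of participant metadata.
#' @export
read_participants_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", "group", "hinting_score"),
                          names(raw))
  if (length(missing_cols) > 0L) {
    stop("participant CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    participant_id = as.character(raw$participant_id),
    group = as.character(raw$group),
    hinting_score = as.numeric(raw$hinting_score),
    total_time = if ("total_time" %in% names(raw))
      as.numeric(raw$total_time) else NA_real_,
    speaking_turns = if ("speaking_turns" %in% names(raw))
      as.numeric(raw$speaking_turns) else NA_real_,
    stringsAsFactors = FALSE)
  validate_participants(out)
  out
}

#' Write a dataset back to the canonical CSV pair
#'
#' Emits the canonical schema so that re-reading yields an equal
#' dataset field for field.
#'
#' @param dataset A [pp_dataset()].
#' @param path Output path for the token CSV.
#' @param participants_path Output path for the participant CSV;
#'   default replaces the token file's extension with
#'   `_participants.csv`.
#' @return `path`, invisibly.
#' @export
write_tokens_csv <- function(dataset, path,
                             participants_path = default_participants_path(path)) {
  validate_dataset(dataset)
  tokens <- dataset$tokens[, TOKEN_COLUMNS, drop = FALSE]
  tokens$disfluent <- ifelse(tokens$disfluent, "true", "false")
  tokens$labeling_error <- ifelse(tokens$labeling_error, "true", "false")
  write.csv(tokens, path, row.names = FALSE, quote = FALSE)
  write.csv(dataset$participants[, PARTICIPANT_COLUMNS, drop = FALSE],
            participants_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_participants_path <- function(path) {
  sub("\\.csv$", "_participants.csv", path)
}

parse_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && length(out) > 0L) {
    stop("column ", col, " contains values that are not true/false",
         call. = FALSE)
  }
  out
}
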