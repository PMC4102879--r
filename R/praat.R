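# Parsers for Praat's text serialisations (TextGrid, PitchTier), in both
# the verbose "long" and the value-per-line "short" ooTextFile variants.
# Files may be UTF-8 or UTF-16 (with BOM), per Praat convention.

read_praat_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  enc <- "UTF-8"
  if (length(bytes) >= 2) {
    if (bytes[1] == as.raw(0xFE) && bytes[2] == as.raw(0xFF)) enc <- "UTF-16BE"
    if (bytes[1] == as.raw(0xFF) && bytes[2] == as.raw(0xFE)) enc <- "UTF-16LE"
  }
  txt <- if (enc == "UTF-8") {
    rawToChar(bytes)
  } else {
    iconv(list(bytes), from = enc, to = "UTF-8")
  }
  txt <- sub(intToUtf8(0xFEFF), "", txt, fixed = TRUE)
  strsplit(txt, "\r\n|\r|\n")[[1]]
}

# Praat long/short formats share one token stream once structural
# decoration is stripped: every line carries either `key = value`, a
# bare value, a flag like `<exists>`, or a pure header (`item [1]:`,
# `points: size = 3`). We reduce each line to its payload tokens and
# parse the stream positionally.
praat_token_stream <- function(lines) {
  toks <- character(0)
  for (ln in lines) {
    s <- trimws(ln)
    if (s == "" || grepl("^File type", s) || grepl("^Object class", s)) next
    # pure structural headers carry no value
    if (grepl("^(item|intervals|points)\\s*\\[[0-9]*\\]\\s*:?\\s*$", s)) next
    if (grepl("^item\\s*\\[\\]\\s*:?\\s*$", s)) next
    # `intervals: size = 5` / `points: size = 3` -> keep the size value
    if (grepl("^(intervals|points)\\s*:\\s*size\\s*=", s)) {
      toks <- c(toks, sub(".*=\\s*", "", s))
      next
    }
    if (grepl("=", s)) s <- sub("^[^=]*=\\s*", "", s)
    if (grepl("<exists>", s)) { toks <- c(toks, "<exists>"); next }
    toks <- c(toks, trimws(s))
  }
  toks
}

praat_unquote <- function(x) {
  x <- trimws(x)
  if (grepl('^".*"$', x)) x <- substr(x, 2L, nchar(x) - 1L)
  gsub('""', '"', x)
}

praat_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("expected a number in Praat file, got: ", x, call. = FALSE)
  v
}

#' Read a Praat TextGrid (text format)
#'
#' Parses both the long (verbose `ooTextFile`) and short text variants,
#' in UTF-8 or UTF-16 encoding.
#'
#' @param path Path to a `.TextGrid` file.
#' @return A list with `xmin`, `xmax` and `tiers`; each tier is a list
#'   with `name`, `type` (`"interval"` or `"point"`) and a data.frame
#'   (`xmin`, `xmax`, `text` for interval tiers; `time`, `mark` for
#'   point tiers).
#' @export
read_textgrid <- function(path) {
  lines <- read_praat_lines(path)
  if (!any(grepl("TextGrid", lines[seq_len(min(5, length(lines)))]))) {
    stop("not a TextGrid file: ", path, call. = FALSE)
  }
  toks <- praat_token_stream(lines)
  i <- 1L
  take <- function() { v <- toks[i]; i <<- i + 1L; v }
  xmin <- praat_num(take()); xmax <- praat_num(take())
  flag <- take()
  if (!identical(flag, "<exists>")) {
    stop("TextGrid without tiers is not supported", call. = FALSE)
  }
  n_tiers <- praat_num(take())
  tiers <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    cls <- praat_unquote(take())
    name <- praat_unquote(take())
    take(); take()                      # tier xmin / xmax, unused
    n <- praat_num(take())
    if (cls == "IntervalTier") {
      xmins <- xmaxs <- numeric(n); texts <- character(n)
      for (k in seq_len(n)) {
        xmins[k] <- praat_num(take()); xmaxs[k] <- praat_num(take())
        texts[k] <- praat_unquote(take())
      }
      tiers[[t]] <- list(name = name, type = "interval",
                         entries = data.frame(xmin = xmins, xmax = xmaxs,
                                              text = texts,
                                              stringsAsFactors = FALSE))
    } else if (cls == "TextTier") {
      times <- numeric(n); marks <- character(n)
      for (k in seq_len(n)) {
        times[k] <- praat_num(take())
        marks[k] <- praat_unquote(take())
      }
      tiers[[t]] <- list(name = name, type = "point",
                         entries = data.frame(time = times, mark = marks,
                                              stringsAsFactors = FALSE))
    } else {
      stop("unsupported tier class: ", cls, call. = FALSE)
    }
  }
  list(xmin = xmin, xmax = xmax, tiers = tiers)
}

#' Read a Praat PitchTier (text format)
#'
#' Parses long and short `ooTextFile` variants.
#'
#' @param path Path to a `.PitchTier` file.
#' @return A data.frame with columns `time` (s) and `f0` (Hz), plus
#'   attributes `xmin`/`xmax`.
#' @export
read_pitchtier <- function(path) {
  lines <- read_praat_lines(path)
  if (!any(grepl("PitchTier", lines[seq_len(min(5, length(lines)))]))) {
    stop("not a PitchTier file: ", path, call. = FALSE)
  }
  toks <- praat_token_stream(lines)
  i <- 1L
  take <- function() { v <- toks[i]; i <<- i + 1L; v }
  xmin <- praat_num(take()); xmax <- praat_num(take())
  n <- praat_num(take())
  times <- f0 <- numeric(n)
  for (k in seq_len(n)) {
    times[k] <- praat_num(take()); f0[k] <- praat_num(take())
  }
  out <- data.frame(time = times, f0 = f0)
  attr(out, "xmin") <- xmin; attr(out, "xmax") <- xmax
  out
}

# f0 at arbitrary times, linearly interpolated between bracketing
# samples (Praat's PitchTier semantics). Times outside the sampled
# range are an error, not an extrapolation.
pitchtier_at <- function(pt, times) {
  rng <- range(pt$time)
  outside <- times < rng[1] | times > rng[2]
  if (any(outside)) {
    stop("point time(s) outside the PitchTier's sampled range [",
         rng[1], ", ", rng[2], "]: ",
         paste(format(times[outside]), collapse = ", "), call. = FALSE)
  }
  stats::approx(pt$time, pt$f0, xout = times, method = "linear",
                ties = "ordered")$y
}

#' Import token annotations from Praat TextGrid + PitchTier files
#'
#' Builds the acoustic fields of token annotations from a segmentation
#' TextGrid and an f0 PitchTier. The TextGrid must contain an interval
#' tier in which the target noun's first and last full syllables are
#' labelled `S1` and `S2` in adjacent pairs, and a point tier with one
#' `L` (early f0 minimum) and one `H` (S2-region f0 maximum) point per
#' token. f0 at the L/H times is linearly interpolated from the
#' PitchTier samples.
#'
#' H points are accepted up to `h_slack` seconds beyond the end of S2
#' ("or just beyond it"); any such point is flagged in the result's
#' `h_beyond_s2` column rather than silently accepted.
#'
#' @param textgrid_path Path to the TextGrid.
#' @param pitchtier_path Path to the PitchTier.
#' @param tier_config Named list mapping roles to tier names; defaults
#'   `list(syllables = "syllables", tones = "tones")`.
#' @param h_slack Seconds beyond the S2 offset within which an H point
#'   is still associated with the token (default 0.05).
#' @return A data.frame of annotation fragments with columns
#'   `token_index`, `dur_s1`, `dur_s2`, `f0_l`, `f0_h`, `t_s1_on`,
#'   `t_s2_off`, `h_beyond_s2`.
#' @export
import_textgrid_tokens <- function(textgrid_path, pitchtier_path,
                                   tier_config = list(syllables = "syllables",
                                                      tones = "tones"),
                                   h_slack = 0.05) {
  tg <- read_textgrid(textgrid_path)
  pt <- read_pitchtier(pitchtier_path)
  names_ <- vapply(tg$tiers, `[[`, "", "name")
  syl <- tg$tiers[[match_tier(names_, tier_config$syllables, "interval", tg)]]
  ton <- tg$tiers[[match_tier(names_, tier_config$tones, "point", tg)]]

  iv <- syl$entries[syl$entries$text %in% c("S1", "S2"), , drop = FALSE]
  if (nrow(iv) == 0L) stop("no S1/S2 intervals found in tier '",
                           syl$name, "'", call. = FALSE)
  labs <- iv$text
  # must read S1, S2, S1, S2, ...
  if (length(labs) %% 2L != 0L ||
      !all(labs[seq(1, length(labs), by = 2)] == "S1") ||
      !all(labs[seq(2, length(labs), by = 2)] == "S2")) {
    bad <- which(labs != rep(c("S1", "S2"), length.out = length(labs)))[1L]
    stop("malformed S1/S2 sequence in tier '", syl$name,
         "': expected alternating S1,S2 pairs but found '", labs[bad],
         "' at labelled interval ", bad, call. = FALSE)
  }
  s1 <- iv[seq(1, nrow(iv), by = 2), ]
  s2 <- iv[seq(2, nrow(iv), by = 2), ]
  n_tok <- nrow(s1)

  pts <- ton$entries
  assoc <- function(mark, lo, hi) {
    cand <- pts[pts$mark == mark, , drop = FALSE]
    sel <- cand$time >= lo & cand$time <= hi
    if (sum(sel) != 1L) {
      stop("expected exactly one '", mark, "' point in [",
           format(lo), ", ", format(hi), "] but found ", sum(sel),
           call. = FALSE)
    }
    cand$time[sel]
  }
  t_l <- t_h <- numeric(n_tok); beyond <- logical(n_tok)
  for (k in seq_len(n_tok)) {
    t_l[k] <- assoc("L", s1$xmin[k], s2$xmax[k])
    t_h[k] <- assoc("H", s1$xmin[k], s2$xmax[k] + h_slack)
    beyond[k] <- t_h[k] > s2$xmax[k]
  }
  # any L/H point not claimed by a token is an association error
  claimed <- c(t_l, t_h)
  lh <- pts[pts$mark %in% c("L", "H"), , drop = FALSE]
  orphan <- setdiff(lh$time, claimed)
  if (length(orphan) > 0L) {
    stop("L/H point(s) outside any token's span at time(s): ",
         paste(format(orphan), collapse = ", "), call. = FALSE)
  }
  data.frame(
    token_index = seq_len(n_tok),
    dur_s1 = s1$xmax - s1$xmin,
    dur_s2 = s2$xmax - s2$xmin,
    f0_l = pitchtier_at(pt, t_l),
    f0_h = pitchtier_at(pt, t_h),
    t_s1_on = s1$xmin,
    t_s2_off = s2$xmax,
    h_beyond_s2 = beyond)
}

match_tier <- function(names_, wanted, type, tg) {
  idx <- which(names_ == wanted)
  if (length(idx) != 1L) {
    stop("TextGrid must contain exactly one tier named '", wanted,
         "' (found ", length(idx), "); tiers present: ",
         paste(names_, collapse = ", "), call. = FALSE)
  }
  if (tg$tiers[[idx]]$type != type) {
    stop("tier '", wanted, "' must be a ", type, " tier", call. = FALSE)
  }
  idx
}
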