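# Shared builders for tokens, datasets and Praat files written at test
# time. Acoustic archetypes: `ac_one` fails both criteria, `ac_two`
# passes both.
ac_one <- list(dur_s1 = 0.20, dur_s2 = 0.20, f0_l = 180, f0_h = 185)
ac_two <- list(dur_s1 = 0.20, dur_s2 = 0.26, f0_l = 180, f0_h = 220)

make_tokens <- function(n, participant = "P01", group = "HC",
                        condition = "given", acoustics = ac_two,
                        disfluent = FALSE, labeling_error = FALSE,
                        item_offset = 0L) {
  data.frame(
    token_id = sprintf("%s_T%03d", rep_len(participant, n),
                       seq_len(n) + item_offset),
    participant_id = rep_len(participant, n),
    group = rep_len(group, n),
    item_id = sprintf("I%03d", seq_len(n) + item_offset),
    condition = rep_len(condition, n),
    dur_s1 = rep_len(acoustics$dur_s1, n),
    dur_s2 = rep_len(acoustics$dur_s2, n),
    f0_l = rep_len(acoustics$f0_l, n),
    f0_h = rep_len(acoustics$f0_h, n),
    disfluent = rep_len(disfluent, n),
    labeling_error = rep_len(labeling_error, n),
    stringsAsFactors = FALSE)
}

make_participants <- function(ids, groups = "HC", hinting = 15) {
  n <- length(ids)
  data.frame(participant_id = ids, group = rep_len(groups, n),
             hinting_score = rep_len(hinting, n),
             total_time = rep(NA_real_, n),
             speaking_turns = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

extdata <- function(name) {
  system.file("extdata", name, package = "prosocontrast", mustWork = TRUE)
}

# Short-format twins of the bundled long-format fixtures.
fixture_textgrid_short <- function(path) {
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "0", "2", "<exists>", "2",
    '"IntervalTier"', '"syllables"', "0", "2", "6",
    "0", "0.10", '""',
    "0.10", "0.30", '"S1"',
    "0.30", "0.56", '"S2"',
    "0.56", "1.00", '""',
    "1.00", "1.22", '"S1"',
    "1.22", "1.44", '"S2"',
    '"TextTier"', '"tones"', "0", "2", "4",
    "0.32", '"L"', "0.50", '"H"', "1.24", '"L"', "1.40", '"H"'), path)
  path
}

fixture_pitchtier_short <- function(path) {
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "PitchTier"', "",
    "0", "2", "6",
    "0.20", "170", "0.40", "190", "0.50", "210",
    "1.10", "160", "1.24", "150", "1.40", "180"), path)
  path
}

# Long-format TextGrid with the tones tier first (tier-order variant).
fixture_textgrid_reordered <- function(path) {
  lines <- readLines(extdata("fixture.TextGrid"))
  i1 <- grep("item \\[1\\]:", lines)
  i2 <- grep("item \\[2\\]:", lines)
  head_ <- lines[seq_len(i1 - 1L)]
  tier1 <- lines[i1:(i2 - 1L)]
  tier2 <- lines[i2:length(lines)]
  writeLines(c(head_, sub("\\[2\\]", "[1]", tier2),
               sub("\\[1\\]", "[2]", tier1)), path)
  path
}

write_utf16 <- function(path, src_path) {
  txt <- paste(readLines(src_path), collapse = "\n")
  raw <- iconv(txt, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
  writeBin(c(as.raw(0xFF), as.raw(0xFE), raw), path)
  path
}

# Textbook Spearman oracle: explicit average-rank construction plus
# the sum-based Pearson formula, independent of rank() and cor().
spearman_oracle_rho <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}
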