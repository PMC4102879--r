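test_that("token CSV reading preserves order and resolves participants", {
  tok <- rbind(make_tokens(2, "P01", "HC"),
               make_tokens(2, "P02", "SZ", condition = "contrastive"))
  ds <- pp_dataset(tok, make_participants(c("P01", "P02"), c("HC", "SZ")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tokens_csv(ds, path)
  back <- read_tokens_csv(path, sub("\\.csv$", "_participants.csv", path))
  expect_equal(nrow(back$tokens), 4L)
  expect_equal(nrow(back$participants), 2L)
  expect_identical(back$tokens$token_id, tok$token_id)
})

test_that("a missing required column is a schema error naming it", {
  tok <- make_tokens(3)
  tok$dur_s2 <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tok, path, row.names = FALSE)
  expect_error(read_tokens_csv(path), "dur_s2")
})

test_that("validation rejects exactly the offending rows, naming tokens", {
  tok <- make_tokens(3)
  tok$f0_l[2] <- -5
  expect_error(pp_dataset(tok, make_participants("P01")), "P01_T002")
  tok <- make_tokens(3)
  tok$dur_s1[3] <- 0
  expect_error(pp_dataset(tok, make_participants("P01")), "P01_T003")
  # a duplicated (participant, item) pair is refused
  tok <- make_tokens(2)
  tok$item_id[2] <- tok$item_id[1]
  expect_error(pp_dataset(tok, make_participants("P01")), "duplicated")
  # tokens without metadata are refused
  expect_error(pp_dataset(make_tokens(2), make_participants("P99")),
               "no metadata")
})

test_that("CSV round-trip is lossless on randomized datasets", {
  for (seed in c(11L, 12L, 13L)) {
    ds <- generate_dataset(generator_config(
      n_participants_per_group = 3L, n_items = 6L, seed = seed,
      criterion_noise = 0.2, dropout_prob = 0.3))
    path <- withr::local_tempfile(fileext = ".csv")
    write_tokens_csv(ds, path)
    back <- read_tokens_csv(path, sub("\\.csv$", "_participants.csv", path))
    expect_true(isTRUE(all.equal(ds, back, tolerance = 1e-12)))
  }
})

test_that("writing an empty dataset yields a header-only file", {
  ds <- pp_dataset(make_tokens(0), make_participants(character(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tokens_csv(ds, path)
  expect_length(readLines(path), 1L)
  one <- pp_dataset(make_tokens(1), make_participants("P01"))
  write_tokens_csv(one, path)
  expect_length(readLines(path), 2L)
})

test_that("TextGrid + PitchTier import recovers hand-checked values", {
  frag <- import_textgrid_tokens(extdata("fixture.TextGrid"),
                                 extdata("fixture.PitchTier"))
  expect_equal(nrow(frag), 2L)
  # durations read off the fixture's interval bounds
  expect_equal(frag$dur_s1, c(0.20, 0.22), tolerance = 1e-9)
  expect_equal(frag$dur_s2, c(0.26, 0.22), tolerance = 1e-9)
  # L at 0.32 interpolates between (0.2, 170) and (0.4, 190)
  expect_equal(frag$f0_l[1], 182, tolerance = 1e-9)
  # points at sample times take the sample value exactly
  expect_equal(frag$f0_h, c(210, 180), tolerance = 1e-12)
  expect_equal(frag$f0_l[2], 150, tolerance = 1e-12)
  expect_false(any(frag$h_beyond_s2))
})

test_that("short-format Praat files parse identically to long format", {
  tg <- fixture_textgrid_short(withr::local_tempfile(fileext = ".TextGrid"))
  pt <- fixture_pitchtier_short(withr::local_tempfile(fileext = ".PitchTier"))
  frag_short <- import_textgrid_tokens(tg, pt)
  frag_long <- import_textgrid_tokens(extdata("fixture.TextGrid"),
                                      extdata("fixture.PitchTier"))
  expect_equal(frag_short, frag_long, tolerance = 1e-12)
})

test_that("import is invariant to tier ordering in the file", {
  tg <- fixture_textgrid_reordered(withr::local_tempfile(fileext = ".TextGrid"))
  frag <- import_textgrid_tokens(tg, extdata("fixture.PitchTier"))
  ref <- import_textgrid_tokens(extdata("fixture.TextGrid"),
                                extdata("fixture.PitchTier"))
  expect_equal(frag, ref, tolerance = 1e-12)
})

test_that("UTF-16 encoded Praat files parse like UTF-8 ones", {
  tg16 <- write_utf16(withr::local_tempfile(fileext = ".TextGrid"),
                      extdata("fixture.TextGrid"))
  pt16 <- write_utf16(withr::local_tempfile(fileext = ".PitchTier"),
                      extdata("fixture.PitchTier"))
  frag <- import_textgrid_tokens(tg16, pt16)
  ref <- import_textgrid_tokens(extdata("fixture.TextGrid"),
                                extdata("fixture.PitchTier"))
  expect_equal(frag, ref, tolerance = 1e-12)
})

test_that("an S1 interval followed by another S1 is a structure error", {
  lines <- readLines(extdata("fixture.TextGrid"))
  lines <- sub('text = "S2"', 'text = "S1"', lines)
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(lines, path)
  expect_error(import_textgrid_tokens(path, extdata("fixture.PitchTier")),
               "S1")
})

test_that("L/H points outside token spans or the sampled f0 range error", {
  # move the first L before its token's S1 onset
  lines <- readLines(extdata("fixture.TextGrid"))
  lines <- sub("number = 0.32", "number = 0.05", lines)
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(lines, path)
  expect_error(import_textgrid_tokens(path, extdata("fixture.PitchTier")),
               "point")
  # truncate the PitchTier so the last H time is outside its range
  ptl <- readLines(extdata("fixture.PitchTier"))
  keep <- seq_len(grep("number = 1.24", ptl) + 1L)
  ptl2 <- c(sub("points: size = 6", "points: size = 5", ptl[keep]))
  ppath <- withr::local_tempfile(fileext = ".PitchTier")
  writeLines(ptl2, ppath)
  expect_error(import_textgrid_tokens(extdata("fixture.TextGrid"), ppath),
               "sampled range")
})

test_that("H points just beyond S2 are accepted but flagged", {
  lines <- readLines(extdata("fixture.TextGrid"))
  lines <- sub("number = 1.40", "number = 1.46", lines)  # 0.02 past S2 end
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(lines, path)
  ptl <- sub("number = 1.40", "number = 1.46", readLines(extdata("fixture.PitchTier")))
  ppath <- withr::local_tempfile(fileext = ".PitchTier")
  writeLines(ptl, ppath)
  frag <- import_textgrid_tokens(path, ppath)
  expect_identical(frag$h_beyond_s2, c(FALSE, TRUE))
  # and rejected once past the slack
  expect_error(import_textgrid_tokens(path, ppath, h_slack = 0.01), "H")
})
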