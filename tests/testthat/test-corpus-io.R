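test_that("transcript JSON round-trips and resolves coarse classes", {
  tr <- fixture_a_transcript()
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript(tr, path)
  tr2 <- read_transcript(path)
  expect_identical(tr2$participant_id, "fixA")
  r1 <- tr$responses[[1]]; r2 <- tr2$responses[[1]]
  expect_equal(r2$tokens$surface, r1$tokens$surface)
  expect_equal(r2$tokens$char_count, r1$tokens$char_count)
  expect_equal(r2$tokens$coarse_class, r1$tokens$coarse_class)
  expect_equal(r2$trailing_pause_s, r1$trailing_pause_s)
  # table-lookup resolution
  expect_identical(resolve_coarse_class("Nh", "他", FALSE, quiet = TRUE), "PRON")
  expect_identical(resolve_coarse_class("P", "被", FALSE, quiet = TRUE),
                   "PASSIVE_MARKER_BEI")
  expect_identical(resolve_coarse_class("P", "把", FALSE, quiet = TRUE),
                   "PASSIVE_MARKER_BA")
  # unknown raw tags resolve to OTHER (with a note)
  expect_message(cls <- resolve_coarse_class("Zz9", "x", FALSE),
                 "unknown raw tags")
  expect_identical(cls, "OTHER")
  # a filled pause is always OTHER, marker or not
  expect_identical(resolve_coarse_class("P", "被", TRUE, quiet = TRUE), "OTHER")
})

test_that("transcript validation names the offending field", {
  path <- withr::local_tempfile(fileext = ".json")
  bad <- list(participant_id = "x", responses = list(list(
    image_id = 1, utterances = list(list(
      tokens = list(list(surface = "茶", char_count = 1, raw_tag = "Na",
                         flags = list())),
      trailing_pause_s = -1),
      list(tokens = list(list(surface = "好", char_count = 1, raw_tag = "VH",
                              flags = list())))))))
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_transcript(path), "trailing_pause_s")
  bad$responses[[1]]$utterances[[1]]$trailing_pause_s <- 0.5
  bad$responses[[1]]$utterances[[1]]$tokens[[1]]$char_count <- 2
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_transcript(path), "char_count")
  writeLines("{not json", path)
  expect_error(read_transcript(path), "malformed")
})

test_that("lexicon reader enforces its two-column contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("茶\t500", "泡\t200"), path)
  lex <- read_lexicon(path)
  expect_length(lex$freq, 2)
  expect_equal(unname(lex$freq["茶"]), 500)
  # duplicates: last entry wins, with a warning
  writeLines(c("茶\t500", "茶\t600"), path)
  expect_warning(lex2 <- read_lexicon(path), "duplicate")
  expect_equal(unname(lex2$freq["茶"]), 600)
  # non-numeric frequency names the row
  writeLines(c("茶\tabc"), path)
  expect_error(read_lexicon(path), "row 1")
  # round trip
  write_lexicon(lex, path)
  expect_equal(read_lexicon(path)$freq, lex$freq)
})

test_that("cohort reader preserves group counts and validates rows", {
  df <- data.frame(
    participant_id = sprintf("s%02d", 1:80),
    group = rep(c("NC", "early_AD"), c(32, 48)),
    age = round(rnorm(80, 74, 6), 1), education = round(rnorm(80, 12, 4), 1),
    gender = sample(c("F", "M"), 80, TRUE),
    suvr = c(NA, round(runif(79, 1, 1.8), 3)),
    hippocampus_cm3 = round(runif(80, 3.5, 6), 2),
    MMSE = round(runif(80, 18, 30)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as_cohort_table(df), path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 80)
  expect_equal(as.vector(table(back$group)[c("NC", "early_AD")]), c(32, 48))
  expect_true(is.na(back$suvr[1]))        # empty optional cell stays unset
  expect_true(all(is.na(back$CTT1)))      # absent optional column added as NA
  # missing age is a validation error
  df2 <- df; df2$age[3] <- NA
  expect_error(as_cohort_table(df2), "age")
  df3 <- df; df3$participant_id[2] <- df3$participant_id[1]
  expect_error(as_cohort_table(df3), "duplicate")
  df4 <- df; df4$group[1] <- "control"
  expect_error(as_cohort_table(df4), "group")
})

test_that("feature tables round-trip bit-exactly and check completeness", {
  set.seed(42)
  feats <- as.data.frame(matrix(runif(30) / 3, nrow = 2,
                                dimnames = list(NULL, feature_names())))
  feats$MLU <- c(11 / 3, 8.11)  # awkward decimals on purpose
  feats <- cbind(participant_id = c("a", "b"), feats)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, path)
  expect_length(readLines(path), 3L)  # header + 2 rows
  back <- read_feature_table(path)
  for (f in feature_names()) expect_identical(back[[f]], feats[[f]])
  expect_error(write_feature_table(feats[, setdiff(names(feats), "LPR")], path),
               "LPR")
})

test_that("tag mappings serialize and enforce their invariants", {
  m <- default_tag_mapping()
  path <- withr::local_tempfile(fileext = ".json")
  write_tag_mapping(m, path)
  m2 <- read_tag_mapping(path)
  expect_equal(m2$tag_map, m$tag_map)
  expect_equal(m2$bei_forms, m$bei_forms)
  expect_error(tag_mapping(c(Na = "NOUN"), bei_forms = "被", ba_forms = "被"),
               "disjoint")
  expect_error(tag_mapping(c(Na = "NOUNS")), "coarse class")
})
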