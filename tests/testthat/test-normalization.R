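test_that("immediate repetitions of words and utterances collapse", {
  # "brew-brew a pot of tea" -> "brew a pot of tea"
  tk <- rbind(tok(1, "泡", 1, "VC"), tok(1, "泡", 1, "VC", rep = TRUE),
              tok(1, "茶", 1, "Na"))
  resp <- image_response(1, tk, NA_real_)
  out <- collapse_repetitions(resp)
  expect_equal(out$tokens$surface, c("泡", "茶"))
  # unflagged surface-identical repeats also collapse
  tk2 <- rbind(tok(1, "泡", 1, "VC"), tok(1, "泡", 1, "VC"), tok(1, "茶", 1, "Na"))
  expect_equal(collapse_repetitions(image_response(1, tk2, NA_real_))$tokens$surface,
               c("泡", "茶"))
  # runs of three collapse to one
  tk3 <- rbind(tok(1, "泡", 1, "VC"), tok(1, "泡", 1, "VC"),
               tok(1, "泡", 1, "VC"), tok(1, "茶", 1, "Na"))
  expect_equal(collapse_repetitions(image_response(1, tk3, NA_real_))$tokens$surface,
               c("泡", "茶"))
  # identical adjacent utterances [U, U, V] -> [U, V]
  tku <- rbind(tok(1, "喝", 1, "VC"), tok(1, "茶", 1, "Na"),
               tok(2, "喝", 1, "VC"), tok(2, "茶", 1, "Na"),
               tok(3, "好", 1, "VH"))
  out2 <- collapse_repetitions(image_response(1, tku, c(0.2, 3.0, NA)))
  expect_equal(max(out2$tokens$utterance), 2L)
  # the surviving copy keeps the gap to the next distinct utterance
  expect_equal(out2$trailing_pause_s, c(3.0, NA))
  # no adjacent duplicates: identity
  r <- fixture_a_response()
  expect_equal(collapse_repetitions(r)$tokens$surface, r$tokens$surface)
})

test_that("collapse_repetitions is idempotent and never grows the response", {
  cfg <- fast_config()
  for (s in 1:8) {
    tr <- generate_transcript("early_AD", cfg, seed = s)
    for (resp in tr$responses) {
      once <- collapse_repetitions(resp)
      twice <- collapse_repetitions(once)
      expect_identical(twice$tokens$surface, once$tokens$surface)
      expect_identical(twice$trailing_pause_s, once$trailing_pause_s)
      expect_lte(nrow(once$tokens), nrow(resp$tokens))
    }
  }
})

test_that("filler separation counts, conserves and merges gaps", {
  tk <- rbind(tok(1, "他", 1, "Nh"), tok(1, "呃", 1, "I", fp = TRUE),
              tok(1, "泡", 1, "VC"), tok(1, "茶", 1, "Na"))
  out <- separate_fillers(image_response(1, tk, NA_real_))
  expect_equal(out$filled_pause_count, 1L)
  expect_equal(out$response$tokens$surface, c("他", "泡", "茶"))
  # no fillers: identity with count zero
  tk0 <- rbind(tok(1, "他", 1, "Nh"), tok(1, "泡", 1, "VC"))
  out0 <- separate_fillers(image_response(1, tk0, NA_real_))
  expect_equal(out0$filled_pause_count, 0L)
  # an utterance emptied by removal is dropped; its gap merges additively
  tk1 <- rbind(tok(1, "他", 1, "Nh"), tok(2, "呃", 1, "I", fp = TRUE),
               tok(3, "茶", 1, "Na"))
  out1 <- separate_fillers(image_response(1, tk1, c(1.2, 0.9, NA)))
  expect_equal(utt_count <- length(out1$response$trailing_pause_s), 2L)
  expect_equal(out1$filled_pause_count, 1L)
  expect_equal(out1$response$trailing_pause_s, c(1.2 + 0.9, NA))
  # token conservation on generated data: words out + fillers = tokens in
  cfg <- fast_config()
  for (s in 1:5) {
    tr <- generate_transcript("NC", cfg, seed = s)
    for (resp in tr$responses) {
      sep <- separate_fillers(resp)
      expect_equal(nrow(sep$response$tokens) + sep$filled_pause_count,
                   nrow(resp$tokens))
    }
  }
})

test_that("utterance segmentation places boundaries at silences >= 120 ms", {
  tk <- rbind(tok(1, "他", 1, "Nh"), tok(1, "泡", 1, "VC"),
              tok(1, "好", 1, "VH"), tok(1, "茶", 1, "Na"))
  tk$utterance <- NULL
  out <- segment_utterances(tk, c(0.05, 0.2, 0.05))
  expect_equal(max(out$tokens$utterance), 2L)
  expect_equal(as.vector(table(out$tokens$utterance)), c(2L, 2L))
  expect_equal(out$trailing_pause_s, c(0.2, NA))
  # all-zero silences: a single utterance
  out0 <- segment_utterances(tk, c(0, 0, 0))
  expect_equal(max(out0$tokens$utterance), 1L)
  # the threshold is inclusive
  out1 <- segment_utterances(tk, c(0.12, 0, 0))
  expect_equal(max(out1$tokens$utterance), 2L)
  expect_error(segment_utterances(tk, c(-0.1, 0, 0)), "negative")
  # segmentation only regroups: token content is unchanged
  expect_equal(out$tokens$surface, tk$surface)
})

test_that("sentence recognition requires a subject before a predicate", {
  expect_true(is_sentence(c("PRON", "VERB", "NOUN")))
  expect_false(is_sentence(c("ADV", "ADJ")))       # no subject
  expect_true(is_sentence(c("NOUN", "OTHER", "ADJ")))
  expect_false(is_sentence(c("VERB", "NOUN")))     # predicate precedes subject
  expect_false(is_sentence(character()))
  # filled pauses are ignored
  tk <- rbind(tok(1, "呃", 1, "I", fp = TRUE), tok(1, "他", 1, "Nh"),
              tok(1, "喝", 1, "VC"))
  expect_true(is_sentence(tk))
})

test_that("passive constructions need their flanking structure", {
  expect_equal(count_passives(c("NOUN", "PASSIVE_MARKER_BEI", "VERB")), 1L)
  expect_equal(count_passives("PASSIVE_MARKER_BEI"), 0L)
  expect_equal(count_passives(c("PASSIVE_MARKER_BA", "NOUN", "VERB", "VERB")), 1L)
  # bei without a following verb, or without a preceding NP, does not count
  expect_equal(count_passives(c("PASSIVE_MARKER_BEI", "VERB")), 0L)
  expect_equal(count_passives(c("NOUN", "PASSIVE_MARKER_BEI")), 0L)
  # ba needs NP then VERB after the marker, in that order
  expect_equal(count_passives(c("PASSIVE_MARKER_BA", "VERB", "NOUN")), 0L)
  # each marker counts at most once
  expect_equal(count_passives(c("NOUN", "PASSIVE_MARKER_BEI", "VERB", "VERB")), 1L)
  # property: count never exceeds the number of markers
  cfg <- fast_config()
  for (s in 1:5) {
    tr <- generate_transcript("NC", cfg, seed = s)
    for (resp in tr$responses) {
      cls <- resp$tokens$coarse_class
      for (u in unique(resp$tokens$utterance)) {
        cu <- cls[resp$tokens$utterance == u]
        expect_lte(count_passives(cu), sum(grepl("^PASSIVE_MARKER", cu)))
      }
    }
  }
})

test_that("long pauses are inter-utterance gaps of two seconds or more", {
  tk <- rbind(tok(1, "他", 1, "Nh"), tok(2, "泡", 1, "VC"),
              tok(3, "好", 1, "VH"), tok(4, "茶", 1, "Na"))
  resp <- image_response(1, tk, c(0.5, 2.5, 1.9, NA))
  expect_equal(count_long_pauses(resp), 1L)
  # "2 s or more": the boundary counts
  resp2 <- image_response(1, tk, c(2.0, 0.1, 0.1, NA))
  expect_equal(count_long_pauses(resp2), 1L)
  # a single utterance has no gaps
  one <- image_response(1, tok(1, "茶", 1, "Na"), NA_real_)
  expect_equal(count_long_pauses(one), 0L)
})
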