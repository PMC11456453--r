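# Shared fixture builders. Everything is constructed in code; no stored data.

# one token row with the coarse class resolved through the default mapping
tok <- function(u, s, cc, tag, fp = FALSE, rep = FALSE, rev = FALSE,
                inc = FALSE) {
  data.frame(utterance = u, surface = s, char_count = cc, raw_tag = tag,
             coarse_class = resolve_coarse_class(tag, s, fp, quiet = TRUE),
             filled_pause = fp, repetition = rep, revision = rev,
             incomplete = inc, stringsAsFactors = FALSE)
}

# Fixture A: three utterances over one image --
#   U1 = [he/PRON, uh/filler, brew/VERB, tea/NOUN]
#   U2 = [very/ADV, tasty/ADJ(2 chars)]
#   U3 = [tea/NOUN, bei/MARKER, drink/VERB, finish/VERB, le/OTHER]
# gaps 2.5 s (long) and 0.4 s; hand-counted feature values are frozen in
# test-features.R / test-acceptance.R
fixture_a_response <- function() {
  tk <- rbind(
    tok(1, "他", 1, "Nh"), tok(1, "呃", 1, "I", fp = TRUE),
    tok(1, "泡", 1, "VC"), tok(1, "茶", 1, "Na"),
    tok(2, "很", 1, "D"), tok(2, "好喝", 2, "A"),
    tok(3, "茶", 1, "Na"), tok(3, "被", 1, "P"), tok(3, "喝", 1, "VC"),
    tok(3, "完", 1, "VC"), tok(3, "了", 1, "T"))
  image_response(1, tk, c(2.5, 0.4, NA))
}

fixture_a_transcript <- function() {
  speech_transcript("fixA", list(fixture_a_response()))
}

fixture_a_lexicon <- function() {
  frequency_lexicon(c("他" = 5000, "泡" = 200, "茶" = 500, "很" = 8000,
                      "好喝" = 50, "喝" = 900, "完" = 300))
}

fixture_a_expected <- function() {
  c(TW = 10, UW = 9, TTR = 0.9, CW = 8, CD = 0.8, CWF = 1931.25,
    U = 3, S = 2, MLU = 11 / 3, MLS = 4, PCR = 1 / 3, VR = 3 / 8, PR = 1 / 8,
    FR = 1 / 11, LPR = 1 / 11)
}

# lexicon shared by the hand-computed fixtures
hand_fixture_lexicon <- function() {
  frequency_lexicon(c("茶" = 500, "喝" = 900, "他" = 5000, "好" = 100,
                      "大家" = 420, "聊天" = 150))
}

# ten single-image fixtures with fully hand-derived expected feature vectors
hand_fixture_cases <- function() {
  mk <- function(tk, gaps) speech_transcript("h", list(image_response(1, tk, gaps)))
  list(
    # 1: single one-word utterance: ratios at their degenerate values
    list(tr = mk(tok(1, "茶", 1, "Na"), NA_real_),
         exp = c(TW = 1, UW = 1, TTR = 1, CW = 1, CD = 1, CWF = 500, U = 1,
                 S = 0, MLU = 1, MLS = NA, PCR = 0, VR = 0, PR = 0, FR = 0,
                 LPR = 0)),
    # 2: alternating one-word utterances: two distinct types among four words
    # (non-adjacent, so nothing collapses)
    list(tr = mk(rbind(tok(1, "茶", 1, "Na"), tok(2, "喝", 1, "VC"),
                       tok(3, "茶", 1, "Na"), tok(4, "喝", 1, "VC")),
                 c(0.3, 0.3, 0.3, NA)),
         exp = c(TW = 4, UW = 2, TTR = 0.5, CW = 4, CD = 1, CWF = 700, U = 4,
                 S = 0, MLU = 1, MLS = NA, PCR = 0, VR = 0.5, PR = 0, FR = 0,
                 LPR = 0)),
    # 3: subject + verb sentence of two-character words
    list(tr = mk(rbind(tok(1, "大家", 2, "Na"), tok(1, "聊天", 2, "VA")),
                 NA_real_),
         exp = c(TW = 2, UW = 2, TTR = 1, CW = 2, CD = 1, CWF = 285, U = 1,
                 S = 1, MLU = 4, MLS = 2, PCR = 0, VR = 0.5, PR = 0, FR = 0,
                 LPR = 0)),
    # 4: two fillers around one word: filler ratio 2/3
    list(tr = mk(rbind(tok(1, "呃", 1, "I", fp = TRUE), tok(1, "茶", 1, "Na"),
                       tok(1, "嗯", 1, "I", fp = TRUE)), NA_real_),
         exp = c(TW = 1, UW = 1, TTR = 1, CW = 1, CD = 1, CWF = 500, U = 1,
                 S = 0, MLU = 1, MLS = NA, PCR = 0, VR = 0, PR = 0, FR = 2 / 3,
                 LPR = 0)),
    # 5: repetition collapses before anything is counted
    list(tr = mk(rbind(tok(1, "喝", 1, "VC"), tok(1, "喝", 1, "VC", rep = TRUE),
                       tok(1, "茶", 1, "Na")), NA_real_),
         exp = c(TW = 2, UW = 2, TTR = 1, CW = 2, CD = 1, CWF = 700, U = 1,
                 S = 0, MLU = 2, MLS = NA, PCR = 0, VR = 0.5, PR = 0, FR = 0,
                 LPR = 0)),
    # 6: bei passive with flanking structure; also a sentence
    list(tr = mk(rbind(tok(1, "茶", 1, "Na"), tok(1, "被", 1, "P"),
                       tok(1, "喝", 1, "VC")), NA_real_),
         exp = c(TW = 3, UW = 3, TTR = 1, CW = 2, CD = 2 / 3, CWF = 700, U = 1,
                 S = 1, MLU = 3, MLS = 3, PCR = 1, VR = 0.5, PR = 0, FR = 0,
                 LPR = 0)),
    # 7: bare bei with no flanking structure; a long 2.2 s gap
    list(tr = mk(rbind(tok(1, "被", 1, "P"), tok(2, "茶", 1, "Na")),
                 c(2.2, NA)),
         exp = c(TW = 2, UW = 2, TTR = 1, CW = 1, CD = 0.5, CWF = 500, U = 2,
                 S = 0, MLU = 1, MLS = NA, PCR = 0, VR = 0, PR = 0, FR = 0,
                 LPR = 0.5)),
    # 8: incomplete word counts toward TW and MLU but not CW
    list(tr = mk(rbind(tok(1, "他", 1, "Nh"), tok(1, "喝", 1, "VC"),
                       tok(1, "茶", 1, "Na", inc = TRUE)), NA_real_),
         exp = c(TW = 3, UW = 3, TTR = 1, CW = 2, CD = 2 / 3, CWF = 2950,
                 U = 1, S = 1, MLU = 3, MLS = 3, PCR = 0, VR = 0.5, PR = 0.5,
                 FR = 0, LPR = 0)),
    # 9: long pauses at exactly 2.0 s and above among three gaps
    list(tr = mk(rbind(tok(1, "他", 1, "Nh"), tok(2, "喝", 1, "VC"),
                       tok(3, "茶", 1, "Na"), tok(4, "好", 1, "VH")),
                 c(2.0, 1.9, 3.4, NA)),
         exp = c(TW = 4, UW = 4, TTR = 1, CW = 4, CD = 1, CWF = 1625, U = 4,
                 S = 0, MLU = 1, MLS = NA, PCR = 0, VR = 0.5, PR = 0.25,
                 FR = 0, LPR = 0.5)),
    # 10: ba passive inside a longer utterance plus a filler
    list(tr = mk(rbind(tok(1, "他", 1, "Nh"), tok(1, "把", 1, "P"),
                       tok(1, "茶", 1, "Na"), tok(1, "喝", 1, "VC"),
                       tok(1, "呃", 1, "I", fp = TRUE), tok(1, "好", 1, "VH")),
                 NA_real_),
         exp = c(TW = 5, UW = 5, TTR = 1, CW = 4, CD = 0.8, CWF = 1625, U = 1,
                 S = 1, MLU = 5, MLS = 5, PCR = 1, VR = 0.5, PR = 0.25,
                 FR = 1 / 6, LPR = 0)))
}

expect_feature_vector <- function(fv, exp, label = "") {
  for (f in feature_names()) {
    if (is.na(exp[[f]])) {
      testthat::expect_true(is.na(fv[[f]]),
                            label = sprintf("%s %s is NA", label, f))
    } else {
      testthat::expect_equal(fv[[f]], exp[[f]], tolerance = 1e-12,
                             label = sprintf("%s feature %s", label, f))
    }
  }
}

# a fast synthetic configuration that skips runtime calibration (exponents and
# pause rates fixed) -- for structural tests that do not check planted means
fast_config <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    groups = list(
      NC = list(zipf_exponent = 1.25, long_pause_prob = 0.02),
      early_AD = list(zipf_exponent = 1.4, long_pause_prob = 0.08)),
    latent = list(lpr_loading = 0.25),
    ...)
}

# small two-group feature cohort with one informative Gaussian feature
gaussian_cohort <- function(n_per_group, delta, sd = 1, seed = 1,
                            n_noise = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  df <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    group = rep(c("NC", "early_AD"), each = n_per_group),
    age = rnorm(n, 74, 6), education = rnorm(n, 12, 4),
    feat = c(rnorm(n_per_group, 0, sd), rnorm(n_per_group, delta, sd)))
  if (n_noise > 0) {
    for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  }
  df
}
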