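test_that("the synthetic lexicon is Zipf-shaped, tagged and reproducible", {
  cfg <- synthetic_config(lexicon = list(
    vocab_sizes = c(NOUN = 400, VERB = 250, ADJ = 100, ADV = 100, PRON = 50,
                    OTHER = 100)))
  lx <- generate_lexicon(cfg)
  v <- lx$vocab
  expect_equal(sum(table(v$class)), 1000)
  # rank-1 over rank-2 frequency equals 2 at exponent 1
  nn <- v[v$class == "NOUN", ]
  expect_equal(nn$frequency[nn$rank == 1] / nn$frequency[nn$rank == 2], 2)
  # requested class proportions realized exactly (deterministic layout)
  props <- table(v$class) / nrow(v)
  expect_equal(as.vector(props[c("NOUN", "VERB")]), c(0.4, 0.25),
               tolerance = 0.02)
  expect_false(anyDuplicated(v$word) > 0)
  expect_true(all(v$char_count == nchar(v$word)))
  # same seed, same lexicon
  lx2 <- generate_lexicon(cfg)
  expect_identical(lx$vocab, lx2$vocab)
  # marker surfaces are reserved for the markers
  expect_false(any(v$word %in% c("被", "把")))
})

test_that("zero insertion probabilities yield exactly zero ratios", {
  cfg <- synthetic_config(
    groups = list(NC = list(zipf_exponent = 1.25, long_pause_prob = 0,
                            passive_prob = 0, filler_rate = 0)),
    latent = list(lpr_loading = 0))
  lx <- generate_lexicon(cfg)
  for (s in 1:3) {
    tr <- generate_transcript("NC", cfg, seed = s)
    fv <- suppressWarnings(extract_features(tr, lx$lexicon))
    expect_equal(fv[["PCR"]], 0)
    expect_equal(fv[["LPR"]], 0)
    expect_equal(fv[["FR"]], 0)
  }
})

test_that("generated transcripts survive a serialization round trip", {
  cfg <- fast_config()
  tr <- generate_transcript("early_AD", cfg, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript(tr, path)
  tr2 <- read_transcript(path, quiet = TRUE)
  for (i in seq_along(tr$responses)) {
    expect_equal(tr2$responses[[i]]$tokens$surface,
                 tr$responses[[i]]$tokens$surface)
    expect_equal(tr2$responses[[i]]$tokens$coarse_class,
                 tr$responses[[i]]$tokens$coarse_class)
    expect_equal(tr2$responses[[i]]$trailing_pause_s,
                 tr$responses[[i]]$trailing_pause_s)
  }
})

test_that("identical master seeds give identical cohorts", {
  cfg <- fast_config(n_nc = 6, n_ad = 8)
  c1 <- generate_cohort(cfg, seed = 99)
  c2 <- generate_cohort(cfg, seed = 99)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$transcripts[[3]], c2$transcripts[[3]])
  c3 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(c1$cohort$MLU, c3$cohort$MLU))
})

test_that("zero latent loadings decouple biomarkers from speech", {
  cfg <- synthetic_config(
    groups = list(early_AD = list(zipf_exponent = 1.4, long_pause_prob = 0.08)),
    latent = list(lpr_loading = 0, suvr_loading = 0, hippocampus_loading = 0,
                  exponent_loading = 0))
  g <- generate_group(300, "early_AD", cfg, seed = 21)
  lx <- generate_lexicon(cfg)
  f <- suppressWarnings(extract_feature_table(g$transcripts, lx$lexicon))
  expect_lt(abs(cor(g$latents$hippocampus_cm3, f$LPR)), 0.15)
  expect_lt(abs(cor(g$latents$suvr, f$UW)), 0.15)
})

test_that("cognitive scores follow the planted linear models", {
  syn <- generate_cohort(fast_config(n_nc = 60, n_ad = 60), seed = 5)
  co <- syn$cohort
  # MLU enters the global-cognition model positively and the dementia-severity
  # model negatively
  expect_gt(cor(co$MMSE, co$MLU), 0.1)
  expect_lt(cor(co$CDR_SB, co$LPR, use = "complete.obs"), 0.5)
  expect_gt(cor(co$CTT1, co$LPR), 0)       # slower times with more long pauses
  expect_gt(cor(co$MMSE, co$TTR), 0)
  # intercepts sit near the cohort mean by construction
  expect_lt(abs(mean(co$MMSE) - 24.29), 1.5)
})

test_that("the planted-truth table is reproducible and lists the targets", {
  cfg <- fast_config()
  tt <- planted_truth(cfg, m = 40, mc_seed = 777L)
  tt2 <- planted_truth(cfg, m = 40, mc_seed = 777L)
  expect_identical(tt, tt2)
  expect_equal(tt$value[tt$quantity == "MLU" & tt$group == "NC"], 8.11)
  expect_equal(tt$value[tt$quantity == "MLU" & tt$group == "early_AD"], 5.53)
  expect_equal(tt$value[tt$quantity == "FR" & tt$group == "NC"],
               (0.05 / 0.95) / (1 + 0.05 / 0.95), tolerance = 1e-12)
  expect_true("cor_hippocampus_LPR" %in% tt$quantity)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(groups = list(NC = list(mlu_sd = -1))),
               "SDs must be positive")
  expect_error(synthetic_config(groups = list(NC = list(passive_prob = 1.2))),
               "probabilities")
  expect_error(synthetic_config(lexicon = list(vocab_sizes = c(NOUN = 10))),
               "at least 50")
})
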