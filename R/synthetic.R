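## Synthetic-cohort generator.
##
## Generation is parametric-by-construction: transcripts are built word by
## word (utterance counts, utterance lengths, class mixtures, passive
## insertions, fillers, repetitions, silent gaps), so the full normalization
## and feature-extraction pipeline is exercised rather than bypassed. Group
## calibration defaults reproduce the published cohort's group-wise feature
## and biomarker distributions; lexical concentration and long-pause rates
## are tuned by the planted-truth oracle so that the *extracted* features hit
## the planted means.

## ---- configuration ---------------------------------------------------------

default_group_params <- function(group = c("NC", "early_AD")) {
  group <- match.arg(group)
  if (group == "NC") {
    list(
      utterances_per_image = 21.68, utterance_cv = 0.45,
      utterance_mlu_cor = -0.49,
      mlu_mean = 8.11, mlu_sd = 3.02,
      ttr_target = 0.56, ttr_jitter_sd = 0.05,
      diversity_output_coupling = -0.20,
      zipf_exponent = NA_real_,
      content_density = 0.48, verb_share = 0.22, pron_share = 0.03,
      adj_share = 0.10, adv_share = 0.15,
      passive_prob = 0.03,
      filler_rate = 0.05 / 0.95,       # per-word odds giving FR = 0.05
      lpr_target = 0.0035,             # long pauses are rare in controls
      long_pause_prob = NA_real_,
      incomplete_rate = 0.005, repeat_rate = 0.03,
      utterance_repeat_rate = 0.01, revision_rate = 0.01,
      age_mean = 72.23, age_sd = 6.03,
      education_mean = 13.66, education_sd = 3.49,
      female_prob = 14 / 32,
      suvr_mean = 1.08, suvr_sd = 0.08,
      hippocampus_mean = 5.12, hippocampus_sd = 0.48)
  } else {
    list(
      utterances_per_image = 29.81, utterance_cv = 0.70,
      utterance_mlu_cor = -0.68,
      mlu_mean = 5.53, mlu_sd = 1.62,
      ttr_target = 0.51, ttr_jitter_sd = 0.13,
      diversity_output_coupling = -0.25,
      zipf_exponent = NA_real_,
      content_density = 0.46, verb_share = 0.22, pron_share = 0.05,
      adj_share = 0.10, adv_share = 0.15,
      passive_prob = 0.01,
      filler_rate = 0.06 / 0.94,       # FR = 0.06
      lpr_target = 0.02,
      long_pause_prob = NA_real_,
      incomplete_rate = 0.01, repeat_rate = 0.05,
      utterance_repeat_rate = 0.015, revision_rate = 0.02,
      age_mean = 75.02, age_sd = 6.58,
      education_mean = 10.03, education_sd = 4.86,
      female_prob = 31 / 48,
      suvr_mean = 1.47, suvr_sd = 0.19,
      hippocampus_mean = 4.36, hippocampus_sd = 0.72)
  }
}

## planted standardized coefficients of the score-generating linear models
## (one column per cognitive outcome; zero = predictor not in that model)
default_score_models <- function() {
  terms <- c("(Intercept)", "age", "education", "TTR", "UW", "CWF", "VR",
             "PR", "PCR", "MLU", "MLS", "LPR", "FR")
  m <- cbind(
    MMSE   = c(24.29, -0.92,  0.96,  1.90,  0.82, -0.66, -0.54,  0.13,  0.91,  1.28,  0.36, -1.11, -0.37),
    CDR_SB = c( 1.92,  0.42,  0.21, -0.64, -0.37,  0.38,  0.53, -0.21, -0.26, -0.44,  0.22,  0.85,  0.61),
    WLM_I  = c( 8.82, -1.13,  0.60,  1.48,  1.13, -0.15, -0.93, -0.54,  0.97,  0.74, -0.06, -1.17, -0.73),
    WLM_II = c( 8.32, -1.08,  0.89,  1.74,  1.46,  0.23, -0.60, -0.59,  1.14,  1.12, -0.03, -0.85, -0.83),
    DS     = c( 9.04,  0.00,  0.00,  2.04,  1.31,  0.00,  0.00,  0.00,  1.01,  0.00,  0.00, -0.92,  0.00),
    CTT1   = c(119.54, 0.00,  0.00, -40.74, 0.00,  0.00, 17.66,  0.00,  0.00, -20.68, 0.00, 41.78,  0.00),
    CTT2   = c(206.77, 23.34, 19.18, -55.89, -29.57, 24.11, 28.44, 0.00, 0.00, -29.09, 0.00, 36.42, 0.00),
    VF     = c(12.80, -1.72,  0.00,  1.59,  1.39,  0.00, -0.45,  0.00,  1.46,  0.92,  0.00, -0.81, -1.18),
    BNT    = c(21.54, -1.34,  0.00,  1.85,  1.67, -1.07, -0.83, -0.55,  1.35,  0.00,  0.00, -0.72,  0.00))
  rownames(m) <- terms
  m
}

default_score_r2 <- function() {
  c(MMSE = 0.49, CDR_SB = 0.49, WLM_I = 0.49, WLM_II = 0.51, DS = 0.34,
    CTT1 = 0.40, CTT2 = 0.51, VF = 0.42, BNT = 0.61)
}

#' Build a synthetic-cohort configuration
#'
#' Defaults encode the study conditions: group sizes 32 NC / 48 early-AD;
#' per-group utterance, utterance-length, lexical-mixture, passive, filler
#' and pause parameters matching the published group-wise feature means and
#' SDs; biomarker and demographic distributions matching the published cohort
#' table; a latent severity factor tying biomarkers to disfluency and lexical
#' concentration (so the reported hippocampal-volume correlations with the
#' long-pauses ratio and unique-word count are planted); and score-generating
#' linear models with the published standardized coefficients. Fields left
#' `NA` (Zipf sampling exponents, long-pause probabilities, the disfluency
#' loading) are tuned by [calibrate_synthetic()] so the extracted features
#' recover their targets.
#'
#' @param seed Master seed for cohort generation.
#' @param n_nc,n_ad Group sizes.
#' @param n_images Picture descriptions per participant.
#' @param groups Named list of per-group parameter overrides.
#' @param latent Latent severity-factor loadings: `suvr_loading`,
#'   `hippocampus_loading` (share of biomarker SD carried by the factor),
#'   `lpr_loading` (log-scale modulation of the long-pause rate; `NA` =
#'   calibrated) and `exponent_loading` (shift of the lexical concentration
#'   exponent per severity SD).
#' @param lexicon Lexicon layout: per-class vocabulary sizes, Zipf frequency
#'   exponent, frequency scale, per-class two-character word probabilities
#'   and the fixed lexicon seed (the vocabulary is part of the configuration,
#'   not of a cohort draw).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_nc = 32, n_ad = 48, n_images = 3,
                             groups = list(), latent = list(),
                             lexicon = list()) {
  grp <- list(NC = default_group_params("NC"),
              early_AD = default_group_params("early_AD"))
  for (g in names(groups)) grp[[g]][names(groups[[g]])] <- groups[[g]]
  lat <- list(suvr_loading = 0.6, hippocampus_loading = 0.6,
              lpr_loading = NA_real_, exponent_loading = 0.15)
  lat[names(latent)] <- latent
  lex <- list(vocab_sizes = c(NOUN = 500, VERB = 250, ADJ = 120, ADV = 80,
                              PRON = 12, OTHER = 140),
              freq_exponent = 1.0, freq_scale = 2800,
              two_char_prob = c(NOUN = 0.6, VERB = 0.5, ADJ = 0.55, ADV = 0.45,
                                PRON = 0.3, OTHER = 0.2),
              seed = 7421L)
  lex[names(lexicon)] <- lexicon
  cfg <- list(seed = seed, n_nc = n_nc, n_ad = n_ad, n_images = n_images,
              groups = grp, latent = lat, lexicon = lex,
              score_models = default_score_models(),
              score_r2 = default_score_r2())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (g in names(cfg$groups)) {
    p <- cfg$groups[[g]]
    sds <- c(p$mlu_sd, p$age_sd, p$education_sd, p$suvr_sd, p$hippocampus_sd)
    if (any(sds <= 0)) stop("group ", g, ": planted SDs must be positive")
    probs <- c(p$passive_prob, p$incomplete_rate, p$repeat_rate,
               p$utterance_repeat_rate, p$revision_rate, p$female_prob)
    if (any(probs < 0 | probs > 1)) stop("group ", g, ": probabilities must be in [0, 1]")
    if (p$content_density <= 0 || p$content_density >= 1) {
      stop("group ", g, ": content_density must be in (0, 1)")
    }
    shares <- p$verb_share + p$pron_share + p$adj_share + p$adv_share
    if (shares >= 1) stop("group ", g, ": content-class shares must sum below 1")
  }
  if (sum(cfg$lexicon$vocab_sizes) < 50) stop("vocabulary must have at least 50 words")
  invisible(cfg)
}

## ---- lexicon ---------------------------------------------------------------

#' Generate a synthetic word-frequency lexicon with a tagged vocabulary
#'
#' Builds unique CJK-range words per coarse class with Zipf-distributed
#' frequencies (`freq_scale * rank^-freq_exponent` within each class) and a
#' representative raw tag per class. Deterministic under `seed`; the default
#' seed comes from the configuration, because the lexicon is part of the
#' study conditions rather than of any single cohort draw.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to the lexicon seed in `config`).
#' @return List with `lexicon` (a [frequency_lexicon()]) and `vocab` (data
#'   frame: word, class, rank, char_count, frequency, raw_tag).
#' @export
generate_lexicon <- function(config = synthetic_config(), seed = config$lexicon$seed) {
  lex <- config$lexicon
  set.seed(seed)
  sizes <- lex$vocab_sizes
  classes <- names(sizes)
  ## character pool; the bei/ba marker characters are reserved
  pool <- intToUtf8(setdiff(0x4E00:0x62FF, c(0x88AB, 0x628A)), multiple = TRUE)
  pool <- sample(pool)
  one_char_cursor <- 0L
  words_all <- character(0)
  vocab <- list()
  for (cl in classes) {
    v <- sizes[[cl]]
    two <- stats::runif(v) < lex$two_char_prob[[cl]]
    w <- character(v)
    n_one <- sum(!two)
    if (n_one > 0) {
      w[!two] <- pool[one_char_cursor + seq_len(n_one)]
      one_char_cursor <- one_char_cursor + n_one
    }
    n_two <- sum(two)
    if (n_two > 0) {
      made <- character(0)
      while (length(made) < n_two) {
        cand <- paste0(sample(pool, n_two, replace = TRUE),
                       sample(pool, n_two, replace = TRUE))
        made <- unique(c(made, setdiff(cand, words_all)))
      }
      w[two] <- made[seq_len(n_two)]
    }
    words_all <- c(words_all, w)
    raw_tag <- switch(cl, NOUN = "Na", VERB = "VC", ADJ = "A", ADV = "D",
                      PRON = "Nh", OTHER = "T")
    vocab[[cl]] <- data.frame(
      word = w, class = cl, rank = seq_len(v),
      char_count = ifelse(two, 2L, 1L),
      frequency = lex$freq_scale * seq_len(v)^(-lex$freq_exponent),
      raw_tag = raw_tag, stringsAsFactors = FALSE)
  }
  vocab <- do.call(rbind, c(vocab, make.row.names = FALSE))
  if (anyDuplicated(vocab$word)) {
    vocab <- vocab[!duplicated(vocab$word), , drop = FALSE]  # defensive
  }
  list(lexicon = frequency_lexicon(stats::setNames(vocab$frequency, vocab$word)),
       vocab = vocab)
}

## ---- per-participant machinery --------------------------------------------

## stratified standard-normal draws: one draw per equal-probability stratum,
## in random order (variance reduction for planted-mean recovery)
stratified_normal <- function(n) {
  stats::qnorm((sample.int(n) - stats::runif(n)) / n)
}

lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## class mixture over sampled tokens (markers enter only via passives)
class_probs <- function(p) {
  cd_raw <- p$content_density / (1 - p$incomplete_rate)
  noun <- 1 - p$verb_share - p$pron_share - p$adj_share - p$adv_share
  c(NOUN = cd_raw * noun, VERB = cd_raw * p$verb_share,
    ADJ = cd_raw * p$adj_share, ADV = cd_raw * p$adv_share,
    PRON = cd_raw * p$pron_share, OTHER = 1 - cd_raw)
}

## per-class sampling weights at concentration exponent s, plus the expected
## character count of a sampled token
class_weights <- function(vocab_split, s) {
  lapply(vocab_split, function(v) {
    w <- v$rank^(-s)
    w / sum(w)
  })
}

expected_char <- function(vocab_split, weights, probs) {
  ec <- vapply(names(probs), function(cl) {
    sum(weights[[cl]] * vocab_split[[cl]]$char_count)
  }, numeric(1))
  sum(probs * ec)
}

## draw latent per-participant parameters for one group; stratified across
## the cohort so planted group means are recovered tightly
draw_latents <- function(n, p, lat, exponent) {
  z <- stratified_normal(n)
  ## utterance rate and utterance length are negatively correlated on the log
  ## scale: total output varies less than either component alone
  n_mlu <- stratified_normal(n)
  rho_um <- p$utterance_mlu_cor
  n_utt <- rho_um * n_mlu + sqrt(1 - rho_um^2) * stratified_normal(n)
  mlu_p <- lognormal_pars(p$mlu_mean, p$mlu_sd)
  mlu <- exp(mlu_p["meanlog"] + mlu_p["sdlog"] * n_mlu)
  utt_p <- lognormal_pars(p$utterances_per_image,
                          p$utterance_cv * p$utterances_per_image)
  lambda_u <- exp(utt_p["meanlog"] + utt_p["sdlog"] * n_utt)
  ## lexical concentration: baseline exponent + stratified jitter + severity
  ## loading, partially offset by verbal output (speakers who produce more
  ## sample deeper into their vocabulary, keeping the diversity spread at the
  ## planted scale)
  sd_out <- sqrt(mlu_p["sdlog"]^2 + utt_p["sdlog"]^2 +
                   2 * rho_um * mlu_p["sdlog"] * utt_p["sdlog"])
  n_out <- (mlu_p["sdlog"] * n_mlu + utt_p["sdlog"] * n_utt) / sd_out
  s_i <- pmax(exponent + p$ttr_jitter_sd * stratified_normal(n) +
                lat$exponent_loading * z +
                p$diversity_output_coupling * n_out, 0.2)
  lam <- lat$lpr_loading
  q_i <- pmin(pmax(p$long_pause_prob * exp(lam * z - lam^2 / 2), 0), 0.9)
  age <- p$age_mean + p$age_sd * stratified_normal(n)
  education <- pmax(6, p$education_mean + p$education_sd * stratified_normal(n))
  gender <- ifelse(stats::runif(n) < p$female_prob, "F", "M")
  rho_s <- lat$suvr_loading
  rho_h <- lat$hippocampus_loading
  suvr <- p$suvr_mean + p$suvr_sd *
    (rho_s * z + sqrt(1 - rho_s^2) * stratified_normal(n))
  hippo <- p$hippocampus_mean + p$hippocampus_sd *
    (-rho_h * z + sqrt(1 - rho_h^2) * stratified_normal(n))
  data.frame(z = z, mlu = mlu, lambda_u = lambda_u, s = s_i, q = q_i,
             age = age, education = education, gender = gender,
             suvr = suvr, hippocampus_cm3 = pmax(hippo, 0.5))
}

## build one participant's transcript from latent parameters
build_transcript <- function(id, lat_row, p, vocab_split, n_images, seed) {
  set.seed(seed)
  weights <- class_weights(vocab_split, lat_row$s)
  probs <- class_probs(p)
  cbar <- expected_char(vocab_split, weights, probs)
  kbar <- max(lat_row$mlu / cbar, 1)
  classes <- names(probs)
  vw <- lapply(vocab_split, function(v) v$word)
  vc <- lapply(vocab_split, function(v) v$char_count)
  vt <- lapply(vocab_split, function(v) v$raw_tag)
  draw_idx <- function(cl, n) {
    sample.int(length(vw[[cl]]), n, replace = TRUE, prob = weights[[cl]])
  }
  responses <- vector("list", n_images)
  for (img in seq_len(n_images)) {
    n_utt <- max(1L, stats::rpois(1, lat_row$lambda_u))
    k_vec <- 1L + stats::rpois(n_utt, kbar - 1)
    total <- sum(k_vec)
    cls_draw <- sample(classes, total, replace = TRUE, prob = probs)
    utt_id <- rep.int(seq_len(n_utt), k_vec)
    idx <- integer(total)
    for (cl in classes) {
      sel <- cls_draw == cl
      if (any(sel)) idx[sel] <- draw_idx(cl, sum(sel))
    }
    surf <- character(total); chars <- integer(total); tags <- character(total)
    for (cl in classes) {
      sel <- cls_draw == cl
      surf[sel] <- vw[[cl]][idx[sel]]
      chars[sel] <- vc[[cl]][idx[sel]]
      tags[sel] <- vt[[cl]][idx[sel]]
    }
    cls <- cls_draw
    ## reject accidental immediate within-utterance duplicates (repetitions
    ## are planted explicitly, never sampled by accident)
    pass <- 0L
    repeat {
      dup <- which(c(FALSE, surf[-1] == surf[-total] &
                       utt_id[-1] == utt_id[-total]))
      pass <- pass + 1L
      if (!length(dup) || pass > 5L) break
      for (i in dup) {
        cl <- cls_draw[i]
        for (try in 1:10) {
          j <- draw_idx(cl, 1L)
          if (vw[[cl]][j] != surf[i - 1L]) break
        }
        surf[i] <- vw[[cl]][j]; chars[i] <- vc[[cl]][j]; tags[i] <- vt[[cl]][j]
      }
    }
    ## passive constructions with valid flanking structure
    passive_utts <- which(stats::runif(n_utt) < p$passive_prob & k_vec >= 3L)
    for (u in passive_utts) {
      pos <- which(utt_id == u)[1:3]
      np_cl <- if (stats::runif(1) < 0.15) "PRON" else "NOUN"
      np <- draw_idx(np_cl, 1L)
      vb <- draw_idx("VERB", 1L)
      if (stats::runif(1) < 0.5) {   # NP + bei + VP
        surf[pos] <- c(vw[[np_cl]][np], "被", vw[["VERB"]][vb])
        chars[pos] <- c(vc[[np_cl]][np], 1L, vc[["VERB"]][vb])
        tags[pos] <- c(vt[[np_cl]][np], "P", vt[["VERB"]][vb])
        cls[pos] <- c(np_cl, "PASSIVE_MARKER_BEI", "VERB")
      } else {                        # ba + NP + VP
        surf[pos] <- c("把", vw[[np_cl]][np], vw[["VERB"]][vb])
        chars[pos] <- c(1L, vc[[np_cl]][np], vc[["VERB"]][vb])
        tags[pos] <- c("P", vt[[np_cl]][np], vt[["VERB"]][vb])
        cls[pos] <- c("PASSIVE_MARKER_BA", np_cl, "VERB")
      }
    }
    marker <- grepl("^PASSIVE_MARKER", cls)
    incomplete <- stats::runif(total) < p$incomplete_rate & !marker
    revision <- stats::runif(total) < p$revision_rate & !marker
    tk <- data.frame(utterance = utt_id, surface = surf, char_count = chars,
                     raw_tag = tags, coarse_class = cls,
                     filled_pause = FALSE, repetition = FALSE,
                     revision = revision, incomplete = incomplete,
                     stringsAsFactors = FALSE)
    ## word order key: words keep their sequence; fillers drop in at random
    ## positions between them
    tk$.key <- stats::ave(seq_len(total), utt_id, FUN = seq_along)
    ## fillers (extra tokens; removed by the pipeline, counted in FR)
    n_fill <- stats::rbinom(n_utt, k_vec, min(p$filler_rate, 1))
    if (sum(n_fill) > 0) {
      fill_rows <- data.frame(
        utterance = rep.int(seq_len(n_utt), n_fill),
        surface = sample(c("呃", "嗯", "啊"), sum(n_fill), TRUE),
        char_count = 1L, raw_tag = "I", coarse_class = "OTHER",
        filled_pause = TRUE, repetition = FALSE, revision = FALSE,
        incomplete = FALSE, stringsAsFactors = FALSE)
      fill_rows$.key <- stats::runif(nrow(fill_rows), 0,
                                     rep.int(k_vec, n_fill) + 1) - 0.5
      tk <- rbind(tk, fill_rows)
      tk <- tk[order(tk$utterance, tk$.key), , drop = FALSE]
    }
    ## planted immediate word repetitions (collapse restores the original)
    tk$.key <- seq_len(nrow(tk))
    rep_idx <- which(stats::runif(nrow(tk)) < p$repeat_rate & !tk$filled_pause)
    if (length(rep_idx)) {
      copies <- tk[rep_idx, , drop = FALSE]
      copies$repetition <- TRUE
      copies$.key <- copies$.key + 0.5
      tk <- rbind(tk, copies)
      tk <- tk[order(tk$utterance, tk$.key), , drop = FALSE]
    }
    tk$.key <- NULL
    ## silent gaps on the clean utterance structure
    gaps <- rep(NA_real_, n_utt)
    if (n_utt > 1L) {
      long <- stats::runif(n_utt - 1L) < lat_row$q
      gaps[-n_utt] <- ifelse(long, 2 + stats::rexp(n_utt - 1L, 1),
                             stats::runif(n_utt - 1L, 0.12, 1.9))
    }
    ## planted utterance perseverations: the copy is inserted after the
    ## original with a short internal gap; collapsing keeps the last copy,
    ## which carries the original's gap
    dup_utts <- which(stats::runif(n_utt) < p$utterance_repeat_rate)
    if (length(dup_utts)) {
      pieces <- list(); new_gaps <- numeric(0); new_id <- 0L
      for (u in seq_len(n_utt)) {
        part <- tk[tk$utterance == u, , drop = FALSE]
        new_id <- new_id + 1L
        part$utterance <- new_id
        pieces[[length(pieces) + 1L]] <- part
        if (u %in% dup_utts) {
          new_gaps <- c(new_gaps, 0.15)
          copy <- part
          copy$repetition <- TRUE
          new_id <- new_id + 1L
          copy$utterance <- new_id
          pieces[[length(pieces) + 1L]] <- copy
        }
        new_gaps <- c(new_gaps, gaps[u])
      }
      tk <- do.call(rbind, pieces)
      gaps <- new_gaps
    }
    rownames(tk) <- NULL
    responses[[img]] <- image_response(img, tk, gaps)
  }
  speech_transcript(id, responses)
}

## ---- calibration -----------------------------------------------------------

.calibration_cache <- new.env(parent = emptyenv())

calibration_key <- function(cfg) {
  rel <- list(groups = cfg$groups, latent = cfg$latent, lexicon = cfg$lexicon,
              n_images = cfg$n_images,
              prop = cfg$n_ad / (cfg$n_nc + cfg$n_ad))
  paste(deparse(rel), collapse = "")
}

## generate a group's transcripts at given parameters and measure mean
## extracted features (used only by the calibration loop)
measure_group <- function(cfg, group, n, lex, seed) {
  gen <- generate_group(n, group, cfg, lex, seed = seed)
  feats <- extract_feature_table(gen$transcripts, lex$lexicon)
  list(ttr = mean(feats$TTR), lpr = mean(feats$LPR),
       mlu = mean(feats$MLU), feats = feats, latents = gen$latents)
}

#' Calibrate the free generator parameters against their planted targets
#'
#' Tunes, per group, the Zipf sampling exponent (so the mean extracted
#' type-to-token ratio matches its target) and the long-pause probability (so
#' the mean extracted long-pauses ratio matches its target), and then the
#' latent disfluency loading (so the hippocampal-volume / long-pauses-ratio
#' correlation in a mixed cohort matches its target). Tuning runs the real
#' generation + extraction pipeline on calibration cohorts under a fixed
#' internal seed, so calibrated configurations are deterministic; results are
#' cached per configuration within the session.
#'
#' @param config A [synthetic_config()].
#' @param m Calibration cohort size per group.
#' @param target_r Planted hippocampus-LPR correlation.
#' @param quiet Suppress progress notes.
#' @return The configuration with `zipf_exponent`, `long_pause_prob` and
#'   `lpr_loading` filled in.
#' @export
calibrate_synthetic <- function(config, m = 400, target_r = -0.489,
                                quiet = TRUE) {
  cfg <- config
  needs <- any(vapply(cfg$groups, function(p) {
    is.na(p$zipf_exponent) || is.na(p$long_pause_prob)
  }, logical(1))) || is.na(cfg$latent$lpr_loading)
  if (!needs) return(cfg)
  key <- calibration_key(cfg)
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) {
    for (g in names(hit$groups)) cfg$groups[[g]][names(hit$groups[[g]])] <- hit$groups[[g]]
    cfg$latent$lpr_loading <- hit$lpr_loading
    return(cfg)
  }
  lex <- generate_lexicon(cfg)
  if (is.na(cfg$latent$lpr_loading)) cfg$latent$lpr_loading <- 0.5
  cal_seed <- 900001L
  for (g in names(cfg$groups)) {
    p <- cfg$groups[[g]]
    ## rough starting points from the closed-form structure
    if (is.na(p$long_pause_prob)) {
      tw_guess <- p$utterances_per_image * p$mlu_mean / 1.5
      p$long_pause_prob <- min(0.5, p$lpr_target * tw_guess *
                                 (1 + p$filler_rate) /
                                 max(p$utterances_per_image - 1, 1))
    }
    ## common random numbers across iterations make the tuned quantities
    ## smooth deterministic functions of the parameters
    if (is.na(p$zipf_exponent)) {
      ## secant iteration on the exponent against mean extracted TTR
      s0 <- 1.0; s1 <- 1.6
      p$zipf_exponent <- s0
      cfg$groups[[g]] <- p
      f0 <- measure_group(cfg, g, m, lex, cal_seed)$ttr - p$ttr_target
      p$zipf_exponent <- s1
      cfg$groups[[g]] <- p
      meas <- measure_group(cfg, g, m, lex, cal_seed)
      f1 <- meas$ttr - p$ttr_target
      for (it in seq_len(6)) {
        if (abs(f1) < 0.002 || abs(f1 - f0) < 1e-9) break
        s2 <- s1 - f1 * (s1 - s0) / (f1 - f0)
        s2 <- min(max(s2, 0.3), 3.5)
        s0 <- s1; f0 <- f1; s1 <- s2
        p$zipf_exponent <- s2
        cfg$groups[[g]] <- p
        meas <- measure_group(cfg, g, m, lex, cal_seed)
        f1 <- meas$ttr - p$ttr_target
      }
      if (!quiet) message(g, ": exponent ", round(p$zipf_exponent, 3),
                          " (TTR ", round(f1 + p$ttr_target, 4), ")")
    } else {
      cfg$groups[[g]] <- p
      meas <- measure_group(cfg, g, m, lex, cal_seed)
    }
    ## the extracted LPR is linear in the long-pause probability: rescale,
    ## then verify once
    for (pass in 1:2) {
      lpr_hat <- meas$lpr
      if (lpr_hat > 0 && abs(lpr_hat - p$lpr_target) > 2e-4) {
        p$long_pause_prob <- min(0.9, p$long_pause_prob * p$lpr_target / lpr_hat)
        cfg$groups[[g]] <- p
        meas <- measure_group(cfg, g, m, lex, cal_seed)
      } else break
    }
    if (!quiet) message(g, ": long_pause_prob ", round(p$long_pause_prob, 4),
                        " (LPR ", round(meas$lpr, 4), ")")
    cfg$groups[[g]] <- p
  }
  ## latent disfluency loading against the mixed-cohort correlation
  measure_r <- function(lam, seed) {
    cfg$latent$lpr_loading <- lam
    n_mix <- 600L
    n_ad <- round(n_mix * cfg$n_ad / (cfg$n_nc + cfg$n_ad))
    gen_nc <- generate_group(n_mix - n_ad, "NC", cfg, lex, seed = seed)
    gen_ad <- generate_group(n_ad, "early_AD", cfg, lex, seed = seed + 1L)
    feats <- extract_feature_table(c(gen_nc$transcripts, gen_ad$transcripts),
                                   lex$lexicon)
    hippo <- c(gen_nc$latents$hippocampus_cm3, gen_ad$latents$hippocampus_cm3)
    stats::cor(hippo, feats$LPR)
  }
  l0 <- 0.25; l1 <- 0.9
  r0 <- measure_r(l0, cal_seed + 50L) - target_r
  r1 <- measure_r(l1, cal_seed + 50L) - target_r
  lam <- l1
  for (it in seq_len(5)) {
    if (abs(r1) < 0.02 || abs(r1 - r0) < 1e-9) break
    l2 <- min(max(l1 - r1 * (l1 - l0) / (r1 - r0), 0), 2.5)
    l0 <- l1; r0 <- r1; l1 <- l2
    r1 <- measure_r(l2, cal_seed + 50L) - target_r
    lam <- l2
  }
  cfg$latent$lpr_loading <- lam
  if (!quiet) message("lpr_loading ", round(lam, 3), " (r ", round(r1 + target_r, 3), ")")
  .calibration_cache[[key]] <- list(
    groups = lapply(cfg$groups, function(p) {
      p[c("zipf_exponent", "long_pause_prob")]
    }),
    lpr_loading = cfg$latent$lpr_loading)
  cfg
}

## ---- generation ------------------------------------------------------------

#' Generate one group's synthetic participants
#'
#' Draws latent per-participant parameters (severity factor, mean utterance
#' length, utterance rate, lexical concentration, long-pause rate,
#' demographics, biomarkers) with stratified sampling across the group, then
#' builds each participant's transcript word by word. The configuration must
#' be calibrated; [calibrate_synthetic()] is applied automatically.
#'
#' @param n Number of participants.
#' @param group `"NC"` or `"early_AD"`.
#' @param config A [synthetic_config()].
#' @param lex Optional pre-built [generate_lexicon()] result.
#' @param seed Integer seed.
#' @param id_prefix Participant-id prefix.
#' @return List with `transcripts`, `latents` (data frame incl. biomarkers
#'   and demographics) and `lex`.
#' @export
generate_group <- function(n, group = c("NC", "early_AD"),
                           config = synthetic_config(), lex = NULL,
                           seed = config$seed, id_prefix = NULL) {
  group <- match.arg(group)
  p <- config$groups[[group]]
  if (is.na(p$zipf_exponent) || is.na(p$long_pause_prob) ||
      is.na(config$latent$lpr_loading)) {
    config <- calibrate_synthetic(config)
    p <- config$groups[[group]]
  }
  if (is.null(lex)) lex <- generate_lexicon(config)
  vocab_split <- split(lex$vocab, lex$vocab$class)
  set.seed(seed)
  latents <- draw_latents(n, p, config$latent, p$zipf_exponent)
  part_seeds <- sample.int(.Machine$integer.max, n)
  if (is.null(id_prefix)) id_prefix <- if (group == "NC") "NC" else "AD"
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  transcripts <- vector("list", n)
  for (i in seq_len(n)) {
    transcripts[[i]] <- build_transcript(ids[i], latents[i, ], p, vocab_split,
                                         config$n_images, part_seeds[i])
  }
  latents$participant_id <- ids
  latents$group <- group
  list(transcripts = transcripts, latents = latents, lex = lex)
}

#' Generate a single synthetic transcript
#'
#' Convenience wrapper drawing one participant (unstratified latents).
#'
#' @param group `"NC"` or `"early_AD"`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [speech_transcript()].
#' @export
generate_transcript <- function(group = c("NC", "early_AD"),
                                config = synthetic_config(), seed = 1) {
  generate_group(1L, match.arg(group), config, seed = seed)$transcripts[[1]]
}

#' Generate a complete synthetic cohort
#'
#' Produces transcripts, extracted features, demographics, biomarkers and
#' cognitive scores for `n_nc + n_ad` participants. Biomarkers share a latent
#' severity factor with the transcript parameters, planting the reported
#' feature-biomarker correlations; cognitive scores are generated from linear
#' models of the standardized extracted features and covariates with planted
#' coefficients and noise chosen to match each model's planted R-squared.
#' A single master seed drives a per-participant seed sequence, so identical
#' seeds give identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @param seed Master seed (defaults to the configuration's).
#' @return Object of class `synthetic_cohort`: `cohort` (a cohort table with
#'   feature columns), `features`, `transcripts`, `lexicon`, `truth`
#'   (calibrated configuration).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  config <- calibrate_synthetic(config)
  lex <- generate_lexicon(config)
  set.seed(seed)
  seed_nc <- sample.int(.Machine$integer.max, 1)
  seed_ad <- sample.int(.Machine$integer.max, 1)
  seed_scores <- sample.int(.Machine$integer.max, 1)
  gen_nc <- generate_group(config$n_nc, "NC", config, lex, seed = seed_nc)
  gen_ad <- generate_group(config$n_ad, "early_AD", config, lex, seed = seed_ad)
  transcripts <- c(gen_nc$transcripts, gen_ad$transcripts)
  latents <- rbind(gen_nc$latents, gen_ad$latents)
  feats <- extract_feature_table(transcripts, lex$lexicon)
  stopifnot(identical(feats$participant_id, latents$participant_id))
  ## cognitive scores from planted linear models of the extracted features
  set.seed(seed_scores)
  coefs <- config$score_models
  terms <- setdiff(rownames(coefs), "(Intercept)")
  design <- cbind(age = latents$age, education = latents$education,
                  as.matrix(feats[, setdiff(terms, c("age", "education")),
                                  drop = FALSE]))
  design <- design[, terms, drop = FALSE]
  zdesign <- scale(design)
  zdesign[is.na(zdesign)] <- 0
  scores <- matrix(NA_real_, nrow = nrow(latents), ncol = ncol(coefs),
                   dimnames = list(NULL, colnames(coefs)))
  for (oc in colnames(coefs)) {
    xb <- coefs["(Intercept)", oc] + zdesign %*% coefs[terms, oc]
    r2 <- config$score_r2[[oc]]
    sd_sig <- stats::sd(xb)
    sd_noise <- if (sd_sig > 0) sd_sig * sqrt((1 - r2) / r2) else 1
    scores[, oc] <- as.numeric(xb) + stats::rnorm(nrow(latents), 0, sd_noise)
  }
  cohort <- data.frame(participant_id = latents$participant_id,
                       group = latents$group,
                       age = latents$age, education = latents$education,
                       gender = latents$gender, suvr = latents$suvr,
                       hippocampus_cm3 = latents$hippocampus_cm3,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(scores))
  cohort <- cbind(cohort, feats[, feature_names(), drop = FALSE])
  cohort <- as_cohort_table(cohort)
  structure(list(cohort = cohort, features = feats, transcripts = transcripts,
                 lexicon = lex, config = config, seed = seed,
                 latents = latents),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d NC + %d early-AD participants, seed %s\n",
              sum(x$cohort$group == "NC"), sum(x$cohort$group == "early_AD"),
              format(x$seed)))
  invisible(x)
}

#' Planted-truth table for a configuration
#'
#' The oracle for parameter-recovery tests: the expected value of every
#' calibrated feature target, biomarker moment and planted correlation
#' implied by the configuration, either in closed form (planted means,
#' filler-ratio odds) or by Monte-Carlo on a large calibration cohort
#' (reported with its own fixed seed so the table is reproducible).
#'
#' @param config A [synthetic_config()].
#' @param m Monte-Carlo cohort size per group.
#' @param mc_seed Seed for the Monte-Carlo estimates.
#' @return Data frame: `quantity`, `group`, `value`, `source`.
#' @export
planted_truth <- function(config = synthetic_config(), m = 300,
                          mc_seed = 424242L) {
  cfg <- calibrate_synthetic(config)
  lex <- generate_lexicon(cfg)
  rows <- list()
  add <- function(q, g, v, src) {
    rows[[length(rows) + 1L]] <<- data.frame(quantity = q, group = g,
                                             value = v, source = src)
  }
  for (g in names(cfg$groups)) {
    p <- cfg$groups[[g]]
    add("MLU", g, p$mlu_mean, "planted")
    add("TTR", g, p$ttr_target, "calibrated")
    add("LPR", g, p$lpr_target, "calibrated")
    add("FR", g, p$filler_rate / (1 + p$filler_rate), "closed-form")
    add("suvr_mean", g, p$suvr_mean, "planted")
    add("suvr_sd", g, p$suvr_sd, "planted")
    add("hippocampus_mean", g, p$hippocampus_mean, "planted")
    add("hippocampus_sd", g, p$hippocampus_sd, "planted")
    add("U", g, p$utterances_per_image, "planted")
    gen <- generate_group(m, g, cfg, lex, seed = mc_seed)
    feats <- extract_feature_table(gen$transcripts, lex$lexicon)
    for (f in c("PCR", "CD", "VR", "PR", "TW", "UW", "CWF")) {
      add(f, g, mean(feats[[f]], na.rm = TRUE), "monte-carlo")
    }
  }
  set.seed(mc_seed)
  n_mix <- 2L * m
  n_ad <- round(n_mix * cfg$n_ad / (cfg$n_nc + cfg$n_ad))
  gen_nc <- generate_group(n_mix - n_ad, "NC", cfg, lex, seed = mc_seed + 3L)
  gen_ad <- generate_group(n_ad, "early_AD", cfg, lex, seed = mc_seed + 4L)
  feats <- extract_feature_table(c(gen_nc$transcripts, gen_ad$transcripts),
                                 lex$lexicon)
  hippo <- c(gen_nc$latents$hippocampus_cm3, gen_ad$latents$hippocampus_cm3)
  add("cor_hippocampus_LPR", "mixed", stats::cor(hippo, feats$LPR), "monte-carlo")
  add("cor_hippocampus_UW", "mixed", stats::cor(hippo, feats$UW), "monte-carlo")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
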