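## The fifteen linguistic features, computed per image and averaged across the
## (up to three) picture descriptions of a participant.
##
## A "word" is any non-filler token, including particles and passive markers;
## incomplete fragments count as words (and toward utterance character totals)
## but never as content words. Undefined ratios are NA, never 0.

#' Lexical-content features
#'
#' Computes TW (total words), UW (unique surface forms), TTR (UW/TW), CW
#' (content words: noun/verb/adjective/pronoun/adverb tokens not flagged
#' incomplete), CD (CW/TW) and CWF (mean corpus frequency over content-word
#' tokens). Out-of-vocabulary content tokens are handled by the lexicon's
#' `oov_policy`: `"skip"` drops them from numerator and denominator,
#' `"min_frequency"` substitutes the smallest lexicon frequency.
#'
#' @param normalized A [normalize_response()] result.
#' @param lexicon A [frequency_lexicon()].
#' @return Named numeric vector `c(TW, UW, TTR, CW, CD, CWF)`.
#' @export
lexical_features <- function(normalized, lexicon) {
  tk <- normalized$response$tokens
  tw <- nrow(tk)
  if (tw == 0L) {
    warning("no word tokens; lexical ratios undefined")
    return(c(TW = 0, UW = 0, TTR = NA_real_, CW = 0, CD = NA_real_, CWF = NA_real_))
  }
  uw <- length(unique(tk$surface))
  content <- tk$coarse_class %in% content_classes() & !tk$incomplete
  cw <- sum(content)
  cwf <- NA_real_
  if (cw > 0L) {
    freq <- unname(lexicon$freq[tk$surface[content]])
    oov <- is.na(freq)
    if (any(oov)) {
      if (lexicon$oov_policy == "min_frequency") {
        freq[oov] <- min(lexicon$freq)
      } else {
        freq <- freq[!oov]
      }
    }
    if (length(freq)) cwf <- mean(freq)
  }
  c(TW = tw, UW = uw, TTR = uw / tw, CW = cw, CD = cw / tw, CWF = cwf)
}

#' Syntactic-complexity features
#'
#' Computes U (utterance count), S (utterances forming a complete sentence),
#' MLU (total Chinese characters over all word tokens divided by U), MLS
#' (word tokens within sentences divided by S), PCR (passive constructions
#' per utterance), VR (verb tokens / CW) and PR (pronoun tokens / CW).
#'
#' @param normalized A [normalize_response()] result.
#' @return Named numeric vector `c(U, S, MLU, MLS, PCR, VR, PR)`.
#' @export
syntactic_features <- function(normalized) {
  resp <- normalized$response
  tk <- resp$tokens
  u <- utt_count(resp)
  sent <- sentence_flags(resp)
  s <- sum(sent)
  mlu <- sum(tk$char_count) / u
  mls <- if (s > 0L) {
    sum(tabulate(tk$utterance, nbins = u)[sent]) / s
  } else {
    warning("no complete sentences; MLS undefined")
    NA_real_
  }
  pcr <- sum(passive_counts(resp)) / u
  content <- tk$coarse_class %in% content_classes() & !tk$incomplete
  cw <- sum(content)
  if (cw > 0L) {
    vr <- sum(tk$coarse_class == "VERB" & !tk$incomplete) / cw
    pr <- sum(tk$coarse_class == "PRON" & !tk$incomplete) / cw
  } else {
    warning("no content words; VR and PR undefined")
    vr <- NA_real_
    pr <- NA_real_
  }
  c(U = u, S = s, MLU = mlu, MLS = mls, PCR = pcr, VR = vr, PR = pr)
}

#' Disfluency features
#'
#' Total verbal output is TW plus the number of filled pauses. FR is filled
#' pauses over verbal output; LPR is long silent pauses (inter-utterance gaps
#' of 2 s or more) over verbal output.
#'
#' @param normalized A [normalize_response()] result.
#' @return Named numeric vector `c(FR, LPR)`.
#' @export
disfluency_features <- function(normalized) {
  tw <- nrow(normalized$response$tokens)
  verbal <- tw + normalized$filled_pause_count
  if (verbal == 0L) {
    warning("zero verbal output; FR and LPR undefined")
    return(c(FR = NA_real_, LPR = NA_real_))
  }
  c(FR = normalized$filled_pause_count / verbal,
    LPR = normalized$long_pause_count / verbal)
}

#' Average per-image feature vectors across images
#'
#' Unweighted arithmetic mean of each feature over the available images; a
#' feature missing for some image is excluded from that feature's mean (with a
#' warning naming the feature).
#'
#' @param vectors List of per-image named feature vectors (1 to 3 entries).
#' @return Named numeric vector over [feature_names()].
#' @export
aggregate_images <- function(vectors) {
  if (!length(vectors)) stop("no per-image feature vectors to aggregate")
  m <- do.call(rbind, lapply(vectors, function(v) v[feature_names()]))
  partial <- colSums(is.na(m)) > 0 & colSums(!is.na(m)) > 0
  if (any(partial)) {
    warning("feature(s) averaged over a subset of images: ",
            paste(feature_names()[partial], collapse = ", "))
  }
  out <- colMeans(m, na.rm = TRUE)
  out[colSums(!is.na(m)) == 0] <- NA_real_
  names(out) <- feature_names()
  out
}

#' Extract the fifteen linguistic features from a transcript
#'
#' Runs the cleaning pipeline (repetition collapsing, filler separation,
#' long-pause tallying) on each image response, computes the lexical,
#' syntactic and disfluency feature groups per image, and averages across
#' images.
#'
#' @param transcript A [speech_transcript()].
#' @param lexicon A [frequency_lexicon()].
#' @param long_pause_s Long-pause threshold in seconds (inclusive).
#' @return Named numeric vector over [feature_names()].
#' @export
extract_features <- function(transcript, lexicon, long_pause_s = 2) {
  stopifnot(inherits(transcript, "speech_transcript"),
            inherits(lexicon, "frequency_lexicon"))
  per_image <- lapply(transcript$responses, function(resp) {
    norm <- normalize_response(resp, long_pause_s = long_pause_s)
    c(lexical_features(norm, lexicon),
      syntactic_features(norm),
      disfluency_features(norm))
  })
  aggregate_images(per_image)
}

#' Extract features for a list of transcripts
#'
#' @param transcripts List of [speech_transcript()] objects.
#' @param lexicon A [frequency_lexicon()].
#' @param long_pause_s Long-pause threshold in seconds.
#' @return Data frame: `participant_id` plus the 15 feature columns.
#' @export
extract_feature_table <- function(transcripts, lexicon, long_pause_s = 2) {
  rows <- lapply(transcripts, function(tr) extract_features(tr, lexicon, long_pause_s))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(participant_id = vapply(transcripts, function(tr) tr$participant_id,
                                       character(1)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
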