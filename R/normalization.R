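## Transcript cleaning and structural rules.
##
## Pipeline order is fixed: collapse_repetitions -> separate_fillers ->
## sentence / passive / pause computations. Pause thresholds are inclusive
## (>= 120 ms segments, >= 2 s long pauses).

utt_count <- function(response) length(response$trailing_pause_s)

#' Collapse immediate repetitions of words and utterances
#'
#' Runs of surface-identical adjacent words within an utterance are reduced to
#' a single copy, as are runs of identical adjacent utterances ("brew-brew a
#' pot of tea" is recorded as "brew a pot of tea"). Annotation flags are not
#' required: surface-identical immediate repeats qualify even when unflagged.
#' When identical adjacent utterances collapse, the surviving copy keeps the
#' silent gap that follows the last copy (the gap to the next distinct
#' utterance); the internal gaps between copies are discarded.
#'
#' @param response An [image_response()].
#' @return The collapsed [image_response()]. Idempotent.
#' @export
collapse_repetitions <- function(response) {
  tk <- response$tokens
  n <- nrow(tk)
  if (n > 1L) {
    dup <- c(FALSE, tk$surface[-1] == tk$surface[-n] &
                    tk$utterance[-1] == tk$utterance[-n])
    if (any(dup)) tk <- tk[!dup, , drop = FALSE]
  }
  ## utterance-level: identical adjacent token sequences collapse to the last copy
  sig <- tapply(tk$surface, tk$utterance, paste, collapse = "\x1f")
  n_utt <- length(sig)
  pauses <- response$trailing_pause_s
  if (n_utt > 1L) {
    drop_utt <- c(unname(sig[-n_utt]) == unname(sig[-1]), FALSE)
    if (any(drop_utt)) {
      keep_ids <- which(!drop_utt)
      tk <- tk[tk$utterance %in% keep_ids, , drop = FALSE]
      pauses <- pauses[keep_ids]
      tk$utterance <- match(tk$utterance, keep_ids)
    }
  }
  rownames(tk) <- NULL
  structure(list(image_id = response$image_id, tokens = tk,
                 trailing_pause_s = pauses),
            class = "image_response")
}

#' Remove filled pauses and count them
#'
#' Filled pauses are not words: tokens carrying the `filled_pause` flag are
#' removed and counted. An utterance emptied by the removal is dropped and its
#' trailing silent gap merged additively into the predecessor's gap (a leading
#' emptied utterance simply disappears; its gap precedes the first remaining
#' utterance and is discarded).
#'
#' @param response An [image_response()].
#' @return List with elements `response` (filler-free [image_response()]) and
#'   `filled_pause_count`. Token conservation: words out + fillers = tokens in.
#' @export
separate_fillers <- function(response) {
  tk <- response$tokens
  fp <- tk$filled_pause
  count <- sum(fp)
  if (count == 0L) {
    return(list(response = response, filled_pause_count = 0L))
  }
  tk2 <- tk[!fp, , drop = FALSE]
  if (nrow(tk2) == 0L) {
    stop("image response contains only filled pauses; no words remain")
  }
  pauses <- response$trailing_pause_s
  n_utt <- length(pauses)
  survives <- seq_len(n_utt) %in% unique(tk2$utterance)
  for (i in which(!survives)) {
    ## merge this utterance's gap into the nearest surviving predecessor
    pred <- max(which(survives[seq_len(i)]), -Inf)
    if (is.finite(pred) && !is.na(pauses[i])) {
      pauses[pred] <- sum(pauses[pred], pauses[i], na.rm = TRUE)
    }
  }
  keep_ids <- which(survives)
  pauses <- pauses[keep_ids]
  if (length(pauses)) pauses[length(pauses)] <- {
    ## a surviving utterance promoted to last position carries no trailing gap
    if (keep_ids[length(keep_ids)] == n_utt) pauses[length(pauses)] else NA_real_
  }
  tk2$utterance <- match(tk2$utterance, keep_ids)
  rownames(tk2) <- NULL
  list(response = structure(list(image_id = response$image_id, tokens = tk2,
                                 trailing_pause_s = pauses),
                            class = "image_response"),
       filled_pause_count = count)
}

#' Segment a timed token stream into utterances
#'
#' For transcripts that are not already segmented: a boundary is placed at
#' every inter-token silence of at least `min_pause_s` (inclusive threshold,
#' default 120 ms); shorter silences never create boundaries. The silence at
#' each boundary becomes the trailing gap of the utterance it closes.
#'
#' @param tokens Token data frame (no `utterance` column required).
#' @param silences_s Numeric vector of inter-token silences, length
#'   `nrow(tokens) - 1`, seconds.
#' @param min_pause_s Boundary threshold in seconds.
#' @param image_id Image id for the resulting response.
#' @return An [image_response()].
#' @export
segment_utterances <- function(tokens, silences_s, min_pause_s = 0.12,
                               image_id = 1L) {
  n <- nrow(tokens)
  if (length(silences_s) != n - 1L) {
    stop("silences_s must have length nrow(tokens) - 1")
  }
  if (any(silences_s < 0)) stop("silences_s: negative silence duration")
  boundary <- silences_s >= min_pause_s
  tokens$utterance <- cumsum(c(1L, as.integer(boundary)))
  pauses <- c(silences_s[boundary], NA_real_)
  structure(list(image_id = as.integer(image_id), tokens = tokens,
                 trailing_pause_s = pauses),
            class = "image_response")
}

subject_classes <- function() c("NOUN", "PRON")
predicate_classes <- function() c("VERB", "ADJ")

#' Is an utterance a complete sentence?
#'
#' True when some noun or pronoun precedes (not necessarily adjacently) a verb
#' or adjective within the utterance — the subject + predicate patterns
#' "noun/pronoun + main verb" and "noun/pronoun + adjective phrase". Any
#' verb-class token counts as a main verb; filled pauses are ignored.
#'
#' @param utterance A token data frame for one utterance, or a character
#'   vector of coarse classes in token order.
#' @return Logical.
#' @export
is_sentence <- function(utterance) {
  cls <- if (is.data.frame(utterance)) utterance$coarse_class else utterance
  if (is.data.frame(utterance) && "filled_pause" %in% names(utterance)) {
    cls <- cls[!utterance$filled_pause]
  }
  if (!length(cls)) return(FALSE)
  subj <- which(cls %in% subject_classes())
  pred <- which(cls %in% predicate_classes())
  length(subj) > 0L && length(pred) > 0L && min(subj) < max(pred)
}

## vectorized sentence flags over an image response
sentence_flags <- function(response) {
  tk <- response$tokens
  keep <- !tk$filled_pause
  cls <- tk$coarse_class[keep]
  utt <- tk$utterance[keep]
  n_utt <- utt_count(response)
  pos <- seq_along(cls)
  out <- logical(n_utt)
  subj <- cls %in% subject_classes()
  pred <- cls %in% predicate_classes()
  if (any(subj) && any(pred)) {
    first_subj <- vapply(split(pos[subj], factor(utt[subj], levels = seq_len(n_utt))),
                         function(v) if (length(v)) min(v) else NA_integer_, numeric(1))
    last_pred <- vapply(split(pos[pred], factor(utt[pred], levels = seq_len(n_utt))),
                        function(v) if (length(v)) max(v) else NA_integer_, numeric(1))
    out <- !is.na(first_subj) & !is.na(last_pred) & first_subj < last_pred
  }
  out
}

#' Count passive constructions in an utterance
#'
#' A bei marker counts when a noun or pronoun occurs somewhere before it and a
#' verb somewhere after (NP + bei + VP); a ba marker counts when a noun or
#' pronoun occurs after it, followed in turn by a verb (ba + NP + VP). Each
#' marker is counted at most once, so the count never exceeds the number of
#' marker tokens.
#'
#' @param utterance A token data frame for one utterance, or a character
#'   vector of coarse classes in token order.
#' @return Integer count.
#' @export
count_passives <- function(utterance) {
  cls <- if (is.data.frame(utterance)) utterance$coarse_class else utterance
  passive_count_vec(cls)
}

passive_count_vec <- function(cls) {
  n <- length(cls)
  if (!n) return(0L)
  np <- cls %in% subject_classes()
  vb <- cls == "VERB"
  count <- 0L
  for (m in which(cls == "PASSIVE_MARKER_BEI")) {
    if (m > 1L && any(np[seq_len(m - 1L)]) && m < n && any(vb[(m + 1L):n])) {
      count <- count + 1L
    }
  }
  for (m in which(cls == "PASSIVE_MARKER_BA")) {
    if (m < n) {
      np_after <- which(np & seq_len(n) > m)
      if (length(np_after) && any(vb & seq_len(n) > min(np_after))) {
        count <- count + 1L
      }
    }
  }
  count
}

## vectorized per-utterance passive counts
passive_counts <- function(response) {
  tk <- response$tokens
  n_utt <- utt_count(response)
  out <- integer(n_utt)
  marker <- grepl("^PASSIVE_MARKER", tk$coarse_class)
  if (!any(marker)) return(out)
  for (u in unique(tk$utterance[marker])) {
    out[u] <- passive_count_vec(tk$coarse_class[tk$utterance == u])
  }
  out
}

#' Count long silent pauses between utterances
#'
#' Long pauses are inter-utterance silences of `threshold_s` seconds or more
#' (inclusive; default 2 s). Silences inside utterances are never counted.
#'
#' @param response An [image_response()].
#' @param threshold_s Long-pause threshold in seconds.
#' @return Integer count, at most `number of utterances - 1`.
#' @export
count_long_pauses <- function(response, threshold_s = 2) {
  gaps <- response$trailing_pause_s
  sum(gaps >= threshold_s, na.rm = TRUE)
}

#' Apply the full cleaning pipeline to one image response
#'
#' Collapses immediate repetitions, separates filled pauses and tallies long
#' pauses, returning everything the feature extractors need.
#'
#' @param response An [image_response()].
#' @param long_pause_s Long-pause threshold in seconds.
#' @return An object of class `normalized_response`: the cleaned response,
#'   per-utterance word counts, `filled_pause_count` and `long_pause_count`.
#' @export
normalize_response <- function(response, long_pause_s = 2) {
  stopifnot(inherits(response, "image_response"))
  collapsed <- collapse_repetitions(response)
  sep <- separate_fillers(collapsed)
  cleaned <- sep$response
  words_per_utt <- tabulate(cleaned$tokens$utterance, nbins = utt_count(cleaned))
  structure(
    list(response = cleaned,
         word_tokens_per_utterance = words_per_utt,
         filled_pause_count = sep$filled_pause_count,
         long_pause_count = count_long_pauses(cleaned, long_pause_s)),
    class = "normalized_response")
}
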