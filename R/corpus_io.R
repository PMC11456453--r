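## Canonical vocabulary -------------------------------------------------------

#' Coarse word classes used throughout the package
#'
#' Content words are nouns, verbs, adjectives, pronouns and adverbs; the two
#' passive-construction markers (bei, ba) are tracked as their own classes so
#' syntactic patterns can be detected after part-of-speech tags have been
#' collapsed.
#'
#' @return Character vector of the eight coarse classes.
#' @export
coarse_classes <- function() {
  c("NOUN", "VERB", "ADJ", "PRON", "ADV",
    "PASSIVE_MARKER_BEI", "PASSIVE_MARKER_BA", "OTHER")
}

#' Content-word classes
#' @return Character vector of the five classes counted as content words.
#' @export
content_classes <- function() c("NOUN", "VERB", "ADJ", "PRON", "ADV")

#' Names of the fifteen linguistic features, in canonical order
#'
#' Order follows the standard presentation: lexical content (TW, UW, TTR, CW,
#' CD, CWF), syntactic complexity (U, S, MLU, MLS, PCR, VR, PR) and disfluency
#' (FR, LPR).
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("TW", "UW", "TTR", "CW", "CD", "CWF",
    "U", "S", "MLU", "MLS", "PCR", "VR", "PR",
    "FR", "LPR")
}

#' Cognitive outcome columns carried in a cohort table
#' @return Character vector of score column names.
#' @export
score_names <- function() {
  c("MMSE", "CDR_SB", "WLM_I", "WLM_II", "DS", "CTT1", "CTT2", "VF", "BNT")
}

token_flags <- function() c("filled_pause", "repetition", "revision", "incomplete")

cohort_columns <- function() {
  c("participant_id", "group", "age", "education", "gender",
    "suvr", "hippocampus_cm3", score_names())
}

## Tag mapping ----------------------------------------------------------------

#' Construct a part-of-speech tag mapping
#'
#' Maps raw tags from an upstream tagger onto the package's coarse classes and
#' records which surface forms act as bei/ba passive markers and which as
#' fillers. Tags absent from the map resolve to `OTHER`.
#'
#' @param tag_map Named character vector, raw tag -> coarse class.
#' @param bei_forms,ba_forms Surface forms of the bei / ba passive markers.
#'   The two lists must be disjoint.
#' @param filler_forms Surface forms commonly used as filled pauses. Informative
#'   only: fillerhood is always taken from the `filled_pause` annotation flag,
#'   never guessed from the surface form.
#' @return An object of class `tag_mapping`.
#' @export
tag_mapping <- function(tag_map, bei_forms = "被", ba_forms = "把",
                        filler_forms = character()) {
  tag_map <- unlist(tag_map)
  if (is.null(names(tag_map)) || any(!nzchar(names(tag_map)))) {
    stop("tag_map must be a named vector (raw_tag -> coarse_class)")
  }
  bad <- setdiff(unique(tag_map), coarse_classes())
  if (length(bad)) stop("unknown coarse class in tag_map: ", paste(bad, collapse = ", "))
  if (length(intersect(bei_forms, ba_forms))) {
    stop("bei_forms and ba_forms must be disjoint")
  }
  structure(
    list(tag_map = tag_map,
         bei_forms = as.character(bei_forms),
         ba_forms = as.character(ba_forms),
         filler_forms = as.character(filler_forms)),
    class = "tag_mapping"
  )
}

#' Default mapping for the CKIP tagset
#'
#' A documented approximation to the Chinese Knowledge and Information
#' Processing (CKIP) tagset: noun tags (Na, Nb, Nc, ...) map to `NOUN`, `Nh` to
#' `PRON`, all `V*` tags to `VERB`, `A` to `ADJ`, `D*` adverb tags to `ADV`,
#' and prepositions tagged `P` whose surface is a bei/ba form become passive
#' markers. Everything else is `OTHER`.
#'
#' @return A [tag_mapping()] object.
#' @export
default_tag_mapping <- function() {
  noun <- c("Na", "Nb", "Nc", "Ncd", "Nd", "Nv")
  verb <- c("VA", "VAC", "VB", "VC", "VCL", "VD", "VE", "VF", "VG", "VH",
            "VHC", "VI", "VJ", "VK", "VL", "V_2")
  adv  <- c("D", "Da", "Dfa", "Dfb", "Di", "Dk")
  other <- c("P", "T", "I", "C", "Caa", "Cab", "Cba", "Cbb", "DE", "SHI",
             "FW", "Neu", "Nes", "Nep", "Neqa", "Neqb", "Nf", "Ng")
  map <- c(
    stats::setNames(rep("NOUN", length(noun)), noun),
    Nh = "PRON",
    stats::setNames(rep("VERB", length(verb)), verb),
    A = "ADJ",
    stats::setNames(rep("ADV", length(adv)), adv),
    stats::setNames(rep("OTHER", length(other)), other)
  )
  tag_mapping(map,
              bei_forms = "被",
              ba_forms = "把",
              filler_forms = c("呃", "喯", "啊", "嗯"))
}

#' Resolve coarse classes for raw tags and surfaces
#'
#' A `P`-tagged (or otherwise mapped) token whose surface is a bei/ba form
#' becomes the corresponding passive marker; tokens flagged as filled pauses
#' are always `OTHER`; unknown raw tags resolve to `OTHER`.
#'
#' @param raw_tag,surface Character vectors of equal length.
#' @param filled_pause Logical vector (recycled), the filled-pause annotation.
#' @param mapping A [tag_mapping()].
#' @param quiet Suppress the note listing unknown tags.
#' @return Character vector of coarse classes.
#' @export
resolve_coarse_class <- function(raw_tag, surface, filled_pause = FALSE,
                                 mapping = default_tag_mapping(), quiet = FALSE) {
  stopifnot(inherits(mapping, "tag_mapping"))
  filled_pause <- rep_len(as.logical(filled_pause), length(raw_tag))
  cls <- unname(mapping$tag_map[raw_tag])
  unknown <- is.na(cls)
  if (any(unknown) && !quiet) {
    message("unknown raw tags mapped to OTHER: ",
            paste(unique(raw_tag[unknown]), collapse = ", "))
  }
  cls[unknown] <- "OTHER"
  cls[surface %in% mapping$bei_forms & !filled_pause] <- "PASSIVE_MARKER_BEI"
  cls[surface %in% mapping$ba_forms & !filled_pause] <- "PASSIVE_MARKER_BA"
  cls[filled_pause] <- "OTHER"
  cls
}

#' Read a tag mapping from JSON
#' @param path Path to a JSON file with fields `tag_map`, `bei_forms`,
#'   `ba_forms`, `filler_forms`.
#' @return A [tag_mapping()].
#' @export
read_tag_mapping <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tag_mapping(x$tag_map, x$bei_forms, x$ba_forms,
              if (is.null(x$filler_forms)) character() else x$filler_forms)
}

#' Write a tag mapping to JSON
#' @param mapping A [tag_mapping()].
#' @param path Output path.
#' @export
write_tag_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "tag_mapping"))
  jsonlite::write_json(
    list(tag_map = as.list(mapping$tag_map),
         bei_forms = mapping$bei_forms,
         ba_forms = mapping$ba_forms,
         filler_forms = mapping$filler_forms),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## Transcript containers ------------------------------------------------------

empty_token_frame <- function() {
  data.frame(utterance = integer(), surface = character(),
             char_count = integer(), raw_tag = character(),
             coarse_class = character(), filled_pause = logical(),
             repetition = logical(), revision = logical(),
             incomplete = logical(), stringsAsFactors = FALSE)
}

#' Build an image response from a token table
#'
#' The workhorse container for one picture description: a token table (one row
#' per token, with an `utterance` index, surface form, character count, raw and
#' coarse part-of-speech information and annotation flags) plus the silent-gap
#' durations trailing each utterance (`NA` for the last utterance, which has no
#' following gap).
#'
#' @param image_id Integer in 1..3.
#' @param tokens Data frame with columns `utterance`, `surface`, `char_count`,
#'   `raw_tag`, `coarse_class`, `filled_pause`, `repetition`, `revision`,
#'   `incomplete`.
#' @param trailing_pause_s Numeric vector, one value per utterance; the last
#'   entry must be `NA` (no trailing gap is recorded for the final utterance).
#' @return An object of class `image_response`.
#' @export
image_response <- function(image_id, tokens, trailing_pause_s) {
  validate_image_response(structure(
    list(image_id = as.integer(image_id),
         tokens = tokens,
         trailing_pause_s = as.numeric(trailing_pause_s)),
    class = "image_response"))
}

validate_image_response <- function(x) {
  tk <- x$tokens
  need <- names(empty_token_frame())
  missing_cols <- setdiff(need, names(tk))
  if (length(missing_cols)) {
    stop("image_response tokens missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tk) == 0L) stop("image_response must contain at least one token")
  utt <- tk$utterance
  n_utt <- max(utt)
  if (!all(utt %in% seq_len(n_utt)) || !all(seq_len(n_utt) %in% utt)) {
    stop("utterance indices must be consecutive starting at 1")
  }
  if (is.unsorted(utt)) stop("tokens must be ordered by utterance")
  if (any(tk$char_count < 1L)) stop("char_count: every token needs char_count >= 1")
  if (length(x$trailing_pause_s) != n_utt) {
    stop("trailing_pause_s must have one entry per utterance")
  }
  gaps <- x$trailing_pause_s[-n_utt]
  if (anyNA(gaps)) stop("trailing_pause_s: only the final utterance may omit its gap")
  if (any(gaps < 0)) stop("trailing_pause_s must be >= 0")
  if (!is.na(x$trailing_pause_s[n_utt])) {
    stop("trailing_pause_s: final utterance must not carry a trailing gap")
  }
  bad_cls <- setdiff(unique(tk$coarse_class), coarse_classes())
  if (length(bad_cls)) stop("unknown coarse_class: ", paste(bad_cls, collapse = ", "))
  if (any(tk$filled_pause & tk$coarse_class != "OTHER")) {
    stop("filled_pause tokens must have coarse_class OTHER")
  }
  if (any(tk$filled_pause & grepl("^PASSIVE_MARKER", tk$coarse_class))) {
    stop("passive-marker tokens cannot be filled pauses")
  }
  x
}

#' Build an annotated transcript
#'
#' @param participant_id Non-empty string.
#' @param responses List of [image_response()] objects, at most one per image.
#' @return An object of class `speech_transcript`.
#' @export
speech_transcript <- function(participant_id, responses) {
  if (!is.character(participant_id) || !nzchar(participant_id)) {
    stop("participant_id must be a non-empty string")
  }
  if (!length(responses)) stop("a transcript needs at least one image response")
  ids <- vapply(responses, function(r) r$image_id, integer(1))
  if (anyDuplicated(ids)) stop("image_id: at most one response per image")
  if (!all(ids %in% 1:3)) stop("image_id must be in 1..3")
  structure(list(participant_id = participant_id, responses = responses),
            class = "speech_transcript")
}

#' @export
print.speech_transcript <- function(x, ...) {
  n_tok <- sum(vapply(x$responses, function(r) nrow(r$tokens), integer(1)))
  cat(sprintf("<speech_transcript> participant %s: %d image(s), %d tokens\n",
              x$participant_id, length(x$responses), n_tok))
  invisible(x)
}

## Transcript JSON ------------------------------------------------------------

#' Read an annotated transcript from JSON
#'
#' The file format is a package-defined JSON schema:
#' `{participant_id, responses: [{image_id, utterances: [{tokens: [{surface,
#' char_count, raw_tag, flags}], trailing_pause_s}]}]}`. Coarse classes are
#' resolved through `mapping`; unknown raw tags map to `OTHER` with a note.
#' For purely CJK surfaces the stored `char_count` is validated against the
#' character length of the surface; romanized test surfaces are allowed, with
#' the stored count authoritative.
#'
#' @param path Path to a transcript JSON file (UTF-8).
#' @param mapping A [tag_mapping()]; defaults to the CKIP mapping.
#' @param quiet Suppress unknown-tag notes.
#' @return A [speech_transcript()].
#' @export
read_transcript <- function(path, mapping = default_tag_mapping(), quiet = FALSE) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed transcript JSON in '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  if (is.null(x$participant_id)) stop("participant_id: missing field")
  if (is.null(x$responses) || !length(x$responses)) stop("responses: missing or empty")
  responses <- lapply(x$responses, function(resp) {
    if (is.null(resp$image_id)) stop("image_id: missing field")
    if (is.null(resp$utterances) || !length(resp$utterances)) {
      stop("utterances: missing or empty for image ", resp$image_id)
    }
    n_utt <- length(resp$utterances)
    rows <- vector("list", n_utt)
    pauses <- rep(NA_real_, n_utt)
    for (i in seq_len(n_utt)) {
      u <- resp$utterances[[i]]
      if (is.null(u$tokens) || !length(u$tokens)) {
        stop("tokens: utterance ", i, " of image ", resp$image_id, " is empty")
      }
      tp <- u$trailing_pause_s
      if (!is.null(tp)) {
        if (!is.numeric(tp) || is.na(tp) || tp < 0) {
          stop("trailing_pause_s: must be a nonnegative number (utterance ", i, ")")
        }
        pauses[i] <- tp
      }
      surf <- vapply(u$tokens, function(t) {
        if (is.null(t$surface)) stop("surface: missing field in utterance ", i)
        as.character(t$surface)
      }, character(1))
      cc <- vapply(u$tokens, function(t) {
        if (is.null(t$char_count)) stop("char_count: missing field in utterance ", i)
        as.integer(t$char_count)
      }, integer(1))
      tag <- vapply(u$tokens, function(t) {
        if (is.null(t$raw_tag)) stop("raw_tag: missing field in utterance ", i)
        as.character(t$raw_tag)
      }, character(1))
      flags <- lapply(u$tokens, function(t) {
        fl <- unlist(t$flags)
        if (is.null(fl)) fl <- character()
        bad <- setdiff(fl, token_flags())
        if (length(bad)) stop("flags: unknown flag ", paste(bad, collapse = ", "))
        fl
      })
      if (any(cc < 1L)) stop("char_count: must be >= 1 (utterance ", i, ")")
      cjk <- grepl("^\\p{Han}+$", surf, perl = TRUE)
      mism <- cjk & cc != nchar(surf)
      if (any(mism)) {
        stop("char_count: does not match surface length for '",
             surf[which(mism)[1]], "'")
      }
      rows[[i]] <- data.frame(
        utterance = i, surface = surf, char_count = cc, raw_tag = tag,
        coarse_class = NA_character_,
        filled_pause = vapply(flags, function(f) "filled_pause" %in% f, logical(1)),
        repetition   = vapply(flags, function(f) "repetition" %in% f, logical(1)),
        revision     = vapply(flags, function(f) "revision" %in% f, logical(1)),
        incomplete   = vapply(flags, function(f) "incomplete" %in% f, logical(1)),
        stringsAsFactors = FALSE)
    }
    if (!is.na(pauses[n_utt])) {
      stop("trailing_pause_s: final utterance of image ", resp$image_id,
           " must not carry a trailing gap")
    }
    tk <- do.call(rbind, rows)
    tk$coarse_class <- resolve_coarse_class(tk$raw_tag, tk$surface,
                                            tk$filled_pause, mapping, quiet = quiet)
    image_response(resp$image_id, tk, pauses)
  })
  speech_transcript(as.character(x$participant_id), responses)
}

#' Write an annotated transcript to JSON
#'
#' Inverse of [read_transcript()]: `read_transcript(write_transcript(x))` is
#' the identity on valid transcripts (coarse classes are re-derived from the
#' raw tags on read).
#'
#' @param transcript A [speech_transcript()].
#' @param path Output path.
#' @export
write_transcript <- function(transcript, path) {
  stopifnot(inherits(transcript, "speech_transcript"))
  responses <- lapply(transcript$responses, function(resp) {
    utts <- lapply(seq_along(resp$trailing_pause_s), function(i) {
      tk <- resp$tokens[resp$tokens$utterance == i, , drop = FALSE]
      toks <- lapply(seq_len(nrow(tk)), function(j) {
        fl <- token_flags()[c(tk$filled_pause[j], tk$repetition[j],
                              tk$revision[j], tk$incomplete[j])]
        out <- list(surface = tk$surface[j], char_count = tk$char_count[j],
                    raw_tag = tk$raw_tag[j])
        out$flags <- as.list(fl)
        out
      })
      u <- list(tokens = toks)
      if (!is.na(resp$trailing_pause_s[i])) u$trailing_pause_s <- resp$trailing_pause_s[i]
      u
    })
    list(image_id = resp$image_id, utterances = utts)
  })
  jsonlite::write_json(list(participant_id = transcript$participant_id,
                            responses = responses),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Lexicon --------------------------------------------------------------------

#' Construct a word-frequency lexicon
#'
#' @param freq Named numeric vector, word -> corpus frequency (>= 0).
#' @param oov_policy How content-word-frequency averaging treats words missing
#'   from the lexicon: `"skip"` drops them from both numerator and denominator;
#'   `"min_frequency"` substitutes the smallest frequency in the lexicon.
#' @return An object of class `frequency_lexicon`.
#' @export
frequency_lexicon <- function(freq, oov_policy = c("skip", "min_frequency")) {
  oov_policy <- match.arg(oov_policy)
  if (is.null(names(freq)) || any(!nzchar(names(freq)))) {
    stop("lexicon frequencies must be named by word")
  }
  if (any(freq < 0)) stop("frequencies must be >= 0")
  structure(list(freq = freq, oov_policy = oov_policy), class = "frequency_lexicon")
}

#' @export
print.frequency_lexicon <- function(x, ...) {
  cat(sprintf("<frequency_lexicon> %d words, oov_policy = %s\n",
              length(x$freq), x$oov_policy))
  invisible(x)
}

#' Read a word-frequency lexicon from tab-separated text
#'
#' Two columns (word, frequency), UTF-8, no header. Duplicate words keep the
#' last entry with a warning; a non-numeric frequency is an error naming the
#' offending row.
#'
#' @param path Path to the TSV file.
#' @param oov_policy See [frequency_lexicon()].
#' @return A [frequency_lexicon()].
#' @export
read_lexicon <- function(path, oov_policy = "skip") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape)) stop("lexicon row ", bad_shape[1], ": expected word<TAB>frequency")
  words <- vapply(parts, `[`, character(1), 1L)
  freq <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(freq)) {
    stop("lexicon row ", which(is.na(freq))[1], ": non-numeric frequency")
  }
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warning("duplicate lexicon entries (last wins): ", paste(dup, collapse = ", "))
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]; freq <- freq[keep]
  }
  frequency_lexicon(stats::setNames(freq, words), oov_policy)
}

#' Write a lexicon as tab-separated text
#' @param lexicon A [frequency_lexicon()].
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "frequency_lexicon"))
  writeLines(paste(names(lexicon$freq),
                   formatC(lexicon$freq, digits = 17, format = "g"),
                   sep = "\t"),
             path, useBytes = FALSE)
  invisible(path)
}

## Cohort table ---------------------------------------------------------------

#' Read a cohort table from CSV
#'
#' Expected header: `participant_id, group, age, education, gender, suvr,
#' hippocampus_cm3` followed by the cognitive score columns (see
#' [score_names()]). `group` must be coded `NC` / `early_AD`; age and
#' education are required for every row; biomarker and score cells may be
#' empty (read as `NA`).
#'
#' @param path Path to the CSV file.
#' @return A data frame with class `cohort_table`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#' @param df Data frame with at least `participant_id`, `group`, `age`,
#'   `education`; optional columns are added as `NA` when absent.
#' @return `df` with class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  need <- c("participant_id", "group", "age", "education")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(df$participant_id[duplicated(df$participant_id)]), collapse = ", "))
  }
  bad_grp <- setdiff(unique(df$group), c("NC", "early_AD"))
  if (length(bad_grp)) stop("unknown group label: ", paste(bad_grp, collapse = ", "))
  if (anyNA(df$age)) stop("age: missing for participant ",
                          df$participant_id[which(is.na(df$age))[1]])
  if (anyNA(df$education)) stop("education: missing for participant ",
                                df$participant_id[which(is.na(df$education))[1]])
  for (col in setdiff(cohort_columns(), names(df))) df[[col]] <- NA_real_
  df <- df[, c(cohort_columns(), setdiff(names(df), cohort_columns())), drop = FALSE]
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#' @param cohort A cohort table.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(fmt_numeric_df(as.data.frame(cohort)), path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Feature tables -------------------------------------------------------------

fmt_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      x <- df[[nm]]
      out <- formatC(x, digits = 17, format = "g")
      out[is.na(x)] <- NA
      int_like <- !is.na(x) & x == round(x) & abs(x) < 1e15
      out[int_like] <- formatC(x[int_like], format = "d")
      df[[nm]] <- out
    }
  }
  df
}

#' Write a per-participant feature table
#'
#' One row per participant, feature columns in canonical [feature_names()]
#' order, written with enough digits that re-reading reproduces the doubles
#' bit-exactly.
#'
#' @param features Data frame with `participant_id` and all 15 feature columns.
#' @param path Output path (CSV).
#' @export
write_feature_table <- function(features, path) {
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) stop("feature table missing: ", paste(miss, collapse = ", "))
  if (!"participant_id" %in% names(features)) stop("feature table missing: participant_id")
  out <- features[, c("participant_id", feature_names()), drop = FALSE]
  utils::write.csv(fmt_numeric_df(out), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path Path to the CSV file.
#' @return Data frame with `participant_id` and the 15 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(feature_names(), names(df))
  if (length(miss)) stop("feature table missing: ", paste(miss, collapse = ", "))
  df
}
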