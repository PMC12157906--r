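#' @include scoring.R
NULL

#' Re-rank scored candidates and keep the top K
#'
#' Descending by relevance score; ties broken by smaller distance, then by
#' `(user_id, instance_id)`.
#'
#' @param scored data.frame from [scoreCandidates()].
#' @param top_k number of candidates to keep.
#' @return the `min(top_k, nrow(scored))` best rows.
#' @export
rerankTopK <- function(scored, top_k) {
  if (!nrow(scored)) stop("no scored candidates to re-rank")
  stopifnot(top_k >= 1L)
  ord <- order(-scored$score, scored$distance, scored$user_id,
               scored$instance_id)
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  head(out, min(top_k, nrow(out)))
}

#' Pick the two support shots from the re-ranked top K
#'
#' When both classes are present among the top candidates, the
#' highest-scored example of each class is taken (label balance); otherwise
#' the two highest-scored candidates overall. The higher-scored shot comes
#' first in the prompt.
#'
#' @param top data.frame from [rerankTopK()] with at least 2 rows.
#' @return 2-row data.frame (shot 1, shot 2).
#' @export
pickShots <- function(top) {
  if (nrow(top) < 2L) stop("need at least 2 candidates to build shots")
  labs <- unique(top$label)
  if (length(labs) >= 2L) {
    first_of <- function(lab) top[top$label == lab, , drop = FALSE][1L, ]
    shots <- rbind(first_of(.FATIGUE), first_of(.NON_FATIGUE))
    shots <- shots[order(-shots$score, shots$distance), , drop = FALSE]
  } else {
    shots <- top[1:2, , drop = FALSE]
  }
  rownames(shots) <- NULL
  shots
}

#' Build the two-shot classification prompt
#'
#' Each shot contributes its per-segment numeric summary, its relevance
#' score with reason, and a conclusion line stating its label; the query's
#' numeric data follow with the final single-word decision instruction.
#'
#' @param shots 2-row data.frame from [pickShots()].
#' @param query_fv named numeric feature vector of the new instance.
#' @param features the [FeatureSet-class] holding the shot instances.
#' @return character(1) prompt text.
#' @export
buildClassificationPrompt <- function(shots, query_fv, features) {
  stopifnot(nrow(shots) == 2L)
  pretty <- function(lab) ifelse(lab == .FATIGUE, "fatigue", "non-fatigue")
  blocks <- vapply(1:2, function(i) {
    fv <- featureVector(features, shots$instance_id[i])
    paste0("Example ", i, ":\n", formatSegmentBlock(fv), "\n",
           sprintf("Relevance score: %.4f. Reason: %s\n", shots$score[i],
                   shots$reason[i]),
           "Conclusion: The label is ", pretty(shots$label[i]), ".")
  }, character(1))
  paste0(
    "Classify a new accelerometer instance as fatigue or non-fatigue ",
    "using the two labeled examples below.\n\n",
    blocks[1], "\n\n", blocks[2], "\n\n",
    "New data:\n", formatSegmentBlock(query_fv), "\n\n",
    "Please compare the new data with Example 1 and Example 2 and ",
    "determine the final label: 'fatigue' or 'non-fatigue'. ",
    "Answer with a single word.")
}

#' Parse a classification reply into a label
#'
#' Total resolution of arbitrary reply text. A reply that normalizes to a
#' single label maps directly. Otherwise occurrences of "non-fatigue" are
#' counted first and consumed (so they are not double-counted as
#' "fatigue"), remaining "fatigue" occurrences are counted, and the higher
#' frequency wins; a tie (including no occurrences at all) resolves to the
#' label of the higher-relevance shot.
#'
#' @param reply_text any character(1) (NA allowed).
#' @param shots 2-row data.frame from [pickShots()] (tie resolution).
#' @return list with `label`, `raw_reply`, and `resolution` in
#'   `c("direct", "frequency_fallback", "tie_rule")`.
#' @examples
#' sh <- data.frame(instance_id = c("a", "b"), user_id = "u",
#'                  label = c("fatigue", "non_fatigue"),
#'                  distance = c(1, 2), score = c(0.9, 0.4),
#'                  reason = "", parse_status = "parsed")
#' parseLabelReply("Non-Fatigue", sh)$resolution  # direct
#' parseLabelReply("I believe it is non-fatigue, but maybe fatigue?", sh)
#' @export
parseLabelReply <- function(reply_text, shots) {
  if (length(reply_text) != 1L || is.na(reply_text)) reply_text <- ""
  norm <- tolower(trimws(reply_text))
  norm <- gsub("[_ ]+", "-", norm)
  bare <- gsub("^[^a-z]+|[^a-z]+$", "", gsub("non-fatigue", "nonfatigue", norm))
  if (bare == "nonfatigue")
    return(list(label = .NON_FATIGUE, raw_reply = reply_text,
                resolution = "direct"))
  if (bare == "fatigue")
    return(list(label = .FATIGUE, raw_reply = reply_text,
                resolution = "direct"))
  n_non <- length(gregexpr("non-?fatigue", norm)[[1]])
  if (gregexpr("non-?fatigue", norm)[[1]][1] == -1L) n_non <- 0L
  remaining <- gsub("non-?fatigue", "", norm)
  n_fat <- length(gregexpr("fatigue", remaining)[[1]])
  if (gregexpr("fatigue", remaining)[[1]][1] == -1L) n_fat <- 0L
  if (n_non > n_fat)
    list(label = .NON_FATIGUE, raw_reply = reply_text,
         resolution = "frequency_fallback")
  else if (n_fat > n_non)
    list(label = .FATIGUE, raw_reply = reply_text,
         resolution = "frequency_fallback")
  else
    list(label = shots$label[which.max(shots$score)], raw_reply = reply_text,
         resolution = "tie_rule")
}

# classification-stage reply; the heuristic backend answers with the label
# of the shot whose feature vector is nearer to the query (deterministic
# mock predictor closing the offline loop)
classificationReply <- function(backend, prompt, shots, query_fv, features) {
  if (is(backend, "HeuristicBackend")) {
    d <- vapply(shots$instance_id, function(id)
      euclideanDistance(featureVector(features, id), query_fv), numeric(1))
    lab <- shots$label[which.min(d)]
    return(ifelse(lab == .FATIGUE, "fatigue", "non-fatigue"))
  }
  completeWithRetry(backend, prompt)
}

#' Predict the label of one query instance (full hybrid pipeline)
#'
#' Composes distance filtering, relevance scoring, re-ranking, label-balanced
#' shot selection, prompt construction and reply parsing:
#' [nearestCandidates()] -> [scoreCandidates()] -> [rerankTopK()] ->
#' [pickShots()] -> [buildClassificationPrompt()] -> backend ->
#' [parseLabelReply()]. The query instance itself is never part of its own
#' candidate pool.
#'
#' @param query an `instance_id` in `features`, or a named feature vector.
#' @param features a [FeatureSet-class].
#' @param cfg a [SelectionConfig-class] (or preset; see
#'   [selectionPreset()]).
#' @param backend an [LLMBackend] implementation.
#' @param dk a [DomainKnowledge-class].
#' @param pool_ids optional explicit candidate pool (instance ids).
#' @return list with `label`, `resolution`, `raw_reply`, `shots` (2-row
#'   data.frame), `scored` (all scored candidates) and `transcripts`.
#' @export
predictLabel <- function(query, features, cfg = selectionPreset("paramA"),
                         backend = heuristicBackend(),
                         dk = defaultDomainKnowledge(), pool_ids = NULL) {
  validObject(cfg)
  query_fv <- if (is.character(query)) featureVector(features, query) else query
  cands <- nearestCandidates(query, features, distance_k = cfg@distance_k,
                             pool_ids = pool_ids)
  scored <- scoreCandidates(cands, query_fv, features, backend = backend,
                            dk = dk)
  top <- rerankTopK(scored, cfg@top_k)
  shots <- pickShots(top)
  prompt <- buildClassificationPrompt(shots, query_fv, features)
  reply <- classificationReply(backend, prompt, shots, query_fv, features)
  pred <- parseLabelReply(reply, shots)
  transcripts <- c(attr(scored, "transcripts"),
                   list(list(stage = "classification",
                             query_id = if (is.character(query)) query else NA_character_,
                             candidate_id = NA_character_,
                             prompt = prompt, reply = reply,
                             score = NA_real_, status = pred$resolution)))
  list(label = pred$label, resolution = pred$resolution,
       raw_reply = pred$raw_reply, shots = shots, scored = scored,
       transcripts = transcripts)
}
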