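#' @include AllClasses.R backends.R candidates.R
NULL

# "Segment k: mean=0.4321, std=..., ..." lines for a named 30-vector
formatSegmentBlock <- function(fv, n_segments = 3L) {
  base <- sub("^seg[0-9]+_", "", featureNames(n_segments)[1:10])
  lines <- vapply(seq_len(n_segments), function(k) {
    vals <- fv[paste0("seg", k, "_", base)]
    paste0("Segment ", k, ": ",
           paste(sprintf("%s=%.4f", base, vals), collapse = ", "))
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Render domain-knowledge rules as prompt text
#'
#' @param dk a [DomainKnowledge-class]; when disabled an empty string is
#'   returned (ablation mode).
#' @return character(1) bulleted rule text.
#' @export
renderDomainKnowledge <- function(dk) {
  if (!dk@enabled || !nrow(dk@rules)) return("")
  pretty <- function(lab) ifelse(lab == .FATIGUE, "fatigue", "non-fatigue")
  seg_text <- vapply(strsplit(as.character(dk@rules$segment), ","),
                     function(s) {
                       s <- trimws(s)
                       if (length(s) == 1L) paste("segment", s)
                       else paste("segments", paste(s, collapse = " and "))
                     }, character(1))
  lines <- sprintf("- %s %s %.2f in %s indicates %s.",
                   toupper(dk@rules$feature), dk@rules$op,
                   dk@rules$threshold, seg_text, pretty(dk@rules$implies))
  paste(c("Domain knowledge:", lines), collapse = "\n")
}

#' Class label implied by the domain-knowledge rules
#'
#' Evaluates every rule on a query's named feature vector; each fired rule
#' votes for its class and the majority wins. No fired rules, or a tie,
#' yields `NA` (indeterminate).
#'
#' @param fv named numeric feature vector (names as in [featureNames()]).
#' @param dk a [DomainKnowledge-class].
#' @return `"fatigue"`, `"non_fatigue"`, or `NA_character_`.
#' @export
dkImpliedLabel <- function(fv, dk) {
  if (!dk@enabled || !nrow(dk@rules)) return(NA_character_)
  r <- dk@rules
  fired <- vapply(seq_len(nrow(r)), function(i) {
    segs <- trimws(strsplit(as.character(r$segment[i]), ",")[[1]])
    val <- fv[paste0("seg", segs, "_", r$feature[i])]
    all(if (r$op[i] == ">") val > r$threshold[i] else val < r$threshold[i])
  }, logical(1))
  votes <- r$implies[fired]
  if (!length(votes)) return(NA_character_)
  nf <- sum(votes == .FATIGUE)
  nn <- sum(votes == .NON_FATIGUE)
  if (nf > nn) .FATIGUE else if (nn > nf) .NON_FATIGUE else NA_character_
}

#' Build the relevance-scoring prompt for one candidate
#'
#' The prompt presents the per-segment numeric features of the labeled
#' candidate and of the query, the candidate's label, the segment-by-segment
#' comparison guidance, the rendered domain-knowledge rules (when enabled),
#' and requests a reply in the `SCORE:`/`REASON:` template.
#'
#' @param candidate_fv,query_fv named numeric feature vectors.
#' @param candidate_label the candidate's class label.
#' @param dk a [DomainKnowledge-class].
#' @return character(1) prompt text.
#' @export
buildScoringPrompt <- function(candidate_fv, query_fv, candidate_label, dk) {
  candidate_label <- canonicalLabel(candidate_label)
  dk_text <- renderDomainKnowledge(dk)
  paste0(
    "You assess how relevant a labeled example is for classifying a new ",
    "accelerometer instance as fatigue or non-fatigue.\n\n",
    "Labeled subject (label: ",
    ifelse(candidate_label == .FATIGUE, "fatigue", "non-fatigue"), "):\n",
    formatSegmentBlock(candidate_fv), "\n\n",
    "New subject (unlabeled):\n",
    formatSegmentBlock(query_fv), "\n\n",
    "Please compare the numeric data segment by segment. If the differences ",
    "in Mean, Std, RMS etc. are very small => high relevance. Also check ",
    "whether the labeled subject labels (Fatigue/Non-Fatigue) are aligned ",
    "with the numeric pattern of the new subject.\n",
    if (nzchar(dk_text)) paste0(dk_text, "\n") else "",
    "\nReply with exactly two lines:\nSCORE: <number between 0 and 1>\n",
    "REASON: <one concise sentence>")
}

#' Parse a relevance-score reply
#'
#' Total function: extracts the first number after a case-insensitive
#' `SCORE` marker, clamping out-of-range values into [0, 1]
#' (`parse_status = "clamped"`); the text after a `REASON` marker becomes
#' the reason. Unparsable replies fall back to 0.5
#' (`parse_status = "fallback"`).
#'
#' @param reply_text any character(1) (NA allowed).
#' @return list with `value` in [0,1], `reason`, and `parse_status` in
#'   `c("parsed", "clamped", "fallback")`.
#' @examples
#' parseScoreReply("SCORE: 0.9\nREASON: close RMS")$value
#' parseScoreReply("score: 1.7 because")$parse_status  # "clamped"
#' parseScoreReply("cannot assess")$value              # 0.5
#' @export
parseScoreReply <- function(reply_text) {
  fallback <- list(value = 0.5, reason = "", parse_status = "fallback")
  if (length(reply_text) != 1L || is.na(reply_text)) return(fallback)
  m <- regmatches(reply_text,
                  regexpr("(?i)score\\s*[:=]?\\s*(-?[0-9]*\\.?[0-9]+)",
                          reply_text, perl = TRUE))
  if (!length(m)) return(fallback)
  value <- as.numeric(sub("(?i)score\\s*[:=]?\\s*", "", m, perl = TRUE))
  status <- "parsed"
  if (value < 0 || value > 1) {
    value <- min(max(value, 0), 1)
    status <- "clamped"
  }
  rm_ <- regmatches(reply_text,
                    regexpr("(?i)reason\\s*[:=]?\\s*[^\n]*", reply_text,
                            perl = TRUE))
  reason <- if (length(rm_))
    trimws(sub("(?i)reason\\s*[:=]?\\s*", "", rm_, perl = TRUE)) else ""
  list(value = value, reason = reason, parse_status = status)
}

#' Deterministic heuristic relevance score
#'
#' Closed-form stand-in for language-model scoring, so the whole pipeline
#' runs offline and reproducibly. The score combines a numeric-similarity
#' term with a label-synergy term:
#' `score = w_sim * exp(-distance / tau) + w_syn * synergy`, where the
#' synergy is 1 when the domain-knowledge rules imply the candidate's label
#' for the query, 0 when they contradict it, and 0.5 when indeterminate
#' (including ablation mode, where the score then depends on distance only).
#'
#' @param distance Euclidean distance between candidate and query.
#' @param candidate_label the candidate's class label.
#' @param implied_label the query's rule-implied label
#'   (see [dkImpliedLabel()]); `NA` for indeterminate.
#' @param w_sim,w_syn term weights (defaults 0.5 each).
#' @param tau positive distance scale of the similarity term.
#' @return list as in [parseScoreReply()], `parse_status = "parsed"`.
#' @export
heuristicScore <- function(distance, candidate_label, implied_label,
                           w_sim = 0.5, w_syn = 0.5, tau = 1) {
  stopifnot(tau > 0, distance >= 0)
  candidate_label <- canonicalLabel(candidate_label)
  sim <- exp(-distance / tau)
  syn <- if (is.na(implied_label)) 0.5
         else if (implied_label == candidate_label) 1 else 0
  value <- min(max(w_sim * sim + w_syn * syn, 0), 1)
  reason <- sprintf(
    "similarity %.3f at distance %.4f; rule-implied query label %s %s '%s'",
    sim, distance,
    if (is.na(implied_label)) "indeterminate" else implied_label,
    if (is.na(implied_label)) "vs" else if (syn == 1) "matches" else
      "contradicts",
    candidate_label)
  list(value = value, reason = reason, parse_status = "parsed")
}

#' Score distance-filtered candidates for contextual relevance
#'
#' Each candidate is scored independently against the query. With a
#' text-completing backend the scoring prompt is sent via [llmComplete()]
#' (one retry on transport failure, then a 0.5 fallback score); the
#' [HeuristicBackend][LLMBackend] short-circuits to [heuristicScore()] with
#' `tau` defaulting to the median candidate distance. Full prompt/reply
#' transcripts are attached to the result.
#'
#' @param candidates data.frame from [nearestCandidates()].
#' @param query named numeric feature vector, or an `instance_id`.
#' @param features the [FeatureSet-class] the candidates came from.
#' @param backend an [LLMBackend] implementation.
#' @param dk a [DomainKnowledge-class].
#' @return `candidates` with added columns `score`, `reason`,
#'   `parse_status` (input order preserved) and a `"transcripts"` attribute
#'   (list of per-candidate records).
#' @export
scoreCandidates <- function(candidates, query, features,
                            backend = heuristicBackend(),
                            dk = defaultDomainKnowledge()) {
  stopifnot(nrow(candidates) >= 1L)
  query_id <- NA_character_
  if (is.character(query) && length(query) == 1L) {
    query_id <- query
    query <- featureVector(features, query)
  }
  heuristic <- is(backend, "HeuristicBackend")
  tau <- NA_real_
  implied <- NA_character_
  if (heuristic) {
    tau <- backend@tau
    if (is.na(tau)) tau <- max(median(candidates$distance), 1e-9)
    implied <- dkImpliedLabel(query, dk)
  }
  out <- candidates
  out$score <- NA_real_
  out$reason <- NA_character_
  out$parse_status <- NA_character_
  transcripts <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand_fv <- featureVector(features, candidates$instance_id[i])
    prompt <- buildScoringPrompt(cand_fv, query, candidates$label[i], dk)
    if (heuristic) {
      sc <- heuristicScore(candidates$distance[i], candidates$label[i],
                           implied, w_sim = backend@w_sim,
                           w_syn = backend@w_syn, tau = tau)
      reply <- sprintf("SCORE: %.4f\nREASON: %s", sc$value, sc$reason)
    } else {
      reply <- completeWithRetry(backend, prompt)
      sc <- parseScoreReply(reply)
    }
    out$score[i] <- sc$value
    out$reason[i] <- sc$reason
    out$parse_status[i] <- sc$parse_status
    transcripts[[i]] <- list(stage = "scoring", query_id = query_id,
                             candidate_id = candidates$instance_id[i],
                             prompt = prompt, reply = reply,
                             score = sc$value, status = sc$parse_status)
  }
  attr(out, "transcripts") <- transcripts
  out
}
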