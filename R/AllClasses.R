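#' @include hedlm-package.R
NULL

## ---- FilterSpec -------------------------------------------------------------

#' Low-pass filter specification
#'
#' Parameters of the zero-phase Butterworth low-pass filter applied to each
#' trace segment: cutoff frequency in Hz, filter order, and the sampling
#' frequency of the signal. The cutoff must lie strictly below the Nyquist
#' frequency `fs/2`.
#'
#' @slot cutoff_hz numeric(1), cutoff frequency in Hz.
#' @slot order integer(1), filter order (>= 1).
#' @slot fs numeric(1), sampling frequency in Hz.
#' @export
setClass("FilterSpec",
  representation(cutoff_hz = "numeric", order = "integer", fs = "numeric"),
  prototype(cutoff_hz = 30, order = 4L, fs = 256))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (length(object@cutoff_hz) != 1L || !is.finite(object@cutoff_hz) ||
      object@cutoff_hz <= 0 || object@cutoff_hz >= object@fs / 2)
    msg <- c(msg, "cutoff_hz must satisfy 0 < cutoff_hz < fs/2")
  if (length(object@order) != 1L || is.na(object@order) || object@order < 1L)
    msg <- c(msg, "order must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @param cutoff_hz,order,fs see slots.
#' @rdname FilterSpec-class
#' @return `filterSpec()` returns a validated `FilterSpec`.
#' @examples
#' filterSpec()                 # 30 Hz cutoff, order 4, 256 Hz sampling
#' filterSpec(cutoff_hz = 20)
#' @export
filterSpec <- function(cutoff_hz = 30, order = 4L, fs = 256) {
  new("FilterSpec", cutoff_hz = cutoff_hz, order = as.integer(order), fs = fs)
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: Butterworth low-pass, order %d, cutoff %g Hz @ fs %g Hz (normalized %.6f)\n",
    object@order, object@cutoff_hz, object@fs,
    object@cutoff_hz / (object@fs / 2)))
})

## ---- TraceSet / FeatureSet --------------------------------------------------

#' Set of labeled acceleration-magnitude traces
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"magnitude"` holds one trace per column (rows are time samples, 180 by
#' default). `colData` carries `user_id`, `instance_id` and `label`
#' (`"fatigue"`, `"non_fatigue"`, or `NA` for unlabeled queries); the
#' sampling frequency is stored in `metadata(x)$fs`.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("user_id", "instance_id", "label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData is missing:", paste(miss, collapse = ", ")))
  if (!"magnitude" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'magnitude' is required")
  else if (!all(is.finite(assay(object, "magnitude"))))
    msg <- c(msg, "all magnitude samples must be finite")
  fs <- metadata(object)$fs
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    msg <- c(msg, "metadata(x)$fs must be a positive sampling frequency")
  if (!length(miss) && anyDuplicated(cd$instance_id))
    msg <- c(msg, "instance_id values must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a TraceSet
#'
#' @param samples numeric matrix, one trace per column (`n_samples` rows).
#' @param user_id,instance_id,label per-trace column metadata; `label` may
#'   contain `NA` and is canonicalized via [canonicalLabel()].
#' @param fs sampling frequency in Hz.
#' @return a validated [TraceSet-class].
#' @examples
#' m <- matrix(rnorm(360, 9.8), nrow = 180)
#' ts <- traceSet(m, user_id = c("u1", "u1"), instance_id = c("i1", "i2"),
#'                label = c("fatigue", "non-fatigue"))
#' traceLength(ts)
#' @export
traceSet <- function(samples, user_id, instance_id = NULL, label = NA,
                     fs = 256) {
  samples <- as.matrix(samples)
  n <- ncol(samples)
  if (is.null(instance_id)) instance_id <- sprintf("inst%04d", seq_len(n))
  label <- canonicalLabel(rep_len(label, n))
  cd <- DataFrame(user_id = as.character(rep_len(user_id, n)),
                  instance_id = as.character(instance_id),
                  label = label)
  dimnames(samples) <- list(NULL, cd$instance_id)
  se <- SummarizedExperiment(assays = list(magnitude = samples), colData = cd,
                             metadata = list(fs = fs))
  new("TraceSet", se)
}

#' Set of 30-dimensional feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay `"features"`
#' holds one feature vector per column. Rows are the 30 features in fixed
#' order (10 per segment, segments first): for each segment
#' `mean, std, min, max, peak_to_peak, rms, skewness, kurtosis,
#' dominant_freq, low_freq_energy`. `colData` mirrors [TraceSet-class];
#' `metadata` records the filter specification and the low-frequency band
#' edge used during extraction.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  cd <- colData(object)
  miss <- setdiff(c("user_id", "instance_id", "label"), colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData is missing:", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'features' is required")
  } else {
    m <- assay(object, "features")
    if (!all(is.finite(m))) msg <- c(msg, "all feature values must be finite")
    if (!identical(rownames(m), featureNames()))
      msg <- c(msg, "feature rows must match featureNames() exactly")
  }
  if (length(msg)) msg else TRUE
})

#' Canonical feature names and ordering
#'
#' @param n_segments number of trace segments (default 3).
#' @return character vector `seg<k>_<feature>` in the fixed extraction order.
#' @examples
#' featureNames()[1:10]
#' @export
featureNames <- function(n_segments = 3L) {
  base <- c("mean", "std", "min", "max", "peak_to_peak", "rms",
            "skewness", "kurtosis", "dominant_freq", "low_freq_energy")
  as.vector(t(outer(paste0("seg", seq_len(n_segments), "_"), base, paste0)))
}

featureSetFromMatrix <- function(values, colData, filter = filterSpec(),
                                 low_band_hz = 10) {
  rownames(values) <- featureNames(nrow(values) / 10L)
  colnames(values) <- colData$instance_id
  se <- SummarizedExperiment(
    assays = list(features = values), colData = colData,
    metadata = list(filter = filter, low_band_hz = low_band_hz))
  new("FeatureSet", se)
}

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet: %d traces x %d samples @ %g Hz, %d user(s)\n",
              ncol(object), nrow(object), metadata(object)$fs,
              length(unique(colData(object)$user_id))))
  print(table(label = colData(object)$label, useNA = "ifany"))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d instances x %d features, %d user(s)\n",
              ncol(object), nrow(object),
              length(unique(colData(object)$user_id))))
})

## ---- SelectionConfig --------------------------------------------------------

#' Candidate-selection configuration
#'
#' `distance_k` nearest labeled candidates are retained by Euclidean
#' filtering; the `top_k` highest relevance scores survive re-ranking
#' (`1 <= top_k <= distance_k`). Two named presets match the reference
#' configurations: `"paramA"` (5, 3) and `"paramB"` (10, 5).
#'
#' @slot distance_k integer(1), candidates kept after distance filtering.
#' @slot top_k integer(1), candidates kept after relevance re-ranking.
#' @export
setClass("SelectionConfig",
  representation(distance_k = "integer", top_k = "integer"),
  prototype(distance_k = 5L, top_k = 3L))

setValidity("SelectionConfig", function(object) {
  if (length(object@distance_k) != 1L || length(object@top_k) != 1L ||
      is.na(object@distance_k) || is.na(object@top_k) ||
      object@top_k < 1L || object@top_k > object@distance_k)
    "need 1 <= top_k <= distance_k" else TRUE
})

#' @param distance_k,top_k see slots.
#' @rdname SelectionConfig-class
#' @examples
#' selectionConfig(10, 5)
#' selectionPreset("paramA")
#' @export
selectionConfig <- function(distance_k = 5L, top_k = 3L) {
  new("SelectionConfig", distance_k = as.integer(distance_k),
      top_k = as.integer(top_k))
}

#' @param name `"paramA"` (distance_k 5, top_k 3) or `"paramB"` (10, 5).
#' @rdname SelectionConfig-class
#' @export
selectionPreset <- function(name = c("paramA", "paramB")) {
  switch(match.arg(name),
         paramA = selectionConfig(5L, 3L),
         paramB = selectionConfig(10L, 5L))
}

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf("SelectionConfig: distance_k = %d, top_k = %d\n",
              object@distance_k, object@top_k))
})

## ---- DomainKnowledge --------------------------------------------------------

#' Domain-knowledge threshold rules
#'
#' A small rule base over named segment features, injected into scoring
#' prompts and used by the deterministic heuristic scorer to decide which
#' class a query's signal pattern suggests. Each rule fires when
#' `feature <op> threshold` holds for the named segment and then votes for
#' `implies`.
#'
#' @slot rules data.frame with columns `segment` (character; a segment
#'   index or a comma-separated conjunction like `"2,3"` that must hold in
#'   every listed segment), `feature` (character, one of the 10 per-segment
#'   feature names), `op` (`">"` or `"<"`), `threshold` (numeric),
#'   `implies` (`"fatigue"`/`"non_fatigue"`).
#' @slot enabled logical(1); when `FALSE` the rules are withheld from
#'   prompts and the heuristic synergy term is indeterminate (ablation mode).
#' @export
setClass("DomainKnowledge",
  representation(rules = "data.frame", enabled = "logical"),
  prototype(rules = data.frame(), enabled = TRUE))

setValidity("DomainKnowledge", function(object) {
  msg <- character()
  r <- object@rules
  if (nrow(r)) {
    need <- c("segment", "feature", "op", "threshold", "implies")
    if (!all(need %in% colnames(r)))
      return(paste("rules need columns:", paste(need, collapse = ", ")))
    base <- sub("^seg[0-9]+_", "", featureNames())
    if (!all(r$feature %in% base))
      msg <- c(msg, "rules reference unknown feature names")
    if (!all(r$op %in% c(">", "<")))
      msg <- c(msg, "rule op must be '>' or '<'")
    if (!all(r$implies %in% .LABELS))
      msg <- c(msg, "rule implies must be 'fatigue' or 'non_fatigue'")
    segs <- unlist(strsplit(as.character(r$segment), ","))
    if (!all(trimws(segs) %in% c("1", "2", "3")))
      msg <- c(msg, "rule segment entries must be 1, 2 or 3")
  }
  if (length(msg)) msg else TRUE
})

#' @param rules,enabled see slots.
#' @rdname DomainKnowledge-class
#' @export
domainKnowledge <- function(rules, enabled = TRUE) {
  new("DomainKnowledge", rules = rules, enabled = enabled)
}

#' Default fatigue-detection rule base
#'
#' The two canonical expert thresholds on min-max-normalized segments:
#' RMS above 0.5 in segments 2 and 3 (jointly) indicates fatigue, and a
#' segment mean below 0.31 strongly suggests fatigue. The RMS rule is
#' conjunctive over the two late segments, which keeps its precision high
#' on borderline signals.
#'
#' @param enabled set `FALSE` for the ablation (no-domain-knowledge) mode.
#' @return a [DomainKnowledge-class] object.
#' @examples
#' defaultDomainKnowledge()
#' @export
defaultDomainKnowledge <- function(enabled = TRUE) {
  domainKnowledge(data.frame(
    segment = c("2,3", "1", "2", "3"),
    feature = c("rms", "mean", "mean", "mean"),
    op = c(">", "<", "<", "<"),
    threshold = c(0.5, 0.31, 0.31, 0.31),
    implies = rep(.FATIGUE, 4)), enabled = enabled)
}

setMethod("show", "DomainKnowledge", function(object) {
  cat(sprintf("DomainKnowledge: %d rule(s), %s\n", nrow(object@rules),
              if (object@enabled) "enabled" else "disabled (ablation)"))
  if (nrow(object@rules)) print(object@rules)
})

## ---- MethodScoreTable -------------------------------------------------------

#' Users x methods macro-F1 table
#'
#' The per-user macro F1 scores (in percent) of each compared selection
#' method; the input of the statistical comparison suite.
#'
#' @slot values numeric matrix, users in rows, methods in columns, no
#'   missing cells.
#' @export
setClass("MethodScoreTable", representation(values = "matrix"))

setValidity("MethodScoreTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || anyNA(v)) msg <- c(msg, "values must be numeric with no missing cells")
  if (nrow(v) < 2L || ncol(v) < 2L) msg <- c(msg, "need at least 2 users and 2 methods")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have user rownames and method colnames")
  if (length(msg)) msg else TRUE
})

#' @param values see slot; a users x methods numeric matrix with dimnames.
#' @rdname MethodScoreTable-class
#' @export
methodScoreTable <- function(values) {
  new("MethodScoreTable", values = as.matrix(values))
}

#' @describeIn MethodScoreTable-class extract the score matrix.
#' @param x a `MethodScoreTable`.
#' @export
scoreMatrix <- function(x) {
  stopifnot(is(x, "MethodScoreTable"))
  x@values
}

setMethod("show", "MethodScoreTable", function(object) {
  v <- object@values
  cat(sprintf("MethodScoreTable: %d users x %d methods (macro F1, %%)\n",
              nrow(v), ncol(v)))
  print(round(rbind(v, `(mean)` = colMeans(v)), 2))
})

## ---- SyntheticSpec ----------------------------------------------------------

#' Synthetic dataset specification
#'
#' Parameters of the seeded gait-proxy generator. Each class is a
#' harmonic-plus-noise stride waveform; `overlap` interpolates both class
#' parameter sets toward their common midpoint (0 = fully separated classes,
#' 1 = identical classes). See `vignette("hedlm-methods")` for the waveform
#' model and the rationale behind the class defaults.
#'
#' @slot n_users,instances_per_user integer(1).
#' @slot class_balance numeric(1) in (0,1), probability of the fatigue class.
#' @slot stride_freq_hz numeric(1), nominal stride frequency in Hz.
#' @slot fatigue_params,nonfatigue_params named lists with elements
#'   `baseline_mean`, `oscillation_amp`, `noise_sd` (m/s^2), `drift`
#'   (signed slope, m/s^2 per second), `square_mix` (0..1, weight of the
#'   square-loading archetype vs the impact-pulse archetype),
#'   `square_duty` (duty offset of the square wave; larger means less time
#'   in the high-loading phase), `square_soft` (transition softness),
#'   `tri_amp` (triangular bulk amplitude), `pulse_amp` (positive impact
#'   pulse amplitude), `dip_amp` (free-fall dip amplitude).
#' @slot overlap numeric(1) in [0,1].
#' @slot seed integer(1), master seed of the dataset-level RNG stream.
#' @export
setClass("SyntheticSpec",
  representation(n_users = "integer", instances_per_user = "integer",
                 class_balance = "numeric", stride_freq_hz = "numeric",
                 fatigue_params = "list", nonfatigue_params = "list",
                 overlap = "numeric", seed = "integer"))

.PARAM_FIELDS <- c("baseline_mean", "oscillation_amp", "noise_sd", "drift",
                   "square_mix", "square_duty", "square_soft", "tri_amp",
                   "pulse_amp", "dip_amp")

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@n_users < 1L || object@instances_per_user < 2L)
    msg <- c(msg, "need n_users >= 1 and instances_per_user >= 2")
  if (object@class_balance <= 0 || object@class_balance >= 1)
    msg <- c(msg, "class_balance must lie in (0,1)")
  if (object@overlap < 0 || object@overlap > 1)
    msg <- c(msg, "overlap must lie in [0,1]")
  if (object@stride_freq_hz <= 0)
    msg <- c(msg, "stride_freq_hz must be positive")
  for (side in c("fatigue_params", "nonfatigue_params")) {
    p <- slot(object, side)
    if (!all(.PARAM_FIELDS %in% names(p)))
      msg <- c(msg, paste(side, "must contain:",
                          paste(.PARAM_FIELDS, collapse = ", ")))
    else {
      pos <- c("baseline_mean", "oscillation_amp", "noise_sd", "square_soft")
      if (any(unlist(p[pos]) <= 0))
        msg <- c(msg, paste(side, "physical parameters must be positive"))
      if (p$square_mix < 0 || p$square_mix > 1)
        msg <- c(msg, paste(side, "square_mix must lie in [0,1]"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param n_users,instances_per_user,class_balance,stride_freq_hz,overlap,seed
#'   see slots.
#' @param fatigue_params,nonfatigue_params optional overrides of the class
#'   defaults (lists merged by name).
#' @rdname SyntheticSpec-class
#' @examples
#' syntheticSpec(n_users = 3, instances_per_user = 40, seed = 7)
#' @export
syntheticSpec <- function(n_users = 5L, instances_per_user = 60L,
                          class_balance = 0.5, stride_freq_hz = 2.5,
                          overlap = 0.5, seed = 1L,
                          fatigue_params = list(), nonfatigue_params = list()) {
  fat <- list(baseline_mean = 9.0, oscillation_amp = 3.0, noise_sd = 0.2,
              drift = -0.8, square_mix = 1, square_duty = 0.60,
              square_soft = 0.04, tri_amp = 0.10, pulse_amp = 1.05,
              dip_amp = 0.35)
  non <- list(baseline_mean = 9.8, oscillation_amp = 3.5, noise_sd = 0.2,
              drift = 0.1, square_mix = 0, square_duty = 0.60,
              square_soft = 0.04, tri_amp = 0.10, pulse_amp = 1.05,
              dip_amp = 0.35)
  new("SyntheticSpec", n_users = as.integer(n_users),
      instances_per_user = as.integer(instances_per_user),
      class_balance = class_balance, stride_freq_hz = stride_freq_hz,
      fatigue_params = modifyList(fat, fatigue_params),
      nonfatigue_params = modifyList(non, nonfatigue_params),
      overlap = overlap, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d user(s) x %d instances, ",
                     "balance %.2f, overlap %.2f, seed %d\n"),
              object@n_users, object@instances_per_user,
              object@class_balance, object@overlap, object@seed))
})

## ---- LLM backends -----------------------------------------------------------

#' Language-model backends
#'
#' A backend turns a prompt string into a reply string via [llmComplete()].
#' Three implementations ship with the package:
#' \describe{
#'   \item{`ScriptedBackend`}{replays a fixed prompt-to-reply map (exact
#'     prompt match, else the default reply); for tests and transcripts.}
#'   \item{`HeuristicBackend`}{fully offline deterministic stand-in: scoring
#'     requests are answered from the closed-form relevance formula
#'     ([heuristicScore()]) and classification requests with the label of
#'     the shot whose features are nearer to the query.}
#'   \item{`ApiBackend`}{remote chat-completions endpoint; requires network
#'     access and an API key in the environment variable named by
#'     `api_key_env`.}
#' }
#'
#' @slot model_name character(1) label recorded in transcripts.
#' @slot temperature numeric(1), sampling temperature passed to remote
#'   models (default 0.3).
#' @aliases LLMBackend-class ScriptedBackend-class HeuristicBackend-class
#'   ApiBackend-class
#' @name LLMBackend
NULL

#' @rdname LLMBackend
#' @export
setClass("LLMBackend",
  representation("VIRTUAL", model_name = "character", temperature = "numeric"),
  prototype(model_name = "unspecified", temperature = 0.3))

#' @rdname LLMBackend
#' @export
setClass("ScriptedBackend", contains = "LLMBackend",
  representation(replies = "character", default_reply = "character"),
  prototype(replies = character(), default_reply = "SCORE: 0.5\nREASON: scripted default",
            model_name = "scripted"))

#' @rdname LLMBackend
#' @export
setClass("HeuristicBackend", contains = "LLMBackend",
  representation(w_sim = "numeric", w_syn = "numeric", tau = "numeric"),
  prototype(w_sim = 0.5, w_syn = 0.5, tau = NA_real_, model_name = "heuristic"))

setValidity("HeuristicBackend", function(object) {
  if (object@w_sim < 0 || object@w_syn < 0 ||
      (!is.na(object@tau) && object@tau <= 0))
    "weights must be non-negative and tau positive" else TRUE
})

#' @rdname LLMBackend
#' @export
setClass("ApiBackend", contains = "LLMBackend",
  representation(endpoint = "character", api_key_env = "character"),
  prototype(endpoint = "https://api.openai.com/v1/chat/completions",
            api_key_env = "OPENAI_API_KEY", model_name = "gpt-4o-mini"))

#' @param replies named character vector mapping exact prompts to replies.
#' @param default_reply reply for prompts absent from `replies`.
#' @param model_name,temperature recorded in transcripts.
#' @rdname LLMBackend
#' @examples
#' b <- scriptedBackend(default_reply = "SCORE: 0.3\nREASON: constant")
#' llmComplete(b, "anything")
#' @export
scriptedBackend <- function(replies = character(),
                            default_reply = "SCORE: 0.5\nREASON: scripted default",
                            model_name = "scripted", temperature = 0.3) {
  new("ScriptedBackend", replies = replies, default_reply = default_reply,
      model_name = model_name, temperature = temperature)
}

#' @param w_sim,w_syn weights of the similarity and label-synergy terms.
#' @param tau distance scale of the similarity term; `NA` (default) uses the
#'   median candidate distance of the pool being scored.
#' @rdname LLMBackend
#' @export
heuristicBackend <- function(w_sim = 0.5, w_syn = 0.5, tau = NA_real_,
                             model_name = "heuristic") {
  new("HeuristicBackend", w_sim = w_sim, w_syn = w_syn, tau = tau,
      model_name = model_name, temperature = 0)
}

#' @param endpoint chat-completions URL.
#' @param api_key_env name of the environment variable holding the API key.
#' @rdname LLMBackend
#' @export
apiBackend <- function(model_name = "gpt-4o-mini", temperature = 0.3,
                       endpoint = "https://api.openai.com/v1/chat/completions",
                       api_key_env = "OPENAI_API_KEY") {
  new("ApiBackend", model_name = model_name, temperature = temperature,
      endpoint = endpoint, api_key_env = api_key_env)
}

setMethod("show", "LLMBackend", function(object) {
  cat(sprintf("<%s> model '%s', temperature %g\n", class(object),
              object@model_name, object@temperature))
})
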