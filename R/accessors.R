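#' @include AllClasses.R
NULL

#' Accessors for TraceSet and FeatureSet column metadata
#'
#' Convenience accessors over the underlying
#' [SummarizedExperiment::colData()]: per-instance identifiers, user ids
#' and class labels, plus the trace geometry.
#'
#' @param x a [TraceSet-class] or [FeatureSet-class].
#' @return character vectors (`instanceIds`, `userIds`, `instanceLabels`)
#'   or single numbers (`traceLength`, `sampleRate`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
instanceIds <- function(x) as.character(colData(x)$instance_id)

#' @rdname accessors
#' @export
userIds <- function(x) as.character(colData(x)$user_id)

#' @rdname accessors
#' @export
instanceLabels <- function(x) as.character(colData(x)$label)

#' @rdname accessors
#' @export
traceLength <- function(x) {
  stopifnot(is(x, "TraceSet"))
  nrow(x)
}

#' @rdname accessors
#' @export
sampleRate <- function(x) {
  stopifnot(is(x, "TraceSet"))
  metadata(x)$fs
}
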