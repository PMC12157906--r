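#' @include AllClasses.R
NULL

#' Euclidean distance between feature vectors
#'
#' @param a,b numeric vectors of equal length (30 in the standard pipeline).
#' @return non-negative distance; 0 iff the vectors are identical.
#' @examples
#' euclideanDistance(c(0, 3), c(4, 0))  # 5
#' @export
euclideanDistance <- function(a, b) {
  if (length(a) != length(b))
    stop("feature vectors differ in length (", length(a), " vs ",
         length(b), ")")
  sqrt(sum((a - b)^2))
}

# feature column lookup by instance_id
featureVector <- function(features, instance_id) {
  j <- match(instance_id, colData(features)$instance_id)
  if (is.na(j)) stop("unknown instance_id: ", instance_id)
  assay(features, "features")[, j]
}

#' Distance-filtered candidate pool for a query
#'
#' Ranks the labeled pool instances by Euclidean distance to the query
#' feature vector and keeps the `distance_k` nearest. Exact distance ties
#' are broken by `(user_id, instance_id)` for platform-independent
#' reproducibility.
#'
#' @param query numeric feature vector, or an `instance_id` present in
#'   `features` (which is then excluded from the pool automatically).
#' @param features a [FeatureSet-class] holding the pool.
#' @param distance_k number of candidates to keep.
#' @param pool_ids optional character vector restricting the pool (e.g. to
#'   one user, or to enforce the leakage contract explicitly). Instances
#'   without a label are always dropped.
#' @return data.frame with columns `instance_id`, `user_id`, `label`,
#'   `distance`, sorted by ascending distance.
#' @export
nearestCandidates <- function(query, features, distance_k = 5L,
                              pool_ids = NULL) {
  stopifnot(is(features, "FeatureSet"))
  cd <- as.data.frame(colData(features))
  if (is.character(query) && length(query) == 1L) {
    qid <- query
    query <- featureVector(features, qid)
    if (is.null(pool_ids)) pool_ids <- setdiff(cd$instance_id, qid)
    else if (qid %in% pool_ids)
      stop("query instance ", qid, " must not appear in its own pool")
  }
  if (is.null(pool_ids)) pool_ids <- cd$instance_id
  keep <- cd$instance_id %in% pool_ids & !is.na(cd$label)
  if (!any(keep)) stop("candidate pool is empty")
  mat <- assay(features, "features")[, keep, drop = FALSE]
  d <- sqrt(colSums((mat - query)^2))
  out <- data.frame(instance_id = cd$instance_id[keep],
                    user_id = cd$user_id[keep],
                    label = cd$label[keep],
                    distance = unname(d),
                    stringsAsFactors = FALSE)
  ord <- order(out$distance, out$user_id, out$instance_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  head(out, min(distance_k, nrow(out)))
}
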