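#' @include inference.R
NULL

#' Macro F1 score for binary labels
#'
#' Unweighted mean of the per-class F1 scores over both classes
#' (fatigue, non-fatigue), with a class's F1 defined as 0 when its
#' precision and recall are both 0. Both classes always enter the mean,
#' whether or not they occur in `truth`.
#'
#' @param truth,pred equal-length label vectors
#'   (canonicalized via [canonicalLabel()]).
#' @return numeric(1) in [0, 1].
#' @examples
#' macroF1(c("fatigue", "non_fatigue"), c("fatigue", "fatigue"))  # 1/3
#' @export
macroF1 <- function(truth, pred) {
  if (length(truth) != length(pred) || !length(truth))
    stop("truth and pred must have equal positive length")
  truth <- canonicalLabel(truth)
  pred <- canonicalLabel(pred)
  f1 <- vapply(.LABELS, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Per-user evaluation split
#'
#' Builds the leakage-free per-user split: one seeded train pair (the first
#' fatigue and first non-fatigue instance in shuffled pool order) for the
#' offline ML baseline, with every remaining instance a test instance. All
#' prompt-based methods reuse exactly this test set; each test instance's
#' candidate pool is the user's full slice minus the instance itself.
#'
#' @param features a [FeatureSet-class].
#' @param user a `user_id` present in `features`.
#' @param seed integer seed for the train-pair shuffle.
#' @return list with `user_id`, `all_ids`, `train_pair` (2 ids, one per
#'   class), `test_ids`.
#' @export
makeUserSplit <- function(features, user, seed = 42L) {
  cd <- as.data.frame(colData(features))
  cd <- cd[cd$user_id == user & !is.na(cd$label), , drop = FALSE]
  if (!nrow(cd)) stop("no labeled instances for user ", user)
  if (length(unique(cd$label)) < 2L)
    stop("user ", user, " lacks one of the two classes")
  perm <- withSeed(seed, sample.int(nrow(cd)))
  shuffled <- cd[perm, , drop = FALSE]
  pair <- c(shuffled$instance_id[match(.FATIGUE, shuffled$label)],
            shuffled$instance_id[match(.NON_FATIGUE, shuffled$label)])
  list(user_id = user, all_ids = cd$instance_id, train_pair = pair,
       test_ids = setdiff(cd$instance_id, pair))
}

labelsOf <- function(features, ids) {
  cd <- colData(features)
  cd$label[match(ids, cd$instance_id)]
}

# shared scaffolding: iterate test instances, enforce the leakage contract,
# classify via the prompt pipeline, and score with macro F1
runPromptMethod <- function(split, features, method, shotsFor, backend, dk) {
  preds <- lapply(split$test_ids, function(id) {
    pool <- setdiff(split$all_ids, id)
    res <- shotsFor(id, pool)
    if (id %in% res$shots$instance_id)
      stop("leakage: test instance ", id, " selected as its own shot")
    res
  })
  pred_labels <- vapply(preds, `[[`, character(1), "label")
  truth <- labelsOf(features, split$test_ids)
  data_out <- data.frame(
    instance_id = split$test_ids, truth = truth, pred = pred_labels,
    resolution = vapply(preds, `[[`, character(1), "resolution"),
    shot1 = vapply(preds, function(p) p$shots$instance_id[1], character(1)),
    shot2 = vapply(preds, function(p) p$shots$instance_id[2], character(1)),
    stringsAsFactors = FALSE)
  list(method = method, user_id = split$user_id,
       macro_f1 = 100 * macroF1(truth, pred_labels),
       predictions = data_out,
       n_transcripts = sum(vapply(preds, function(p)
         length(p$transcripts %||% list()), integer(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

baselineShots <- function(cands, reason) {
  cands$score <- 0.5
  cands$reason <- reason
  cands$parse_status <- "parsed"
  cands
}

classifyWithShots <- function(shots, query_fv, features, backend) {
  prompt <- buildClassificationPrompt(shots, query_fv, features)
  reply <- classificationReply(backend, prompt, shots, query_fv, features)
  pred <- parseLabelReply(reply, shots)
  list(label = pred$label, resolution = pred$resolution, shots = shots,
       transcripts = list(list(stage = "classification", prompt = prompt,
                               reply = reply)))
}

#' Random example-selection baseline
#'
#' Per test instance, two support examples are sampled uniformly without
#' replacement from the user's pool (excluding the instance itself) and used
#' as the prompt shots; seeded for reproducibility.
#'
#' @param split from [makeUserSplit()].
#' @param features a [FeatureSet-class].
#' @param backend,dk backend and domain knowledge for the classification
#'   stage.
#' @param seed integer sampling seed.
#' @return method result: list with `method`, `user_id`, `macro_f1`
#'   (percent) and a per-instance `predictions` data.frame.
#' @export
runRandomBaseline <- function(split, features, backend = heuristicBackend(),
                              dk = defaultDomainKnowledge(), seed = 42L) {
  if (length(split$all_ids) < 3L) stop("pool too small for random baseline")
  i <- 0L
  runPromptMethod(split, features, "random", function(id, pool) {
    i <<- i + 1L
    pick <- withSeed(deriveSeed(seed, i),
                     sample(pool, 2L, replace = FALSE))
    query_fv <- featureVector(features, id)
    cands <- data.frame(
      instance_id = pick,
      user_id = split$user_id,
      label = as.character(labelsOf(features, pick)),
      distance = vapply(pick, function(p)
        euclideanDistance(featureVector(features, p), query_fv), numeric(1)),
      stringsAsFactors = FALSE)
    shots <- baselineShots(cands, "selected uniformly at random")
    classifyWithShots(shots, query_fv, features, backend)
  }, backend, dk)
}

#' Distance-only example-selection baseline
#'
#' Per test instance, the two nearest pool members in the 30-dimensional
#' feature space become the shots directly; no relevance scoring.
#'
#' @inheritParams runRandomBaseline
#' @return method result as in [runRandomBaseline()].
#' @export
runDistanceBaseline <- function(split, features,
                                backend = heuristicBackend(),
                                dk = defaultDomainKnowledge()) {
  runPromptMethod(split, features, "distance", function(id, pool) {
    cands <- nearestCandidates(id, features, distance_k = 2L,
                               pool_ids = pool)
    shots <- baselineShots(cands, "selected by Euclidean distance")
    classifyWithShots(shots, featureVector(features, id), features, backend)
  }, backend, dk)
}

#' Offline random-forest baseline
#'
#' Trains a 100-tree random forest on exactly two examples (the split's
#' seeded train pair, one per class) and evaluates on the held-out test
#' set. Fully offline: no prompts, no backend calls. If the forest cannot
#' be grown (e.g. the two training rows are identical, so in-bag samples
#' cannot contain both classes), the baseline degrades to nearest-neighbor
#' classification on the train pair, with ties going to the fatigue
#' example, so the result is always defined.
#'
#' @param split from [makeUserSplit()].
#' @param features a [FeatureSet-class].
#' @param seed integer seed for the forest's bootstrap randomness.
#' @return method result as in [runRandomBaseline()].
#' @export
runMlBaseline <- function(split, features, seed = 42L) {
  mat <- assay(features, "features")
  train_x <- t(mat[, match(split$train_pair,
                           colData(features)$instance_id), drop = FALSE])
  train_y <- factor(labelsOf(features, split$train_pair), levels = .LABELS)
  test_x <- t(mat[, match(split$test_ids,
                          colData(features)$instance_id), drop = FALSE])
  fit <- tryCatch(
    withSeed(seed, randomForest(x = train_x, y = train_y, ntree = 100L)),
    error = function(e) NULL)
  pred <- if (!is.null(fit)) {
    as.character(predict(fit, test_x))
  } else {
    apply(test_x, 1L, function(row) {
      d <- colSums((t(train_x) - row)^2)
      as.character(train_y[which.min(d)])
    })
  }
  truth <- labelsOf(features, split$test_ids)
  list(method = "ml", user_id = split$user_id,
       macro_f1 = 100 * macroF1(truth, pred),
       predictions = data.frame(instance_id = split$test_ids, truth = truth,
                                pred = pred, resolution = "direct",
                                shot1 = split$train_pair[1],
                                shot2 = split$train_pair[2],
                                stringsAsFactors = FALSE),
       n_transcripts = 0L)
}

#' Hybrid distance + relevance-scoring method on one user split
#'
#' Runs the full [predictLabel()] pipeline for every test instance of the
#' split, with the candidate pool restricted to the user's slice minus the
#' instance itself.
#'
#' @inheritParams runRandomBaseline
#' @param cfg a [SelectionConfig-class] or the result of
#'   [selectionPreset()].
#' @return method result as in [runRandomBaseline()], with `method` set to
#'   `"hedlm"`.
#' @export
runHedlm <- function(split, features, cfg = selectionPreset("paramA"),
                     backend = heuristicBackend(),
                     dk = defaultDomainKnowledge()) {
  runPromptMethod(split, features, "hedlm", function(id, pool) {
    predictLabel(id, features, cfg = cfg, backend = backend, dk = dk,
                 pool_ids = pool)
  }, backend, dk)
}

#' Evaluate all methods over all users
#'
#' Runs the selected methods on every user that has both classes (users
#' lacking a class are skipped with a warning), reusing the identical
#' per-user test set across methods. Per-user and per-method seeds are
#' derived deterministically from `seed`.
#'
#' @param features a [FeatureSet-class].
#' @param methods subset of
#'   `c("ml", "random", "distance", "hedlm_paramA", "hedlm_paramB")`.
#' @param backend,dk backend and domain knowledge shared by the
#'   prompt-based methods.
#' @param seed master seed.
#' @return a [MethodScoreTable-class] (users x methods, macro F1 percent)
#'   with the per-run results in `attr(, "results")`.
#' @export
evaluateAll <- function(features,
                        methods = c("ml", "random", "distance",
                                    "hedlm_paramA", "hedlm_paramB"),
                        backend = heuristicBackend(),
                        dk = defaultDomainKnowledge(), seed = 42L) {
  methods <- match.arg(methods, several.ok = TRUE)
  cd <- as.data.frame(colData(features))
  users <- unique(cd$user_id)
  ok <- vapply(users, function(u) {
    labs <- unique(cd$label[cd$user_id == u & !is.na(cd$label)])
    length(labs) >= 2L
  }, logical(1))
  if (any(!ok))
    warning("skipping user(s) lacking both classes: ",
            paste(users[!ok], collapse = ", "))
  users <- users[ok]
  if (!length(users)) stop("no user has both classes")
  results <- list()
  values <- matrix(NA_real_, length(users), length(methods),
                   dimnames = list(users, methods))
  for (ui in seq_along(users)) {
    split <- makeUserSplit(features, users[ui], seed = deriveSeed(seed, ui))
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      res <- switch(m,
        ml = runMlBaseline(split, features, seed = deriveSeed(seed, ui, 1L)),
        random = runRandomBaseline(split, features, backend = backend,
                                   dk = dk,
                                   seed = deriveSeed(seed, ui, 2L)),
        distance = runDistanceBaseline(split, features, backend = backend,
                                       dk = dk),
        hedlm_paramA = runHedlm(split, features,
                                cfg = selectionPreset("paramA"),
                                backend = backend, dk = dk),
        hedlm_paramB = runHedlm(split, features,
                                cfg = selectionPreset("paramB"),
                                backend = backend, dk = dk))
      res$method <- m
      values[ui, mi] <- res$macro_f1
      results[[paste(users[ui], m, sep = ".")]] <- res
    }
  }
  out <- methodScoreTable(values)
  attr(out, "results") <- results
  out
}
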