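test_that("macroF1 matches hand-computed confusion matrices", {
  expect_equal(macroF1(c("fatigue", "non_fatigue"),
                       c("fatigue", "non_fatigue")), 1)
  # truth FFNN vs pred FNFN: each class P = R = 0.5
  expect_equal(macroF1(c("fatigue", "fatigue", "non_fatigue", "non_fatigue"),
                       c("fatigue", "non_fatigue", "fatigue", "non_fatigue")),
               0.5)
  # all-fatigue predictions on balanced truth: F1 2/3 and 0
  expect_equal(macroF1(c("fatigue", "non_fatigue"), c("fatigue", "fatigue")),
               (2 / 3 + 0) / 2)
  # invariant under consistent class swap
  set.seed(31)
  truth <- sample(c("fatigue", "non_fatigue"), 40, TRUE)
  pred <- sample(c("fatigue", "non_fatigue"), 40, TRUE)
  swap <- function(x) ifelse(x == "fatigue", "non_fatigue", "fatigue")
  expect_equal(macroF1(truth, pred), macroF1(swap(truth), swap(pred)))
  expect_gte(macroF1(truth, pred), 0)
  expect_lte(macroF1(truth, pred), 1)
  expect_error(macroF1(c("fatigue"), c("fatigue", "fatigue")), "length")
})

test_that("user split holds out a seeded one-per-class train pair", {
  fs <- syntheticFeatures()
  sp <- makeUserSplit(fs, "user01", seed = 9)
  labs <- instanceLabels(fs)[match(sp$train_pair, instanceIds(fs))]
  expect_setequal(labs, c("fatigue", "non_fatigue"))
  expect_length(intersect(sp$train_pair, sp$test_ids), 0L)
  expect_setequal(c(sp$train_pair, sp$test_ids), sp$all_ids)
  expect_identical(sp$train_pair, makeUserSplit(fs, "user01", seed = 9)$train_pair)
  expect_error(makeUserSplit(fs, "nouser"), "no labeled")
})

test_that("random baseline is seeded and uses 2 uniform support examples", {
  fs <- syntheticFeatures()
  sp <- makeUserSplit(fs, "user01", seed = 1)
  r1 <- runRandomBaseline(sp, fs, seed = 5)
  r2 <- runRandomBaseline(sp, fs, seed = 5)
  expect_identical(r1$predictions, r2$predictions)   # same seed, same run
  r3 <- runRandomBaseline(sp, fs, seed = 6)
  expect_false(identical(r1$predictions[c("shot1", "shot2")],
                         r3$predictions[c("shot1", "shot2")]))
  # leakage: own id never among the shots
  expect_false(any(r1$predictions$instance_id == r1$predictions$shot1 |
                   r1$predictions$instance_id == r1$predictions$shot2))
})

test_that("distance baseline takes the two nearest and is deterministic", {
  fs <- syntheticFeatures()
  sp <- makeUserSplit(fs, "user01", seed = 1)
  r1 <- runDistanceBaseline(sp, fs)
  expect_identical(r1$predictions, runDistanceBaseline(sp, fs)$predictions)
  # a duplicated query becomes shot 1 with distance zero
  id <- sp$test_ids[1]
  m <- SummarizedExperiment::assay(fs, "features")
  twin_pool <- setdiff(sp$all_ids, id)
  cands <- nearestCandidates(id, fs, distance_k = 2, pool_ids = twin_pool)
  q <- hedlm:::featureVector(fs, id)
  dup <- nearestCandidates(q, fs, distance_k = 2,
                           pool_ids = c(twin_pool, id))
  expect_equal(dup$instance_id[1], id)
  expect_equal(dup$distance[1], 0)
})

test_that("ml baseline trains a seeded forest on the pair", {
  fs <- syntheticFeatures()
  sp <- makeUserSplit(fs, "user02", seed = 3)
  r1 <- runMlBaseline(sp, fs, seed = 11)
  r2 <- runMlBaseline(sp, fs, seed = 11)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(r1$n_transcripts, 0L)                  # fully offline
  # linearly separable toy: perfect macro F1
  mat <- matrix(0.5, nrow = 30, ncol = 10)
  mat[1, 1:5] <- 0.9
  mat[1, 6:10] <- 0.1
  toy <- makeToyFeatures(mat, user_id = rep("u", 10),
                         label = rep(c("fatigue", "non_fatigue"), each = 5))
  spt <- makeUserSplit(toy, "u", seed = 1)
  expect_equal(runMlBaseline(spt, toy, seed = 1)$macro_f1, 100)
  # degenerate identical train pair with conflicting labels: defined result
  mat2 <- matrix(0.5, nrow = 30, ncol = 4)
  dg <- makeToyFeatures(mat2, user_id = rep("u", 4),
                        label = c("fatigue", "non_fatigue",
                                  "fatigue", "non_fatigue"))
  spd <- makeUserSplit(dg, "u", seed = 1)
  expect_no_error(runMlBaseline(spd, dg, seed = 1))
})

test_that("hedlm run scores distance_k candidates per test instance", {
  fs <- syntheticFeatures()
  sp <- makeUserSplit(fs, "user01", seed = 1)
  rA <- runHedlm(sp, fs, cfg = selectionPreset("paramA"))
  # transcripts: (distance_k scoring + 1 classification) per test instance
  expect_equal(rA$n_transcripts, length(sp$test_ids) * (5L + 1L))
  rB <- runHedlm(sp, fs, cfg = selectionPreset("paramB"))
  expect_equal(rB$n_transcripts, length(sp$test_ids) * (10L + 1L))
})

test_that("constant-score backend with top_k 2 reduces to the distance baseline", {
  fs <- syntheticFeatures()
  const <- scriptedBackend(default_reply = "SCORE: 1.0\nREASON: constant")
  for (u in c("user01", "user02")) {
    sp <- makeUserSplit(fs, u, seed = 2)
    hed <- runHedlm(sp, fs, cfg = selectionConfig(5, 2), backend = const)
    dist <- runDistanceBaseline(sp, fs, backend = const)
    expect_equal(hed$predictions$pred, dist$predictions$pred)
  }
})

test_that("evaluateAll builds the score table with shared test sets", {
  fs <- syntheticFeatures()
  tab <- evaluateAll(fs, methods = c("ml", "distance"), seed = 17)
  v <- scoreMatrix(tab)
  expect_equal(dim(v), c(2L, 2L))
  expect_equal(rownames(v), c("user01", "user02"))
  expect_true(all(v >= 0 & v <= 100))
  res <- attr(tab, "results")
  # identical test-set membership across methods per user
  expect_identical(res[["user01.ml"]]$predictions$instance_id,
                   res[["user01.distance"]]$predictions$instance_id)
  # summary row equals arithmetic means of the user rows
  expect_equal(summarizeScores(tab)$mean, unname(colMeans(v)))
  # determinism of the whole protocol
  tab2 <- evaluateAll(fs, methods = c("ml", "distance"), seed = 17)
  expect_identical(scoreMatrix(tab2), v)
})

test_that("users lacking a class are skipped with a warning", {
  fs <- syntheticFeatures()
  mat <- SummarizedExperiment::assay(fs, "features")
  one <- matrix(mat[, 1:4], nrow = 30)
  extra <- makeToyFeatures(one, user_id = rep("u3", 4), label = "fatigue",
                           instance_id = paste0("x", 1:4))
  both <- cbind(SummarizedExperiment::assay(fs, "features"),
                SummarizedExperiment::assay(extra, "features"))
  cd <- rbind(SummarizedExperiment::colData(fs),
              SummarizedExperiment::colData(extra))
  merged <- hedlm:::featureSetFromMatrix(both, cd)
  expect_warning(tab <- evaluateAll(merged, methods = c("ml", "distance"),
                                    seed = 1), "u3")
  expect_equal(nrow(scoreMatrix(tab)), 2L)
})
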