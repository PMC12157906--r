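scoredFrame <- function(scores, labels = NULL, distances = NULL,
                        ids = NULL) {
  n <- length(scores)
  data.frame(
    instance_id = ids %||% sprintf("c%02d", seq_len(n)),
    user_id = "u1",
    label = labels %||% rep("fatigue", n),
    distance = distances %||% seq_len(n),
    score = scores, reason = "r", parse_status = "parsed",
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rerankTopK sorts by score with distance tie-break", {
  sc <- scoredFrame(c(0.2, 0.9, 0.5))
  top <- rerankTopK(sc, 2)
  expect_equal(top$score, c(0.9, 0.5))
  tie <- rerankTopK(scoredFrame(c(0.7, 0.7), distances = c(2, 1)), 2)
  expect_equal(tie$distance, c(1, 2))          # nearer first on equal score
  expect_equal(nrow(rerankTopK(sc, 10)), 3L)   # truncation bound
  expect_error(rerankTopK(sc[0, ], 2), "no scored")
  # output is a subset with non-increasing scores
  set.seed(12)
  for (i in 1:15) {
    sc <- scoredFrame(runif(8), distances = runif(8))
    top <- rerankTopK(sc, sample(1:8, 1))
    expect_true(all(top$instance_id %in% sc$instance_id))
    expect_true(all(diff(top$score) <= 0))
  }
})

test_that("pickShots balances labels whenever both classes are present", {
  top <- scoredFrame(c(0.9, 0.8, 0.6),
                     labels = c("fatigue", "fatigue", "non_fatigue"))
  sh <- pickShots(top)
  expect_setequal(sh$label, c("fatigue", "non_fatigue"))
  expect_equal(sh$score, c(0.9, 0.6))          # best of each class
  # single-class fallback: the two best overall
  mono <- pickShots(scoredFrame(c(0.9, 0.8, 0.7)))
  expect_equal(mono$score, c(0.9, 0.8))
  expect_equal(mono$label, c("fatigue", "fatigue"))
  # forced pair of two mixed labels
  two <- pickShots(scoredFrame(c(0.4, 0.3),
                               labels = c("non_fatigue", "fatigue")))
  expect_equal(nrow(two), 2L)
  expect_error(pickShots(scoredFrame(0.5)), "at least 2")
  # property: one shot per class whenever both classes exist in top-K
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    top <- scoredFrame(runif(n),
                       labels = sample(c("fatigue", "non_fatigue"), n, TRUE),
                       distances = runif(n))
    top <- rerankTopK(top, n)
    sh <- pickShots(top)
    if (length(unique(top$label)) == 2L) {
      expect_setequal(sh$label, c("fatigue", "non_fatigue"))
      expect_gte(sh$score[1], sh$score[2])     # higher score first
    } else {
      expect_equal(sh$score, top$score[1:2])
    }
  }
})

test_that("classification prompt has two example blocks and the query", {
  fs <- toyUserFeatures()
  ids <- instanceIds(fs)
  shots <- makeShots()
  shots$instance_id <- ids[1:2]
  q <- hedlm:::featureVector(fs, ids[3])
  p <- buildClassificationPrompt(shots, q, fs)
  expect_equal(lengths(regmatches(p, gregexpr("Example [12]:", p))), 2L)
  expect_equal(lengths(regmatches(p, gregexpr("New data:", p))), 1L)
  expect_match(p, "Conclusion: The label is fatigue.", fixed = TRUE)
  expect_match(p, "Conclusion: The label is non-fatigue.", fixed = TRUE)
  expect_match(p, "determine the final label", fixed = TRUE)
  # rendered numbers parse back to the query features within 1e-4
  nd <- sub(".*New data:\n", "", p)
  nd <- sub("\n\nPlease compare.*", "", nd)
  nums <- as.numeric(unlist(regmatches(nd, gregexpr("-?[0-9]+\\.[0-9]+", nd))))
  expect_equal(nums, unname(q), tolerance = 1e-4)
})

test_that("parseLabelReply resolves direct, counted and tied replies", {
  sh <- makeShots()    # shot1 fatigue scored 0.9, shot2 non_fatigue 0.4
  d <- parseLabelReply("fatigue", sh)
  expect_equal(d$label, "fatigue")
  expect_equal(d$resolution, "direct")
  expect_equal(parseLabelReply("Non-Fatigue", sh)$label, "non_fatigue")
  expect_equal(parseLabelReply(" non fatigue ", sh)$resolution, "direct")
  cnt <- parseLabelReply("Definitely non-fatigue. Non-fatigue pattern.", sh)
  expect_equal(cnt$label, "non_fatigue")       # counts 2 vs 0
  expect_equal(cnt$resolution, "frequency_fallback")
  amb <- parseLabelReply("I believe it is non-fatigue, but maybe fatigue?",
                         sh)
  expect_equal(amb$resolution, "tie_rule")     # counts 1 vs 1
  expect_equal(amb$label, "fatigue")           # higher-scored shot wins
  # total: arbitrary text always yields a label
  set.seed(4)
  for (i in 1:25) {
    txt <- paste(sample(c(letters, " ", "fatigue", "non-fatigue", "?"),
                        8, TRUE), collapse = " ")
    out <- parseLabelReply(txt, sh)
    expect_true(out$label %in% c("fatigue", "non_fatigue"))
  }
  expect_equal(parseLabelReply(NA_character_, sh)$resolution, "tie_rule")
})

test_that("predictLabel composes the full pipeline deterministically", {
  fs <- toyUserFeatures()
  ids <- instanceIds(fs)
  # constant scripted backend always answering fatigue
  b <- scriptedBackend(default_reply = "fatigue")
  p <- predictLabel(ids[8], fs, backend = b)
  expect_equal(p$label, "fatigue")
  expect_equal(p$resolution, "direct")
  expect_false(ids[8] %in% p$scored$instance_id)  # leakage contract
  # transcripts: one per scored candidate plus the classification call
  expect_length(p$transcripts, nrow(p$scored) + 1L)
  # pool of 2 (one per label): those two become the shots regardless of cfg
  pool <- ids[c(1, 7)]
  p2 <- predictLabel(ids[8], fs, cfg = selectionPreset("paramB"),
                     backend = heuristicBackend(), pool_ids = pool)
  expect_setequal(p2$shots$instance_id, pool)
  # end-to-end determinism with deterministic backends
  r1 <- predictLabel(ids[3], fs, backend = heuristicBackend())
  r2 <- predictLabel(ids[3], fs, backend = heuristicBackend())
  expect_identical(r1$label, r2$label)
  expect_identical(r1$scored$score, r2$scored$score)
  expect_identical(r1$transcripts, r2$transcripts)
})
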