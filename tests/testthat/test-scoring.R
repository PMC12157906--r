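test_that("scoring prompt carries features, label, guidance and rules", {
  fs <- toyUserFeatures()
  cand <- hedlm:::featureVector(fs, instanceIds(fs)[1])
  query <- hedlm:::featureVector(fs, instanceIds(fs)[7])
  p <- buildScoringPrompt(cand, query, "fatigue", defaultDomainKnowledge())
  expect_match(p, "segment by segment")
  expect_match(p, "RMS > 0.50 in segments 2 and 3", fixed = TRUE)
  expect_match(p, "MEAN < 0.31", fixed = TRUE)
  expect_match(p, "SCORE:", fixed = TRUE)
  expect_match(p, "label: fatigue", fixed = TRUE)
  # ablation: no threshold rules in the prompt
  p0 <- buildScoringPrompt(cand, query, "fatigue",
                           defaultDomainKnowledge(enabled = FALSE))
  expect_no_match(p0, "0.31")
  expect_no_match(p0, "Domain knowledge")
  # identical candidate and query render identical feature blocks
  p2 <- buildScoringPrompt(query, query, "non_fatigue",
                           defaultDomainKnowledge())
  blocks <- strsplit(p2, "\n\n")[[1]]
  expect_equal(sub(".*?\n", "", blocks[2]), sub(".*?\n", "", blocks[3]))
})

test_that("parseScoreReply is total, clamps and falls back", {
  r <- parseScoreReply("SCORE: 0.90\nREASON: Segments 1 and 2 similar RMS")
  expect_equal(r$value, 0.9)
  expect_equal(r$parse_status, "parsed")
  expect_match(r$reason, "Segments 1 and 2")
  expect_equal(parseScoreReply("score: 1.7 because")$value, 1)
  expect_equal(parseScoreReply("score: 1.7 because")$parse_status, "clamped")
  expect_equal(parseScoreReply("score = -0.3")$value, 0)
  fb <- parseScoreReply("cannot assess")
  expect_equal(fb$value, 0.5)
  expect_equal(fb$parse_status, "fallback")
  expect_equal(parseScoreReply(NA_character_)$parse_status, "fallback")
  # never raises on arbitrary text
  set.seed(8)
  for (i in 1:30) {
    txt <- paste(sample(c(letters, "0", ".", ":", "\n", "SCORE", "score "),
                        20, TRUE), collapse = "")
    out <- parseScoreReply(txt)
    expect_gte(out$value, 0)
    expect_lte(out$value, 1)
  }
})

test_that("rule-implied label follows majority of fired rules", {
  fv <- setNames(rep(0.6, 30), featureNames())
  dk <- defaultDomainKnowledge()
  # rms in segments 2 and 3 both above 0.5 -> fatigue
  expect_equal(dkImpliedLabel(fv, dk), "fatigue")
  # conjunctive rule: one late segment below threshold does not fire
  fv2 <- fv
  fv2["seg3_rms"] <- 0.4
  expect_true(is.na(dkImpliedLabel(fv2, dk)))
  # mean rule fires per segment
  fv3 <- fv2
  fv3["seg1_mean"] <- 0.2
  expect_equal(dkImpliedLabel(fv3, dk), "fatigue")
  # disabled -> always indeterminate
  expect_true(is.na(dkImpliedLabel(fv, defaultDomainKnowledge(FALSE))))
})

test_that("heuristicScore matches its closed form and is monotone", {
  # identical features, matching implied label: both terms maximal
  hi <- heuristicScore(0, "fatigue", "fatigue", tau = 1)
  expect_gte(hi$value, 0.9)
  # identical features, contradicting label
  lo <- heuristicScore(0, "non_fatigue", "fatigue", tau = 1)
  expect_lte(lo$value, 0.5)
  # hand-computed table over the formula
  tab <- data.frame(d = c(0, 1, 2, 1), lab = c("fatigue", "fatigue",
                                               "non_fatigue", "fatigue"),
                    imp = c("fatigue", NA, "fatigue", "non_fatigue"))
  expected <- c(0.5 * exp(0) + 0.5 * 1,
                0.5 * exp(-1) + 0.5 * 0.5,
                0.5 * exp(-2) + 0.5 * 0,
                0.5 * exp(-1) + 0.5 * 0)
  for (i in 1:4) {
    got <- heuristicScore(tab$d[i], tab$lab[i], tab$imp[i], tau = 1)
    expect_equal(got$value, expected[i], tolerance = 1e-12)
  }
  # decreasing distance never decreases the score
  d <- seq(5, 0, by = -0.5)
  v <- vapply(d, function(x)
    heuristicScore(x, "fatigue", "fatigue", tau = 2)$value, numeric(1))
  expect_true(all(diff(v) >= 0))
  # flipping agree -> contradict never increases it
  for (x in d) {
    expect_gte(heuristicScore(x, "fatigue", "fatigue", tau = 2)$value,
               heuristicScore(x, "non_fatigue", "fatigue", tau = 2)$value)
  }
})

test_that("without domain knowledge the heuristic depends on distance only", {
  dkoff <- defaultDomainKnowledge(enabled = FALSE)
  fs <- toyUserFeatures()
  ids <- instanceIds(fs)
  cands <- nearestCandidates(ids[1], fs, distance_k = 5)
  sc <- scoreCandidates(cands, ids[1], fs, heuristicBackend(), dkoff)
  # same distance ordering as score ordering, label plays no role
  expect_equal(order(-sc$score), order(sc$distance))
  tau <- max(median(cands$distance), 1e-9)
  expect_equal(sc$score, 0.5 * exp(-sc$distance / tau) + 0.25,
               tolerance = 1e-12)
})

test_that("scoreCandidates preserves order and uses the backend", {
  fs <- toyUserFeatures()
  ids <- instanceIds(fs)
  cands <- nearestCandidates(ids[1], fs, distance_k = 5)
  const <- scriptedBackend(default_reply = "SCORE: 0.3\nREASON: constant")
  sc <- scoreCandidates(cands, ids[1], fs, const, defaultDomainKnowledge())
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$instance_id, cands$instance_id)
  expect_equal(sc$score, rep(0.3, 5))
  expect_equal(sc$parse_status, rep("parsed", 5))
  tr <- attr(sc, "transcripts")
  expect_length(tr, 5L)
  expect_match(tr[[1]]$reply, "constant")
  # heuristic backend: a feature-identical candidate with the implied
  # label receives the maximum score of the pool
  q <- hedlm:::featureVector(fs, ids[2])     # fatigue cluster
  cands2 <- nearestCandidates(q, fs, distance_k = 5,
                              pool_ids = setdiff(ids, ids[2]))
  sc2 <- scoreCandidates(cands2, q, fs, heuristicBackend(),
                         defaultDomainKnowledge())
  expect_equal(which.max(sc2$score), 1L)
  expect_equal(sc2$distance[1], min(sc2$distance))
})

test_that("scores stay within [0,1] for any backend output", {
  fs <- toyUserFeatures()
  ids <- instanceIds(fs)
  cands <- nearestCandidates(ids[1], fs, distance_k = 3)
  for (reply in c("SCORE: 99", "SCORE: -4", "junk", "score:0.44")) {
    b <- scriptedBackend(default_reply = reply)
    sc <- scoreCandidates(cands, ids[1], fs, b, defaultDomainKnowledge())
    expect_true(all(sc$score >= 0 & sc$score <= 1))
  }
})
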