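# shared fixtures, built once per test run

# hand-constructed FeatureSet with controlled geometry: two users, labeled
# columns at known coordinates so distances are exact by construction
makeToyFeatures <- function(values, user_id, label,
                            instance_id = sprintf("t%02d", seq_along(user_id))) {
  stopifnot(nrow(values) == 30L)
  cd <- S4Vectors::DataFrame(user_id = user_id, instance_id = instance_id,
                             label = label)
  hedlm:::featureSetFromMatrix(values, cd)
}

# 12 instances of one user: 6 per class, classes offset along feature 1
toyUserFeatures <- function() {
  set.seed(421)
  base <- matrix(runif(30 * 12, 0.2, 0.8), nrow = 30)
  base[1, 1:6] <- base[1, 1:6] + 3       # fatigue cluster pushed away
  makeToyFeatures(base, user_id = rep("u1", 12),
                  label = rep(c("fatigue", "non_fatigue"), each = 6))
}

# small featurized synthetic dataset, cached for the whole run
syntheticFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- generateDataset(syntheticSpec(n_users = 2,
                                          instances_per_user = 12,
                                          overlap = 0.3, seed = 5))
      cache <<- featurize(ts)
    }
    cache
  }
})

# 2-row shots frame as produced by pickShots()
makeShots <- function(labels = c("fatigue", "non_fatigue"),
                      scores = c(0.9, 0.4), distances = c(1, 2)) {
  data.frame(instance_id = c("s1", "s2"), user_id = "u1", label = labels,
             distance = distances, score = scores, reason = "r",
             parse_status = "parsed", stringsAsFactors = FALSE)
}
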