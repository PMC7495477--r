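test_that("stability classes use strict 140/80 boundaries", {
  expect_equal(classify_stability(c(150, 100, 80, 140, 79.9, 140.1)),
               c("stabilising", "neutral", "neutral", "neutral",
                 "destabilising", "stabilising"))
  expect_error(classify_stability(-1), "negative")
})

test_that("abundance weights are per-level class frequencies", {
  level <- c(rep("X", 10), rep("Y", 5))
  cls <- c(rep("stabilising", 4), rep("neutral", 6),
           rep("destabilising", 2), rep("neutral", 3))
  w <- factor_weights(level, cls)
  expect_equal(w$stab_weight[w$level == "X"], 0.4)
  expect_equal(w$destab_weight[w$level == "X"], 0)
  expect_equal(w$destab_weight[w$level == "Y"], 0.4)

  w0 <- factor_weights(c("X", "Y"), c("neutral", "neutral"))
  expect_equal(w0$stab_weight, c(0, 0))
  expect_equal(w0$destab_weight, c(0, 0))
  expect_error(factor_weights(rep("X", 5), rep("neutral", 5)),
               "fewer than 2")
})

test_that("rank scores: 4th of 20 stabilising, least destabilising -> 37", {
  set.seed(7)
  w <- data.frame(level = memstab:::AA_CANONICAL, n = 50,
                  stab_weight = 0, destab_weight = 0)
  # decouple the two orderings: Q 4th-highest stabilising weight,
  # lowest destabilising weight
  stab_order <- c("G", "T", "A", "Q", sample(setdiff(w$level,
                                                     c("G", "T", "A", "Q"))))
  w$stab_weight <- (20:1)[match(w$level, stab_order)] / 20
  destab_order <- c(sample(setdiff(w$level, "Q")), "Q")
  w$destab_weight <- (20:1)[match(w$level, destab_order)] / 20
  s <- weights_to_scores(w)
  q <- s[s$level == "Q", ]
  expect_equal(q$stab_score, 17L)
  expect_equal(q$destab_score, 20L)
  expect_equal(q$combined_score, 37L)
})

test_that("rank scores are permutations with deterministic tie-breaks", {
  set.seed(11)
  for (L in c(2, 5, 20)) {
    w <- data.frame(level = sprintf("L%02d", seq_len(L)),
                    n = sample.int(100, L, replace = TRUE),
                    stab_weight = stats::runif(L),
                    destab_weight = stats::runif(L))
    s <- weights_to_scores(w)
    expect_setequal(s$stab_score, seq_len(L))
    expect_setequal(s$destab_score, seq_len(L))
    expect_true(all(s$combined_score >= 2 & s$combined_score <= 2 * L))
  }
  # two-level bounds
  w2 <- data.frame(level = c("a", "b"), n = c(5, 5),
                   stab_weight = c(0.9, 0.1), destab_weight = c(0.1, 0.9))
  s2 <- weights_to_scores(w2)
  expect_equal(s2$combined_score[s2$level == "a"], 4L)
  expect_equal(s2$combined_score[s2$level == "b"], 2L)
  # ties broken by n then name: equal weights, equal n -> alphabetical
  w3 <- data.frame(level = c("b", "a"), n = c(5, 5),
                   stab_weight = 0.5, destab_weight = 0.5)
  s3 <- weights_to_scores(w3)
  expect_equal(s3$stab_score[s3$level == "a"], 2L)
})

test_that("matrix derivation ignores record order and dataset duplication", {
  fx <- sim_stability_dataset(21, n_records = 400, target_length = 80)
  m1 <- stability_matrix(fx$records, fx$features)
  shuffled <- fx$records[sample.int(nrow(fx$records)), ]
  m2 <- stability_matrix(shuffled, fx$features)
  expect_equal(m1$scores, m2$scores)
  doubled <- rbind(fx$records, fx$records)
  m3 <- stability_matrix(doubled, fx$features)
  expect_equal(m1$scores[, c("factor", "level", "stab_score",
                             "destab_score", "combined_score")],
               m3$scores[, c("factor", "level", "stab_score",
                             "destab_score", "combined_score")])
})

test_that("position scores are products, normalised to the target max", {
  fx <- sim_stability_dataset(22, n_records = 600, target_length = 60)
  m <- stability_matrix(fx$records, fx$features)
  sc <- predict(m, fx$target, fx$features, include_disorder = FALSE)
  expect_equal(sc$final_score,
               sc$score_aa * sc$score_topology * sc$score_conservation *
                 sc$score_lipid * sc$score_helix)
  expect_equal(max(sc$norm_score), 100)
  expect_true(all(sc$norm_score > 0))
  expect_true(all(sc$final_score >= 2^5))
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$final_score) <= 0))
  # determinism: identical features give identical scores
  sc2 <- predict(m, fx$target, fx$features, include_disorder = FALSE)
  expect_identical(sc, sc2)
  # disorder mode multiplies a sixth factor
  sc6 <- predict(m, fx$target, fx$features, include_disorder = TRUE)
  expect_equal(sort(sc6$final_score / sc6$score_disorder),
               sort(sc$final_score))
})

test_that("product scoring is monotone in any single factor score", {
  base <- c(37, 8, 14, 12, 10)
  expect_equal(prod(base), 497280)
  for (i in seq_along(base)) {
    bumped <- base
    bumped[i] <- bumped[i] + 1
    expect_gt(prod(bumped), prod(base))
  }
})

test_that("unknown query levels fall back to the factor median with warning", {
  fx <- sim_stability_dataset(23, n_records = 300, target_length = 50)
  m <- stability_matrix(fx$records, fx$features)
  # drop one amino-acid level from the fitted matrix
  seen <- m$scores$level[m$scores$factor == "amino_acid"]
  drop_aa <- fx$target$sequence
  victim <- substr(drop_aa, 1, 1)
  m$scores <- m$scores[!(m$scores$factor == "amino_acid" &
                           m$scores$level == victim), ]
  expect_warning(sc <- predict(m, fx$target, fx$features),
                 "median combined score")
  med <- stats::median(m$scores$combined_score[
    m$scores$factor == "amino_acid"])
  expect_equal(sc$score_aa[sc$position == 1], med)
})

test_that("planted enrichment shows up in class mean scores", {
  fx <- sim_stability_dataset(24)
  m <- stability_matrix(fx$records, fx$features)
  sc <- predict(m, fx$target, fx$features)
  by_topo <- tapply(sc$norm_score, fx$features$topology[sc$position],
                    mean)
  expect_gt(by_topo[["TM_helix"]], by_topo[["cytosolic_helix"]])
  # planted stabilising amino acids outrank planted destabilising ones
  aa <- m$scores[m$scores$factor == "amino_acid", ]
  expect_gt(mean(aa$combined_score[aa$level %in% fx$planted$stabilising]),
            mean(aa$combined_score[aa$level %in% fx$planted$destabilising]))
})

test_that("scoring matrices survive a TSV round trip", {
  fx <- sim_stability_dataset(25, n_records = 300, target_length = 50)
  m <- stability_matrix(fx$records, fx$features)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scoring_matrix(m, path)
  m2 <- read_scoring_matrix(path)
  sc1 <- predict(m, fx$target, fx$features)
  sc2 <- predict(m2, fx$target, fx$features)
  expect_equal(sc1$final_score, sc2$final_score)
})
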