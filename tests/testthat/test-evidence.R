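test_that("consensus effects are column log-frequency ratios", {
  # column 2: 60% S / 40% G with wt G; pseudocount 0 -> ln(0.6/0.4)
  msa <- c("AG", "AS", "AS", "AS", "AG")
  eff <- consensus_effect_table(msa, pseudocount = 0)
  s_row <- eff[eff$position == 2 & eff$mut_aa == "S", ]
  expect_equal(s_row$effect, log(3 / 2), tolerance = 1e-12)
  # wt present in all sequences -> every effect <= 0 at that column
  col1 <- eff[eff$position == 1, ]
  expect_true(all(col1$effect <= 0))
})

test_that("consensus scorer handles degenerate and invalid alignments", {
  expect_error(consensus_effect_table("ACDEF"), "depth")
  two <- c("ACDEF", "ACDEF")
  eff <- consensus_effect_table(two, pseudocount = 1)
  expect_true(all(is.finite(eff$effect)))
  expect_true(all(eff$effect < 0))
  # gap columns in the query are dropped; positions re-index the query
  gapped <- c("A-CD", "AGCD", "AGCD")
  eff2 <- consensus_effect_table(gapped)
  expect_equal(sort(unique(eff2$position)), 1:3)
})

test_that("consensus effects ignore row order and full duplication", {
  fx <- sim_msa(31, length = 20, depth = 40, n_odd = 2)
  e1 <- consensus_effect_table(fx$msa)
  e2 <- consensus_effect_table(c(fx$msa[1], rev(fx$msa[-1])))
  expect_equal(e1, e2)
  e3 <- consensus_effect_table(c(fx$msa, fx$msa[-1], fx$msa[1]),
                               query_index = 1)
  # doubling all counts moves each ratio toward the pseudocount-free
  # value but preserves every sign
  expect_equal(sign(e1$effect), sign(e3$effect))
})

test_that("deep-sequence selection normalises then thresholds per site", {
  eff <- data.frame(position = c(5, 5, 7, 9),
                    wt_aa = "G", mut_aa = c("A", "V", "S", "T"),
                    effect = c(2.0, 1.0, 1.5, 1.0))
  cl <- select_deep_sequence(eff, cutoff_percent = 70)
  # argmax per site: position 5 proposes A; 100% and 75% kept, 50% dropped
  expect_equal(cl$position, c(5, 7))
  expect_equal(cl$mut_aa, c("A", "S"))
  expect_equal(cl$norm_score, c(100, 75))
  expect_equal(cl$rank, 1:2)

  allneg <- data.frame(position = 1, wt_aa = "G", mut_aa = "A",
                       effect = -1)
  expect_warning(empty <- select_deep_sequence(allneg), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("candidate lists obey rank and normalisation invariants", {
  for (seed in 1:5) {
    fx <- sim_msa(seed, length = 40, depth = 80, n_odd = 4)
    cl <- select_deep_sequence(consensus_effect_table(fx$msa))
    if (nrow(cl) == 0L) next
    expect_equal(cl$norm_score[1], 100)
    expect_true(all(diff(cl$norm_score) <= 0))
    expect_equal(cl$rank, seq_len(nrow(cl)))
    expect_false(anyDuplicated(paste(cl$position, cl$mut_aa)) > 0)
  }
})

test_that("alanine-scan aggregation averages and ranks by model agreement", {
  mk <- function(id, ddg, energy) {
    list(model_id = id, unfolding_energy = energy,
         table = data.frame(position = seq_along(ddg),
                            wt_aa = "G", mut_aa = "A", ddg = ddg))
  }
  # single model reduces to a plain ddg sort
  one <- aggregate_alascan(list(mk("m1", c(-2, -1, 0.5), 100)))
  expect_equal(one$positions$position, c(1, 2, 3))
  set.seed(5)
  rand <- stats::rnorm(30)
  oracle_order <- order(rand)
  got <- aggregate_alascan(list(mk("m1", rand, 100)))$positions$position
  # within same n_models_stab group the order is ddg-ascending, and
  # negatives (n=1) precede non-negatives (n=0), i.e. a plain sort
  expect_equal(got, oracle_order)

  # mean over models
  two <- aggregate_alascan(list(mk("a", c(-2, 1), 100),
                                mk("b", c(-1, 1), 100)))
  expect_equal(two$positions$mean_ddg[two$positions$position == 1], -1.5)

  # equal means, p1 negative in 3/3 models vs p2 in 1/3 -> p1 first
  three <- aggregate_alascan(list(mk("a", c(-1, -3), 100),
                                  mk("b", c(-1, 1), 100),
                                  mk("c", c(-1, -1), 100)))
  expect_equal(three$positions$position, c(1, 2))
  expect_equal(three$positions$mean_ddg, c(-1, -1))
})

test_that("inconsistent model position sets fall back to the intersection", {
  t1 <- list(model_id = "a", unfolding_energy = 100,
             table = data.frame(position = 1:3, wt_aa = "G",
                                mut_aa = "A", ddg = c(-1, -2, -3)))
  t2 <- list(model_id = "b", unfolding_energy = 90,
             table = data.frame(position = 2:4, wt_aa = "G",
                                mut_aa = "A", ddg = c(-1, -2, -3)))
  expect_warning(agg <- aggregate_alascan(list(t1, t2)), "intersection")
  expect_equal(sort(agg$positions$position), c(2, 3))
})

test_that("position-scan selection picks the best substitution per site", {
  fx <- sim_ddg_tables(32, length = 40, n_sites = 5, noise_sd = 0)
  agg <- aggregate_alascan(fx$alascan, cutoff_percent = 50)
  # noise-free: planted sites rank exactly first and pass the cutoff
  expect_equal(sort(agg$positions$position[seq_along(fx$planted_sites)]),
               fx$planted_sites)
  expect_equal(sort(agg$passing), fx$planted_sites)
  cl <- select_model_based(agg$passing, fx$scan)
  expect_setequal(cl$position, fx$planted_sites)
  # each candidate is the argmin-ddg substitution at its site
  for (i in seq_len(nrow(cl))) {
    dp <- fx$scan$table[fx$scan$table$position == cl$position[i], ]
    expect_equal(cl$score[i], -min(dp$ddg))
    expect_equal(cl$mut_aa[i], dp$mut_aa[which.min(dp$ddg)])
  }
  expect_error(select_model_based(c(agg$passing, 999), fx$scan),
               "missing from the position scan")
})

test_that("best model is the one with lowest unfolding energy", {
  t1 <- list(model_id = "a", unfolding_energy = 120, table = NULL)
  t2 <- list(model_id = "b", unfolding_energy = 95, table = NULL)
  expect_equal(best_model(list(t1, t2))$model_id, "b")
})

test_that("sites with no stabilising substitution are dropped with warning", {
  scan <- list(model_id = "m", unfolding_energy = 1,
               table = data.frame(position = rep(1:2, each = 2),
                                  wt_aa = "G",
                                  mut_aa = rep(c("A", "S"), 2),
                                  ddg = c(0.5, 1.0, -0.5, 0.2)))
  expect_warning(cl <- select_model_based(1:2, scan), "no stabilising")
  expect_equal(cl$position, 2)
})
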