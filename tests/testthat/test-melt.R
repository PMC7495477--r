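ten_temp_grid <- c(20, 30, 40, 45, 50, 55, 60, 70, 80, 90)

logistic4 <- function(T, tm, h, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + exp(h * (T - tm)))
}

test_that("noise-free 4PL curves are recovered essentially exactly", {
  y <- logistic4(ten_temp_grid, tm = 49.3, h = 0.5)
  fit <- fit_melt_curve(ten_temp_grid, y)
  expect_lt(abs(fit$tm - 49.3), 1e-6)
  expect_lt(abs(fit$slope - 0.5), 1e-5)
  expect_true(fit$reliable)
})

test_that("fits without a melt transition are flagged unreliable", {
  y_up <- seq(0.2, 1, length.out = length(ten_temp_grid))
  fit <- fit_melt_curve(ten_temp_grid, y_up)
  expect_false(fit$reliable)
  # grid entirely below the transition
  y_flat <- logistic4(ten_temp_grid, tm = 150, h = 0.5)
  fit2 <- fit_melt_curve(ten_temp_grid, y_flat)
  expect_false(fit2$reliable)
})

test_that("melt fit input contracts", {
  expect_error(fit_melt_curve(c(20, 30, 40, 40), c(1, 1, 0, 0)),
               "5 distinct")
  expect_error(fit_melt_curve(ten_temp_grid, rep(1, 10), ice_signal = 0),
               "on-ice")
})

test_that("Tm summaries use sample SEM, absent for single repeats", {
  s <- summarise_tm(c(50, 52, 54))
  expect_equal(s$mean_tm, 52)
  expect_equal(s$sem_tm, stats::sd(c(50, 52, 54)) / sqrt(3))
  expect_equal(s$sem_tm, 2 / sqrt(3) * 1, tolerance = 1e-12)
  s1 <- summarise_tm(57.4)
  expect_equal(s1$mean_tm, 57.4)
  expect_true(is.na(s1$sem_tm))
  expect_equal(summarise_tm(c(51, 51, 51))$sem_tm, 0)
  expect_error(summarise_tm(NA_real_), "no converged")
})

test_that("dTm errors propagate in quadrature", {
  d <- delta_tm(list(mean_tm = 58.4, sem_tm = 1.2),
                list(mean_tm = 49.3, sem_tm = 0.9))
  expect_equal(d$delta_tm, 9.1)
  expect_equal(round(d$sem_delta_tm, 1), 1.5)
  d2 <- delta_tm(list(mean_tm = 47.2, sem_tm = 1.1),
                 list(mean_tm = 44.6, sem_tm = 0.7))
  expect_equal(round(d2$sem_delta_tm, 1), 1.3)
  # quadrature identities
  d3 <- delta_tm(list(mean_tm = 50, sem_tm = 0),
                 list(mean_tm = 49, sem_tm = 0.8))
  expect_equal(d3$sem_delta_tm, 0.8)
  set.seed(9)
  for (i in 1:20) {
    a <- stats::runif(1); b <- stats::runif(1)
    q <- delta_tm(list(mean_tm = 1, sem_tm = a),
                  list(mean_tm = 0, sem_tm = b))$sem_delta_tm
    expect_gte(q, max(a, b))
  }
  qq <- delta_tm(list(mean_tm = 1, sem_tm = 0.6),
                 list(mean_tm = 0, sem_tm = 0.6))$sem_delta_tm
  expect_equal(qq, sqrt(2) * 0.6)
  # absent SEM on either side -> absent propagated SEM
  expect_true(is.na(delta_tm(list(mean_tm = 1, sem_tm = NA),
                             list(mean_tm = 0, sem_tm = 1))$sem_delta_tm))
})

test_that("campaign classification uses the mean propagated SEM cutoff", {
  d <- c(13.0, 0.0, -5.3, 1.2)
  s <- c(1.4, 1.2, 1.0, 1.6)
  cl <- classify_delta_tm(d, s)
  expect_equal(cl$cutoff, 1.3)
  expect_equal(cl$status,
               c("stabilising", "neutral", "destabilising", "neutral"))
  # antisymmetry: negating every dTm swaps the classes
  neg <- classify_delta_tm(-d, s)
  expect_equal(sum(cl$status == "stabilising"),
               sum(neg$status == "destabilising"))
  expect_equal(sum(cl$status == "destabilising"),
               sum(neg$status == "stabilising"))
  expect_error(classify_delta_tm(1, NA_real_), "explicit cutoff")
})

test_that("Tm SEM shrinks roughly as 1/sqrt(n) over repeats", {
  sems <- sapply(c(3, 12), function(n) {
    reps <- sapply(1:40, function(s) {
      curves <- sim_melt_curves(s * 100 + n, noise_sd = 0.03,
                                n_repeats = n)
      tms <- sapply(split(curves, curves$repeat_id), function(r) {
        meas <- r[r$temperature != "ice", ]
        fit_melt_curve(as.numeric(meas$temperature), meas$intensity,
                       ice_signal = r$intensity[r$temperature == "ice"])$tm
      })
      summarise_tm(tms)$sem_tm
    })
    mean(reps)
  })
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.35)
})

test_that("melt_summary pipelines curves into dTm calls", {
  curves <- rbind(
    sim_melt_curves(41, true_tm = 49.3, noise_sd = 0.01, n_repeats = 8,
                    construct = "WT"),
    sim_melt_curves(42, true_tm = 62.3, noise_sd = 0.01, n_repeats = 3,
                    construct = "G130A"),
    sim_melt_curves(43, true_tm = 44.0, noise_sd = 0.01, n_repeats = 3,
                    construct = "L142P"))
  res <- melt_summary(curves, wildtype = "WT")
  g <- res[res$construct == "G130A", ]
  expect_equal(g$delta_tm, 13.0, tolerance = 0.2)
  expect_equal(g$status, "stabilising")
  expect_equal(res$status[res$construct == "L142P"], "destabilising")
  expect_true(is.na(res$status[res$construct == "WT"]))
})

test_that("double gel bands are summed before fitting", {
  curves <- sim_melt_curves(44, noise_sd = 0)
  split_bands <- curves
  split_bands$intensity2 <- split_bands$intensity * 0.4
  split_bands$intensity <- split_bands$intensity * 0.6
  r1 <- melt_summary(curves, wildtype = "WT")
  r2 <- melt_summary(split_bands, wildtype = "WT")
  expect_equal(r1$mean_tm, r2$mean_tm)
})

test_that("single-temperature screen derives a t-based cutoff", {
  set.seed(77)
  # engineer the pooled measurements so the CI lower bound is known
  x <- c(0.95, 1.0, 1.05, 0.6, 0.5, 0.7, 0.3, 0.4, 0.35, 0.9)
  names(x) <- NULL
  ci <- stats::t.test(x, conf.level = 0.95)$conf.int
  scr <- single_temperature_screen(
    construct = c("WT", "WT", "WT", "V1", "V1", "V1",
                  "V2", "V2", "V2", "V3"),
    survival = x)
  expect_equal(scr$cutoff, ci[1])
  med <- scr$medians
  expect_true(med$hit[med$construct == "WT"])
  expect_equal(med$hit[med$construct == "V2"],
               stats::median(c(0.3, 0.4, 0.35)) > ci[1])
  # boundary is strict
  scr2 <- single_temperature_screen(c("a", "a", "a"), c(0.5, 0.5, 0.5),
                                    cutoff = 0.5)
  expect_false(scr2$medians$hit)
  expect_error(single_temperature_screen(c("a", "a"), c(1, 1)),
               "at least 3")
})
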