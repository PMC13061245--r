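# Agreement metrics against hand arithmetic and textbook oracles.

test_that("agreement reproduces hand-computed cases", {
  f <- seq(100, 2000, length.out = 101)
  same <- agreement(f, f, meta = list(trial_id = "x", technique = "CTS",
                                      pairing = "A1L-B3"))
  expect_equal(same$correlation, 1)
  expect_equal(same$rmse, 0)
  expect_equal(same$peak_diff, 0)
  expect_identical(same$rank, "excellent")
  expect_identical(same$shoulder, "A1-L")

  off <- agreement(f, f + 100)
  expect_equal(off$correlation, 1)
  expect_equal(off$rmse, 100)
  expect_equal(off$peak_diff, 100)
  expect_equal(off$nrmse_pct, 100 * 100 / 2000)

  # crossed three-point case: r = 0.5, rmse = sqrt(2e6/3)
  rec <- agreement(c(0, 1000, 2000), c(0, 2000, 1000))
  expect_equal(rec$correlation, 0.5, tolerance = 1e-12)
  expect_equal(rec$rmse, sqrt((0 + 1000^2 + 1000^2) / 3), tolerance = 1e-9)
  expect_equal(rec$rmse, 816.4966, tolerance = 1e-4)

  expect_error(agreement(rep(5, 10), rnorm(10)), class = "scrumforce_data_error")
  expect_error(agreement(rnorm(10), rnorm(9)), class = "scrumforce_shape_error")
})

test_that("correlation ranking respects the band boundaries", {
  expect_identical(as.character(rank_correlation(0.95)), "excellent")
  expect_identical(as.character(rank_correlation(0.75)), "moderate")
  expect_identical(as.character(rank_correlation(0.9)), "good")
  expect_identical(as.character(rank_correlation(0.5)), "poor")
  expect_identical(as.character(rank_correlation(-0.2)), "poor")
  expect_identical(as.character(rank_correlation(0.51)), "moderate")
  expect_identical(as.character(rank_correlation(1)), "excellent")
  expect_identical(as.character(rank_correlation(-1)), "poor")
  expect_error(rank_correlation(1.2), class = "scrumforce_data_error")
})

test_that("agreement matches independent Pearson/RMSE oracles on random curves", {
  set.seed(10)
  for (i in 1:1000) {
    m <- cumsum(runif(101)) * 30
    p <- m * runif(1, 0.5, 1.5) + rnorm(101, 0, 50)
    rec <- agreement(m, p)
    expect_lt(abs(rec$correlation - oracle_pearson(m, p)), 1e-9)
    expect_lt(abs(rec$rmse - oracle_rmse(m, p)), 1e-9)
    expect_lt(abs(rec$peak_diff - abs(max(m) - max(p))), 1e-9)
  }
})

test_that("error percentages are scale invariant", {
  set.seed(11)
  m <- cumsum(runif(101)) * 25 + 10
  p <- m + rnorm(101, 0, 30)
  a <- agreement(m, p)
  b <- agreement(m * 3.7, p * 3.7)
  expect_equal(a$nrmse_pct, b$nrmse_pct, tolerance = 1e-9)
  expect_equal(a$npeak_pct, b$npeak_pct, tolerance = 1e-9)
  expect_equal(a$correlation, b$correlation, tolerance = 1e-12)
})

test_that("Bland-Altman matches hand cases and the textbook oracle", {
  same <- bland_altman(c(1000, 2000, 1500), c(1000, 2000, 1500))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)

  shift <- bland_altman(c(1000, 2000), c(1100, 2100))
  expect_equal(shift$bias, 100)        # predicted - measured
  expect_equal(shift$sd, 0)
  expect_equal(shift$loa_lower, 100)
  expect_equal(shift$loa_upper, 100)

  set.seed(12)
  m <- runif(50, 1000, 4000); p <- m + rnorm(50, 50, 300)
  ba <- bland_altman(m, p)
  orc <- oracle_bland_altman(m, p)
  expect_lt(abs(ba$bias - orc["bias"]), 1e-9)
  expect_lt(abs(ba$loa_lower - orc["lower"]), 1e-9)
  expect_lt(abs(ba$loa_upper - orc["upper"]), 1e-9)
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)

  expect_error(bland_altman(1:5, 1:4), class = "scrumforce_shape_error")
})

test_that("Bland-Altman per-group sub-results are computed on label subsets", {
  set.seed(13)
  lab <- rep(c("CTPE", "CTS", "PreBind"), times = c(10, 12, 8))
  m <- runif(30, 1000, 4000)
  p <- m + rnorm(30, ifelse(lab == "CTS", -40, 110), 250)
  ba <- bland_altman(m, p, group_labels = lab)
  expect_equal(nrow(ba$groups), 3)
  for (gname in unique(lab)) {
    sub <- oracle_bland_altman(m[lab == gname], p[lab == gname])
    row <- ba$groups[ba$groups$group == gname, ]
    expect_equal(row$bias, unname(sub["bias"]), tolerance = 1e-9)
    expect_equal(row$loa_upper, unname(sub["upper"]), tolerance = 1e-9)
  }
})

test_that("limits of agreement converge to 1.96 sigma on simulated differences", {
  set.seed(14)
  n <- 1e5; mu <- 54.3; sigma <- 300
  m <- runif(n, 1000, 4000)
  p <- m + rnorm(n, mu, sigma)
  ba <- bland_altman(m, p)
  expect_lt(abs(ba$bias - mu) / sigma, 0.02)
  half <- (ba$loa_upper - ba$loa_lower) / 2
  expect_lt(abs(half - 1.96 * sigma) / (1.96 * sigma), 0.02)
})

test_that("grouped reports aggregate with the group-level normalization basis", {
  mk_rec <- function(id, tech, sh, r, rmse, peak)
    data.frame(trial_id = id, technique = tech, shoulder = sh, correlation = r,
               rmse = rmse, nrmse_pct = NA, peak_diff = peak, npeak_pct = NA,
               rank = "good", stringsAsFactors = FALSE)
  recs <- rbind(mk_rec("a", "CTS", "A1-L", 0.9, 100, 50),
                mk_rec("b", "CTS", "A1-L", 0.8, 300, 150),
                mk_rec("c", "CTPE", "A2-R", 0.95, 200, 80))
  curves <- list(seq(0, 2000, length.out = 101), seq(0, 2500, length.out = 101),
                 seq(0, 3000, length.out = 101))
  rep_t <- grouped_report(recs, "technique", curves)
  cts <- rep_t[rep_t$technique == "CTS", ]
  expect_equal(cts$n, 2)
  expect_equal(cts$correlation_mean, 0.85)
  expect_equal(cts$rmse_mean, 200)
  expect_equal(cts$rmse_sd, sd(c(100, 300)))
  # group percentage uses the group's maximum force (2500), not trial maxima
  expect_equal(cts$rmse_pct_mean, 100 * 200 / 2500)
  expect_equal(cts$peak_pct_mean, 100 * 100 / 2500)
  ctpe <- rep_t[rep_t$technique == "CTPE", ]
  expect_equal(ctpe$correlation_sd, 0)
  expect_equal(ctpe$rmse_pct_mean, 100 * 200 / 3000)

  # identical records: zero SDs, means equal the record
  recs2 <- rbind(mk_rec("a", "CTS", "A1-L", 0.9, 100, 50),
                 mk_rec("b", "CTS", "A1-L", 0.9, 100, 50))
  rep2 <- grouped_report(recs2, "technique", curves[1:2])
  expect_equal(rep2$correlation_sd, 0)
  expect_equal(rep2$rmse_mean, 100)

  # six shoulder labels -> six rows
  shs <- c("A1-L", "A1-R", "A2-L", "A2-R", "A3-L", "A3-R")
  recs6 <- do.call(rbind, lapply(seq_along(shs), function(i)
    mk_rec(paste0("t", i), "CTS", shs[i], 0.9, 100, 50)))
  rep6 <- grouped_report(recs6, "shoulder", rep(curves[1], 6))
  expect_equal(nrow(rep6), 6)

  recs_na <- recs; recs_na$technique[1] <- NA
  expect_error(grouped_report(recs_na, "technique", curves),
               class = "scrumforce_data_error")
})
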