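t3 <- table3_fixture()
obs <- eto_series(t3, "pan_observed")

test_that("FAC2 counts pairs within a factor of two", {
  expect_equal(fac2(eto_series(t3, "papadakis"), obs), 5 / 12)
  expect_equal(fac2(eto_series(t3, "trajkovic"), obs), 0)
  expect_equal(fac2(obs, obs), 1)
  # zero observations count as outside the factor of two
  expect_equal(fac2(c(1, 1), c(1, 0)), 0.5)
  expect_error(fac2(1:3, 1:4), "mismatch")
})

test_that("bias and error metrics on the published series", {
  abtew <- eto_series(t3, "abtew")
  expect_equal(mean_bias(abtew, obs), 0.10, tolerance = 1e-10)
  expect_equal(mean_gross_error(abtew, obs), 0.1333, tolerance = 1e-3)
  expect_equal(normalized_mean_bias(abtew, obs), 1.2 / 29.4, tolerance = 1e-10)
  expect_equal(normalized_mean_gross_error(abtew, obs), 1.6 / 29.4,
               tolerance = 1e-10)
  expect_equal(rmse(abtew, obs), 0.1780, tolerance = 1e-3)
  expect_equal(pearson_r(abtew, obs), 0.9664, tolerance = 1e-3)
  expect_equal(ioa_refined(abtew, obs), 1 - 1.6 / 11.8, tolerance = 1e-3)
})

test_that("identity and translation behaviour of the metrics", {
  x <- c(2.8, 3.1, 3.4, 3.2, 2.7, 2.0)
  expect_equal(mean_bias(x, x), 0)
  expect_equal(mean_gross_error(x, x), 0)
  expect_equal(rmse(x, x), 0)
  expect_equal(normalized_mean_bias(x, x), 0)
  expect_equal(normalized_mean_gross_error(x, x), 0)
  expect_equal(fac2(x, x), 1)
  expect_equal(ioa_refined(x, x), 1)
  expect_equal(mean_bias(x + 0.3, x), 0.3)
  expect_equal(rmse(x + 0.3, x), 0.3)
  expect_equal(normalized_mean_bias(2 * x, x), 1)
  expect_equal(normalized_mean_gross_error(2 * x, x), 1)
})

test_that("Pearson r handles exact linearity and rejects constants", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(2 * x + 1, x), 1)
  expect_equal(pearson_r(-x, x), -1)
  expect_error(pearson_r(rep(1, 5), x), "constant")
  expect_error(pearson_r(x, rep(2, 5)), "constant")
  expect_error(pearson_r(1, 2), "two pairs")
})

test_that("refined index of agreement branches correctly", {
  x <- c(1, 2, 3, 4)
  # gross-error branch: huge errors drive IOA toward -1
  expect_lt(ioa_refined(x + 1e6, x), -0.99)
  expect_gte(ioa_refined(x + 1e6, x), -1)
  expect_error(ioa_refined(x, rep(2, 4)), "constant")
  expect_error(ioa_refined(x, x, c = 0))
  # continuous at the branch point A = cB
  b <- 2 * sum(abs(x - mean(x)))
  shift <- b / length(x)
  expect_equal(ioa_refined(x + shift, x), 0)
})

test_that("metric card bundles the eight statistics consistently", {
  card <- metric_card(eto_series(t3, "abtew"), obs, "abtew", "pan_observed")
  expect_equal(card$fac2, 1)
  expect_equal(round(card$mb, 2), 0.10)
  expect_equal(round(card$nmb, 2), 0.04)
  expect_equal(round(card$r, 2), 0.97)
  expect_identical(card$n, 12L)
  ident <- metric_card(obs, obs)
  expect_equal(ident$fac2, 1); expect_equal(ident$mb, 0)
  expect_equal(ident$mge, 0); expect_equal(ident$rmse, 0)
  expect_equal(ident$ioa, 1)
})

test_that("rmse >= mge >= |mb| on any card", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_series_pair()
    card <- metric_card(p$m, p$o)
    expect_gte(card$rmse, card$mge - 1e-12)
    expect_gte(card$mge, abs(card$mb) - 1e-12)
  }
})

test_that("all metrics agree with a naive-loop oracle on random pairs", {
  set.seed(2024)
  for (i in 1:1000) {
    p <- random_series_pair(n = sample(5:24, 1))
    card <- metric_card(p$m, p$o)
    orc <- oracle_metrics(p$m, p$o)
    for (k in names(orc))
      expect_equal(card[[k]], orc[[k]], tolerance = 1e-9, label = k)
  }
})

test_that("scale equivariance and invariance under joint rescaling", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_series_pair()
    s <- runif(1, 0.1, 10)
    expect_equal(mean_bias(s * p$m, s * p$o), s * mean_bias(p$m, p$o))
    expect_equal(mean_gross_error(s * p$m, s * p$o),
                 s * mean_gross_error(p$m, p$o))
    expect_equal(rmse(s * p$m, s * p$o), s * rmse(p$m, p$o))
    expect_equal(normalized_mean_bias(s * p$m, s * p$o),
                 normalized_mean_bias(p$m, p$o))
    expect_equal(normalized_mean_gross_error(s * p$m, s * p$o),
                 normalized_mean_gross_error(p$m, p$o))
    expect_equal(fac2(s * p$m, s * p$o), fac2(p$m, p$o))
    expect_equal(pearson_r(s * p$m, s * p$o), pearson_r(p$m, p$o))
    expect_equal(ioa_refined(s * p$m, s * p$o), ioa_refined(p$m, p$o))
  }
})

test_that("Taylor statistics satisfy the law of cosines", {
  ts <- taylor_stats(obs, obs)
  expect_equal(ts$crmsd, 0)
  expect_equal(ts$sigma_model, ts$sigma_obs)
  expect_equal(ts$r, 1)
  expect_equal(taylor_stats(eto_series(t3, "abtew"), obs)$r, 0.9664,
               tolerance = 1e-3)
  set.seed(5)
  for (i in 1:200) {
    p <- random_series_pair()
    ts <- taylor_stats(p$m, p$o)
    expect_equal(ts$crmsd^2,
                 ts$sigma_obs^2 + ts$sigma_model^2 -
                   2 * ts$sigma_obs * ts$sigma_model * ts$r,
                 tolerance = 1e-9)
  }
})

test_that("ranking is deterministic with documented directions", {
  cards <- table4_fixture()
  temp <- rank_models(cards[cards$category == "temperature", ])
  expect_identical(temp$model_id,
                   c("berti", "ivanov", "hargreaves_samani", "kharrufa",
                     "schendel", "papadakis", "blaney_criddle", "trajkovic"))
  rad <- rank_models(cards[cards$category == "radiation", ])
  expect_identical(rad$model_id[1], "abtew")
  expect_identical(rad$model_id[nrow(rad)], "priestley_taylor")
  # single card ranks as itself; rmse key orders ascending
  one <- rank_models(cards[cards$model_id == "berti", ])
  expect_identical(one$model_id, "berti")
  byrmse <- rank_models(cards[cards$category == "radiation", ], key = "rmse")
  expect_true(!is.unsorted(byrmse$rmse))
  expect_error(rank_models(cards, key = "banana"))
  mixed <- rbind(cards, transform(cards[1, ], baseline_id = "other"))
  expect_error(rank_models(mixed), "mix")
})

test_that("generator model is ranked first when it produced the observations", {
  clim <- table1_fixture()
  tab <- compute_eto_table(clim)
  set.seed(99)
  truth <- "turc"
  noisy_obs <- eto_series(tab, truth) + rnorm(12, 0, 0.05)
  ids <- setdiff(tab$model_id, c("pan_observed", "fao_pm"))
  cards <- do.call(rbind, lapply(ids, function(id)
    metric_card(eto_series(tab, id), noisy_obs, id, "synthetic")))
  for (k in c("mb", "mge", "nmb", "nmge", "rmse", "ioa"))
    expect_identical(rank_models(cards, key = k)$model_id[1], truth, label = k)
})
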