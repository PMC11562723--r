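test_that("R2 and RMSE match their definitions", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r2_score(obs, obs), 1)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(r2_score(obs, rep(mean(obs), 4)), 0)
  expect_equal(rmse(c(0, 0, 0), c(3, 4, 0)), sqrt(25 / 3))
  expect_warning(r2 <- r2_score(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(r2))
  expect_error(r2_score(1:3, 1:4), "equal length")
})

test_that("random folds partition the rows nearly equally", {
  tab <- toy_table(n = 103)
  cvr <- kfold_cv(tab, k = 5, forest_config(n_trees = 50, m_try = 2, seed = 1),
                  smote_cfg = NULL, seed = 9)
  expect_equal(sum(cvr$fold_n), 103)
  expect_lte(diff(range(cvr$fold_n)), 1)
  expect_length(cvr$fold_of_row, 103)
  expect_setequal(unique(cvr$fold_of_row), 1:5)
  expect_error(kfold_cv(tab, k = 1, forest_config(seed = 1)), "k must be")
})

test_that("pooled RMSE^2 equals the count-weighted mean of per-fold MSEs", {
  tab <- toy_table(n = 150, noise = 0.3)
  cvr <- kfold_cv(tab, k = 6, forest_config(n_trees = 60, m_try = 2, seed = 2),
                  smote_cfg = NULL, seed = 3)
  pooled <- sum(cvr$fold_mse * cvr$fold_n) / sum(cvr$fold_n)
  expect_equal(cvr$rmse^2, pooled, tolerance = 1e-12)
})

test_that("spatial folds never split a monitor across train and test", {
  tab <- toy_table(n = 200)
  cvs <- spatial_kfold_cv(tab, k = 5,
                          forest_config(n_trees = 50, m_try = 2, seed = 4),
                          smote_cfg = NULL, seed = 7)
  expect_equal(sum(cvs$fold_n), 200)
  for (f in 1:5) {
    test_mon <- unique(tab$monitor_id[cvs$fold_of_row == f])
    train_mon <- unique(tab$monitor_id[cvs$fold_of_row != f])
    expect_length(intersect(test_mon, train_mon), 0)
  }
  # monitors partition across folds
  expect_setequal(unlist(cvs$fold_monitors), unique(tab$monitor_id))
  # limit case: k = number of monitors is leave-one-monitor-out
  k <- length(unique(tab$monitor_id))
  cvl <- spatial_kfold_cv(tab, k = k,
                          forest_config(n_trees = 30, m_try = 2, seed = 4),
                          smote_cfg = NULL, seed = 7)
  expect_equal(cvl$k, k)
  expect_error(spatial_kfold_cv(tab, k = 50, forest_config(seed = 1)),
               "distinct monitors")
})

test_that("cross-validation refuses tables that already contain synthetic rows", {
  tab <- toy_table(n = 60)
  tab$synthetic[1] <- TRUE
  expect_error(kfold_cv(tab, 3, forest_config(seed = 1)), "real rows")
  expect_error(spatial_kfold_cv(tab, 3, forest_config(seed = 1)), "real rows")
})

test_that("OOB metrics exclude synthetic rows and are honest about optimism", {
  tab <- toy_table(n = 400, noise = 0.3)
  tab$pm25 <- tab$pm25 + 35 # shift so some rows cross the minority threshold
  flags <- identify_minority(tab, 37)
  aug <- smote(tab, flags, smote_config(37, 3, 0.6, seed = 2))
  cfg <- forest_config(n_trees = 150, m_try = 2, seed = 5)
  mod <- fit_forest(aug, "pm25", cfg)
  rep <- oob_report(mod, aug)
  expect_equal(rep$n_excluded_synthetic, sum(aug$synthetic))
  # metric rows = real rows minus those never out of bag
  expect_equal(rep$n + sum(!is.finite(mod$oob[!aug$synthetic])), nrow(tab))
  # OOB RMSE is not smaller than in-bag RMSE
  inbag <- rmse(aug$pm25[!aug$synthetic],
                predict(mod, aug[!aug$synthetic, ]))
  expect_gte(rep$rmse, inbag)
  expect_error(oob_report(mod, aug[1:10, ]), "rows")
})

test_that("near-noiseless responses give high OOB R2", {
  tab <- toy_table(n = 2000, noise = 0.02)
  mod <- fit_forest(tab, "pm25", forest_config(n_trees = 300, m_try = 2,
                                               seed = 8))
  rep <- oob_report(mod, tab)
  expect_gt(rep$r2, 0.95)
})

test_that("random CV is at least as accurate as spatial CV on spatially correlated scenes", {
  # spatially clustered response: monitors differ systematically, so unseen
  # locations are the harder generalization; compare means over ten seeds
  diffs <- numeric(10)
  for (s in 1:10) {
    withr::with_seed(1000 + s, {
      n_mon <- 30
      mx <- runif(n_mon); my <- runif(n_mon)
      rows <- 8
      tab <- data.frame(
        monitor_id = rep(sprintf("M%02d", 1:n_mon), each = rows),
        synthetic = FALSE,
        x = rep(mx, each = rows), y = rep(my, each = rows))
      tab$f <- rnorm(nrow(tab))
      tab$pm25 <- 10 * sin(3 * tab$x) * cos(3 * tab$y) + 2 * tab$f +
        rnorm(nrow(tab), 0, 0.5)
    })
    cfg <- forest_config(n_trees = 60, m_try = 2, seed = s)
    r <- kfold_cv(tab, 5, cfg, NULL, seed = s)
    sp <- spatial_kfold_cv(tab, 5, cfg, NULL, seed = s)
    diffs[s] <- r$r2 - sp$r2
  }
  expect_gt(mean(diffs), 0)
})
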