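# a small synthetic feature-table maker: target is a noiseless monotone
# function of one informative feature, other features are noise
toy_tables <- function(n_rows = c(40, 60, 80), seed = 1, n_noise = 9) {
  set.seed(seed)
  lapply(n_rows, function(n) {
    x <- runif(n)
    tb <- data.frame(start_s = seq_len(n) * 3 - 3, end_s = seq_len(n) * 3 + 1,
                     inf_feat = x)
    for (j in seq_len(n_noise)) tb[[paste0("noise", j)]] <- runif(n)
    tb$target_speed_mm_s <- 100 + 200 * x
    tb
  })
}
toy_features <- c("inf_feat", paste0("noise", 1:9))

test_that("training assembly balances seizures and respects the seed", {
  tabs <- toy_tables()
  tr <- assemble_training(tabs, seed = 5, features = toy_features)
  expect_equal(tr$k, 40)
  expect_equal(length(tr$y), 120)
  expect_equal(as.integer(table(tr$seizure)), rep(40L, 3))
  tr2 <- assemble_training(tabs, seed = 5, features = toy_features)
  expect_identical(tr$row_record, tr2$row_record)
  # a table of all-missing targets errors
  tabs[[2]]$target_speed_mm_s <- NA
  expect_error(assemble_training(tabs, features = toy_features),
               "fewer than 5 usable rows")
})

test_that("ensembles learn a noiseless monotone relation and detect a
           degenerate target", {
  tabs <- toy_tables()
  tr <- assemble_training(tabs, seed = 2, features = toy_features)
  models <- train_ensembles(tr, n_ensembles = 3, n_trees = 30, seed = 7)
  expect_length(models, 3)
  expect_true(all(vapply(models, `[[`, 0, "training_r") >= 0.99))
  trc <- tr
  trc$y <- rep(250, length(trc$y))
  expect_error(train_ensembles(trc, 1, 10, seed = 1), "degenerate target")
})

test_that("a bootstrap-disabled single tree reproduces a plain CART fit", {
  tabs <- toy_tables(n_rows = c(30, 30, 30))
  tr <- assemble_training(tabs, seed = 3, features = toy_features)
  set.seed(99)
  forest <- ictalwave:::fit_forest(tr$x, tr$y, seq_along(tr$y), n_trees = 1,
                                   bootstrap = FALSE)
  dat <- data.frame(y = tr$y, tr$x)
  oracle <- rpart::rpart(y ~ ., data = dat, method = "anova",
                         control = rpart::rpart.control(
                           minsplit = 10, minbucket = 5, cp = 0, xval = 0,
                           maxsurrogate = 0, maxcompete = 0))
  expect_equal(ictalwave:::predict_forest(forest, tr$x),
               unname(predict(oracle, dat)))
})

test_that("bagging reduces test error relative to a single tree", {
  tabs <- toy_tables(seed = 4)
  # add noise to the targets so a single deep tree overfits
  tabs <- lapply(tabs, function(tb) {
    tb$target_speed_mm_s <- tb$target_speed_mm_s + rnorm(nrow(tb), 0, 30)
    tb
  })
  tr <- assemble_training(tabs, seed = 4, features = toy_features)
  test_tab <- toy_tables(n_rows = 200, seed = 5)[[1]]
  xt <- as.matrix(test_tab[, toy_features])
  yt <- test_tab$target_speed_mm_s
  wins <- replicate(10, {
    rows <- seq_along(tr$y)
    bag <- ictalwave:::fit_forest(tr$x, tr$y, rows, n_trees = 40)
    single <- ictalwave:::fit_forest(tr$x, tr$y, rows, n_trees = 1,
                                     bootstrap = FALSE)
    e_bag <- mean((ictalwave:::predict_forest(bag, xt) - yt)^2)
    e_one <- mean((ictalwave:::predict_forest(single, xt) - yt)^2)
    e_bag <= e_one
  })
  expect_gte(mean(wins), 0.9)
})

test_that("OOB permutation importance ranks informative over noise features
           and is zero under the identity permutation", {
  tabs <- toy_tables(seed = 6)
  tr <- assemble_training(tabs, seed = 6, features = toy_features)
  models <- train_ensembles(tr, n_ensembles = 3, n_trees = 30, seed = 11)
  for (mdl in models) {
    imp <- oob_importance(mdl)
    expect_length(imp, 10)
    expect_equal(names(which.max(imp)), "inf_feat")
    imp0 <- oob_importance(mdl, permute = "identity")
    expect_true(all(imp0 == 0))
  }
})

test_that("evaluation ranks generalizers and sizes the top set", {
  tabs <- toy_tables(seed = 8)
  tr <- assemble_training(tabs, seed = 8, features = toy_features)
  models <- train_ensembles(tr, n_ensembles = 10, n_trees = 20, seed = 12)
  withheld <- toy_tables(n_rows = 50, seed = 9)[[1]]
  ev <- evaluate_ensembles(models, withheld, importance = FALSE)
  expect_length(ev$withheld_r, 10)
  expect_length(ev$top_idx, 1)  # ceil(0.1 * 10)
  expect_true(all(ev$withheld_r > 0.9))
  expect_equal(ev$top_idx, which.max(ev$withheld_r))
})

test_that("importance of target-independent features stays near zero", {
  set.seed(13)
  tabs <- lapply(1:3, function(i) {
    n <- 40
    tb <- data.frame(start_s = seq_len(n), end_s = seq_len(n) + 4)
    for (j in 1:5) tb[[paste0("noise", j)]] <- runif(n)
    tb$target_speed_mm_s <- rnorm(n)
    tb
  })
  feats <- paste0("noise", 1:5)
  tr <- assemble_training(tabs, seed = 14, features = feats)
  models <- train_ensembles(tr, n_ensembles = 20, n_trees = 20, seed = 15)
  imp <- vapply(models, oob_importance, numeric(5))
  mu <- rowMeans(imp)
  s <- apply(imp, 1, sd)
  expect_true(all(abs(mu) <= 2 * s))
})

test_that("feature epoch comparison rescales, detects trends and is null on
           identical epochs", {
  expect_equal((c(2, 4, 6) - 2) / 4, c(0, 0.5, 1))  # rescale convention
  n <- 40
  mk <- function(vals) data.frame(start_s = seq_len(n) * 3 - 3,
                                  end_s = seq_len(n) * 3 + 1,
                                  trending = vals,
                                  flat = rep(c(1, 2), n / 2))
  set.seed(16)
  tabs <- lapply(1:3, function(i) mk(seq(n, 1) + rnorm(n, 0, 0.5)))
  r <- feature_epoch_comparison(tabs, c("trending", "flat"))
  tr_row <- r[r$feature == "trending", ]
  expect_lt(tr_row$p, 0.01)
  expect_lt(tr_row$median_last, tr_row$median_first)
  flat_row <- r[r$feature == "flat", ]
  expect_gt(flat_row$p, 0.05)
  # constant feature within a seizure: excluded and counted
  tabs2 <- c(tabs, list(mk(rep(5, n))))
  r2 <- feature_epoch_comparison(tabs2, "trending")
  expect_equal(r2$n_excluded_seizures, 1L)
})
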