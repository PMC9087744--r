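# Bagged regression-tree ensembles predicting traveling-wave speed from
# windowed multimodal features, with out-of-bag permutation importance.

#' Assemble a balanced training set from three seizures
#'
#' Rows with missing speed targets are dropped; then, with `k` the
#' usable row count of the smallest table, the longer tables are
#' subsampled uniformly without replacement to `k` rows, so the training
#' set holds exactly `k` observations per seizure.
#'
#' @param tables list of three feature tables ([build_feature_table()]).
#' @param seed RNG seed for the subsampling.
#' @param features feature columns to use (default the ten multimodal
#'   features).
#' @return object of class `"training_set"`: list with `x` (rows x
#'   features), `y` (speed targets), `seizure` (labels), `k`,
#'   `row_record` (which rows of each table were kept).
#' @export
assemble_training <- function(tables, seed = 1,
                              features = feature_names()) {
  stopifnot(length(tables) >= 2)
  usable <- lapply(tables, function(tb) which(!is.na(tb$target_speed_mm_s)))
  if (any(lengths(usable) < 5))
    stop("a table has fewer than 5 usable rows")
  k <- min(lengths(usable))
  picks <- with_seed(seed, lapply(usable, function(u) {
    if (length(u) == k) u else sort(sample(u, k))
  }))
  x <- do.call(rbind, lapply(seq_along(tables), function(i)
    as.matrix(tables[[i]][picks[[i]], features, drop = FALSE])))
  y <- unlist(lapply(seq_along(tables), function(i)
    tables[[i]]$target_speed_mm_s[picks[[i]]]))
  structure(list(x = x, y = y,
                 seizure = rep(seq_along(tables), each = k),
                 k = k, row_record = picks, features = features),
            class = "training_set")
}

# Fit one bagged forest of regression trees on rows `rows` of the
# training set. Trees are CART (variance-reduction splitting), grown
# deep with minimum leaf size `min_leaf`; each tree sees a bootstrap
# resample of `rows` and records its out-of-bag complement.
fit_forest <- function(x, y, rows, n_trees, min_leaf = 5, bootstrap = TRUE) {
  dat <- data.frame(y = y[rows], x[rows, , drop = FALSE])
  ctrl <- rpart::rpart.control(minsplit = 2 * min_leaf, minbucket = min_leaf,
                               cp = 0, xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  n <- length(rows)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[b]] <- rpart::rpart(y ~ ., data = dat[boot, , drop = FALSE],
                               method = "anova", control = ctrl)
    oob[[b]] <- rows[setdiff(seq_len(n), unique(boot))]
  }
  list(trees = trees, oob = oob, rows = rows)
}

predict_forest <- function(forest, newx) {
  nd <- as.data.frame(newx)
  preds <- vapply(forest$trees, function(tr) unname(predict(tr, nd)),
                  numeric(nrow(nd)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(nd))
  rowMeans(preds)
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Train bagged regression-tree ensembles with cross validation
#'
#' For each ensemble the training rows are split into `cv_folds` folds;
#' one bagged forest of `n_trees` CART regression trees is grown on each
#' fold's complement, and the fold model with the best held-out Pearson
#' r is kept as that ensemble's model. All randomness (fold assignment,
#' bootstrap resamples) derives from `seed`.
#'
#' @param training a `"training_set"`.
#' @param n_ensembles number of ensembles.
#' @param n_trees trees per forest (default 100).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed master RNG seed.
#' @param min_leaf minimum leaf size (default 5).
#' @return list of `"ensemble_model"` objects; each carries `forest`
#'   (trees + per-tree OOB row sets), `cv_score` (held-out r of the
#'   kept fold model), `training_r` (r on all training rows), `seed`.
#' @export
train_ensembles <- function(training, n_ensembles, n_trees = 100,
                            cv_folds = 5, seed = 1, min_leaf = 5) {
  stopifnot(inherits(training, "training_set"), n_ensembles >= 1)
  x <- training$x; y <- training$y
  n <- length(y)
  if (n < 2 * cv_folds) stop("too few rows for the requested folds")
  if (sd(y) == 0) stop("degenerate target (constant speed)")
  lapply(seq_len(n_ensembles), function(e) {
    es <- derive_seed(seed, 1000L + e)
    with_seed(es, {
      fold <- sample(rep_len(seq_len(cv_folds), n))
      best <- NULL; best_r <- -Inf
      for (f in seq_len(cv_folds)) {
        rows <- which(fold != f)
        forest <- fit_forest(x, y, rows, n_trees, min_leaf)
        held <- which(fold == f)
        r <- safe_cor(predict_forest(forest, x[held, , drop = FALSE]),
                      y[held])
        if (!is.na(r) && r > best_r) {
          best_r <- r; best <- forest
        }
      }
      if (is.null(best)) {  # all folds degenerate: keep the last fit
        best <- forest; best_r <- NA_real_
      }
      structure(list(forest = best, cv_score = best_r,
                     training_r = safe_cor(predict_forest(best, x), y),
                     x = x, y = y, features = training$features,
                     seed = es),
                class = "ensemble_model")
    })
  })
}

#' Out-of-bag permutation importance
#'
#' For every tree and feature, the feature's values are permuted across
#' the tree's out-of-bag rows and the increase in OOB mean squared error
#' over baseline is recorded. Per-feature importance is the mean of
#' these deltas over trees divided by their SD over trees. Trees with an
#' empty OOB set are skipped with a warning.
#'
#' @param model an `"ensemble_model"` from [train_ensembles()].
#' @param permute `"random"` (seeded from the model) or `"identity"`
#'   (test hook: delta error is exactly 0).
#' @return named numeric vector of importances (one per feature).
#' @export
oob_importance <- function(model, permute = c("random", "identity")) {
  permute <- match.arg(permute)
  x <- model$x; y <- model$y
  feats <- colnames(x)
  forest <- model$forest
  keep <- lengths(forest$oob) > 0
  if (!all(keep))
    warning(sprintf("%d tree(s) with empty OOB set skipped", sum(!keep)))
  trees <- forest$trees[keep]
  oob <- forest$oob[keep]
  delta <- with_seed(derive_seed(model$seed, 77L), {
    vapply(seq_along(trees), function(b) {
      rows <- oob[[b]]
      xo <- x[rows, , drop = FALSE]
      base_pred <- unname(predict(trees[[b]], as.data.frame(xo)))
      base_mse <- mean((base_pred - y[rows])^2)
      vapply(seq_along(feats), function(j) {
        xp <- xo
        perm <- if (permute == "random") sample.int(nrow(xo))
        else seq_len(nrow(xo))
        xp[, j] <- xo[perm, j]
        pp <- unname(predict(trees[[b]], as.data.frame(xp)))
        mean((pp - y[rows])^2) - base_mse
      }, 0)
    }, numeric(length(feats)))
  })
  mu <- apply(delta, 1, mean)
  s <- apply(delta, 1, sd)
  imp <- ifelse(s > 0, mu / s, 0)
  names(imp) <- feats
  imp
}

#' Evaluate ensembles on a withheld seizure
#'
#' Computes each ensemble's Pearson r between observed and predicted
#' speed on the withheld feature table, identifies the top 10% of
#' ensembles by withheld r ("best generalizing"), and summarizes OOB
#' permutation importance over all models and over the top set. Models
#' with undefined r (constant predictions) rank last.
#'
#' @param models list of `"ensemble_model"` objects.
#' @param withheld feature table of the withheld seizure.
#' @param top_frac fraction kept as best generalizers (default 0.1).
#' @param importance logical: compute importance summaries (default
#'   TRUE; the expensive part).
#' @return object of class `"evaluation_report"`: list with
#'   `withheld_r`, `training_r`, `top_idx`, `importance_all`,
#'   `importance_top` (matrices features x models), `importance_summary`
#'   (data.frame feature, mean_all, mean_top).
#' @export
evaluate_ensembles <- function(models, withheld, top_frac = 0.1,
                               importance = TRUE) {
  usable <- which(!is.na(withheld$target_speed_mm_s))
  if (length(usable) < 5) stop("withheld table has fewer than 5 usable rows")
  feats <- models[[1]]$features
  xw <- as.matrix(withheld[usable, feats, drop = FALSE])
  yw <- withheld$target_speed_mm_s[usable]
  r <- vapply(models, function(mdl)
    safe_cor(predict_forest(mdl$forest, xw), yw), 0)
  n_top <- ceiling(top_frac * length(models))
  ord <- order(ifelse(is.na(r), -Inf, r), decreasing = TRUE)
  top_idx <- ord[seq_len(n_top)]
  imp_all <- imp_top <- summary_df <- NULL
  if (importance) {
    imp_all <- vapply(models, oob_importance, numeric(length(feats)))
    imp_top <- imp_all[, top_idx, drop = FALSE]
    summary_df <- data.frame(feature = feats,
                             mean_all = rowMeans(imp_all),
                             mean_top = rowMeans(imp_top))
  }
  structure(list(withheld_r = r,
                 training_r = vapply(models, `[[`, 0, "training_r"),
                 top_idx = top_idx,
                 importance_all = imp_all, importance_top = imp_top,
                 importance_summary = summary_df),
            class = "evaluation_report")
}

#' Feature evolution between seizure epochs
#'
#' Per seizure, min-max rescales each named feature to `[0, 1]`; pools
#' the windows from the first and last `frac` of each seizure's duration
#' across seizures; and runs a two-sided Mann-Whitney U test per
#' feature. Only windows carrying a traveling-wave observation (a
#' non-missing speed target, i.e. in-seizure bins) enter the
#' comparison, so the seizure duration is measured from the discharge
#' activity rather than the recording bounds. Seizures in which a
#' feature is constant are excluded for that feature (rescaling
#' undefined) and counted.
#'
#' @param tables list of feature tables (the training seizures).
#' @param features character vector of feature columns to compare.
#' @param frac epoch fraction of the seizure duration (default 0.25).
#' @return data.frame per feature: `U`, `p`, `median_first`,
#'   `median_last`, `n_first`, `n_last`, `n_excluded_seizures`.
#' @export
feature_epoch_comparison <- function(tables, features, frac = 0.25) {
  tables <- lapply(tables, function(tb) {
    if ("target_speed_mm_s" %in% names(tb))
      tb <- tb[!is.na(tb$target_speed_mm_s), , drop = FALSE]
    tb
  })
  out <- lapply(features, function(fn) {
    first <- c(); last <- c(); excl <- 0L
    for (tb in tables) {
      v <- tb[[fn]]
      rng <- range(v)
      if (diff(rng) == 0) { excl <- excl + 1L; next }
      sc <- (v - rng[1]) / diff(rng)
      ctr <- (tb$start_s + tb$end_s) / 2
      t0 <- min(tb$start_s); t1 <- max(tb$end_s); span <- t1 - t0
      fi <- sc[ctr <= t0 + frac * span]
      la <- sc[ctr >= t1 - frac * span]
      if (length(fi) < 3 || length(la) < 3) {
        excl <- excl + 1L; next
      }
      first <- c(first, fi); last <- c(last, la)
    }
    if (length(first) == 0 || length(last) == 0)
      return(data.frame(feature = fn, U = NA, p = NA,
                        median_first = NA, median_last = NA,
                        n_first = 0L, n_last = 0L,
                        n_excluded_seizures = excl))
    w <- suppressWarnings(
      wilcox.test(first, last, exact = FALSE, correct = FALSE))
    data.frame(feature = fn, U = unname(w$statistic), p = w$p.value,
               median_first = median(first), median_last = median(last),
               n_first = length(first), n_last = length(last),
               n_excluded_seizures = excl)
  })
  do.call(rbind, out)
}
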