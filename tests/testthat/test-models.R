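make_linear_data <- function(n = 120, p = 6, noise = 0, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  beta <- c(2, -1, 0.5, rep(0, p - 3))
  list(x = x, y = as.numeric(x %*% beta + rnorm(n, sd = noise)))
}

test_that("base learners are deterministic and fit their regimes", {
  d <- make_linear_data(n = 40, noise = 0)
  rf <- train_base(pcm_spec("random_forest", list(num_trees = 200L)), d$x, d$y, seed = 5)
  rf2 <- train_base(pcm_spec("random_forest", list(num_trees = 200L)), d$x, d$y, seed = 5)
  expect_identical(predict(rf, d$x), predict(rf2, d$x))
  # deep forest on tiny noiseless data: near-zero training RMSE
  expect_lt(compute_metrics(d$y, predict(rf, d$x))$rmse, stats::sd(d$y) / 3)
  # PLS with full components reproduces exactly linear data
  pls <- train_base(pcm_spec("partial_least_squares", list(ncomp = 6L)), d$x, d$y)
  expect_equal(compute_metrics(d$y, predict(pls, d$x))$r2, 1, tolerance = 1e-6)
  expect_error(train_base(pcm_spec("partial_least_squares", list(ncomp = 50L)),
                          d$x, d$y), "rank")
  gb <- train_base(pcm_spec("gradient_boosting", list(nrounds = 50L)), d$x, d$y, seed = 5)
  gb2 <- train_base(pcm_spec("gradient_boosting", list(nrounds = 50L)), d$x, d$y, seed = 5)
  expect_identical(predict(gb, d$x), predict(gb2, d$x))
  expect_error(pcm_spec("random_forest", list(bogus = 1)), "invalid hyperparameters")
})

test_that("metrics implement the coefficient of determination", {
  expect_equal(compute_metrics(c(1, 2, 3), c(1, 2, 3)), list(r2 = 1, rmse = 0))
  y <- c(2, 4, 6, 8)
  m <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(m$r2, 0)
  m2 <- compute_metrics(c(0, 2), c(1, 1))
  expect_equal(m2$rmse, 1)
  # predicting the observed mean everywhere: SS_res equals SS_tot
  expect_equal(m2$r2, 0)
  expect_warning(res <- compute_metrics(c(5, 5), c(4, 6)), "constant")
  expect_true(is.na(res$r2))
})

test_that("grid search sweeps the full Cartesian grid deterministically", {
  d <- make_linear_data(n = 80, noise = 0.2)
  one <- grid_search(pcm_spec("partial_least_squares"), list(ncomp = 3L), d$x, d$y)
  expect_equal(one$best$ncomp, 3L)
  expect_equal(nrow(one$table), 1L)
  gs <- grid_search(pcm_spec("partial_least_squares"),
                    list(ncomp = c(1L, 2L, 3L, 4L, 50L)), d$x, d$y, seed = 11)
  expect_equal(nrow(gs$table), 5L) # exhaustive, one row per cell
  expect_equal(gs$table$cv_r2[5], -Inf) # rank-deficient cell fails, scored -Inf
  # a component count near the generating one is within 0.02 of the best cell
  expect_gte(gs$best_r2, max(gs$table$cv_r2[1:4]) - 0.02)
  gs2 <- grid_search(pcm_spec("partial_least_squares"),
                     list(ncomp = c(1L, 2L, 3L, 4L, 50L)), d$x, d$y, seed = 11)
  expect_identical(gs$table, gs2$table)
  # rf grid over mixed mtry rules covers all combinations
  rf <- grid_search(pcm_spec("random_forest"),
                    list(num_trees = c(50L, 100L), mtry = c("sqrt", "0.5")),
                    d$x, d$y, folds = 3L)
  expect_equal(nrow(rf$table), 4L)
  expect_equal(table1_grid("random_forest")$num_trees, c(100L, 250L, 500L, 1000L))
})

test_that("forward block selection finds planted signal and stalls honestly", {
  set.seed(21)
  n <- 120
  sig <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  noise1 <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("a", 1:4)))
  noise2 <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("b", 1:4)))
  y <- as.numeric(sig %*% c(2, -2, 1, 1))
  rec <- data.frame(standardized_smiles = paste0("m", 1:n), target_id = "p")
  rownames(sig) <- rownames(noise1) <- rownames(noise2) <- rec$standardized_smiles
  f <- assemble_features(rec, list(informative = sig, junk_a = noise1, junk_b = noise2))
  sel <- stepwise_block_selection(f, y, pcm_spec("partial_least_squares", list(ncomp = 2L)),
                                  folds = 4L, seed = 2)
  expect_equal(sel$selected[1], "informative")
  acc <- sel$trajectory[sel$trajectory$accepted, ]
  expect_true(all(diff(acc$cv_r2) >= -1e-9)) # accepted steps never decrease
  # identical blocks: terminates after patience non-improvements
  f2 <- assemble_features(rec, list(b1 = sig, b2 = sig, b3 = sig, b4 = sig, b5 = sig))
  sel2 <- stepwise_block_selection(f2, y, pcm_spec("partial_least_squares", list(ncomp = 2L)),
                                   patience = 2L, folds = 4L, seed = 2)
  expect_lte(length(sel2$selected), 3L)
  expect_gte(nrow(sel2$trajectory), length(sel2$selected))
})

test_that("meta-features have stacking width and leakage-safe structure", {
  d <- make_linear_data(n = 60, noise = 0.3)
  specs <- list(pcm_spec("partial_least_squares", list(ncomp = 2L)),
                pcm_spec("partial_least_squares", list(ncomp = 2L)))
  mf <- make_meta_features(specs, d$x, d$y, k = 5L, seed = 9)
  expect_equal(ncol(mf$meta), 4L) # 2 bases x (mean, sd)
  # identical base specs give pairwise-identical meta columns
  expect_equal(unname(mf$meta[, 1]), unname(mf$meta[, 3]))
  expect_equal(unname(mf$meta[, 2]), unname(mf$meta[, 4]))
  expect_error(make_meta_features(specs, d$x, d$y, k = 1000L), "exceeds")
})

test_that("the stacked model tracks its bases and is reproducible", {
  bs <- bench_stack()
  best_base <- max(bs$rf_r2, bs$gb_r2)
  expect_gte(bs$stack_metrics$r2, best_base - 0.05)
  st2 <- pcm_stack(bs$xtr, bs$ytr, seed = 12345L)
  expect_identical(predict(bs$model, bs$xte), predict(st2, bs$xte))
  # meta over one base must not degrade a near-unbiased base much
  d <- make_linear_data(n = 100, noise = 0.3)
  sp <- split_random_holdout(100, 0.3, seed = 4)
  base_spec <- pcm_spec("partial_least_squares", list(ncomp = 3L))
  st1 <- pcm_stack(d$x[sp$train, ], d$y[sp$train], base_specs = list(base_spec),
                   meta_spec = pcm_spec("partial_least_squares", list(ncomp = 1L)),
                   k = 5L, seed = 4)
  single <- train_base(base_spec, d$x[sp$train, ], d$y[sp$train], seed = 4)
  rmse_stack <- compute_metrics(d$y[sp$test], predict(st1, d$x[sp$test, ]))$rmse
  rmse_base <- compute_metrics(d$y[sp$test], predict(single, d$x[sp$test, ]))$rmse
  expect_lte(rmse_stack, 1.05 * rmse_base)
})

test_that("split plans are disjoint, exhaustive, and reproducible", {
  sp <- split_random_holdout(10, 0.3, seed = 1)
  expect_length(sp$test, 3L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(split_random_holdout(10, 0.3, seed = 1), sp)
  expect_error(split_random_holdout(1, 0.3), "at least two")

  tm <- split_temporal(c(2008, 2009, 2010, 2011), cut_year = 2010)
  expect_length(tm$train, 2L) # boundary year goes to the test side
  expect_length(tm$test, 2L)
  tm2 <- split_temporal(c(2005, NA, 2015), cut_year = 2010)
  expect_true(2L %in% tm2$train) # missing year trains
  expect_warning(split_temporal(c(2001, 2002), cut_year = 2010), "empty test")
  set.seed(8)
  yrs <- sample(c(rep(2005, 70), rep(2015, 30)))
  tm3 <- split_temporal(yrs, cut_year = 2010)
  expect_length(tm3$train, 70L)
  expect_length(tm3$test, 30L)
})

test_that("target-based splits keep each protein on one side", {
  pd2 <- matrix(rnorm(10), 2, 5, dimnames = list(c("p1", "p2"), NULL))
  ids2 <- c(rep("p1", 7), rep("p2", 3))
  sp2 <- split_target_based(ids2, pd2, train_fraction = 0.7, seed = 1)
  expect_length(intersect(ids2[sp2$train], ids2[sp2$test]), 0L)
  # 20-protein fixture: record share of the training side near 70%
  set.seed(12)
  prots <- paste0("p", 1:20)
  pd <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(prots, NULL))
  ids <- sample(prots, 1000, replace = TRUE)
  sp <- split_target_based(ids, pd, train_fraction = 0.7, seed = 2)
  share <- length(sp$train) / 1000
  expect_gte(share, 0.6)
  expect_lte(share, 0.8)
  expect_length(intersect(unique(ids[sp$train]), unique(ids[sp$test])), 0L)
  expect_identical(split_target_based(ids, pd, train_fraction = 0.7, seed = 2)$train,
                   sp$train)
  expect_error(split_target_based(rep("p1", 5), pd[1, , drop = FALSE]),
               "at least two proteins")
})
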