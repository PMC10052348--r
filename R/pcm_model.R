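# Base learners (random forest, gradient boosting, partial least squares),
# full-grid hyperparameter search, greedy forward selection over descriptor
# blocks, and the stacked ensemble: out-of-fold base predictions (mean and
# fold-spread) feed a second-level meta learner.

.algorithms <- c("random_forest", "gradient_boosting", "partial_least_squares")

.hp_names <- list(
  random_forest = c("num_trees", "mtry", "min_node_size", "max_depth"),
  gradient_boosting = c("nrounds", "eta", "gamma", "max_depth",
                        "subsample", "colsample_bytree"),
  partial_least_squares = c("ncomp")
)

#' Specify a base model
#'
#' @param algorithm one of `"random_forest"`, `"gradient_boosting"`,
#'   `"partial_least_squares"`.
#' @param hyperparameters named list; names must be valid for the
#'   algorithm (`num_trees`, `mtry` (a count, a fraction <= 1, or
#'   `"sqrt"`/`"log2"`), `min_node_size`, `max_depth` for the forest;
#'   `nrounds`, `eta`, `gamma`, `max_depth`, `subsample`,
#'   `colsample_bytree` for boosting; `ncomp` for PLS).
#' @param blocks optional character vector of descriptor block names the
#'   spec is meant to be trained with (bookkeeping only).
#' @return object of class `"pcm_spec"`.
#' @export
pcm_spec <- function(algorithm = .algorithms, hyperparameters = list(), blocks = NULL) {
  algorithm <- match.arg(algorithm)
  bad <- setdiff(names(hyperparameters), .hp_names[[algorithm]])
  assert_that(length(bad) == 0L,
              paste("invalid hyperparameters for", algorithm, ":", paste(bad, collapse = ", ")))
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 blocks = blocks),
            class = "pcm_spec")
}

#' @export
print.pcm_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste(names(x$hyperparameters), unlist(lapply(x$hyperparameters, format)),
          sep = "=", collapse = ", ")
  } else "defaults"
  cat("pcm_spec:", x$algorithm, "(", hp, ")\n")
  invisible(x)
}

.resolve_mtry <- function(mtry, p) {
  if (is.null(mtry)) return(max(1L, floor(sqrt(p))))
  if (is.character(mtry)) {
    num <- suppressWarnings(as.numeric(mtry))
    if (is.na(num)) {
      return(switch(mtry, sqrt = max(1L, floor(sqrt(p))),
                    log2 = max(1L, floor(log2(p))),
                    stop("unknown mtry rule: ", mtry)))
    }
    mtry <- num
  }
  if (mtry <= 1) return(max(1L, floor(mtry * p)))
  min(as.integer(mtry), p)
}

#' Train one base model
#'
#' Deterministic for a given seed (all engines run single-threaded).
#'
#' @param spec a [pcm_spec()].
#' @param x numeric feature matrix.
#' @param y numeric response.
#' @param seed integer seed.
#' @return object of class `"pcm_base_fit"` with a [predict][stats::predict]
#'   method.
#' @export
train_base <- function(spec, x, y, seed = 12345L) {
  stopifnot(inherits(spec, "pcm_spec"), is.matrix(x), nrow(x) == length(y))
  assert_that(all(is.finite(y)), "labels must be finite")
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    random_forest = {
      md <- hp$max_depth
      ranger::ranger(x = x, y = y,
                     num.trees = hp$num_trees %||% 100L,
                     mtry = .resolve_mtry(hp$mtry, ncol(x)),
                     min.node.size = hp$min_node_size %||% 1L,
                     max.depth = if (is.null(md) || is.infinite(md)) 0L else md,
                     seed = seed, num.threads = 1L)
    },
    gradient_boosting = {
      params <- list(objective = "reg:squarederror",
                     eta = hp$eta %||% 0.3,
                     gamma = hp$gamma %||% 0,
                     max_depth = hp$max_depth %||% 6L,
                     subsample = hp$subsample %||% 1,
                     colsample_bytree = hp$colsample_bytree %||% 1,
                     nthread = 1L, seed = seed)
      xgboost::xgb.train(params, xgboost::xgb.DMatrix(x, label = y),
                         nrounds = hp$nrounds %||% 100L, verbose = 0)
    },
    partial_least_squares = {
      keep <- which(apply(x, 2, stats::var) > 0)
      ncomp <- hp$ncomp %||% 2L
      if (ncomp > min(nrow(x) - 1L, length(keep))) {
        stop("PLS components (", ncomp, ") exceed the rank of the data")
      }
      xm <- x[, keep, drop = FALSE]
      if (is.null(colnames(xm))) colnames(xm) <- paste0("x", keep)
      pf <- mixOmics::pls(xm, y, ncomp = ncomp, mode = "regression", scale = FALSE)
      list(fit = pf, keep = keep, ncomp = ncomp, colnames = colnames(xm))
    })
  structure(list(spec = spec, fit = fit, seed = seed, p = ncol(x)),
            class = "pcm_base_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.pcm_base_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$p)
  switch(object$spec$algorithm,
    random_forest = stats::predict(object$fit, newdata, num.threads = 1L)$predictions,
    gradient_boosting = stats::predict(object$fit, xgboost::xgb.DMatrix(newdata)),
    partial_least_squares = {
      f <- object$fit
      nd <- newdata[, f$keep, drop = FALSE]
      colnames(nd) <- f$colnames
      as.numeric(stats::predict(f$fit, nd)$predict[, 1, f$ncomp])
    })
}

#' @export
print.pcm_base_fit <- function(x, ...) {
  cat("Fitted base model:\n")
  print(x$spec)
  invisible(x)
}

#' Coefficient of determination and RMSE
#'
#' R2 is the coefficient of determination 1 - SS_res/SS_tot (not squared
#' Pearson), so it can be negative for predictions worse than the mean.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return list(r2, rmse); `r2` is `NA` (with a warning) when the observed
#'   values are constant.
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  rmse <- sqrt(mean((observed - predicted)^2))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("constant observed values: R2 undefined")
    return(list(r2 = NA_real_, rmse = rmse))
  }
  list(r2 = 1 - sum((observed - predicted)^2) / ss_tot, rmse = rmse)
}

# Cross-validated R2 of a spec on (x, y); failures score -Inf.
cv_r2 <- function(spec, x, y, folds = 5L, seed = 12345L) {
  fold <- fold_assignment(nrow(x), folds, seed)
  pred <- rep(NA_real_, nrow(x))
  for (f in seq_len(folds)) {
    tr <- fold != f
    ok <- try({
      fit <- train_base(spec, x[tr, , drop = FALSE], y[tr], seed = seed + f)
      pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    }, silent = TRUE)
    if (inherits(ok, "try-error")) return(-Inf)
  }
  compute_metrics(y, pred)$r2
}

#' Full-grid hyperparameter search
#'
#' Evaluates every cell of the Cartesian grid by k-fold cross-validated R2
#' and returns the best cell; the full score table is kept for audit. Cells
#' that fail to fit score -Inf. Ties break to the first cell in grid order.
#'
#' @param spec a [pcm_spec()] (its hyperparameters are overridden by the
#'   grid cells).
#' @param grid named list of value vectors, e.g.
#'   `list(num_trees = c(100, 250), mtry = c("sqrt", 0.5))`; see
#'   [table1_grid()] for the defaults used in this pipeline.
#' @param x,y features and response.
#' @param folds CV folds.
#' @param seed fold seed.
#' @return list with `best` (named list of hyperparameters), `best_r2`, and
#'   `table` (data.frame of all cells with their CV R2).
#' @export
grid_search <- function(spec, grid, x, y, folds = 5L, seed = 12345L) {
  stopifnot(inherits(spec, "pcm_spec"), length(grid) >= 1)
  cells <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hp <- as.list(cells[i, , drop = FALSE])
    names(hp) <- names(cells)
    s <- pcm_spec(spec$algorithm, hyperparameters = hp, blocks = spec$blocks)
    scores[i] <- cv_r2(s, x, y, folds = folds, seed = seed)
  }
  best_i <- which.max(scores) # first index on ties
  best <- as.list(cells[best_i, , drop = FALSE])
  names(best) <- names(cells)
  tab <- cbind(cells, cv_r2 = scores)
  list(best = best, best_r2 = scores[best_i], table = tab)
}

#' Hyperparameter grids used for full-grid optimization
#'
#' The per-algorithm grids swept in this pipeline: forests over number of
#' trees (100-1000), mtry rules (sqrt, log2, 10/50/90% of columns), node
#' sizes and depths; boosting over rounds, learning rate, gamma, depth, and
#' row/column subsampling; PLS over the component count.
#'
#' @param algorithm base-model algorithm.
#' @return named list of value vectors for [grid_search()].
#' @export
table1_grid <- function(algorithm = .algorithms) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    random_forest = list(
      num_trees = c(100L, 250L, 500L, 1000L),
      mtry = c("sqrt", "log2", "0.1", "0.5", "0.9"),
      min_node_size = c(1L, 5L, 7L),
      max_depth = c(5, 7, Inf)),
    gradient_boosting = list(
      nrounds = c(100L, 250L, 500L, 1000L),
      eta = c(0.1, 0.3, 0.5),
      gamma = c(0, 0.3, 0.5),
      max_depth = c(5L, 7L),
      subsample = c(0.1, 0.5, 1.0),
      colsample_bytree = c(0.5, 0.7)),
    partial_least_squares = list(ncomp = c(100L, 200L, 300L)))
}

#' Greedy forward selection over descriptor blocks
#'
#' Starting from no blocks, each iteration adds the candidate block with
#' the largest gain in k-fold cross-validated R2. The best first block is
#' always kept; afterwards the search stops after `max_iter` iterations,
#' after `patience` consecutive iterations without improvement, or when no
#' candidate block remains.
#'
#' @param features a `"pcm_features"` object (see [assemble_features()]).
#' @param y response.
#' @param spec base-model spec used for scoring.
#' @param max_iter,patience stopping controls.
#' @param folds,seed cross-validation controls.
#' @return list with `selected` (block names in acceptance order) and
#'   `trajectory` (data.frame: iteration, block, cv_r2, accepted).
#' @export
stepwise_block_selection <- function(features, y, spec, max_iter = 25L,
                                     patience = 3L, folds = 5L, seed = 12345L) {
  stopifnot(inherits(features, "pcm_features"))
  blocks <- names(features$block_index)
  assert_that(length(blocks) >= 1L, "need at least one candidate block")
  selected <- character(0)
  remaining <- blocks
  best_r2 <- -Inf
  stall <- 0L
  traj <- data.frame(iteration = integer(0), block = character(0),
                     cv_r2 = numeric(0), accepted = logical(0))
  for (it in seq_len(max_iter)) {
    if (length(remaining) == 0L || stall >= patience) break
    gains <- vapply(remaining, function(b) {
      cols <- unlist(features$block_index[c(selected, b)], use.names = FALSE)
      cv_r2(spec, features$x[, cols, drop = FALSE], y, folds = folds, seed = seed)
    }, numeric(1))
    cand <- names(gains)[which.max(gains)]
    accept <- gains[cand] > best_r2 || length(selected) == 0L
    traj <- rbind(traj, data.frame(iteration = it, block = cand,
                                   cv_r2 = unname(gains[cand]), accepted = accept))
    if (accept) {
      best_r2 <- max(best_r2, gains[cand])
      selected <- c(selected, cand)
      remaining <- setdiff(remaining, cand)
      stall <- 0L
    } else {
      stall <- stall + 1L
      remaining <- setdiff(remaining, cand)
    }
  }
  list(selected = selected, trajectory = traj)
}

# Fit the k fold-models of one base spec; returns the models plus the fold
# assignment used.
fit_fold_models <- function(spec, x, y, k, seed) {
  fold <- fold_assignment(nrow(x), k, seed)
  models <- lapply(seq_len(k), function(f) {
    train_base(spec, x[fold != f, , drop = FALSE], y[fold != f], seed = seed + f)
  })
  list(models = models, fold = fold)
}

#' Out-of-fold meta-features for stacking
#'
#' For each base spec, k fold-models are fit on k-1 folds each. On the
#' training rows the mean column is the out-of-fold prediction (from the
#' single fold-model whose training data excluded the row, so it is
#' leakage-free) and the spread column is the standard deviation of the
#' row's predictions across all k fold-models. On new rows both are taken
#' across all k fold-models.
#'
#' @param base_specs list of [pcm_spec()] objects (1-2 typically).
#' @param x,y training features and response.
#' @param k fold count.
#' @param seed fold seed.
#' @return list with `meta` (training meta-feature matrix, 2 columns per
#'   base: `<algo><i>_mean`, `<algo><i>_sd`) and `bases` (per-spec fold
#'   models, reusable at inference).
#' @export
make_meta_features <- function(base_specs, x, y, k = 10L, seed = 12345L) {
  stopifnot(k >= 2L)
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of rows (", nrow(x), ")")
  # one shared fold assignment and seed: duplicated base specs yield
  # identical meta columns, and all bases see the same resampling
  bases <- lapply(base_specs, fit_fold_models, x = x, y = y, k = k, seed = seed)
  cols <- lapply(seq_along(bases), function(i) {
    b <- bases[[i]]
    preds <- vapply(b$models, function(m) predict(m, x), numeric(nrow(x)))
    oof <- preds[cbind(seq_len(nrow(x)), b$fold)]
    m <- cbind(oof, apply(preds, 1, stats::sd))
    colnames(m) <- paste0(base_specs[[i]]$algorithm, i, c("_mean", "_sd"))
    m
  })
  list(meta = do.call(cbind, cols), bases = bases)
}

meta_features_new <- function(bases, base_specs, newdata) {
  cols <- lapply(seq_along(bases), function(i) {
    preds <- vapply(bases[[i]]$models, function(m) predict(m, newdata),
                    numeric(nrow(newdata)))
    if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
    m <- cbind(rowMeans(preds), apply(preds, 1, stats::sd))
    colnames(m) <- paste0(base_specs[[i]]$algorithm, i, c("_mean", "_sd"))
    m
  })
  do.call(cbind, cols)
}

#' Fit a stacked proteochemometric model
#'
#' The central fitting function of the package: trains the base learners'
#' fold-model ensembles, builds the out-of-fold meta-features (per-base
#' mean and fold spread of predicted affinity), and fits the meta learner
#' on them. Prediction runs new rows through every fold-model and the meta
#' model.
#'
#' @param x numeric feature matrix (see [assemble_features()]).
#' @param y numeric response (pChEMBL values).
#' @param base_specs list of [pcm_spec()] base models (default: random
#'   forest + gradient boosting).
#' @param meta_spec the second-level model (default: partial least squares
#'   on the meta-features, as in the final pipeline configuration).
#' @param k fold count for the meta-features.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return object of class `"pcm_stack"`.
#' @export
pcm_stack <- function(x, y,
                      base_specs = list(pcm_spec("random_forest"),
                                        pcm_spec("gradient_boosting")),
                      meta_spec = pcm_spec("partial_least_squares",
                                           list(ncomp = 2L)),
                      k = 10L, seed = 12345L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  mf <- make_meta_features(base_specs, x, y, k = k, seed = seed)
  meta_fit <- train_base(meta_spec, mf$meta, y, seed = seed)
  oof_pred <- predict(meta_fit, mf$meta)
  structure(list(base_specs = base_specs, meta_spec = meta_spec,
                 bases = mf$bases, meta_fit = meta_fit, k = k, seed = seed,
                 p = ncol(x), n = nrow(x),
                 training_metrics = compute_metrics(y, oof_pred)),
            class = "pcm_stack")
}

#' @export
predict.pcm_stack <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$p)
  mf <- meta_features_new(object$bases, object$base_specs, newdata)
  predict(object$meta_fit, mf)
}

#' @export
print.pcm_stack <- function(x, ...) {
  cat("Stacked PCM model\n")
  cat("  bases:", paste(vapply(x$base_specs, function(s) s$algorithm, ""),
                        collapse = " + "), "\n")
  cat("  meta: ", x$meta_spec$algorithm, "\n")
  cat("  trained on", x$n, "records x", x$p, "descriptors,",
      x$k, "folds, seed", x$seed, "\n")
  invisible(x)
}

#' @export
summary.pcm_stack <- function(object, ...) {
  print(object)
  tm <- object$training_metrics
  cat(sprintf("  training (out-of-fold meta input) R2 %.3f, RMSE %.3f\n",
              tm$r2, tm$rmse))
  invisible(object)
}

#' @export
plot.pcm_stack <- function(x, newdata, observed, ...) {
  pred <- predict(x, newdata)
  graphics::plot(observed, pred, xlab = "observed pChEMBL",
                 ylab = "predicted pChEMBL", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pred)
}

#' Random hold-out split
#'
#' @param n number of records (or a data.frame, whose rows are counted).
#' @param fraction test fraction in (0, 1).
#' @param seed assignment seed.
#' @return object of class `"split_plan"`: list(kind, train, test) of row
#'   indices, disjoint and exhaustive.
#' @export
split_random_holdout <- function(n, fraction, seed = 12345L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(fraction > 0, fraction < 1)
  assert_that(n >= 2L, "need at least two records to split")
  n_test <- max(1L, round(fraction * n))
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  structure(list(kind = "random_holdout", train = setdiff(seq_len(n), test),
                 test = test), class = "split_plan")
}

#' Temporal split at a publication-year cutoff
#'
#' Records published before `cut_year` train; records from `cut_year`
#' onward test. Records without a year go to the training side (a compound
#' of unknown vintage must never inflate the future test set).
#'
#' @param years integer vector of publication years (NA allowed).
#' @param cut_year boundary year (goes to the test side).
#' @return a `"split_plan"`.
#' @export
split_temporal <- function(years, cut_year = 2010L) {
  test <- which(!is.na(years) & years >= cut_year)
  train <- setdiff(seq_along(years), test)
  if (length(test) == 0L) warning("temporal split: empty test side")
  if (length(train) == 0L) warning("temporal split: empty training side")
  structure(list(kind = "temporal", train = train, test = test,
                 cut_year = cut_year), class = "split_plan")
}

#' Target-based split by protein-descriptor clustering
#'
#' Puts every record of a protein on exactly one side. Proteins are
#' clustered by K-means (k = max(2, round(sqrt(p)))) on the principal
#' components covering >= 90% of descriptor variance; clusters are then
#' assigned greedily to the training side until its record share first
#' reaches `train_fraction`.
#'
#' @param target_ids per-record protein ids.
#' @param protein_descriptors numeric matrix with protein-id rownames.
#' @param train_fraction target share of records on the training side.
#' @param seed K-means seed.
#' @return a `"split_plan"` with the additional element `train_proteins`.
#' @export
split_target_based <- function(target_ids, protein_descriptors,
                               train_fraction = 0.7, seed = 12345L) {
  prots <- unique(target_ids)
  assert_that(length(prots) >= 2L, "target-based split needs at least two proteins")
  pd <- protein_descriptors[prots, , drop = FALSE]
  pd <- pd[, apply(pd, 2, stats::var) > 0, drop = FALSE]
  if (ncol(pd) == 0L) pd <- matrix(stats::rnorm(length(prots)), ncol = 1L,
                                   dimnames = list(prots, "jitter"))
  pc <- stats::prcomp(pd, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(1L, which(cum >= 0.9)[1])
  emb <- pc$x[, seq_len(ncomp), drop = FALSE]
  k <- min(max(2L, round(sqrt(length(prots)))), length(prots))
  cl <- if (k >= length(prots)) seq_along(prots) else {
    with_seed(seed, stats::kmeans(emb, centers = k, nstart = 5L))$cluster
  }
  counts <- table(target_ids)[prots]
  # greedy: largest clusters first, until the training share is reached;
  # the cluster that crosses the threshold is then swapped for whichever
  # remaining cluster lands the share closest to the target fraction
  cl_sizes <- vapply(seq_len(k), function(g) sum(counts[cl == g]), numeric(1))
  ord <- order(cl_sizes, decreasing = TRUE)
  total <- length(target_ids)
  taken <- integer(0)
  got <- 0
  for (g in ord) {
    if (got / total >= train_fraction) break
    taken <- c(taken, g)
    got <- got + cl_sizes[g]
  }
  rest <- setdiff(ord, taken)
  if (length(taken) > 0L && length(rest) > 0L) {
    last <- taken[length(taken)]
    base_share <- (got - cl_sizes[last]) / total
    cand <- c(last, rest)
    shares <- base_share + cl_sizes[cand] / total
    best <- cand[which.min(abs(shares - train_fraction))]
    taken[length(taken)] <- best
  }
  train_prots <- prots[cl %in% taken]
  if (length(train_prots) == length(prots)) { # keep at least one test protein
    drop_g <- taken[which.min(cl_sizes[taken])]
    train_prots <- setdiff(train_prots, prots[cl == drop_g])
  }
  train <- which(target_ids %in% train_prots)
  structure(list(kind = "target_based", train = train,
                 test = setdiff(seq_along(target_ids), train),
                 train_proteins = train_prots), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan (", x$kind, "): ", length(x$train), " train / ",
      length(x$test), " test\n", sep = "")
  invisible(x)
}
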