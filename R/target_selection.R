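# Data-driven selection of related training targets: thresholded sequence
# similarity networks and phylogenetic layers around a seed protein, each
# candidate layer scored with an out-of-the-box random forest.

#' All-versus-all protein similarity scores
#'
#' Smith-Waterman local alignment scores under BLOSUM62 with BLAST-like gap
#' penalties (open 11, extend 1). The matrix is symmetrized by taking the
#' larger of the two alignment orders.
#'
#' @param sequences named character vector or `Biostrings::AAStringSet`.
#' @param gap_opening,gap_extension gap penalties.
#' @return symmetric numeric score matrix with sequence names on both
#'   dimensions.
#' @export
all_vs_all_scores <- function(sequences, gap_opening = 11, gap_extension = 1) {
  sequences <- as_named_chr(sequences)
  n <- length(sequences)
  assert_that(n >= 1L, "need at least one sequence")
  assert_that(all(nzchar(sequences)), "empty sequence")
  assert_that(!is.null(names(sequences)) && !anyNA(names(sequences)),
              "sequences must be named")
  aa <- Biostrings::AAStringSet(sequences)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  m <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n)) {
    pa <- Biostrings::pairwiseAlignment(aa, aa[[i]], type = "local",
                                        substitutionMatrix = sub,
                                        gapOpening = gap_opening,
                                        gapExtension = gap_extension,
                                        scoreOnly = TRUE)
    m[, i] <- pa
  }
  pmax(m, t(m))
}

#' Build a similarity network at a score threshold
#'
#' @param scores symmetric similarity matrix (see [all_vs_all_scores()]).
#' @param threshold minimum score for an edge; self-edges are excluded.
#' @return object of class `"similarity_network"`: list with `graph`
#'   (igraph), `threshold`, `nodes`, and `edges` (data.frame from, to,
#'   score).
#' @export
build_network <- function(scores, threshold) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores), threshold >= 0)
  idx <- which(upper.tri(scores) & scores >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(scores)[idx[, 1]],
                      to = colnames(scores)[idx[, 2]],
                      score = scores[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = rownames(scores)))
  structure(list(graph = g, threshold = threshold, nodes = rownames(scores),
                 edges = edges),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Similarity network: ", length(x$nodes), " proteins, ",
      nrow(x$edges), " edges at score threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Connected component containing the seed protein
#'
#' @param network a `"similarity_network"`.
#' @param seed seed protein id (must be a node).
#' @return character vector of protein ids in the seed's component.
#' @export
seed_component <- function(network, seed) {
  stopifnot(inherits(network, "similarity_network"))
  assert_that(seed %in% network$nodes, paste("seed", seed, "is not a node"))
  comp <- igraph::components(network$graph)
  members <- names(comp$membership)[comp$membership == comp$membership[seed]]
  sort(members)
}

#' Seed components across a descending threshold sweep
#'
#' @param scores symmetric similarity matrix.
#' @param seed seed protein id.
#' @param thresholds strictly decreasing score cutoffs (the defaults follow
#'   raw-BLAST-score conventions and should be adapted to the scoring
#'   scheme in use).
#' @return list with one element per threshold: list(threshold, proteins);
#'   protein sets weakly grow as the threshold falls.
#' @export
threshold_sweep <- function(scores, seed, thresholds = c(850, 650, 550, 350, 100)) {
  stopifnot(length(thresholds) >= 1, all(diff(thresholds) < 0) || length(thresholds) == 1)
  lapply(thresholds, function(t) {
    list(threshold = t, proteins = seed_component(build_network(scores, t), seed))
  })
}

#' Nested phylogenetic layers around the seed protein
#'
#' Builds a neighbor-joining tree from pairwise global-alignment
#' fractional-identity distances, roots it at the leaf farthest from the
#' seed (so the seed sits at maximal depth), and returns the leaf sets
#' under successive ancestors of the seed leaf: the first layer is the
#' seed itself, the last layer is every leaf. Identical consecutive
#' layers are deduplicated.
#'
#' @param sequences named character vector (>= 2, including the seed).
#' @param seed seed protein id.
#' @return list with `layers` (list of character vectors, ordered by
#'   inclusion) and `tree` (the rooted `ape::phylo` tree).
#' @export
build_phylo_layers <- function(sequences, seed) {
  sequences <- as_named_chr(sequences)
  assert_that(length(sequences) >= 2L, "need at least two sequences")
  assert_that(seed %in% names(sequences), paste("seed", seed, "not among sequences"))
  aa <- Biostrings::AAStringSet(sequences)
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(aa[(i + 1L):n], aa[[i]], type = "global")
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - Biostrings::pid(pa) / 100
  }
  tree <- ape::nj(stats::as.dist(d))
  # root at the leaf farthest from the seed, so layers grow up from the seed
  far <- names(sequences)[order(-d[seed, names(sequences)], names(sequences))][1]
  tree <- ape::root(tree, outgroup = far, resolve.root = TRUE)
  tip <- match(seed, tree$tip.label)
  # walk from the seed tip to the root, collecting subtree leaf sets
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  layers <- list(seed)
  node <- tip
  repeat {
    p <- parent_of(node)
    if (length(p) == 0L) break
    tips <- ape::extract.clade(tree, p)$tip.label
    layers[[length(layers) + 1L]] <- sort(tips)
    node <- p
  }
  keep <- c(TRUE, vapply(seq_along(layers)[-1], function(i) {
    !identical(layers[[i]], layers[[i - 1L]])
  }, logical(1)))
  list(layers = layers[keep], tree = tree)
}

#' Evaluate one candidate training layer
#'
#' Fits the fixed out-of-the-box random-forest configuration (100 trees,
#' mtry = sqrt(p), minimum node size 1, unlimited depth) and reports the
#' internally cross-validated (5-fold) coefficient of determination and
#' RMSE under a seeded fold assignment.
#'
#' @param features `"pcm_features"` object (or a plain matrix) for the
#'   layer's records.
#' @param labels numeric response (pChEMBL values).
#' @param folds number of CV folds.
#' @param min_records layers with fewer records are marked unevaluable.
#' @param seed fold-assignment and forest seed.
#' @return list(cv_r2, cv_rmse, n, evaluable).
#' @export
evaluate_layer <- function(features, labels, folds = 5L, min_records = 20L,
                           seed = 12345L) {
  x <- if (inherits(features, "pcm_features")) features$x else features
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (n < min_records) {
    return(list(cv_r2 = NA_real_, cv_rmse = NA_real_, n = n, evaluable = FALSE))
  }
  fold <- fold_assignment(n, folds, seed)
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = labels[tr],
                          num.trees = 100L, mtry = floor(sqrt(ncol(x))),
                          min.node.size = 1L, seed = seed + f, num.threads = 1L)
    pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE],
                                num.threads = 1L)$predictions
  }
  m <- compute_metrics(labels, pred)
  list(cv_r2 = m$r2, cv_rmse = m$rmse, n = n, evaluable = TRUE)
}

#' Choose the training layer
#'
#' Among evaluable layers whose cross-validated R2 is within `r2_tolerance`
#' of the best, returns the one with the most records (a larger, comparably
#' scoring training set is preferred); ties break to the earlier layer in
#' the supplied order.
#'
#' @param layers list of layer descriptors, each a list with at least
#'   `label`, `n`, `cv_r2`, `evaluable`.
#' @param r2_tolerance layers within this margin of the best R2 count as
#'   comparable.
#' @return the chosen element of `layers`.
#' @export
select_dataset <- function(layers, r2_tolerance = 0.01) {
  ev <- Filter(function(l) isTRUE(l$evaluable), layers)
  assert_that(length(ev) >= 1L, "no evaluable layers")
  r2 <- vapply(ev, function(l) l$cv_r2, numeric(1))
  n <- vapply(ev, function(l) l$n, numeric(1))
  ok <- which(r2 >= max(r2) - r2_tolerance)
  ev[[ok[which.max(n[ok])]]]
}

#' Build, evaluate, and choose among nested training layers
#'
#' End-to-end driver for training-set selection: alignment scores, the
#' descending similarity-network threshold sweep, phylogenetic layers over
#' the widest component, deduplication of overlapping layer pairs by
#' protein-set equality, per-layer evaluation, and the final choice.
#'
#' @param records curated activity records (see [curate_dataset()]).
#' @param sequences named character vector of protein sequences.
#' @param seed_target the protein whose ligand space is being expanded.
#' @param thresholds descending similarity-network cutoffs.
#' @param feature_fun function(records) returning a `"pcm_features"` object
#'   (or matrix) for a layer's records.
#' @param r2_tolerance see [select_dataset()].
#' @param folds,min_records,seed passed to [evaluate_layer()].
#' @return list with `layers` (all evaluated layers: label, proteins, n,
#'   cv_r2, cv_rmse, evaluable), `chosen` (the selected layer), `scores`,
#'   and `tree`.
#' @export
select_training_set <- function(records, sequences, seed_target,
                                thresholds = c(850, 650, 550, 350, 100),
                                feature_fun, r2_tolerance = 0.01,
                                folds = 5L, min_records = 20L, seed = 12345L) {
  sequences <- as_named_chr(sequences)
  scores <- all_vs_all_scores(sequences)
  sweep <- threshold_sweep(scores, seed_target, thresholds)
  widest <- sweep[[length(sweep)]]$proteins
  cand <- lapply(sweep, function(s) {
    list(label = paste0("SN", s$threshold), proteins = s$proteins)
  })
  tree <- NULL
  if (length(widest) >= 2L) {
    ph <- build_phylo_layers(sequences[widest], seed_target)
    tree <- ph$tree
    cand <- c(cand, lapply(seq_along(ph$layers), function(i) {
      list(label = paste0("layer", i), proteins = ph$layers[[i]])
    }))
  }
  # overlapping network/phylo layer pairs are evaluated once
  keys <- vapply(cand, function(l) paste(sort(l$proteins), collapse = ","), "")
  cand <- cand[!duplicated(keys)]
  layers <- lapply(cand, function(l) {
    rec <- records[records$target_id %in% l$proteins, , drop = FALSE]
    ev <- if (nrow(rec) >= min_records) {
      evaluate_layer(feature_fun(rec), rec$pchembl, folds = folds,
                     min_records = min_records, seed = seed)
    } else list(cv_r2 = NA_real_, cv_rmse = NA_real_, n = nrow(rec), evaluable = FALSE)
    c(l, ev, list(records = rec))
  })
  chosen <- select_dataset(layers, r2_tolerance)
  list(layers = layers, chosen = chosen, scores = scores, tree = tree)
}
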