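# Hierarchical density-based clustering (HDBSCAN). Single-linkage over
# mutual-reachability distances, condensed at a minimum cluster size, with
# excess-of-mass cluster selection. Implemented here because no installed
# package provides it; validated against planted-structure fixtures.

#' HDBSCAN clustering from a distance matrix
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param min_cluster_size smallest cluster that may survive condensation.
#' @param min_samples neighborhood size for core distances (defaults to
#'   `min_cluster_size`, the common single-parameter convention).
#' @return integer vector of cluster labels; 0 marks noise, clusters are
#'   numbered 1..k in decreasing size order. Every non-noise cluster has at
#'   least `min_cluster_size` members.
#' @export
hdbscan_labels <- function(d, min_cluster_size = 19L, min_samples = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  mcs <- as.integer(min_cluster_size)
  stopifnot(mcs >= 2L)
  ms <- as.integer(min_samples %||% mcs)
  if (n < max(mcs, 2L)) return(rep(0L, n))

  # core distance: distance to the ms-th nearest neighbor, self included
  core <- vapply(seq_len(n), function(i) {
    sort(d[i, ], partial = ms)[ms]
  }, numeric(1))
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")

  merge <- hc$merge
  height <- hc$height
  pos <- height[height > 0]
  eps <- if (length(pos)) max(min(pos) * 1e-3, 1e-12) else 1e-12
  lam <- 1 / pmax(height, eps) # lambda at which each dendrogram node splits

  # leaf counts and point lists per dendrogram node
  node_pts <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    kids <- merge[m, ]
    pts <- integer(0)
    for (kid in kids) {
      pts <- c(pts, if (kid < 0) -kid else node_pts[[kid]])
    }
    node_pts[[m]] <- pts
  }

  # condensed tree: clusters born at a lambda, losing points / splitting as
  # lambda rises. Built iteratively from the dendrogram root down.
  clusters <- list() # each: parent, lambda_birth, stability, children ids
  point_cluster <- integer(n) # condensed cluster each point is attached to
  point_lambda <- numeric(n)
  new_cluster <- function(parent, lambda_birth) {
    clusters[[length(clusters) + 1L]] <<- list(parent = parent,
                                               lambda_birth = lambda_birth,
                                               stability = 0, children = integer(0))
    id <- length(clusters)
    if (parent > 0L) clusters[[parent]]$children <<- c(clusters[[parent]]$children, id)
    id
  }
  root_id <- new_cluster(0L, 0)
  # stack of (dendrogram node, condensed cluster id)
  stack <- list(c(n - 1L, root_id))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; cid <- top[2]
    lambda <- lam[node]
    kids <- merge[node, ]
    sizes <- vapply(kids, function(kid) if (kid < 0) 1L else length(node_pts[[kid]]),
                    integer(1))
    big <- sizes >= mcs
    if (all(big)) {
      # true split: current cluster dies, two children are born
      pts_here <- node_pts[[node]]
      lb <- clusters[[cid]]$lambda_birth
      clusters[[cid]]$stability <- clusters[[cid]]$stability +
        length(pts_here) * (lambda - lb)
      for (kid in kids) {
        child_id <- new_cluster(cid, lambda)
        stack[[length(stack) + 1L]] <- c(kid, child_id)
      }
    } else {
      # points of sub-threshold children fall out of the cluster at lambda
      lb <- clusters[[cid]]$lambda_birth
      for (j in seq_along(kids)) {
        kid <- kids[j]
        pts <- if (kid < 0) -kid else node_pts[[kid]]
        if (!big[j]) {
          clusters[[cid]]$stability <- clusters[[cid]]$stability +
            length(pts) * (lambda - lb)
          point_cluster[pts] <- cid
          point_lambda[pts] <- lambda
        } else {
          stack[[length(stack) + 1L]] <- c(kid, cid)
        }
      }
    }
  }

  # excess-of-mass selection, bottom-up. The root is never selected unless
  # the hierarchy produced no split at all (one homogeneous clump).
  nc <- length(clusters)
  selected <- logical(nc)
  subtree_stab <- numeric(nc)
  for (cid in rev(seq_len(nc))) { # children are always created after parents
    ch <- clusters[[cid]]$children
    child_sum <- sum(subtree_stab[ch])
    own <- clusters[[cid]]$stability
    if (cid == root_id) {
      subtree_stab[cid] <- child_sum
      if (nc == 1L && n >= mcs) selected[cid] <- TRUE
    } else if (length(ch) == 0L || own > child_sum) {
      selected[cid] <- TRUE
      subtree_stab[cid] <- max(own, child_sum)
      # deselect all descendants
      desc <- ch
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(lapply(desc, function(x) clusters[[x]]$children))
      }
    } else {
      subtree_stab[cid] <- child_sum
    }
  }

  # label: walk from each point's attachment up to the first selected cluster
  labels <- integer(n)
  sel_label <- integer(nc)
  sel_ids <- which(selected)
  sel_label[sel_ids] <- seq_along(sel_ids)
  for (i in seq_len(n)) {
    cid <- point_cluster[i]
    while (cid > 0L && !selected[cid]) cid <- clusters[[cid]]$parent
    labels[i] <- if (cid > 0L) sel_label[cid] else 0L
  }
  # renumber in decreasing size order
  if (any(labels > 0L)) {
    tab <- sort(table(labels[labels > 0L]), decreasing = TRUE)
    remap <- integer(max(labels))
    remap[as.integer(names(tab))] <- seq_along(tab)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}
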