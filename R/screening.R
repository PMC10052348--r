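# Virtual screening: stream a compound library through the fitted model,
# keep predicted actives, enforce the similarity-band novelty filter against
# the training set, cluster survivors, and flag cluster representatives.

#' Screen a compound library with a fitted PCM model
#'
#' Streams the library in batches (bounded memory in the library size):
#' each batch is standardized, fingerprinted, assembled against the seed
#' target's protein descriptors, and scored; compounds predicted at or
#' above the affinity threshold are retained. Unparseable SMILES are
#' counted and skipped.
#'
#' @param model a fitted model with a `predict` method over feature rows
#'   (typically a [pcm_stack()]).
#' @param library a file path (SMILES per line, optional id after
#'   whitespace, `.gz` allowed) or a character vector of SMILES.
#' @param make_features function(standardized_smiles) returning the feature
#'   matrix rows for a batch of compounds (the caller fixes the protein
#'   side to the seed target).
#' @param threshold pChEMBL retention cutoff; 7.0 is 100 nM. Compounds at
#'   the threshold are kept.
#' @param batch_size compounds per streamed batch.
#' @return list with `hits` (data.frame: smiles, id, predicted_pchembl,
#'   sorted by decreasing prediction) and counts `n_read`, `n_scored`,
#'   `n_skipped`.
#' @export
screen_library <- function(model, library, make_features, threshold = 7.0,
                           batch_size = 2000L) {
  stopifnot(is.function(make_features))
  if (is.character(library) && length(library) == 1L && file.exists(library)) {
    con <- if (grepl("\\.gz$", library)) gzfile(library, "r") else file(library, "r")
    on.exit(close(con))
    read_batch <- function() readLines(con, n = batch_size)
  } else {
    stopifnot(is.character(library))
    pos <- 0L
    read_batch <- function() {
      if (pos >= length(library)) return(character(0))
      batch <- library[(pos + 1L):min(pos + batch_size, length(library))]
      pos <<- pos + length(batch)
      batch
    }
  }
  hits <- list()
  n_read <- n_scored <- n_skipped <- 0L
  repeat {
    lines <- read_batch()
    if (length(lines) == 0L) break
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) next
    n_read <- n_read + length(lines)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, "")
    std <- standardize_compound(smi)
    ok <- !is.na(std)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    std_ok <- as.character(std)[ok]
    x <- make_features(std_ok)
    pred <- as.numeric(predict(model, x))
    n_scored <- n_scored + length(pred)
    keep <- pred >= threshold
    if (any(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        smiles = std_ok[keep],
        id = ids[ok][keep],
        predicted_pchembl = pred[keep])
    }
  }
  if (n_read == 0L) warning("empty library")
  hits <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(smiles = character(0), id = character(0),
               predicted_pchembl = numeric(0))
  }
  hits <- hits[order(-hits$predicted_pchembl, hits$smiles), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, n_read = n_read, n_scored = n_scored, n_skipped = n_skipped)
}

#' Similarity-band novelty filter
#'
#' Computes each hit's Tanimoto similarity to its nearest training
#' compound and keeps hits strictly inside the band
#' `low < s < high`: compounds at or below `low` are too dissimilar to
#' trust the model (outside the applicability domain), compounds at or
#' above `high` are not novel.
#'
#' @param hits data.frame of screening hits (see [screen_library()]).
#' @param hit_fps fingerprint matrix for `hits` rows.
#' @param training_fps fingerprint matrix of the training compounds (same
#'   length and parameters).
#' @param low,high band edges; both boundaries are excluded.
#' @return the kept subset of `hits`, annotated with
#'   `nearest_training_similarity`.
#' @export
novelty_filter <- function(hits, hit_fps, training_fps, low = 0.50, high = 0.90) {
  assert_that(nrow(training_fps) > 0, "empty training fingerprint set")
  stopifnot(nrow(hits) == nrow(hit_fps), ncol(hit_fps) == ncol(training_fps))
  if (nrow(hits) == 0L) {
    hits$nearest_training_similarity <- numeric(0)
    return(hits)
  }
  s <- apply(tanimoto_matrix(hit_fps, training_fps), 1, max)
  hits$nearest_training_similarity <- s
  out <- hits[s > low & s < high, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster screening hits in fingerprint space
#'
#' Density-based hierarchical clustering ([hdbscan_labels()]) on the
#' Jaccard distance of the hit fingerprints. Clustering operates on the
#' fingerprints directly, never on a 2D embedding.
#'
#' @param fingerprints 0/1 matrix of hit fingerprints.
#' @param min_cluster_size smallest surviving cluster.
#' @return integer label vector (0 = noise).
#' @export
cluster_hits <- function(fingerprints, min_cluster_size = 19L) {
  stopifnot(is.matrix(fingerprints), nrow(fingerprints) >= 1L)
  d <- 1 - tanimoto_matrix(fingerprints, fingerprints)
  hdbscan_labels(d, min_cluster_size = min_cluster_size)
}

#' Flag one representative hit per cluster
#'
#' Within every non-noise cluster the hit with the highest predicted
#' affinity is flagged; ties break to the higher nearest-training
#' similarity, then to lexicographic SMILES order. Noise points are never
#' representatives.
#'
#' @param hits data.frame with `predicted_pchembl`, `cluster_label`, and
#'   (optionally) `nearest_training_similarity` and `smiles` columns.
#' @return `hits` with a logical `is_representative` column.
#' @export
select_representatives <- function(hits) {
  stopifnot(all(c("predicted_pchembl", "cluster_label") %in% names(hits)))
  hits$is_representative <- FALSE
  sim <- hits$nearest_training_similarity %||% rep(0, nrow(hits))
  smi <- hits$smiles %||% rep("", nrow(hits))
  for (cl in setdiff(unique(hits$cluster_label), 0L)) {
    idx <- which(hits$cluster_label == cl)
    ord <- order(-hits$predicted_pchembl[idx], -sim[idx], smi[idx])
    hits$is_representative[idx[ord[1]]] <- TRUE
  }
  if (all(hits$cluster_label == 0L) && nrow(hits) > 0L) {
    warning("all hits are noise: no representatives selected")
  }
  hits
}

#' Run the post-prediction screening pipeline
#'
#' Order: affinity filter (inside [screen_library()]) -> novelty band ->
#' clustering -> representative selection. Both filters are idempotent on
#' their own output.
#'
#' @param screened result of [screen_library()].
#' @param training_smiles standardized SMILES of the training compounds.
#' @param radius,n_bits fingerprint parameters (ECFP-6, 1024 bits by
#'   default).
#' @param low,high novelty band (see [novelty_filter()]).
#' @param min_cluster_size see [cluster_hits()].
#' @return data.frame of kept hits with similarity, cluster labels and the
#'   representative flag.
#' @export
screen_postprocess <- function(screened, training_smiles, radius = 3L,
                               n_bits = 1024L, low = 0.50, high = 0.90,
                               min_cluster_size = 19L) {
  hits <- screened$hits
  if (nrow(hits) == 0L) {
    hits$nearest_training_similarity <- numeric(0)
    hits$cluster_label <- integer(0)
    hits$is_representative <- logical(0)
    return(hits)
  }
  hit_fps <- compound_block_ecfp(hits$smiles, radius = radius, n_bits = n_bits)
  train_fps <- compound_block_ecfp(unique(training_smiles), radius = radius,
                                   n_bits = n_bits)
  kept <- novelty_filter(hits, hit_fps[hits$smiles, , drop = FALSE], train_fps,
                         low = low, high = high)
  if (nrow(kept) == 0L) {
    kept$cluster_label <- integer(0)
    kept$is_representative <- logical(0)
    return(kept)
  }
  kept$cluster_label <- cluster_hits(hit_fps[kept$smiles, , drop = FALSE],
                                     min_cluster_size = min_cluster_size)
  select_representatives(kept)
}
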