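test_that("library screening keeps the affinity boundary and streams faithfully", {
  smi <- c("CCO", "CCN", "CCC")
  model <- stub_model(c(CCO = 6.9, CCN = 7.0, CCC = 7.4))
  scr <- screen_library(model, smi, stub_features, threshold = 7.0)
  expect_equal(nrow(scr$hits), 2L) # the boundary prediction is kept
  expect_setequal(scr$hits$smiles, c("CCN", "CCC"))
  expect_equal(scr$hits$predicted_pchembl[1], 7.4) # ranked by prediction
  none <- screen_library(model, smi, stub_features, threshold = 99)
  expect_equal(nrow(none$hits), 0L)
  expect_warning(screen_library(model, character(0), stub_features), "empty library")
})

test_that("streamed and in-memory screening agree, counting unparseables", {
  deck <- generate_compound_library(400L, seed = 31)
  lines <- paste(deck, paste0("d", seq_along(deck)))
  lines[c(5, 50)] <- c("notasmiles(( x1", "C1CC x2")
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(lines, f)
  std <- as.character(standardize_compound(deck))
  model <- stub_model(stats::setNames(5 + (nchar(std) %% 40) / 10, std))
  mem <- screen_library(model, lines, stub_features, threshold = 7.0, batch_size = 1e6)
  stream <- screen_library(model, f, stub_features, threshold = 7.0, batch_size = 37)
  expect_identical(stream$hits, mem$hits)
  expect_equal(stream$n_skipped, 2L)
  expect_equal(stream$n_read, 400L)
  # gzipped input streams identically
  fg <- withr::local_tempfile(fileext = ".smi.gz")
  con <- gzfile(fg, "w"); writeLines(lines, con); close(con)
  gz <- screen_library(model, fg, stub_features, threshold = 7.0, batch_size = 53)
  expect_identical(gz$hits, mem$hits)
})

test_that("the novelty band keeps strictly intermediate similarities", {
  v <- function(bits, n = 20) { x <- integer(n); x[bits] <- 1L; x }
  train <- rbind(v(1:10), v(11:20))
  hits <- data.frame(smiles = c("a", "b", "c"), id = NA,
                     predicted_pchembl = c(7, 7, 7))
  hit_fps <- rbind(v(c(1:9, 11)),  # 9/11 ~ 0.82 to train 1 -> kept
                   v(1:10),        # 1.00 -> removed (too similar)
                   v(1:5))        # 5/10 = 0.50 -> removed (low boundary)
  kept <- novelty_filter(hits, hit_fps, train, low = 0.5, high = 0.9)
  expect_equal(kept$smiles, "a")
  expect_equal(kept$nearest_training_similarity, 9 / 11, tolerance = 1e-12)
  expect_error(novelty_filter(hits, hit_fps, train[0, , drop = FALSE]),
               "empty training")
})

test_that("novelty filtering matches an exhaustive nearest-neighbor oracle", {
  deck <- generate_compound_library(300L, seed = 41)
  train <- generate_compound_library(60L, seed = 43)
  dfp <- compound_block_ecfp(unique(as.character(standardize_compound(deck))))
  tfp <- compound_block_ecfp(unique(as.character(standardize_compound(train))))
  hits <- data.frame(smiles = rownames(dfp), id = NA,
                     predicted_pchembl = 7.5)
  kept <- novelty_filter(hits, dfp, tfp)
  # oracle: per-compound loop over the scalar tanimoto
  oracle_sim <- vapply(seq_len(nrow(dfp)), function(i) {
    max(vapply(seq_len(nrow(tfp)), function(j) tanimoto(dfp[i, ], tfp[j, ]),
               numeric(1)))
  }, numeric(1))
  expect_setequal(kept$smiles, hits$smiles[oracle_sim > 0.5 & oracle_sim < 0.9])
  expect_equal(kept$nearest_training_similarity,
               oracle_sim[oracle_sim > 0.5 & oracle_sim < 0.9])
  # filtering is idempotent on its own output
  kept2 <- novelty_filter(kept, dfp[kept$smiles, , drop = FALSE], tfp)
  expect_equal(kept2$smiles, kept$smiles)
})

test_that("density clustering respects the minimum cluster size", {
  b <- make_blobs(c(30, 30), seed = 5)
  d <- 1 - pcmscreen:::tanimoto_matrix(b$fp, b$fp)
  lab <- hdbscan_labels(d, min_cluster_size = 19L)
  expect_equal(length(setdiff(unique(lab), 0L)), 2L) # two planted blobs
  expect_gte(min(table(lab[lab > 0])), 19L)
  # agreement with the planted labels up to renaming
  expect_equal(length(unique(paste(lab, b$labels))), 2L)
  # too few points: everything is noise
  few <- make_blobs(c(10), seed = 6)
  dfw <- 1 - pcmscreen:::tanimoto_matrix(few$fp, few$fp)
  expect_true(all(hdbscan_labels(dfw, min_cluster_size = 19L) == 0L))
  # duplicated identical points at least min size form one cluster
  fp <- matrix(rep(c(1L, 0L, 1L, 0L), each = 25), 25, 4)
  dd <- 1 - pcmscreen:::tanimoto_matrix(fp, fp)
  lab2 <- hdbscan_labels(dd, min_cluster_size = 20L)
  expect_equal(unique(lab2), 1L)
  # cluster_hits wraps the fingerprints directly
  expect_equal(length(setdiff(unique(cluster_hits(b$fp, min_cluster_size = 19L)), 0L)), 2L)
})

test_that("non-noise clusters never fall below the size floor", {
  for (s in 1:5) {
    set.seed(s)
    fp <- matrix(rbinom(60 * 32, 1, 0.3), 60, 32)
    lab <- hdbscan_labels(1 - pcmscreen:::tanimoto_matrix(fp, fp),
                          min_cluster_size = 8L)
    expect_length(lab, 60L)
    if (any(lab > 0)) expect_gte(min(table(lab[lab > 0])), 8L)
  }
})

test_that("one representative per cluster, picked by prediction then tie-breaks", {
  hits <- data.frame(
    smiles = c("a", "b", "c", "d", "e", "f"),
    predicted_pchembl = c(7.1, 7.5, 7.2, 8.0, 7.9, 7.5),
    nearest_training_similarity = c(0.6, 0.7, 0.8, 0.6, 0.6, 0.8),
    cluster_label = c(1L, 1L, 1L, 2L, 2L, 0L))
  out <- select_representatives(hits)
  expect_equal(out$smiles[out$is_representative], c("b", "d"))
  expect_false(out$is_representative[out$cluster_label == 0L])
  # tie on prediction: higher similarity wins, then SMILES order
  tie <- data.frame(smiles = c("z", "y"), predicted_pchembl = c(7, 7),
                    nearest_training_similarity = c(0.6, 0.6),
                    cluster_label = c(1L, 1L))
  expect_equal(tie$smiles[select_representatives(tie)$is_representative], "y")
  expect_warning(select_representatives(data.frame(smiles = "a",
                                                   predicted_pchembl = 7,
                                                   cluster_label = 0L)),
                 "noise")
})

test_that("2D embedding is seeded, shape-preserving, and separates blobs", {
  b <- make_blobs(c(35, 35), seed = 8)
  y1 <- embed_2d(b$fp, perplexity = 10, n_iter = 250, seed = 12345)
  y2 <- embed_2d(b$fp, perplexity = 10, n_iter = 250, seed = 12345)
  expect_identical(y1, y2)
  expect_equal(nrow(y1), 70L)
  inter <- mean(as.matrix(stats::dist(y1))[b$labels == 1, b$labels == 2])
  intra1 <- mean(as.matrix(stats::dist(y1[b$labels == 1, ])))
  expect_gt(inter, intra1)
  expect_error(embed_2d(b$fp[1:10, ], perplexity = 10), "at least")
})
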