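# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The standard benchmark world: 12 proteins / 3 tiers, 400 compounds,
# 2,000 records, signal shared by tiers 1-2.
bench_world <- function() cached("world", function() generate_world(seed = 12345L))

bench_curated <- function() cached("curated", function() {
  w <- bench_world()
  curate_dataset(w$bioactivity$activities, w$family$sequences)
})

# Records restricted to the signal-sharing tiers, with assembled features
# (ECFP-4/256 matching the latent model, plus Z-scale ACC).
bench_features <- function() cached("features", function() {
  w <- bench_world()
  rec <- bench_curated()$records
  shared <- w$family$tiers$id[w$family$tiers$tier %in% c(1, 2)]
  rec <- rec[rec$target_id %in% shared, ]
  cb <- compound_block_ecfp(unique(rec$standardized_smiles), radius = 2L, n_bits = 256L)
  pb <- protein_block_zscale_acc(w$family$sequences)
  list(records = rec, compound_block = cb, protein_block = pb,
       features = assemble_features(rec, list(ecfp = cb), list(zacc = pb)))
})

# Stacked model trained on a 70% split of the benchmark records, plus the
# held-out side and base-model metrics.
bench_stack <- function() cached("stack", function() {
  bf <- bench_features()
  x <- bf$features$x
  y <- bf$records$pchembl
  sp <- split_random_holdout(nrow(x), 0.3, seed = 12345L)
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  xte <- x[sp$test, , drop = FALSE]; yte <- y[sp$test]
  rf <- train_base(pcm_spec("random_forest"), xtr, ytr, seed = 12345L)
  gb <- train_base(pcm_spec("gradient_boosting"), xtr, ytr, seed = 12345L)
  st <- pcm_stack(xtr, ytr, seed = 12345L)
  list(model = st, xtr = xtr, ytr = ytr, xte = xte, yte = yte,
       rf_r2 = compute_metrics(yte, predict(rf, xte))$r2,
       gb_r2 = compute_metrics(yte, predict(gb, xte))$r2,
       stack_metrics = compute_metrics(yte, predict(st, xte)))
})

# Feature maker that scores arbitrary SMILES against the seed target with
# the benchmark model's descriptor configuration.
bench_feature_fun <- function() {
  pb <- bench_features()$protein_block
  function(smi) {
    r <- data.frame(standardized_smiles = smi, target_id = "seed")
    assemble_features(r, list(ecfp = compound_block_ecfp(smi, radius = 2L, n_bits = 256L)),
                      list(zacc = pb))$x
  }
}

# One full training-set selection on a freshly generated world; returns
# whether the chosen protein set equals the planted tiers 1-2.
recover_planted_layer <- function(seed) {
  fam <- generate_protein_family(seed = seed)
  cmp <- generate_compound_library(400L, seed = seed + 1L)
  bio <- generate_bioactivity(fam, cmp, n_records = 2000L, seed = seed + 2L)
  cur <- curate_dataset(bio$activities, fam$sequences)
  rec <- cur$records
  cb <- compound_block_ecfp(unique(rec$standardized_smiles), radius = 2L, n_bits = 256L)
  pb <- protein_block_zscale_acc(fam$sequences)
  ff <- function(r) assemble_features(r, list(ecfp = cb), list(zacc = pb))
  sel <- select_training_set(rec, fam$sequences, "seed",
                             thresholds = c(850, 500, 150), feature_fun = ff)
  planted <- sort(fam$tiers$id[fam$tiers$tier %in% c(1, 2)])
  identical(sort(sel$chosen$proteins), planted)
}

# Brute-force connected-component oracle (breadth-first search on an
# adjacency matrix), independent of the igraph-backed implementation.
bfs_component <- function(adj, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# Deterministic stub model for screening tests: predicts a fixed value per
# SMILES from a lookup table.
stub_model <- function(map) structure(list(map = map), class = "pcms_stub_model")
predict.pcms_stub_model <- function(object, newdata, ...) {
  unname(object$map[rownames(newdata)])
}
registerS3method("predict", "pcms_stub_model", predict.pcms_stub_model,
                 envir = asNamespace("stats"))

# Feature maker for the stub model: identity rows labelled by SMILES.
stub_features <- function(smi) {
  m <- matrix(0, length(smi), 1, dimnames = list(smi, "x"))
  m
}

# Random binary fingerprint blobs: `centers` prototype vectors, members
# flip a few bits around their prototype.
make_blobs <- function(sizes, n_bits = 64L, flip = 3L, seed = 1L) {
  set.seed(seed)
  centers <- lapply(seq_along(sizes), function(i) {
    v <- integer(n_bits); v[sample.int(n_bits, 16L)] <- 1L; v
  })
  rows <- list(); labels <- integer(0)
  for (i in seq_along(sizes)) {
    for (j in seq_len(sizes[i])) {
      v <- centers[[i]]
      fl <- sample.int(n_bits, flip)
      v[fl] <- 1L - v[fl]
      rows[[length(rows) + 1L]] <- v
      labels <- c(labels, i)
    }
  }
  list(fp = do.call(rbind, rows), labels = labels)
}
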