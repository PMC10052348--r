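test_that("alignment scores are symmetric with self-scores dominating rows", {
  seqs <- c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            c = "GGGGWWWWPPPPCCCCGGGGWWWW")
  m <- all_vs_all_scores(seqs)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], m["a", "a"]) # identical sequences
  expect_lt(m["a", "c"], m["a", "a"] / 4) # unrelated sequences score far lower
  expect_error(all_vs_all_scores(c(a = "")), "empty sequence")
})

test_that("network construction respects the threshold and its monotonicity", {
  m <- matrix(c(10, 5, 1, 5, 10, 3, 1, 3, 10), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(nrow(build_network(m, 0)$edges), 3L) # complete graph
  expect_equal(nrow(build_network(m, 11)$edges), 0L) # above max off-diagonal
  e2 <- build_network(m, 3)$edges
  e1 <- build_network(m, 2)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e2) %in% key(e1)))
})

test_that("seed components agree with a breadth-first-search oracle", {
  # exhaustive over every graph on <= 4 nodes
  for (n in 2:4) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (mask in 0:(2^nrow(pairs) - 1)) {
      adj <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
      on <- which(bitwAnd(bitwShiftR(mask, seq_len(nrow(pairs)) - 1L), 1L) == 1L)
      for (k in on) adj[pairs[k, 1], pairs[k, 2]] <- adj[pairs[k, 2], pairs[k, 1]] <- 1
      diag(adj) <- 2 # self-score dominates
      net <- build_network(adj, 1)
      expect_equal(seed_component(net, "a"), letters[bfs_component(adj, 1L)])
    }
  }
  # seeded random graphs on 5-8 nodes
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    adj <- matrix(rbinom(n * n, 1, 0.25), n, n,
                  dimnames = list(letters[1:n], letters[1:n]))
    adj <- pmax(adj, t(adj)); diag(adj) <- 2
    net <- build_network(adj, 1)
    start <- sample.int(n, 1)
    expect_equal(seed_component(net, letters[start]),
                 letters[bfs_component(adj, start)])
  }
  expect_error(seed_component(build_network(matrix(1, 1, 1, dimnames = list("a", "a")), 1), "z"),
               "not a node")
})

test_that("threshold sweeps give nested, growing seed components", {
  w <- bench_world()
  sc <- all_vs_all_scores(w$family$sequences)
  sw <- threshold_sweep(sc, "seed", w$sweep_thresholds)
  sizes <- vapply(sw, function(s) length(s$proteins), integer(1))
  expect_true(all(diff(sizes) >= 0))
  for (i in seq_along(sw)[-1]) {
    expect_true(all(sw[[i - 1]]$proteins %in% sw[[i]]$proteins))
    expect_true("seed" %in% sw[[i]]$proteins)
  }
  # a single threshold gives a single set; a tiny threshold reaches all
  expect_length(threshold_sweep(sc, "seed", 500), 1L)
  expect_equal(length(threshold_sweep(sc, "seed", 1)[[1]]$proteins), nrow(sc))
})

test_that("phylogenetic layers are nested chains anchored at the seed", {
  # caterpillar: mutants at increasing distance from the seed
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 10), collapse = "")
  mut <- function(s, at) { x <- strsplit(s, "")[[1]]; x[at] <- "A"; paste(x, collapse = "") }
  seqs <- c(s = base, a = mut(base, 1:12), b = mut(base, 1:45), c = mut(base, 1:95))
  ph <- build_phylo_layers(seqs, "s")
  sizes <- vapply(ph$layers, length, integer(1))
  expect_equal(sizes, 1:4)
  expect_equal(ph$layers[[1]], "s")
  expect_equal(sort(ph$layers[[4]]), sort(names(seqs)))
  for (i in seq_along(ph$layers)[-1]) {
    expect_true(all(ph$layers[[i - 1]] %in% ph$layers[[i]]))
  }
  # star-like family: everyone equidistant from the seed
  star <- c(s = base,
            x = mut(base, seq(1, 120, by = 3)),
            y = mut(base, seq(2, 120, by = 3)),
            z = mut(base, seq(3, 120, by = 3)))
  ps <- build_phylo_layers(star, "s")
  expect_equal(ps$layers[[length(ps$layers)]], sort(names(star)))
  expect_error(build_phylo_layers(c(s = base), "s"), "at least two")
})

test_that("layer evaluation separates signal from noise", {
  set.seed(7)
  x <- matrix(rnorm(10000), 1000, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.numeric(x %*% c(3, -2, 1, rep(0, 7)))
  ev <- evaluate_layer(x, y, seed = 1)
  expect_true(ev$evaluable)
  expect_gte(ev$cv_r2, 0.9) # noiseless linear signal is recoverable
  evn <- evaluate_layer(x, sample(y), seed = 1)
  expect_lte(evn$cv_r2, 0.1) # permuted labels carry no signal
  small <- evaluate_layer(x[1:10, ], y[1:10], min_records = 20L)
  expect_false(small$evaluable)
  expect_true(is.na(small$cv_r2))
})

test_that("dataset selection prefers the largest comparably scoring layer", {
  mk <- function(label, n, r2) list(label = label, n = n, cv_r2 = r2,
                                    cv_rmse = 1, evaluable = TRUE)
  dominant <- select_dataset(list(mk("a", 100, 0.9), mk("b", 500, 0.5)))
  expect_equal(dominant$label, "a")
  # comparable scores: larger set wins (0.72 vs 0.71 at tolerance 0.01)
  comp <- select_dataset(list(mk("small", 5000, 0.72), mk("big", 20000, 0.71)),
                         r2_tolerance = 0.01)
  expect_equal(comp$label, "big")
  strict <- select_dataset(list(mk("u", 10, 0.70), mk("v", 1000, 0.699)),
                           r2_tolerance = 0)
  expect_equal(strict$label, "u")
  expect_error(select_dataset(list(list(label = "x", n = 5, cv_r2 = NA,
                                        evaluable = FALSE))), "no evaluable")
})
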