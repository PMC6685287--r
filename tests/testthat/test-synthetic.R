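test_that("configs that cannot honor the type constraints are rejected", {
  expect_error(synthetic_config(n_types = 1), "n_types")
  expect_error(synthetic_config(noise_rate = 0.5), "noise_rate")
  expect_error(synthetic_config(n_clusters = 2, n_types = 10), "Increase")
  expect_error(synthetic_config(n_drugs = 10, n_pairs = 500), "ordered drug pairs")
  expect_error(synthetic_config(n_types = 10, n_pairs = 120), "increase")
})

test_that("the same seed reproduces a bit-identical world", {
  cfg <- synthetic_config(n_drugs = 20, n_genes = 60, n_terms = 50,
                          fingerprint_length = 32, n_types = 4,
                          n_pairs = 150, n_clusters = 3, seed = 99)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$drugs, w2$drugs)
  expect_identical(w1$ddis, w2$ddis)
  expect_identical(w1$fi_edges, w2$fi_edges)
  expect_identical(w1$go_edges, w2$go_edges)
  w3 <- generate_world(synthetic_config(n_drugs = 20, n_genes = 60,
                                        n_terms = 50, fingerprint_length = 32,
                                        n_types = 4, n_pairs = 150,
                                        n_clusters = 3, seed = 100))
  expect_false(identical(w1$ddis, w3$ddis))
})

test_that("world structure honors its invariants", {
  w <- tiny_world()
  cfg <- w$config
  expect_equal(nrow(w$drugs), cfg$n_drugs)
  expect_true(all(lengths(w$drugs$targets) >= 1))
  expect_true(all(unlist(w$drugs$fingerprint) %in% 0:1))
  # connected giant component covers the gene network
  ig <- igraph::graph_from_data_frame(w$fi_edges, directed = FALSE)
  cmp <- igraph::components(ig)
  expect_gte(max(cmp$csize) / cfg$n_genes, 0.95)
  # every type has at least 5 pairs
  expect_true(all(table(w$ddis$type) >= 5))
  # the planted rule is recorded
  expect_equal(nrow(w$rule$latents), cfg$n_drugs)
  expect_equal(dim(w$rule$table), rep(cfg$n_clusters, 2))
})

test_that("noise-free worlds pass filter_dataset unchanged", {
  w <- tiny_world()
  res <- filter_dataset(w$ddis, w$drugs)
  expect_equal(res$ddis, w$ddis)
  expect_equal(res$drugs$drug_id, w$drugs$drug_id)
})

test_that("label noise resamples approximately the requested fraction", {
  cfg <- synthetic_config(n_drugs = 40, n_genes = 100, n_terms = 60,
                          fingerprint_length = 32, n_types = 5,
                          n_pairs = 1000, n_clusters = 4,
                          noise_rate = 0.2, seed = 5)
  w <- generate_world(cfg)
  disagree <- mean(w$ddis$type != w$rule$planted_type)
  # noisy labels are resampled away from the planted type, so the
  # disagreement rate estimates the noise rate directly
  expect_equal(disagree, 0.2, tolerance = 0.02)
})

test_that("a noise-free two-cluster world is solved by nearest centroid", {
  cfg <- synthetic_config(n_drugs = 30, n_genes = 80, n_terms = 60,
                          fingerprint_length = 64, n_types = 4,
                          n_pairs = 400, n_clusters = 2,
                          noise_rate = 0, seed = 13)
  w <- generate_world(cfg)
  profs <- world_profiles(w)
  x <- do.call(cbind, lapply(profs, function(p)
    suppressMessages(assemble_pair_inputs(w$ddis, p))))
  set.seed(1)
  tr <- sample(nrow(x), 300)
  # trivial nearest-centroid classifier on raw concatenated profiles
  cents <- t(vapply(sort(unique(w$ddis$type[tr])), function(ty) {
    colMeans(x[tr, , drop = FALSE][w$ddis$type[tr] == ty, , drop = FALSE])
  }, numeric(ncol(x))))
  pred <- sort(unique(w$ddis$type[tr]))[
    apply(x[-tr, ], 1, function(r) which.min(colSums((t(cents) - r)^2)))]
  expect_equal(mean(pred == w$ddis$type[-tr]), 1.0)
})

test_that("split_signal allocates latent capacity by modality weight", {
  cfg <- synthetic_config(n_drugs = 30, n_genes = 80, n_terms = 60,
                          fingerprint_length = 48, n_types = 4,
                          n_pairs = 400, n_clusters = 8, seed = 21)
  w_all <- split_signal(cfg, c(1, 1, 1))
  expect_equal(w_all$rule$latent_sizes, c(2L, 2L, 2L))
  w_ssp <- split_signal(cfg, c(1, 0, 0))
  expect_equal(w_ssp$rule$latent_sizes, c(8L, 1L, 1L))
  # a zero-weight modality has a single latent level: no signal
  expect_equal(length(unique(w_ssp$rule$latents$u_tsp)), 1L)
  expect_error(split_signal(cfg, c(0, 0, 0)), "not all zero")
})

test_that("zero-weight modalities carry no class signal, full-weight ones do", {
  cfg <- synthetic_config(n_drugs = 40, n_genes = 100, n_terms = 80,
                          fingerprint_length = 64, n_types = 6,
                          n_pairs = 800, n_clusters = 6,
                          noise_rate = 0, seed = 31)
  w <- split_signal(cfg, c(1, 0, 0))
  profs <- world_profiles(w)
  # 1-nearest-neighbour probe: the planted rule is a per-cell lookup, so
  # any modality carrying the full latent code solves it via the nearest
  # training pair, while a signal-free modality stays near chance
  probe <- function(p) {
    x <- suppressMessages(assemble_pair_inputs(w$ddis, p))
    set.seed(2)
    tr <- sample(nrow(x), 600)
    xtr <- x[tr, , drop = FALSE]; xte <- x[-tr, , drop = FALSE]
    d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
    pred <- w$ddis$type[tr][max.col(-d2)]
    mean(pred == w$ddis$type[-tr])
  }
  acc_ssp <- probe(profs$ssp)
  acc_tsp <- probe(profs$tsp)
  expect_gt(acc_ssp, 0.8)       # all capacity in the structural modality
  expect_lt(acc_tsp, 0.4)       # target modality near chance (1/6)
})

nn1_probe <- function(x, type, n_train, seed = 2) {
  set.seed(seed)
  tr <- sample(nrow(x), n_train)
  xtr <- x[tr, , drop = FALSE]; xte <- x[-tr, , drop = FALSE]
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
  mean(type[tr][max.col(-d2)] == type[-tr])
}

test_that("half/half weights: two modalities combine beyond either alone", {
  cfg <- synthetic_config(n_drugs = 40, n_genes = 100, n_terms = 80,
                          fingerprint_length = 64, n_types = 6,
                          n_pairs = 900, n_clusters = 8,
                          noise_rate = 0, seed = 33)
  w <- split_signal(cfg, c(0.5, 0.5, 0))
  expect_equal(w$rule$latent_sizes[3], 1L)
  profs <- world_profiles(w)
  xs <- lapply(profs, function(p)
    suppressMessages(assemble_pair_inputs(w$ddis, p)))
  acc_ssp <- nn1_probe(xs$ssp, w$ddis$type, 700)
  acc_tsp <- nn1_probe(xs$tsp, w$ddis$type, 700)
  acc_both <- nn1_probe(cbind(xs$ssp, xs$tsp), w$ddis$type, 700)
  expect_gt(acc_both, max(acc_ssp, acc_tsp))
  # and each single modality is capped well below the joint ceiling
  expect_lt(max(acc_ssp, acc_tsp), 0.8)
})

test_that("equal weights give comparable single-modality information", {
  cfg <- synthetic_config(n_drugs = 40, n_genes = 100, n_terms = 80,
                          fingerprint_length = 64, n_types = 6,
                          n_pairs = 900, n_clusters = 8,
                          noise_rate = 0, seed = 37)
  w <- split_signal(cfg, c(1, 1, 1))
  profs <- world_profiles(w)
  accs <- vapply(profs, function(p) {
    nn1_probe(suppressMessages(assemble_pair_inputs(w$ddis, p)),
              w$ddis$type, 700)
  }, numeric(1))
  expect_lt(max(accs) - min(accs), 0.2)
})
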