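# Shared fixtures and independent oracles, built in code at test time.

# Path graph g1-g2-g3 plus an isolated pair g4-g5 (for unreachable cases).
toy_graph <- function() {
  interaction_graph(data.frame(
    a = c("g1", "g2", "g4"),
    b = c("g2", "g3", "g5")))
}

# Independent brute-force oracle for the target-similarity statistic:
# plain nested loops over the Cartesian product, igraph distances queried
# pair by pair. Deliberately naive; never shares code with build_tsp().
oracle_ts <- function(g_a, g_b, edges) {
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  d <- function(x, y) {
    as.numeric(igraph::distances(ig, v = x, to = y, mode = "all"))
  }
  t_a <- 0
  for (x in g_a) for (y in g_a) {
    dd <- d(x, y)
    if (is.finite(dd) && dd > t_a) t_a <- dd
  }
  hits <- 0; total <- 0
  for (x in g_a) for (y in g_b) {
    total <- total + 1
    dd <- d(x, y)
    if (is.finite(dd) && dd <= t_a) hits <- hits + 1
  }
  hits / total
}

# Random connected instance: <= 10 drugs with sets over <= 20 nodes.
random_setsim_instance <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(5:20, 1)
  nodes <- paste0("n", seq_len(n_nodes))
  # random tree plus extra edges keeps the graph connected
  parent <- c(NA, vapply(2:n_nodes, function(i) sample(i - 1, 1), 1L))
  edges <- data.frame(a = nodes[2:n_nodes], b = nodes[parent[2:n_nodes]])
  n_extra <- sample(0:n_nodes, 1)
  if (n_extra > 0) {
    ea <- sample(nodes, n_extra, replace = TRUE)
    eb <- sample(nodes, n_extra, replace = TRUE)
    keep <- ea != eb
    edges <- rbind(edges, data.frame(a = ea[keep], b = eb[keep]))
  }
  n_drugs <- sample(2:10, 1)
  sets <- lapply(seq_len(n_drugs), function(i) {
    sample(nodes, sample(1:4, 1))
  })
  list(edges = edges, sets = sets,
       ids = paste0("d", seq_len(n_drugs)))
}

# Naive metric tallies used as the independent oracle for the metrics module.
oracle_metrics <- function(scores, truth) {
  types <- colnames(scores)
  n <- nrow(scores); l <- length(types)
  acc <- 0
  for (i in seq_len(n)) {
    if (scores[i, as.character(truth[i])] >= 0.5) acc <- acc + 1
  }
  tp <- fp <- fn <- setNames(rep(0, l), types)
  for (i in seq_len(n)) for (ty in types) {
    pred <- scores[i, ty] >= 0.5
    is_true <- as.character(truth[i]) == ty
    if (pred && is_true) tp[ty] <- tp[ty] + 1
    if (pred && !is_true) fp[ty] <- fp[ty] + 1
    if (!pred && is_true) fn[ty] <- fn[ty] + 1
  }
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  list(accuracy = acc / n,
       macro_recall = mean(rec), macro_precision = mean(prec),
       micro_recall = sum(tp) / (sum(tp) + sum(fn)),
       micro_precision = if (sum(tp) + sum(fp) == 0) NA_real_ else
         sum(tp) / (sum(tp) + sum(fp)))
}

# Step-wise AUPRC by explicit threshold enumeration.
oracle_auprc <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in thr) {
    pred <- score >= t
    r <- sum(pred & positive) / sum(positive)
    p <- sum(pred & positive) / sum(pred)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

random_scores <- function(seed, n = NULL, l = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:50, 1)
  if (is.null(l)) l <- sample(2:6, 1)
  types <- paste0("t", seq_len(l))
  scores <- matrix(runif(n * l), n, l, dimnames = list(NULL, types))
  truth <- sample(types, n, replace = TRUE)
  list(scores = scores, truth = truth)
}

# Small world shared across expensive tests (built once per test run).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_drugs = 24, n_genes = 80, n_terms = 60,
                              fingerprint_length = 48, n_types = 4,
                              n_pairs = 240, n_clusters = 3,
                              noise_rate = 0, seed = 42)
      cache <<- generate_world(cfg)
    }
    cache
  }
})

tiny_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- world_profiles(tiny_world())
    cache
  }
})

quick_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 12, batch_size = 64, seed = 1,
         ae_hidden = c(24L, 12L, 24L), clf_hidden = c(48L, 48L)),
    list(...))
  do.call(training_config, args)
}
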