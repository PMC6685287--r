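#' Configuration of a synthetic DDI world
#'
#' Defines the study conditions the generator emulates: a drug universe with
#' latent clusters, binary fingerprints built from cluster prototypes, a
#' community-structured gene network with per-cluster target sets, a rooted
#' GO-term tree with block-structured annotations, and DDI type labels
#' planted as a deterministic function of the ordered cluster pair with a
#' `noise_rate` fraction of labels resampled to a different type.
#'
#' @param n_drugs,n_genes,n_terms Universe sizes.
#' @param fingerprint_length Bits per fingerprint.
#' @param n_types Number of DDI types (>= 2).
#' @param n_pairs Number of labeled ordered drug pairs (sampled without
#'   replacement).
#' @param n_clusters Latent drug clusters carrying the signal.
#' @param noise_rate Fraction of labels resampled to a different type
#'   (< 0.5).
#' @param seed Integer seed; a fixed seed gives a bit-identical world.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 60, n_genes = 300, n_terms = 200,
                             fingerprint_length = 128, n_types = 10,
                             n_pairs = 2000, n_clusters = 8,
                             noise_rate = 0.1, seed = 1L) {
  stopifnot(n_drugs >= 4, n_genes >= 10, n_terms >= 10,
            fingerprint_length >= 8, n_types >= 2)
  if (noise_rate < 0 || noise_rate >= 0.5) {
    abort("`noise_rate` must be in [0, 0.5).")
  }
  if (n_clusters^2 < n_types) {
    abort(paste0("n_clusters^2 (", n_clusters^2, ") < n_types (", n_types,
                 "): the planted rule cannot express every type. ",
                 "Increase `n_clusters`."))
  }
  if (n_pairs > n_drugs * (n_drugs - 1)) {
    abort("`n_pairs` exceeds the number of ordered drug pairs; increase `n_drugs`.")
  }
  min_expected <- floor(n_pairs / n_types / 4)
  if (min_expected < 5) {
    abort(paste0("with ", n_pairs, " pairs over ", n_types, " types some ",
                 "types are unlikely to keep >= 5 records; increase ",
                 "`n_pairs` to at least ", 20 * n_types, "."))
  }
  structure(
    list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
         n_terms = as.integer(n_terms),
         fingerprint_length = as.integer(fingerprint_length),
         n_types = as.integer(n_types), n_pairs = as.integer(n_pairs),
         n_clusters = as.integer(n_clusters), noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic world
#'
#' `generate_world()` plants one shared latent cluster per drug: the
#' fingerprint prototype, the network community of the drug's targets and
#' the annotation block of those targets' GO terms all reflect the same
#' cluster, and the DDI type of a pair is a seeded deterministic table over
#' the ordered cluster pair. `split_signal()` instead draws independent
#' per-modality latent factors whose sizes grow with the given weights, so
#' each modality observes only part of the label-determining code and
#' single-modality classifiers are capped below the all-modality ceiling;
#' a zero-weight modality has a single latent level and carries no signal.
#'
#' @param config A [synthetic_config()].
#' @return A `ddi_world`: `drugs` (a [drug_table()]), `fi_edges`,
#'   `go_edges`, `annotations`, `ddis`, and `rule` (the planted latents,
#'   type table and sizes, for recovery tests).
#' @export
generate_world <- function(config) {
  build_world(config, latent_sizes = NULL)
}

#' @rdname generate_world
#' @param modality_weights Non-negative weights (`ssp`, `tsp`, `gsp`), not
#'   all zero, controlling each modality's share of the planted code.
#' @export
split_signal <- function(config, modality_weights = c(1, 1, 1)) {
  w <- as.numeric(modality_weights)
  if (length(w) != 3 || any(w < 0) || sum(w) == 0) {
    abort("`modality_weights` must be 3 non-negative numbers, not all zero.")
  }
  sizes <- allocate_latents(config$n_clusters, w)
  if (prod(sizes)^2 < config$n_types) {
    abort("allocated latent code too small for `n_types`; increase `n_clusters`.")
  }
  build_world(config, latent_sizes = sizes, weights = w)
}

# Latent levels per modality, log-capacity proportional to the weights.
allocate_latents <- function(k_total, w) {
  r <- w / sum(w)
  pmax(1L, as.integer(round(k_total^r)))
}

BIT_FLIP <- 0.05       # per-bit fingerprint noise
ALIGN_PROB <- 0.9      # per-target community / annotation-block fidelity

build_world <- function(config, latent_sizes = NULL, weights = NULL) {
  set.seed(config$seed)
  n <- config$n_drugs
  shared <- is.null(latent_sizes)
  balanced <- function(k) sample(rep_len(seq_len(k), n))
  if (shared) {
    g <- balanced(config$n_clusters)
    u <- cbind(ssp = g, tsp = g, gsp = g)
    sizes <- rep(config$n_clusters, 3)
  } else {
    sizes <- latent_sizes
    u <- cbind(ssp = balanced(sizes[1]), tsp = balanced(sizes[2]),
               gsp = balanced(sizes[3]))
  }
  comp <- if (shared) u[, "ssp"] else
    (u[, "ssp"] - 1L) * sizes[2] * sizes[3] + (u[, "tsp"] - 1L) * sizes[3] +
      u[, "gsp"]
  k_comp <- if (shared) config$n_clusters else prod(sizes)

  # fingerprints: per-cluster prototype bits plus per-bit flip noise
  proto <- matrix(rbinom(sizes[1] * config$fingerprint_length, 1, 0.3),
                  sizes[1], config$fingerprint_length)
  fp <- proto[u[, "ssp"], , drop = FALSE]
  flips <- matrix(rbinom(length(fp), 1, BIT_FLIP), nrow(fp), ncol(fp))
  fp <- abs(fp - flips)

  # gene network: planted partition aligned to the tsp latent
  community <- sort(rep_len(seq_len(sizes[2]), config$n_genes))
  fi_edges <- planted_partition_edges(config$n_genes, community)
  gene_ids <- paste0("G", seq_len(config$n_genes))

  # GO graph: one rooted subtree per gsp block, plus shortcut edges
  go <- go_tree(config$n_terms, sizes[3])
  term_ids <- go$term_ids

  # gene annotations: block-aligned terms (every gene annotated)
  gene_block <- sample.int(sizes[3], config$n_genes, replace = TRUE)
  annotations <- bind_rows(map(seq_len(config$n_genes), function(i) {
    pool <- term_ids[go$block == gene_block[i]]
    tibble(gene_id = gene_ids[i],
           term_id = sample(pool, min(length(pool), sample(2:4, 1))),
           namespace = "biological_process")
  }))

  # target sets: drawn from the drug's community and annotation block
  targets <- map(seq_len(n), function(i) {
    n_t <- sample(3:6, 1)
    picks <- character(n_t)
    for (t in seq_len(n_t)) {
      c_ok <- runif(1) < ALIGN_PROB
      b_ok <- runif(1) < ALIGN_PROB
      pool <- gene_ids[(!c_ok | community == u[i, "tsp"]) &
                       (!b_ok | gene_block == u[i, "gsp"])]
      if (length(pool) == 0) pool <- gene_ids
      picks[t] <- sample(pool, 1)
    }
    unique(picks)
  })

  drug_ids <- sprintf("D%03d", seq_len(n))
  drugs <- drug_table(drug_ids,
                      fingerprint = lapply(seq_len(n), function(i) fp[i, ]),
                      targets = targets)

  # planted type rule: balanced seeded table over ordered composite pairs
  rule_table <- matrix(sample(rep_len(seq_len(config$n_types), k_comp^2)),
                       k_comp, k_comp)
  all_pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
  all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
  pick <- all_pairs[sample.int(nrow(all_pairs), config$n_pairs), ]
  planted <- rule_table[cbind(comp[pick$a], comp[pick$b])]
  type <- planted
  n_noise <- round(config$noise_rate * config$n_pairs)
  if (n_noise > 0) {
    flip_idx <- sample.int(config$n_pairs, n_noise)
    type[flip_idx] <- map_int(type[flip_idx], function(t) {
      sample(setdiff(seq_len(config$n_types), t), 1)
    })
  }
  ddis <- tibble(drug_a = drug_ids[pick$a], drug_b = drug_ids[pick$b],
                 type = as.integer(type))
  counts <- table(factor(ddis$type, levels = seq_len(config$n_types)))
  if (any(counts < 5)) {
    abort(paste0("type(s) ", paste(names(counts)[counts < 5], collapse = ", "),
                 " ended with fewer than 5 pairs; increase `n_pairs` or ",
                 "lower `n_types`."))
  }

  structure(
    list(drugs = drugs, fi_edges = fi_edges,
         go_edges = go$edges, annotations = annotations, ddis = ddis,
         rule = list(latents = tibble(drug_id = drug_ids,
                                      u_ssp = u[, "ssp"], u_tsp = u[, "tsp"],
                                      u_gsp = u[, "gsp"], composite = comp),
                     table = rule_table, planted_type = as.integer(planted),
                     latent_sizes = sizes, weights = weights,
                     shared = shared),
         config = config),
    class = "ddi_world")
}

#' @export
print.ddi_world <- function(x, ...) {
  cat("<ddi_world> ", nrow(x$drugs), " drugs, ", nrow(x$ddis), " DDIs of ",
      length(unique(x$ddis$type)), " types; latent sizes ",
      paste(x$rule$latent_sizes, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# Community-structured random graph, bridged into a single component.
planted_partition_edges <- function(n_genes, community) {
  ids <- paste0("G", seq_len(n_genes))
  edges <- list()
  for (c in unique(community)) {
    members <- which(community == c)
    size <- length(members)
    if (size < 2) next
    p_in <- min(1, 8 / (size - 1))
    pairs <- which(upper.tri(matrix(0, size, size)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_in
    edges[[length(edges) + 1]] <- tibble(
      gene_a = ids[members[pairs[keep, 1]]],
      gene_b = ids[members[pairs[keep, 2]]])
  }
  n_between <- max(1, round(n_genes / 10))
  a <- sample.int(n_genes, n_between, replace = TRUE)
  b <- sample.int(n_genes, n_between, replace = TRUE)
  ok <- a != b
  edges[[length(edges) + 1]] <- tibble(gene_a = ids[a[ok]], gene_b = ids[b[ok]])
  el <- distinct(bind_rows(edges))
  # bridge disconnected parts so the distance oracle is total
  ig <- igraph::graph_from_data_frame(el, directed = FALSE,
                                      vertices = data.frame(name = ids))
  cmp <- igraph::components(ig)
  if (cmp$no > 1) {
    main <- which.max(cmp$csize)
    anchors <- ids[cmp$membership == main]
    extra <- map(setdiff(seq_len(cmp$no), main), function(ci) {
      tibble(gene_a = sample(ids[cmp$membership == ci], 1),
             gene_b = sample(anchors, 1))
    })
    el <- distinct(bind_rows(el, bind_rows(extra)))
  }
  el
}

# Rooted term tree with one branch per block plus a few shortcut edges.
go_tree <- function(n_terms, n_blocks) {
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  block <- integer(n_terms)
  block[1] <- 0L # root belongs to no block
  body <- 2:n_terms
  block[body] <- sort(rep_len(seq_len(n_blocks), length(body)))
  parent <- integer(n_terms)
  for (b in seq_len(n_blocks)) {
    members <- which(block == b)
    parent[members[1]] <- 1L
    if (length(members) > 1) {
      for (i in 2:length(members)) {
        parent[members[i]] <- sample(members[seq_len(i - 1)], 1)
      }
    }
  }
  edges <- tibble(child = term_ids[body], parent = term_ids[parent[body]],
                  relation = "is_a",
                  namespace = "biological_process")
  n_extra <- max(1, round(0.05 * n_terms))
  a <- sample(body, n_extra, replace = TRUE)
  b <- sample.int(n_terms, n_extra, replace = TRUE)
  ok <- a != b & parent[a] != b
  if (any(ok)) {
    edges <- distinct(bind_rows(edges, tibble(
      child = term_ids[a[ok]], parent = term_ids[b[ok]],
      relation = "part_of", namespace = "biological_process")))
  }
  list(edges = edges, block = block, term_ids = term_ids)
}

#' Compute all three profiles of a world
#'
#' Convenience wrapper building the SSP, TSP and GSP matrices from a
#' synthetic world's drugs, network, GO graph and annotations.
#'
#' @param world A `ddi_world`.
#' @param quiet Suppress mapping warnings.
#' @return Named list of `similarity_profile` matrices.
#' @export
world_profiles <- function(world, quiet = TRUE) {
  f <- if (quiet) suppressWarnings else identity
  fi <- interaction_graph(world$fi_edges)
  go <- interaction_graph(world$go_edges[, c("child", "parent")])
  f(list(
    ssp = build_ssp(world$drugs),
    tsp = build_tsp(world$drugs, fi),
    gsp = build_gsp(world$drugs, go, annotations = world$annotations)
  ))
}
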