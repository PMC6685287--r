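#' Tanimoto coefficient between two binary fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over the set bits of two equal-length binary
#' vectors. Two all-zero fingerprints have an empty union; the coefficient is
#' then defined as 0 and a warning is raised.
#'
#' @param a,b Binary (0/1) vectors of identical length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 2 shared bits / 4 set bits = 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) abort("fingerprints must have equal length.")
  union <- sum(a | b)
  if (union == 0) {
    warn("both fingerprints are all-zero; Tanimoto defined as 0.")
    return(0)
  }
  sum(a & b) / union
}

new_similarity_profile <- function(mat, modality) {
  structure(mat, modality = modality,
            class = c("similarity_profile", class(mat)))
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("<similarity_profile> modality=", attr(x, "modality"),
      ", ", nrow(x), " x ", ncol(x), " drugs\n", sep = "")
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Structural similarity profile (SSP) matrix
#'
#' Row A of the SSP is drug A's vector of Tanimoto coefficients against every
#' drug in the universe (including itself), so the profile length equals the
#' universe size. The matrix is symmetric with unit diagonal.
#'
#' @param drugs A [drug_table()] with a `fingerprint` column.
#' @return An N x N `similarity_profile` matrix with drug ids as dimnames.
#' @export
build_ssp <- function(drugs) {
  if (nrow(drugs) == 0) abort("empty drug universe.")
  fp <- fingerprint_matrix(drugs) > 0
  inter <- tcrossprod(fp * 1)
  nset <- rowSums(fp)
  un <- outer(nset, nset, "+") - inter
  zero_union <- un == 0
  if (any(zero_union)) {
    warn("all-zero fingerprint pair(s); Tanimoto defined as 0.")
  }
  ssp <- ifelse(zero_union, 0, inter / pmax(un, 1))
  # a drug is always identical to itself, even with an empty fingerprint
  diag(ssp) <- 1
  dimnames(ssp) <- list(drugs$drug_id, drugs$drug_id)
  new_similarity_profile(ssp, "ssp")
}

#' Intra-set distance threshold t
#'
#' The maximum pairwise hop distance among a drug's own target genes (or GO
#' terms), the threshold used by [target_similarity()]. Pairs include x = y,
#' so a singleton set has t = 0. Unreachable pairs are skipped when taking
#' the maximum; ids absent from the graph are dropped with a warning.
#'
#' @param genes Character vector of node ids (a drug's target set).
#' @param g An [interaction_graph()].
#' @return Integer hop count.
#' @export
intra_threshold <- function(genes, g) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) abort("empty gene set.")
  genes <- mapped_set(genes, g, "intra_threshold")
  if (length(genes) == 0) abort("no gene in the set is present in the graph.")
  d <- dist_block(g, genes, genes)
  fin <- d[is.finite(d)]
  # d(x,x) = 0 pairs are always present, so fin is never empty
  max(fin)
}

#' Target-gene similarity between two drugs
#'
#' The fraction of ordered gene pairs (x, y) in G_A x G_B whose hop distance
#' in the network is at most t_A, the maximum intra-set distance of drug A's
#' own targets. The statistic is asymmetric because the threshold belongs to
#' drug A; TS of a drug with itself is always 1.
#'
#' @param g_a,g_b Character vectors: target sets of drugs A and B.
#' @param g An [interaction_graph()].
#' @param t_a Optional precomputed threshold (hops); computed from `g_a` when
#'   missing.
#' @return Similarity in `[0, 1]`.
#' @export
target_similarity <- function(g_a, g_b, g, t_a = NULL) {
  g_a <- unique(as.character(g_a)); g_b <- unique(as.character(g_b))
  if (length(g_a) == 0 || length(g_b) == 0) abort("empty target set.")
  g_a <- mapped_set(g_a, g, "target_similarity (A)")
  g_b <- mapped_set(g_b, g, "target_similarity (B)")
  if (length(g_a) == 0 || length(g_b) == 0) {
    abort("no mapped gene left in a target set.")
  }
  if (is.null(t_a)) t_a <- intra_threshold(g_a, g)
  d <- dist_block(g, g_a, g_b)
  sum(is.finite(d) & d <= t_a) / length(d)
}

#' Target similarity profile (TSP) matrix
#'
#' Entry (A, B) is [target_similarity()] of the two drugs' target sets on the
#' functional-interaction network. Rows are drug A's profile over the
#' universe; the diagonal is 1 and the matrix is generally asymmetric.
#' Drugs whose target set has no gene mapped to the network are excluded
#' from the profile with a warning.
#'
#' @param drugs A [drug_table()] with a `targets` column.
#' @param g The functional-interaction network, an [interaction_graph()].
#' @return An N x N `similarity_profile` matrix.
#' @export
build_tsp <- function(drugs, g) {
  build_setsim_profile(drugs$drug_id, drugs$targets, g, "tsp")
}

build_setsim_profile <- function(ids, sets, g, modality) {
  if (length(ids) == 0) abort("empty drug universe.")
  sets <- map(sets, function(s) unique(as.character(s)))
  mapped <- map(sets, function(s) s[graph_has_node(g, s)])
  n_partial <- sum(lengths(mapped) < lengths(sets) & lengths(mapped) > 0)
  if (n_partial > 0) {
    warn(paste0(n_partial, " drug(s) had unmapped ids dropped from their set."))
  }
  dropped_ids <- ids[lengths(mapped) == 0]
  if (length(dropped_ids) > 0) {
    warn(paste0("excluded ", length(dropped_ids), " drug(s) with no id mapped",
                " to the graph: ", paste(head(dropped_ids, 5), collapse = ", ")))
    keep <- lengths(mapped) > 0
    ids <- ids[keep]; mapped <- mapped[keep]
    if (length(ids) == 0) abort("no drug has a mapped set.")
  }
  universe <- unique(unlist(mapped))
  # distance rows cached per gene; assemble the universe block once
  d_all <- dist_block(g, universe, universe)
  n <- length(ids)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  idx <- map(mapped, function(s) match(s, universe))
  for (i in seq_len(n)) {
    di <- d_all[idx[[i]], , drop = FALSE]
    t_i <- max(di[, idx[[i]], drop = FALSE][is.finite(di[, idx[[i]]])])
    hit <- is.finite(di) & di <= t_i
    for (j in seq_len(n)) {
      blk <- hit[, idx[[j]], drop = FALSE]
      out[i, j] <- sum(blk) / length(blk)
    }
  }
  new_similarity_profile(out, modality)
}

#' GO-term set of a drug
#'
#' The union of GO terms annotating any of the drug's target genes,
#' restricted to one namespace (biological process by default). When `go` is
#' supplied and `propagate = TRUE`, annotations are propagated to ancestor
#' terms along the term graph's child-to-parent edges.
#'
#' @param targets Character vector of target-gene ids.
#' @param annotations Data frame `gene_id`, `term_id` and optionally
#'   `namespace`.
#' @param namespace Annotation namespace to keep; `NULL` keeps all.
#' @param propagate Add all ancestors of each annotated term.
#' @param go GO edge table (`child`, `parent`, ...) as read by [read_go()];
#'   only needed when `propagate = TRUE`.
#' @return Character vector of term ids (possibly empty, with a warning).
#' @export
drug_go_terms <- function(targets, annotations,
                          namespace = "biological_process",
                          propagate = FALSE, go = NULL) {
  ann <- as_tibble(annotations)
  if (!is.null(namespace) && "namespace" %in% names(ann)) {
    ann <- filter(ann, .data$namespace == .env$namespace)
  }
  terms <- unique(ann$term_id[ann$gene_id %in% targets])
  if (length(terms) == 0) {
    warn("no annotated target gene; empty GO-term set.")
    return(character())
  }
  if (propagate) {
    if (is.null(go)) abort("`go` edge table required when propagate = TRUE.")
    parent_of <- split(as.character(go$parent), as.character(go$child))
    frontier <- terms
    while (length(frontier) > 0) {
      up <- unique(unlist(parent_of[frontier], use.names = FALSE))
      up <- setdiff(up, terms)
      terms <- c(terms, up)
      frontier <- up
    }
  }
  terms
}

#' GO similarity profile (GSP) matrix
#'
#' [build_tsp()]'s statistic applied to drugs' GO-term sets on the GO graph
#' (is_a/part_of edges taken as undirected for hop distances). Term sets are
#' taken from the drug table's `terms` column, or derived from `targets` via
#' [drug_go_terms()] when `annotations` is given. Drugs with an empty term
#' set are excluded from the profile with a warning.
#'
#' @param drugs A [drug_table()].
#' @param g The GO graph as an [interaction_graph()].
#' @param annotations Optional gene-to-term annotation table.
#' @param namespace Passed to [drug_go_terms()].
#' @return A `similarity_profile` matrix over the drugs with non-empty sets.
#' @export
build_gsp <- function(drugs, g, annotations = NULL,
                      namespace = "biological_process") {
  terms <- drugs$terms
  if (is.null(terms)) {
    if (is.null(annotations)) {
      abort("drug table has no `terms`; supply `annotations`.")
    }
    terms <- map(drugs$targets, function(tg) {
      withCallingHandlers(
        drug_go_terms(tg, annotations, namespace = namespace),
        warning = function(w) invokeRestart("muffleWarning"))
    })
  }
  empty <- lengths(terms) == 0
  if (any(empty)) {
    warn(paste0("excluded ", sum(empty), " drug(s) with an empty GO-term set."))
  }
  build_setsim_profile(drugs$drug_id[!empty], terms[!empty], g, "gsp")
}

#' @describeIn build_ssp Tidy a profile matrix into a long tibble with columns
#'   `drug_a`, `drug_b`, `value`.
#' @param x A `similarity_profile`.
#' @param ... Unused.
#' @export
tidy.similarity_profile <- function(x, ...) {
  tibble(
    drug_a = rep(rownames(x), times = ncol(x)),
    drug_b = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' @export
autoplot.similarity_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_b, y = .data$drug_a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = toupper(attr(object, "modality"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
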