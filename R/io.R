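# Readers and writers for the package's external TSV formats (UTF-8, no
# quoting). Blank lines and #-comments are skipped; malformed lines error
# with their line number; duplicate records are dropped with a warning.

read_tsv_checked <- function(path, col_names) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(paste0("empty file: ", path))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(parts) != length(col_names)
  if (any(bad)) {
    abort(paste0(path, ": line ", idx[which(bad)[1]], " has ",
                 lengths(parts)[which(bad)[1]], " field(s), expected ",
                 length(col_names), "."))
  }
  out <- as_tibble(setNames(
    map(seq_along(col_names), function(j) map_chr(parts, j)),
    col_names))
  dup <- duplicated(out)
  if (any(dup)) {
    warn(paste0(path, ": ", sum(dup), " duplicate line(s) dropped."))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Read the external input formats
#'
#' All inputs are tab-separated text without a header row. `read_drugs()`
#' reads `drug_id<TAB>smiles`; `read_fingerprints()` reads
#' `drug_id<TAB>bitstring` (a string of 0/1 characters);
#' `read_targets()` reads `drug_id<TAB>gene_id`; `read_network()` reads an
#' edge list `gene_a<TAB>gene_b` (duplicate edges in either orientation are
#' deduplicated); `read_annotations()` reads
#' `gene_id<TAB>term_id<TAB>namespace`; `read_ddis()` reads
#' `drug_a<TAB>drug_b<TAB>type`. `read_go()` accepts either an OBO file
#' (id/is_a/relationship part_of/namespace stanzas) or a TSV
#' `child<TAB>parent<TAB>relation`.
#'
#' @param path File path.
#' @return A tibble; see each format above for the columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_drugs <- function(path) read_tsv_checked(path, c("drug_id", "smiles"))

#' @rdname readers
#' @export
read_fingerprints <- function(path) {
  raw <- read_tsv_checked(path, c("drug_id", "bits"))
  bad <- grepl("[^01]", raw$bits)
  if (any(bad)) {
    abort(paste0(path, ": non-binary fingerprint for drug ",
                 raw$drug_id[which(bad)[1]], "."))
  }
  fps <- map(strsplit(raw$bits, ""), as.integer)
  names(fps) <- raw$drug_id
  fps
}

#' @rdname readers
#' @export
read_targets <- function(path) read_tsv_checked(path, c("drug_id", "gene_id"))

#' @rdname readers
#' @export
read_network <- function(path) {
  el <- read_tsv_checked(path, c("gene_a", "gene_b"))
  key <- ifelse(el$gene_a < el$gene_b,
                paste(el$gene_a, el$gene_b), paste(el$gene_b, el$gene_a))
  dup <- duplicated(key)
  if (any(dup)) {
    warn(paste0(path, ": ", sum(dup), " duplicate edge(s) dropped."))
    el <- el[!dup, , drop = FALSE]
  }
  el
}

#' @rdname readers
#' @export
read_annotations <- function(path) {
  read_tsv_checked(path, c("gene_id", "term_id", "namespace"))
}

#' @rdname readers
#' @export
read_ddis <- function(path) {
  out <- read_tsv_checked(path, c("drug_a", "drug_b", "type"))
  mutate(out, type = suppressWarnings(as.integer(.data$type)))
}

#' @rdname readers
#' @export
read_go <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("\\.obo$", path) || grepl("^format-version", first)) {
    parse_obo(path)
  } else {
    read_tsv_checked(path, c("child", "parent", "relation"))
  }
}

# Minimal OBO parser: [Term] stanzas with id/is_a/relationship part_of/
# namespace; obsolete terms skipped.
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && length(cur$parents) > 0) {
      terms[[length(terms) + 1]] <- tibble(
        child = cur$id, parent = map_chr(cur$parents, 1),
        relation = map_chr(cur$parents, 2),
        namespace = cur$namespace %||% NA_character_)
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- list(id = NA_character_, parents = list(), namespace = NULL)
      in_term <- identical(ln, "[Term]")
      next
    }
    if (!in_term || is.null(cur)) next
    if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (grepl("^is_a:", ln)) {
      id <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, list(c(id, "is_a")))
    } else if (grepl("^relationship: *part_of", ln)) {
      id <- trimws(sub("!.*$", "", sub("^relationship: *part_of", "", ln)))
      cur$parents <- c(cur$parents, list(c(id, "part_of")))
    } else if (grepl("^is_obsolete: *true", ln)) {
      cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort(paste0("no usable [Term] stanza in ", path))
  bind_rows(terms)
}

#' Write and re-read profile matrices and result tables
#'
#' `write_profile()` stores a similarity-profile matrix as TSV with a header
#' row and a leading column of drug ids, at full (`%.17g`) precision so a
#' round trip through `read_profile()` is value-exact. `write_metrics()`
#' writes a metric table as TSV or JSON; `write_report()` writes the
#' novel-DDI report; `write_fingerprints()` writes `drug_id<TAB>bitstring`.
#'
#' @param x The object to write.
#' @param path Output file path.
#' @name writers
NULL

#' @rdname writers
#' @export
write_profile <- function(x, path) {
  ids <- rownames(x)
  body <- apply(unclass(x), 1, function(r) paste(sprintf("%.17g", r),
                                                 collapse = "\t"))
  writeLines(c(paste(c("drug_id", colnames(x)), collapse = "\t"),
               paste(ids, body, sep = "\t")), path)
  invisible(path)
}

#' @rdname writers
#' @param modality Modality tag to attach (`ssp`, `tsp`, `gsp`).
#' @export
read_profile <- function(path, modality = "ssp") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) abort(paste0("empty profile file: ", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- do.call(rbind, map(rows, function(r) as.numeric(r[-1])))
  rownames(mat) <- map_chr(rows, 1)
  colnames(mat) <- header
  new_similarity_profile(mat, modality)
}

#' @rdname writers
#' @param format `"tsv"` or `"json"`.
#' @export
write_metrics <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writers
#' @export
write_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param fingerprints Named list of 0/1 integer vectors.
#' @export
write_fingerprints <- function(fingerprints, path) {
  writeLines(paste(names(fingerprints),
                   map_chr(fingerprints, paste, collapse = ""),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname writers
#' @param ddis DDI tibble (`drug_a`, `drug_b`, `type`).
#' @export
write_ddis <- function(ddis, path) {
  writeLines(paste(ddis$drug_a, ddis$drug_b, ddis$type, sep = "\t"), path)
  invisible(path)
}

#' Run configuration with lossless YAML round trip
#'
#' Bundles every file path and model/evaluation parameter. Unknown keys in a
#' configuration file are rejected.
#'
#' @param ... Named values overriding the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    drugs = NULL, fingerprints = NULL, targets = NULL, network = NULL,
    go = NULL, annotations = NULL, ddis = NULL, out_dir = ".",
    seed = 1L, epochs = 850L, batch_size = 256L,
    modalities = c("ssp", "tsp", "gsp"),
    ae_hidden = c(1000L, 200L, 1000L), clf_hidden = rep(2000L, 6),
    ae_lr = 0.001, clf_lr = 0.0001, dropout = 0.3, batchnorm = TRUE,
    recon_loss = "mse", joint_reconstruction_weight = 1,
    joint_classification_weight = 1, folds = 5L, reducer = "ae",
    classifier = "ffn", min_per_type = 5L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(override)] <- override
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!map_lgl(unclass(config), is.null)], path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals)
  ints <- c("seed", "epochs", "batch_size", "folds", "min_per_type")
  for (k in ints) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("ae_hidden", "clf_hidden")) cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}
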