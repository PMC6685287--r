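#' Assemble a validated drug table
#'
#' The drug table is the package's central container: one row per drug, with
#' the molecular fingerprint, the target-gene set and (optionally) the GO-term
#' set stored as list-columns. All profile builders ([build_ssp()],
#' [build_tsp()], [build_gsp()]) take this table first, so calls chain with the
#' pipe.
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param fingerprint List of equal-length binary (0/1) integer vectors, one
#'   per drug. May be `NULL` when only target-based profiles are needed.
#' @param targets List of character vectors of target-gene ids, one per drug.
#'   May be `NULL` when only the structural profile is needed.
#' @param terms Optional list of character vectors of GO-term ids per drug.
#'   Usually derived from `targets` via [drug_go_terms()] rather than supplied.
#'
#' @return A tibble of class `drug_table` with columns `drug_id`,
#'   `fingerprint`, `targets` and, if given, `terms`.
#'
#' @examples
#' drugs <- drug_table(
#'   drug_id = c("d1", "d2"),
#'   fingerprint = list(c(1L, 0L, 1L), c(0L, 1L, 1L)),
#'   targets = list("g1", c("g1", "g2"))
#' )
#' @export
drug_table <- function(drug_id, fingerprint = NULL, targets = NULL,
                       terms = NULL) {
  drug_id <- as.character(drug_id)
  if (anyDuplicated(drug_id)) {
    abort("`drug_id` must be unique.")
  }
  n <- length(drug_id)
  out <- tibble(drug_id = drug_id)
  if (!is.null(fingerprint)) {
    stopifnot(length(fingerprint) == n)
    fingerprint <- map(fingerprint, function(fp) {
      fp <- as.integer(fp)
      if (any(!fp %in% c(0L, 1L))) abort("fingerprints must be binary (0/1).")
      fp
    })
    lens <- lengths(fingerprint)
    if (length(unique(lens)) > 1) {
      abort("all fingerprints must have identical length.")
    }
    out$fingerprint <- fingerprint
  }
  if (!is.null(targets)) {
    stopifnot(length(targets) == n)
    out$targets <- map(targets, function(x) unique(as.character(x)))
  }
  if (!is.null(terms)) {
    stopifnot(length(terms) == n)
    out$terms <- map(terms, function(x) unique(as.character(x)))
  }
  class(out) <- c("drug_table", class(out))
  out
}

#' Compute binary fingerprints from SMILES strings
#'
#' Converts SMILES to 1024-bit atom-pair-derived binary fingerprints via
#' ChemmineR/ChemmineOB. Synthetic worlds supply fingerprints directly and do
#' not need chemistry parsing; this is the entry point for real drug tables.
#'
#' @param smiles Named character vector of SMILES strings (names = drug ids).
#' @return A list of 0/1 integer vectors (length 1024), named by drug id.
#' @export
fingerprints_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("fingerprints_from_smiles() needs ChemmineR and ChemmineOB.")
  }
  if (is.null(names(smiles))) names(smiles) <- paste0("drug", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  fp <- ChemmineR::desc2fp(ap, descnames = 1024, type = "matrix")
  out <- lapply(seq_len(nrow(fp)), function(i) as.integer(fp[i, ]))
  names(out) <- names(smiles)
  out
}

fingerprint_matrix <- function(drugs) {
  if (is.null(drugs$fingerprint)) abort("drug table has no `fingerprint` column.")
  do.call(rbind, drugs$fingerprint)
}
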