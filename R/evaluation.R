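#' Filter the DDI dataset to the evaluable core
#'
#' Applies the dataset inclusion rules to a fixed point: drugs without any
#' target gene are excluded, DDIs touching an excluded (or unknown) drug are
#' dropped, and DDI types left with fewer than `min_per_type` records are
#' dropped. The rules are re-applied until nothing changes, and every step
#' is logged.
#'
#' @param ddis Tibble with `drug_a`, `drug_b`, `type`.
#' @param drugs A [drug_table()] with a `targets` column.
#' @param min_per_type Minimum records per retained type (default 5;
#'   "fewer than five" is strict, so a type with exactly 5 survives).
#' @return List of class `ddi_filter`: `ddis`, `drugs`, `log` (a tibble of
#'   per-step removal counts).
#' @export
filter_dataset <- function(ddis, drugs, min_per_type = 5) {
  if (is.null(drugs$targets)) abort("drug table needs a `targets` column.")
  ddis <- as_tibble(ddis)
  log <- list()
  note <- function(step, removed, ddis_left, drugs_left) {
    log[[length(log) + 1]] <<- tibble(
      step = step, removed = removed,
      ddis_remaining = ddis_left, drugs_remaining = drugs_left)
  }
  repeat {
    changed <- FALSE
    no_targets <- lengths(drugs$targets) == 0
    if (any(no_targets)) {
      drugs <- drugs[!no_targets, , drop = FALSE]
      changed <- TRUE
    }
    note("drugs_without_targets", sum(no_targets), nrow(ddis), nrow(drugs))
    orphan <- !(ddis$drug_a %in% drugs$drug_id &
                ddis$drug_b %in% drugs$drug_id)
    if (any(orphan)) {
      ddis <- ddis[!orphan, , drop = FALSE]
      changed <- TRUE
    }
    note("ddis_with_excluded_drug", sum(orphan), nrow(ddis), nrow(drugs))
    type_n <- table(as.character(ddis$type))
    rare <- names(type_n)[type_n < min_per_type]
    drop_type <- as.character(ddis$type) %in% rare
    if (any(drop_type)) {
      ddis <- ddis[!drop_type, , drop = FALSE]
      changed <- TRUE
    }
    note("rare_types", sum(drop_type), nrow(ddis), nrow(drugs))
    if (!changed) break
  }
  if (nrow(ddis) == 0) abort("filtering removed every DDI record.")
  structure(list(ddis = ddis, drugs = drugs, log = bind_rows(log)),
            class = "ddi_filter")
}

#' @export
print.ddi_filter <- function(x, ...) {
  cat("<ddi_filter> ", nrow(x$ddis), " DDIs of ",
      length(unique(x$ddis$type)), " types over ", nrow(x$drugs),
      " drugs\n", sep = "")
  invisible(x)
}

#' Stratified k-fold assignment of DDI records
#'
#' The split unit is the labeled drug pair (not the drug), matching the
#' cross-validation protocol: a drug may appear in both training and test
#' folds, but no pair does. Types with at least `k` records are stratified
#' (near-equal counts per fold); rarer types are assigned at random. The
#' assignment is deterministic given `seed`.
#'
#' @param ddis Tibble of DDI records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per row of `ddis`.
#' @export
kfold_split <- function(ddis, k = 5, seed = 1L) {
  n <- nrow(ddis)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` exceeds the number of records.")
  set.seed(seed)
  fold <- integer(n)
  for (ty in unique(as.character(ddis$type))) {
    idx <- which(as.character(ddis$type) == ty)
    if (length(idx) >= k) {
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    } else {
      fold[idx] <- sample(seq_len(k), length(idx), replace = TRUE)
    }
  }
  fold
}

#' An experiment plan row set
#'
#' Helper building the plan tibble consumed by [run_experiment()]: one row
#' per configuration of modality subset, feature reducer and classifier.
#'
#' @param modalities List of character vectors (subsets of ssp/tsp/gsp).
#' @param reducer One of `"ae"`, `"pca"`, `"none"` per row.
#' @param classifier One of `"ffn"`, `"svm"`, `"rf"` per row.
#' @return Tibble with list-column `modalities` and columns `reducer`,
#'   `classifier`, `label`.
#' @export
experiment_plan <- function(modalities, reducer, classifier) {
  if (!is.list(modalities)) modalities <- list(modalities)
  plan <- tibble(modalities = modalities, reducer = reducer,
                 classifier = classifier)
  stopifnot(all(plan$reducer %in% c("ae", "pca", "none")),
            all(plan$classifier %in% c("ffn", "svm", "rf")))
  plan$label <- paste0(map_chr(plan$modalities, paste, collapse = "+"),
                       "/", plan$reducer, "/", plan$classifier)
  plan
}

#' Run a cross-validated model-comparison experiment
#'
#' For every plan configuration: split the DDIs into `k` folds, train on
#' k-1 folds (fitting any reducer on the training folds only), score the
#' held-out fold, and average the metrics across folds. Cross-validated
#' scores over all records are kept per configuration, so per-type tables
#' and the novel-DDI report can be derived. A failing configuration is
#' recorded and the run continues.
#'
#' @param ddis Filtered DDI tibble (`drug_a`, `drug_b`, `type`).
#' @param profiles Named list of profile matrices (`ssp`, `tsp`, `gsp`).
#' @param plan An [experiment_plan()].
#' @param k Folds.
#' @param config A [training_config()] providing network sizes, epochs and
#'   the seed; its `modalities` field is overridden per plan row.
#' @return A `ddi_experiment`: `results` (per-config fold-averaged metrics),
#'   `fold_metrics`, `per_type` (accuracy and AUPRC per type), `cv_scores`
#'   (per-config score matrix in `ddis` row order), `errors`.
#' @export
run_experiment <- function(ddis, profiles, plan, k = 5,
                           config = training_config()) {
  ddis <- as_tibble(ddis)
  fold <- kfold_split(ddis, k = k, seed = config$seed)
  types <- sort(unique(as.character(ddis$type)))
  results <- list(); fold_metrics <- list(); per_type <- list()
  cv_scores <- list(); errors <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    label <- row$label
    scores <- matrix(NA_real_, nrow(ddis), length(types),
                     dimnames = list(NULL, types))
    fm <- list()
    res <- tryCatch({
      for (f in seq_len(k)) {
        tr <- ddis[fold != f, , drop = FALSE]
        te <- ddis[fold == f, , drop = FALSE]
        sc <- fit_score_config(tr, te, profiles, row$modalities[[1]],
                               row$reducer, row$classifier, config, types)
        scores[fold == f, ] <- sc
        fm[[f]] <- mutate(ddi_metrics(sc, te$type), fold = f,
                          label = label, .before = 1)
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      errors[[label]] <- res
      next
    }
    fmt <- bind_rows(fm)
    fold_metrics[[label]] <- fmt
    results[[label]] <- fmt %>%
      group_by(.data$label) %>%
      summarise(dplyr::across(c("accuracy", "macro_recall", "macro_precision",
                                "micro_recall", "micro_precision", "auprc"),
                              mean), .groups = "drop") %>%
      mutate(reducer = row$reducer, classifier = row$classifier,
             modalities = paste(row$modalities[[1]], collapse = "+"))
    cv_scores[[label]] <- scores
    aup <- suppressWarnings(pr_auprc(scores, ddis$type)$per_type)
    acc_t <- tibble(
      type = types,
      accuracy = map_dbl(types, function(ty) {
        sel <- as.character(ddis$type) == ty
        if (!any(sel)) return(NA_real_)
        mean(scores[sel, ty] >= 0.5)
      }))
    per_type[[label]] <- mutate(left_join(acc_t, aup, by = "type"),
                                label = label, .before = 1)
  }
  structure(
    list(results = bind_rows(results), fold_metrics = bind_rows(fold_metrics),
         per_type = bind_rows(per_type), cv_scores = cv_scores,
         errors = errors, plan = plan, k = k, ddis = ddis),
    class = "ddi_experiment")
}

# Train one configuration on `tr` and score `te`.
fit_score_config <- function(tr, te, profiles, modalities, reducer,
                             classifier, config, types) {
  config$modalities <- modalities
  if (reducer == "ae" && classifier == "ffn") {
    fit <- fit_ddi(tr, profiles, config)
    sc <- predict(fit, te, profiles)
    return(align_types(sc, types))
  }
  xtr <- do.call(cbind, map(profiles[modalities], function(p) {
    suppressMessages(assemble_pair_inputs(tr, p))
  }))
  xte <- do.call(cbind, map(profiles[modalities], function(p) {
    suppressMessages(assemble_pair_inputs(te, p))
  }))
  if (reducer == "pca") {
    k_red <- min(bottleneck_size(config) * length(modalities),
                 ncol(xtr), nrow(xtr) - 1)
    red <- pca_reduce(xtr, k_red)
    xte <- predict(red, xte)
    xtr <- red$scores
  }
  if (classifier == "ffn") {
    sc <- fit_ffn_score(xtr, tr$type, xte, config)
  } else {
    bl <- baseline_classifier(xtr, tr$type, which = classifier,
                              seed = config$seed)
    sc <- bl$score(xte)
  }
  align_types(sc, types)
}

align_types <- function(scores, types) {
  out <- matrix(0, nrow(scores), length(types),
                dimnames = list(NULL, types))
  shared <- intersect(colnames(scores), types)
  out[, shared] <- scores[, shared, drop = FALSE]
  out
}

# Stand-alone feed-forward classifier (used with the PCA or identity
# reducer): same architecture and optimizer as the joint model's classifier.
fit_ffn_score <- function(xtr, ytr, xte, config) {
  types <- sort(unique(as.character(ytr)))
  y <- matrix(0, nrow(xtr), length(types))
  y[cbind(seq_len(nrow(xtr)), match(as.character(ytr), types))] <- 1
  set.seed(config$seed)
  net <- new_classifier(ncol(xtr), length(types), config)
  opt <- opt_new(net, "adam", config$clf_lr)
  n <- nrow(xtr)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      fw <- nn_forward(net, xtr[idx, , drop = FALSE], training = TRUE)
      ls <- loss_bce_sigmoid(fw$out, y[idx, , drop = FALSE])
      if (!is.finite(ls$value)) abort("non-finite classifier cost.")
      bk <- nn_backward(fw$net, fw$caches, ls$d_preact, wrt = "preact")
      st <- opt_step(fw$net, bk$grads, opt)
      net <- st$net; opt <- st$opt
    }
  }
  sc <- nn_forward(net, xte)$out
  colnames(sc) <- types
  sc
}

#' SVM and random-forest baseline classifiers
#'
#' Baselines operating on the unreduced concatenated profile pairs. The
#' random forest uses Gini splitting, 10 trees, minimum node size 1; the
#' SVM a linear kernel with cost 1 and Platt-scaled class probabilities so
#' its scores live on the same `[0,1]` scale as the network's sigmoid
#' outputs.
#'
#' @param x Feature matrix (samples x features).
#' @param y Type labels.
#' @param which `"svm"` or `"rf"`.
#' @param seed Integer seed (tree bootstrap / probability calibration).
#' @return List with the fitted `model` and `score(newx)`, a function
#'   returning a per-type score matrix.
#' @export
baseline_classifier <- function(x, y, which = c("svm", "rf"), seed = 1L) {
  which <- match.arg(which)
  y <- factor(as.character(y))
  set.seed(seed)
  if (which == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      abort("the rf baseline needs the randomForest package.")
    }
    model <- randomForest::randomForest(x = x, y = y, ntree = 10, nodesize = 1)
    score <- function(newx) {
      p <- predict(model, newx, type = "prob")
      p[, levels(y), drop = FALSE]
    }
  } else {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      abort("the svm baseline needs the e1071 package.")
    }
    model <- e1071::svm(x = x, y = y, kernel = "linear", cost = 1,
                        probability = TRUE, scale = FALSE)
    score <- function(newx) {
      p <- attr(predict(model, newx, probability = TRUE), "probabilities")
      p[, levels(y), drop = FALSE]
    }
  }
  list(model = model, score = score, which = which)
}

#' Novel-DDI report from cross-validated scores
#'
#' Among pairs whose annotated type was correctly recovered (true-type score
#' at least 0.5 in cross-validation), lists every *other* type whose score
#' also clears the threshold: a putative additional interaction effect.
#' Rows are sorted by the novel score, descending.
#'
#' @param scores Cross-validated score matrix in `ddis` row order.
#' @param ddis The DDI records that were scored.
#' @param threshold Score threshold for reporting another type.
#' @return Tibble `drug_a`, `drug_b`, `known_type`, `known_score`,
#'   `novel_type`, `novel_score`.
#' @export
report_novel <- function(scores, ddis, threshold = 0.5) {
  check_scores(scores, ddis$type)
  truth <- as.character(ddis$type)
  true_score <- scores[cbind(seq_len(nrow(scores)),
                             match(truth, colnames(scores)))]
  rows <- list()
  eligible <- which(true_score >= 0.5)
  for (i in eligible) {
    other <- setdiff(colnames(scores)[scores[i, ] >= threshold], truth[i])
    if (length(other) == 0) next
    rows[[length(rows) + 1]] <- tibble(
      drug_a = ddis$drug_a[i], drug_b = ddis$drug_b[i],
      known_type = truth[i], known_score = true_score[i],
      novel_type = other, novel_score = unname(scores[i, other])
    )
  }
  out <- if (length(rows) > 0) bind_rows(rows) else
    tibble(drug_a = character(), drug_b = character(),
           known_type = character(), known_score = double(),
           novel_type = character(), novel_score = double())
  arrange(out, desc(.data$novel_score))
}

#' @describeIn run_experiment Fold-averaged metric table.
#' @param x A `ddi_experiment`.
#' @param ... Unused.
#' @export
tidy.ddi_experiment <- function(x, ...) x$results

#' @export
autoplot.ddi_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(object$results,
                            c("accuracy", "macro_recall", "macro_precision",
                              "micro_recall", "micro_precision", "auprc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
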