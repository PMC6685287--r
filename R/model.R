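#' Training configuration for the joint autoencoder-classifier model
#'
#' Defaults are the reference setting used for the full drug universe: per
#' modality an autoencoder with hidden sizes 1000-200-1000 (sigmoid, batch
#' normalization, dropout 0.3, RMSprop at learning rate 0.001) and a
#' feed-forward classifier with six 2000-unit ReLU hidden layers and a
#' sigmoid output layer (Adam at learning rate 0.0001), batch size 256,
#' 850 epochs. Synthetic-scale runs pass smaller `ae_hidden`, `clf_hidden`
#' and `epochs`.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling weight init, shuffling and dropout.
#' @param modalities Subset of `c("ssp", "tsp", "gsp")`; at least one.
#' @param ae_hidden Odd-length symmetric hidden sizes of each autoencoder;
#'   the middle entry is the bottleneck.
#' @param clf_hidden Hidden-layer sizes of the classifier.
#' @param ae_lr,clf_lr Learning rates (RMSprop / Adam).
#' @param dropout Drop rate for hidden layers.
#' @param batchnorm Apply batch normalization to hidden layers.
#' @param recon_loss Autoencoder reconstruction cost: mean squared error
#'   (default; inputs are similarities in `[0,1]`) or binary cross-entropy.
#' @param joint_weights Named weights of the summed joint cost
#'   (`reconstruction`, `classification`); the default is the unweighted sum.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 850, batch_size = 256, seed = 1L,
                            modalities = c("ssp", "tsp", "gsp"),
                            ae_hidden = c(1000L, 200L, 1000L),
                            clf_hidden = rep(2000L, 6),
                            ae_lr = 0.001, clf_lr = 0.0001,
                            dropout = 0.3, batchnorm = TRUE,
                            recon_loss = c("mse", "bce"),
                            joint_weights = c(reconstruction = 1,
                                              classification = 1)) {
  modalities <- match.arg(modalities, c("ssp", "tsp", "gsp"),
                          several.ok = TRUE)
  if (length(modalities) < 1) abort("select at least one modality.")
  recon_loss <- match.arg(recon_loss)
  if (length(ae_hidden) %% 2 != 1 ||
      !identical(ae_hidden, rev(ae_hidden))) {
    abort("`ae_hidden` must be symmetric with an odd number of layers.")
  }
  stopifnot(epochs >= 0, batch_size >= 1, dropout >= 0, dropout < 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), modalities = modalities,
         ae_hidden = as.integer(ae_hidden),
         clf_hidden = as.integer(clf_hidden),
         ae_lr = ae_lr, clf_lr = clf_lr, dropout = dropout,
         batchnorm = batchnorm, recon_loss = recon_loss,
         joint_weights = joint_weights),
    class = "training_config")
}

bottleneck_size <- function(config) {
  config$ae_hidden[(length(config$ae_hidden) + 1) %/% 2]
}

#' Concatenated profile-pair inputs
#'
#' For each labeled pair (A, B) the per-modality input is the concatenation
#' of A's profile row then B's profile row, length twice the universe size.
#' Order matters: (A, B) and (B, A) give different vectors. Pairs with a
#' drug missing from the profile are skipped and their count reported.
#'
#' @param ddis Tibble with columns `drug_a`, `drug_b`.
#' @param profile A `similarity_profile` matrix.
#' @return Numeric matrix (kept pairs x 2N) with attribute `kept`, a logical
#'   vector over the input rows.
#' @export
assemble_pair_inputs <- function(ddis, profile) {
  ids <- rownames(profile)
  kept <- ddis$drug_a %in% ids & ddis$drug_b %in% ids
  if (any(!kept)) {
    inform(paste0("skipped ", sum(!kept), " pair(s) with a drug missing from",
                  " the profile."))
  }
  a <- match(ddis$drug_a[kept], ids)
  b <- match(ddis$drug_b[kept], ids)
  x <- cbind(unclass(profile)[a, , drop = FALSE],
             unclass(profile)[b, , drop = FALSE])
  dimnames(x) <- NULL
  attr(x, "kept") <- kept
  x
}

new_ae <- function(input_size, config) {
  h <- config$ae_hidden
  mid <- (length(h) + 1) %/% 2
  enc_sizes <- c(input_size, h[1:mid])
  dec_sizes <- c(h[mid:length(h)], input_size)
  list(
    encoder = nn_new(enc_sizes, rep("sigmoid", length(enc_sizes) - 1),
                     config$batchnorm, config$dropout),
    decoder = nn_new(dec_sizes, rep("sigmoid", length(dec_sizes) - 1),
                     config$batchnorm, config$dropout)
  )
}

new_classifier <- function(input_size, n_types, config) {
  sizes <- c(input_size, config$clf_hidden, n_types)
  nn_new(sizes, c(rep("relu", length(config$clf_hidden)), "sigmoid"),
         config$batchnorm, config$dropout)
}

recon_loss_fun <- function(config) {
  if (config$recon_loss == "mse") loss_mse_sigmoid else loss_bce_sigmoid
}

#' Fit the joint autoencoder + feed-forward DDI-type model
#'
#' Each selected modality's profile pairs are reduced by an autoencoder; the
#' bottleneck codes are concatenated and classified by a deep feed-forward
#' network with one sigmoid output per DDI type. Every epoch has two phases:
#' first each autoencoder takes reconstruction-only steps; then a joint pass
#' minimizes the sum of all reconstruction costs and the classification
#' cost, with gradients flowing from the classifier back into the encoders
#' (so the autoencoders are trained twice per epoch).
#'
#' @param ddis Tibble with `drug_a`, `drug_b`, `type` (the labeled DDI list).
#' @param profiles Named list of `similarity_profile` matrices, containing at
#'   least the modalities selected in `config`.
#' @param config A [training_config()].
#' @return A `ddi_fit` object: trained networks, the per-epoch cost history
#'   (reconstruction per modality, classification, total), the type
#'   vocabulary and the drug universe order.
#' @export
fit_ddi <- function(ddis, profiles, config = training_config()) {
  mods <- config$modalities
  missing_mods <- setdiff(mods, names(profiles))
  if (length(missing_mods) > 0) {
    abort(paste0("profiles missing for modalities: ",
                 paste(missing_mods, collapse = ", ")))
  }
  x <- list(); kept <- rep(TRUE, nrow(ddis))
  for (m in mods) kept <- kept & (ddis$drug_a %in% rownames(profiles[[m]]) &
                                  ddis$drug_b %in% rownames(profiles[[m]]))
  if (any(!kept)) {
    inform(paste0("skipped ", sum(!kept),
                  " pair(s) missing from at least one profile."))
  }
  pairs <- ddis[kept, , drop = FALSE]
  if (nrow(pairs) == 0) abort("no usable training pair.")
  for (m in mods) {
    x[[m]] <- suppressMessages(assemble_pair_inputs(pairs, profiles[[m]]))
  }
  types <- sort(unique(as.character(ddis$type)))
  y <- matrix(0, nrow(pairs), length(types))
  y[cbind(seq_len(nrow(pairs)), match(as.character(pairs$type), types))] <- 1

  set.seed(config$seed)
  bundle <- list()
  for (m in mods) bundle[[m]] <- new_ae(ncol(x[[m]]), config)
  clf <- new_classifier(bottleneck_size(config) * length(mods),
                        length(types), config)
  opts <- list(clf = opt_new(clf, "adam", config$clf_lr))
  for (m in mods) {
    opts[[paste0(m, "_enc")]] <- opt_new(bundle[[m]]$encoder, "rmsprop", config$ae_lr)
    opts[[paste0(m, "_dec")]] <- opt_new(bundle[[m]]$decoder, "rmsprop", config$ae_lr)
  }
  rec_loss <- recon_loss_fun(config)
  w_rec <- config$joint_weights[["reconstruction"]]
  w_cls <- config$joint_weights[["classification"]]
  n <- nrow(pairs)
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    # phase 1: reconstruction-only steps, one autoencoder at a time
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      for (m in mods) {
        fe <- nn_forward(bundle[[m]]$encoder, x[[m]][idx, , drop = FALSE],
                         training = TRUE)
        fd <- nn_forward(bundle[[m]]$decoder, fe$out, training = TRUE)
        ls <- rec_loss(fd$out, x[[m]][idx, , drop = FALSE])
        bd <- nn_backward(fd$net, fd$caches, ls$d_preact, wrt = "preact")
        be <- nn_backward(fe$net, fe$caches, bd$d_input, wrt = "activation")
        st <- opt_step(fd$net, bd$grads, opts[[paste0(m, "_dec")]])
        bundle[[m]]$decoder <- st$net; opts[[paste0(m, "_dec")]] <- st$opt
        st <- opt_step(fe$net, be$grads, opts[[paste0(m, "_enc")]])
        bundle[[m]]$encoder <- st$net; opts[[paste0(m, "_enc")]] <- st$opt
      }
    }
    # phase 2: joint step, sum of reconstruction and classification costs
    ep_rec <- setNames(rep(0, length(mods)), mods)
    ep_cls <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      nb <- length(idx)
      fes <- list(); fds <- list(); rls <- list()
      for (m in mods) {
        fes[[m]] <- nn_forward(bundle[[m]]$encoder, x[[m]][idx, , drop = FALSE],
                               training = TRUE)
        fds[[m]] <- nn_forward(bundle[[m]]$decoder, fes[[m]]$out, training = TRUE)
        rls[[m]] <- rec_loss(fds[[m]]$out, x[[m]][idx, , drop = FALSE])
        ep_rec[m] <- ep_rec[m] + rls[[m]]$value * nb
      }
      z <- do.call(cbind, map(fes, "out"))
      fc <- nn_forward(clf, z, training = TRUE)
      cl <- loss_bce_sigmoid(fc$out, y[idx, , drop = FALSE])
      ep_cls <- ep_cls + cl$value * nb
      total <- w_rec * sum(map_dbl(rls, "value")) + w_cls * cl$value
      if (!is.finite(total)) {
        abort(paste0("non-finite joint cost at epoch ", epoch,
                     "; reduce the learning rate or batch size."))
      }
      bc <- nn_backward(fc$net, fc$caches, w_cls * cl$d_preact, wrt = "preact")
      k <- bottleneck_size(config)
      for (mi in seq_along(mods)) {
        m <- mods[mi]
        bd <- nn_backward(fds[[m]]$net, fds[[m]]$caches,
                          w_rec * rls[[m]]$d_preact, wrt = "preact")
        dz <- bd$d_input + bc$d_input[, ((mi - 1) * k + 1):(mi * k), drop = FALSE]
        be <- nn_backward(fes[[m]]$net, fes[[m]]$caches, dz, wrt = "activation")
        st <- opt_step(fds[[m]]$net, bd$grads, opts[[paste0(m, "_dec")]])
        bundle[[m]]$decoder <- st$net; opts[[paste0(m, "_dec")]] <- st$opt
        st <- opt_step(fes[[m]]$net, be$grads, opts[[paste0(m, "_enc")]])
        bundle[[m]]$encoder <- st$net; opts[[paste0(m, "_enc")]] <- st$opt
      }
      st <- opt_step(fc$net, bc$grads, opts$clf)
      clf <- st$net; opts$clf <- st$opt
    }
    rec_means <- ep_rec / n
    cls_mean <- ep_cls / n
    history[[epoch]] <- tibble(
      epoch = epoch,
      modality = c(mods, "classification", "total"),
      cost = c(unname(rec_means), cls_mean,
               w_rec * sum(rec_means) + w_cls * cls_mean)
    )
  }

  structure(
    list(autoencoders = bundle, classifier = clf,
         history = if (config$epochs > 0) bind_rows(history) else
           tibble(epoch = integer(), modality = character(), cost = double()),
         types = types, modalities = mods, config = config,
         profile_ids = map(profiles[mods], rownames),
         input_sizes = map_int(x, ncol)),
    class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("<ddi_fit> modalities: ", paste(x$modalities, collapse = "+"),
      "; ", length(x$types), " DDI types; ",
      x$config$epochs, " epochs\n", sep = "")
  if (nrow(x$history) > 0) {
    fin <- filter(x$history, .data$epoch == max(.data$epoch),
                  .data$modality == "total")
    cat("final joint cost:", signif(fin$cost, 4), "\n")
  }
  invisible(x)
}

#' Predict per-type DDI scores
#'
#' Encodes each pair's profiles with the trained encoders (inference mode:
#' no dropout, running batch-norm statistics) and returns the classifier's
#' sigmoid score for every DDI type. Rows are multi-label scores and need
#' not sum to 1.
#'
#' @param object A `ddi_fit`.
#' @param ddis Tibble with `drug_a`, `drug_b`.
#' @param profiles Named list of profile matrices over the same drug
#'   universe the model was trained on.
#' @param ... Unused.
#' @return Matrix (pairs x types) of scores in `[0,1]`, type labels as
#'   column names.
#' @export
predict.ddi_fit <- function(object, ddis, profiles, ...) {
  zs <- list()
  for (m in object$modalities) {
    xm <- suppressMessages(assemble_pair_inputs(ddis, profiles[[m]]))
    if (any(!attr(xm, "kept"))) abort("all pairs must be present in the profiles.")
    if (ncol(xm) != object$input_sizes[[m]]) {
      abort(paste0("profile width mismatch for ", m, ": got ", ncol(xm) / 2,
                   " drugs, trained on ", object$input_sizes[[m]] / 2, "."))
    }
    zs[[m]] <- nn_forward(object$autoencoders[[m]]$encoder, xm)$out
  }
  scores <- nn_forward(object$classifier, do.call(cbind, zs))$out
  colnames(scores) <- object$types
  scores
}

#' Encode pair inputs to bottleneck codes
#'
#' @inheritParams predict.ddi_fit
#' @return Matrix (pairs x 200 per modality) of encoder activations.
#' @export
encode_pairs <- function(object, ddis, profiles) {
  zs <- list()
  for (m in object$modalities) {
    xm <- suppressMessages(assemble_pair_inputs(ddis, profiles[[m]]))
    zs[[m]] <- nn_forward(object$autoencoders[[m]]$encoder, xm)$out
  }
  do.call(cbind, zs)
}

#' PCA feature reducer fitted on training data only
#'
#' Centers the training matrix and projects onto the top `k` principal
#' components; the returned reducer projects new data with the training
#' center and rotation, so no information leaks from evaluation folds.
#'
#' @param x Numeric matrix (samples x features), `nrow(x) >= 2`.
#' @param k Number of components, at most `ncol(x)`.
#' @return A `pca_reducer` with elements `scores` (training projection),
#'   `rotation`, `center` and `explained_variance`.
#' @export
pca_reduce <- function(x, k = 200) {
  if (nrow(x) < 2) abort("need at least 2 samples.")
  if (k > ncol(x)) abort("`k` exceeds the feature count.")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$rotation))
  tot <- sum(pc$sdev^2)
  structure(
    list(scores = pc$x[, seq_len(k_eff), drop = FALSE],
         rotation = pc$rotation[, seq_len(k_eff), drop = FALSE],
         center = pc$center,
         explained_variance = if (tot > 0) sum(pc$sdev[seq_len(k_eff)]^2) / tot else 1,
         k = k_eff),
    class = "pca_reducer")
}

#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  sweep(newdata, 2, object$center, "-") %*% object$rotation
}

#' Reconstruct data from PCA scores
#'
#' @param object A `pca_reducer`.
#' @param scores Projected data as returned by `predict()`.
#' @return Matrix in the original feature space.
#' @export
pca_restore <- function(object, scores) {
  sweep(scores %*% t(object$rotation), 2, object$center, "+")
}

#' Save / load a fitted model archive
#'
#' The archive is a single RDS file holding the trained weights, the specs,
#' the drug-order lists and the type vocabulary.
#'
#' @param object A `ddi_fit`.
#' @param path File path.
#' @export
save_ddi_fit <- function(object, path) {
  stopifnot(inherits(object, "ddi_fit"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ddi_fit
#' @export
load_ddi_fit <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ddi_fit")) abort("not a ddi_fit archive.")
  obj
}

#' @describeIn fit_ddi Cost history as a tidy tibble (`epoch`, `modality`,
#'   `cost`).
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @export
tidy.ddi_fit <- function(x, ...) x$history

#' @describeIn fit_ddi One-row model summary.
#' @export
glance.ddi_fit <- function(x, ...) {
  n_par <- sum(map_dbl(x$autoencoders, function(ae) {
    sum(map_dbl(c(ae$encoder$layers, ae$decoder$layers),
                function(ly) length(ly$W) + length(ly$b)))
  })) + sum(map_dbl(x$classifier$layers,
                    function(ly) length(ly$W) + length(ly$b)))
  fin <- filter(x$history, .data$epoch == max(c(.data$epoch, 1L)))
  tibble(
    modalities = paste(x$modalities, collapse = "+"),
    n_types = length(x$types),
    epochs = x$config$epochs,
    n_parameters = n_par,
    final_total_cost = if (nrow(fin) > 0)
      fin$cost[fin$modality == "total"] else NA_real_,
    final_classification_cost = if (nrow(fin) > 0)
      fin$cost[fin$modality == "classification"] else NA_real_
  )
}

#' @export
autoplot.ddi_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$cost,
                               colour = .data$modality)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cost", colour = NULL) +
    ggplot2::theme_minimal()
}
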