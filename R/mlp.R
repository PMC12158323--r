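#' Configuration for the circuit-parameter MLP classifier
#'
#' A small fully connected network with two hidden layers of three and
#' two neurons, hyperbolic-tangent hidden activations, and a single
#' sigmoid output unit trained with cross-entropy loss. Weights are
#' optimized with the limited-memory BFGS quasi-Newton method, which
#' suits the very small datasets typical of ex vivo tooth studies. The
#' default feature set is `r1`, `r2`, `q`; the CPE exponent `n` is
#' excluded by default because its small changes do not track the
#' demineralization state and including it tends to degrade
#' performance.
#'
#' @param hidden_layers hidden layer sizes, default `c(3, 2)`.
#' @param features ordered character subset of
#'   `c("r1", "r2", "q", "n")`.
#' @param l2_penalty L2 regularization strength on the weights.
#' @param max_iter optimizer iteration cap.
#' @param seed integer seed for the weight initialization.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_layers = c(3, 2),
                       features = c("r1", "r2", "q"),
                       l2_penalty = 1e-4, max_iter = 2000, seed = 0) {
  stopifnot(length(hidden_layers) >= 1, all(hidden_layers >= 1),
            length(features) >= 1,
            all(features %in% c("r1", "r2", "q", "n")),
            l2_penalty >= 0, max_iter >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 features = features, l2_penalty = l2_penalty,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "mlp_config")
}

#' Per-tooth feature table from a labeled dataset
#'
#' One row per tooth with the circuit-parameter features the MLP
#' consumes. With `source = "provenance"` the generating parameters are
#' used directly; with `source = "fit"` every replicate spectrum is
#' fitted by CNLS and the per-tooth parameters are geometric means over
#' replicates (arithmetic for `n`), which is how measured spectra would
#' be reduced.
#'
#' @param d a [labeled_dataset].
#' @param source `"provenance"` or `"fit"`.
#' @param cfg a [fit_config] used when `source = "fit"`.
#' @return Data frame with columns `tooth_id`, `label`, `r1`, `r2`,
#'   `q`, `n`.
#' @export
dataset_features <- function(d, source = c("provenance", "fit"),
                             cfg = fit_config()) {
  stopifnot(inherits(d, "labeled_dataset"))
  source <- match.arg(source)
  if (source == "provenance") return(d$provenance)
  tid <- vapply(d$spectra, function(s) s$tooth_id, integer(1))
  lab <- vapply(d$spectra, function(s) s$label, character(1))
  fits <- lapply(d$spectra, function(s) fit_spectrum(s, cfg)$params)
  per <- data.frame(tooth_id = tid, label = lab,
                    r1 = log(vapply(fits, `[[`, numeric(1), "r1")),
                    r2 = log(vapply(fits, `[[`, numeric(1), "r2")),
                    q  = log(vapply(fits, `[[`, numeric(1), "q")),
                    n  = vapply(fits, `[[`, numeric(1), "n"))
  out <- do.call(rbind, lapply(split(per, per$tooth_id), function(g) {
    data.frame(tooth_id = g$tooth_id[1], label = g$label[1],
               r1 = exp(mean(g$r1)), r2 = exp(mean(g$r2)),
               q = exp(mean(g$q)), n = mean(g$n))
  }))
  out <- out[order(out$tooth_id), ]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split at the tooth level
#'
#' Rows (teeth) are split class-by-class so the train fraction holds
#' within each label; because the unit of splitting is the tooth,
#' replicates of one tooth can never straddle the split.
#'
#' @param features data frame with a `label` column (one row per
#'   tooth), e.g. from [dataset_features].
#' @param train_frac fraction assigned to training.
#' @param seed integer seed; the split is reproducible.
#' @return List with `train` and `test` data frames (disjoint).
#' @export
split_dataset <- function(features, train_frac = 0.7, seed = 0) {
  stopifnot(is.data.frame(features), "label" %in% names(features),
            train_frac > 0, train_frac < 1)
  labs <- unique(features$label)
  if (length(labs) < 2L)
    stop("both classes must be present to split", call. = FALSE)
  idx_train <- with_local_seed(seed, {
    unlist(lapply(labs, function(l) {
      i <- which(features$label == l)
      n_tr <- round(train_frac * length(i))
      if (n_tr < 1 || n_tr >= length(i))
        stop("too few samples in a class for this split", call. = FALSE)
      sample(i, n_tr)
    }))
  })
  list(train = features[sort(idx_train), , drop = FALSE],
       test = features[setdiff(seq_len(nrow(features)), idx_train), ,
                       drop = FALSE])
}

#' Min-max feature normalizer
#'
#' Learns per-feature minima and maxima from the training data and maps
#' each feature to `(x - min) / (max - min)`. The training set maps
#' into \[0, 1\]; test values may legitimately fall outside and are not
#' clipped. Normalization is required because the circuit parameters
#' differ by many orders of magnitude (kiloohms vs 1e-7 s^n/ohm).
#'
#' @param x numeric matrix or data frame of training features.
#' @return An object of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows", call. = FALSE)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs <= mins))
    stop("constant feature: min-max normalization undefined", call. = FALSE)
  structure(list(min = mins, max = maxs), class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param nrm a `minmax_normalizer` from [fit_normalizer].
#' @export
apply_normalizer <- function(x, nrm) {
  stopifnot(inherits(nrm, "minmax_normalizer"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, nrm$min), 2, nrm$max - nrm$min, "/")
}

# ---- network internals -----------------------------------------------------

mlp_sizes <- function(p, hidden) c(p, hidden, 1L)

mlp_n_weights <- function(sizes) {
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

mlp_unpack <- function(theta, sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    nw <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(theta[pos + seq_len(nw)], sizes[l], sizes[l + 1])
    pos <- pos + nw
    b[[l]] <- theta[pos + seq_len(sizes[l + 1])]
    pos <- pos + sizes[l + 1]
  }
  list(W = W, b = b)
}

mlp_forward <- function(x, wb) {
  L <- length(wb$W)
  a <- x
  acts <- vector("list", L + 1L)
  acts[[1]] <- a
  for (l in seq_len(L - 1L)) {
    a <- tanh(sweep(a %*% wb$W[[l]], 2, wb$b[[l]], "+"))
    acts[[l + 1]] <- a
  }
  z_out <- drop(a %*% wb$W[[L]]) + wb$b[[L]]
  list(z = z_out, acts = acts)
}

# Stable binary cross-entropy from logits.
ce_from_logits <- function(z, y) {
  mean(pmax(z, 0) + log1p(exp(-abs(z))) - y * z)
}

mlp_objective <- function(theta, x, y, sizes, l2) {
  wb <- mlp_unpack(theta, sizes)
  fw <- mlp_forward(x, wb)
  ce_from_logits(fw$z, y) +
    l2 / (2 * nrow(x)) * sum(vapply(wb$W, function(w) sum(w^2), numeric(1)))
}

mlp_gradient <- function(theta, x, y, sizes, l2) {
  wb <- mlp_unpack(theta, sizes)
  fw <- mlp_forward(x, wb)
  n <- nrow(x)
  L <- length(wb$W)
  p <- 1 / (1 + exp(-fw$z))
  delta <- matrix((p - y) / n, ncol = 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(fw$acts[[l]]) %*% delta + (l2 / n) * wb$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(wb$W[[l]])) * (1 - fw$acts[[l]]^2)
  }
  unlist(mapply(function(w, bb) c(as.vector(w), bb), gW, gb,
                SIMPLIFY = FALSE))
}

labels_to_binary <- function(y) {
  if (is.numeric(y)) return(as.numeric(y != 0))
  if (!all(y %in% c("ND", "DM")))
    stop('labels must be "ND"/"DM" (or 0/1)', call. = FALSE)
  as.numeric(y == "DM")
}

#' Train the MLP on (normalized) circuit-parameter features
#'
#' Fits the `(p -> 3 -> 2 -> 1)` tanh network by minimising
#' regularized cross-entropy with `optim(method = "L-BFGS-B")`.
#' Training is deterministic given `cfg$seed` (which fixes the weight
#' initialization). Non-convergence within `cfg$max_iter` produces a
#' warning flag on the returned model, not an error.
#'
#' @param x numeric matrix of features, already normalized (see
#'   [fit_normalizer]); columns must follow `cfg$features`.
#' @param y labels, `"ND"`/`"DM"` or 0/1 with DM = 1.
#' @param cfg an [mlp_config].
#' @param normalizer optionally, the `minmax_normalizer` used to
#'   produce `x`; when embedded, [predict.trained_mlp] accepts raw
#'   (unnormalized) feature tables.
#' @return An object of class `trained_mlp`.
#' @export
train_mlp <- function(x, y, cfg = mlp_config(), normalizer = NULL) {
  stopifnot(inherits(cfg, "mlp_config"))
  x <- as.matrix(x)
  y <- labels_to_binary(y)
  stopifnot(nrow(x) == length(y))
  sizes <- mlp_sizes(ncol(x), cfg$hidden_layers)
  nW <- mlp_n_weights(sizes)
  theta0 <- with_local_seed(cfg$seed, {
    th <- numeric(nW)
    pos <- 0L
    L <- length(sizes) - 1L
    for (l in seq_len(L)) {
      nw <- sizes[l] * sizes[l + 1]
      sc <- sqrt(2 / (sizes[l] + sizes[l + 1]))  # Glorot-style scale
      th[pos + seq_len(nw)] <- stats::rnorm(nw, 0, sc)
      pos <- pos + nw + sizes[l + 1]  # biases stay zero
    }
    th
  })
  opt <- stats::optim(theta0, fn = mlp_objective, gr = mlp_gradient,
                      x = x, y = y, sizes = sizes, l2 = cfg$l2_penalty,
                      method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iter, factr = 1e4))
  if (opt$convergence != 0)
    warning("MLP training did not converge within max_iter", call. = FALSE)
  structure(list(theta = opt$par, sizes = sizes, config = cfg,
                 normalizer = normalizer, loss = opt$value,
                 converged = opt$convergence == 0),
            class = "trained_mlp")
}

#' Predict demineralization probability with a trained MLP
#'
#' @param object a `trained_mlp`.
#' @param newdata matrix or data frame of features. If the model embeds
#'   a normalizer, raw feature values (or a data frame containing the
#'   configured feature columns) are accepted and normalized
#'   internally; otherwise `newdata` must already be normalized.
#' @param ... unused.
#' @return Data frame with `prob` (probability of DM) and `label`
#'   (`"DM"` iff `prob >= 0.5`; the tie goes to DM).
#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  feats <- object$config$features
  if (is.data.frame(newdata) && all(feats %in% names(newdata)))
    newdata <- as.matrix(newdata[, feats, drop = FALSE])
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1])
    stop(sprintf("expected %d features, got %d", object$sizes[1],
                 ncol(newdata)), call. = FALSE)
  if (!is.null(object$normalizer))
    newdata <- apply_normalizer(newdata, object$normalizer)
  wb <- mlp_unpack(object$theta, object$sizes)
  z <- mlp_forward(newdata, wb)$z
  prob <- 1 / (1 + exp(-z))
  data.frame(prob = prob, label = ifelse(prob >= 0.5, "DM", "ND"))
}

#' Train the MLP classifier from a per-tooth feature table
#'
#' Convenience wrapper: selects the configured feature columns, fits
#' the min-max normalizer on them, and trains the network with the
#' normalizer embedded so that prediction accepts raw feature tables.
#'
#' @param features data frame with `label` and the feature columns
#'   (e.g. from [dataset_features]).
#' @param cfg an [mlp_config].
#' @return A `trained_mlp` with embedded normalizer.
#' @export
train_mlp_classifier <- function(features, cfg = mlp_config()) {
  x <- as.matrix(features[, cfg$features, drop = FALSE])
  nrm <- fit_normalizer(x)
  train_mlp(apply_normalizer(x, nrm), features$label, cfg, normalizer = nrm)
}

#' Stratified k-fold cross-validation of the MLP
#'
#' Folds are stratified by label at the tooth level. For each split the
#' normalizer and network are fitted on the training folds only, and
#' accuracy, recall (sensitivity to DM) and AUC are computed on the
#' held-out fold.
#'
#' @param features per-tooth feature table with `label` column.
#' @param cfg an [mlp_config].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `cv_report`: list with `per_split` (data
#'   frame of `split`, `accuracy`, `recall`, `auc`) and `summary`
#'   (mean and SD of each score).
#' @export
cross_validate <- function(features, cfg = mlp_config(), k = 5, seed = 0) {
  stopifnot(is.data.frame(features), "label" %in% names(features), k >= 2)
  if (length(unique(features$label)) < 2L)
    stop("both classes must be present", call. = FALSE)
  for (l in unique(features$label))
    if (sum(features$label == l) < k)
      stop(sprintf("class %s has fewer than k = %d samples", l, k),
           call. = FALSE)
  fold <- integer(nrow(features))
  with_local_seed(seed, {
    for (l in unique(features$label)) {
      i <- which(features$label == l)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  per <- do.call(rbind, lapply(seq_len(k), function(s) {
    tr <- features[fold != s, , drop = FALSE]
    te <- features[fold == s, , drop = FALSE]
    model <- train_mlp_classifier(tr, cfg)
    pr <- predict(model, te)
    cm <- confusion_matrix(te$label, pr$label)
    auc <- if (length(unique(te$label)) == 2L)
      roc_curve(pr$prob, te$label)$auc else NA_real_
    data.frame(split = s,
               accuracy = (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn),
               recall = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn)
                        else NA_real_,
               auc = auc)
  }))
  summ <- data.frame(
    score = c("accuracy", "recall", "auc"),
    mean = c(mean(per$accuracy), mean(per$recall, na.rm = TRUE),
             mean(per$auc, na.rm = TRUE)),
    sd = c(stats::sd(per$accuracy), stats::sd(per$recall),
           stats::sd(per$auc)))
  structure(list(per_split = per, summary = summ, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation:\n", x$k))
  print(x$per_split, row.names = FALSE)
  cat("\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
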