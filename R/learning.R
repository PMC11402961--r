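# Model training machinery: Min-Max scaling, activity labelling, SMOTE
# balancing, a seeded feed-forward network (Adam, early stopping) and
# leave-one-out cross validation with fold-local preprocessing.

#' Model configuration
#'
#' Training protocol constants: maximum 300 epochs, 10% validation split
#' with early stopping, L2 weight 0.005, classification probability
#' threshold 0.5 follow the published protocol; the (64, 32) rectifier
#' architecture, patience 20 and Adam step size are package defaults
#' (per-representation architectures were never published).
#'
#' @param task `"classification"` or `"regression"`.
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param max_epochs Maximum training epochs.
#' @param val_fraction Fraction of training rows held out for early stopping.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (best weights restored).
#' @param l2_sigma L2 (ridge) penalty weight.
#' @param prob_threshold Probability above which `active` is predicted.
#' @param learning_rate Adam step size.
#' @param activity_threshold_mgs %MGS activity threshold for labelling.
#' @param seed Integer seed; all fold/model randomness derives from it.
#' @return A list of class `model_config`.
#' @export
model_config <- function(task = c("regression", "classification"),
                         hidden_layers = c(64, 32),
                         max_epochs = 300,
                         val_fraction = 0.10,
                         early_stop_patience = 20,
                         l2_sigma = 0.005,
                         prob_threshold = 0.5,
                         learning_rate = 0.003,
                         activity_threshold_mgs = 70,
                         seed = 1L) {
  task <- match.arg(task)
  stopifnot(max_epochs >= 1, val_fraction > 0, val_fraction < 1,
            l2_sigma >= 0, prob_threshold > 0, prob_threshold < 1,
            learning_rate > 0, all(hidden_layers >= 1))
  structure(list(task = task, hidden_layers = as.integer(hidden_layers),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 l2_sigma = l2_sigma, prob_threshold = prob_threshold,
                 learning_rate = learning_rate,
                 activity_threshold_mgs = activity_threshold_mgs,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Min-Max scaling
#'
#' Per-column \eqn{(x - min) / (max - min)} with statistics taken from the
#' rows passed to `minmax_fit()` (always the training fold, never held-out
#' data). Constant columns map to 0 (with a warning at fit time) and are
#' left unchanged by inversion.
#'
#' @param x Numeric matrix or data frame (>= 2 rows for fitting).
#' @return `minmax_fit()`: a `minmax_scaler`; `minmax_apply()` /
#'   `minmax_invert()`: a matrix of the same shape as the input.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, is.numeric(x))
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  rng <- maxs - mins
  constant <- rng == 0
  if (any(constant)) {
    warning(sum(constant), " constant column(s) map to 0 under Min-Max scaling")
  }
  structure(list(mins = mins, range = rng, constant = constant),
            class = "minmax_scaler")
}

#' @rdname minmax_fit
#' @param scaler A fitted `minmax_scaler`.
#' @export
minmax_apply <- function(scaler, x) {
  if (!inherits(scaler, "minmax_scaler")) stop("scaler must be fitted before applying")
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$mins))
  rng <- ifelse(scaler$constant, 1, scaler$range)
  sweep(sweep(x, 2, scaler$mins, "-"), 2, rng, "/")
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(scaler, x) {
  if (!inherits(scaler, "minmax_scaler")) stop("scaler must be fitted before inverting")
  x <- as.matrix(x)
  rng <- ifelse(scaler$constant, 1, scaler$range)
  sweep(sweep(x, 2, rng, "*"), 2, scaler$mins, "+")
}

#' Label activity from %MGS
#'
#' `active` iff `mgs < threshold`; the boundary value is `inactive` (active
#' should mean strictly smaller ice grains than the threshold).
#'
#' @param mgs Numeric %MGS values (>= 0).
#' @param threshold Activity threshold (%MGS).
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_activity <- function(mgs, threshold = 70) {
  if (any(mgs < 0, na.rm = TRUE)) stop("negative %MGS value(s)")
  ifelse(mgs < threshold, "active", "inactive")
}

#' SMOTE class balancing
#'
#' Augments the minority class with synthetic rows
#' \eqn{x_i + u (x_{nn} - x_i)}, \eqn{u \sim U(0,1)}, where \eqn{x_{nn}} is
#' one of the `k` nearest minority neighbours of minority row \eqn{x_i},
#' until class counts are equal. Already balanced input is returned
#' unchanged.
#'
#' @param features Numeric matrix (rows = observations).
#' @param labels Class labels (two classes; minority count >= 2).
#' @param seed Integer seed.
#' @param k Number of nearest neighbours considered.
#' @return List with elements `features` and `labels` (originals first,
#'   synthetic rows appended).
#' @export
smote_balance <- function(features, labels, seed = 1L, k = 5) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("SMOTE requires both classes present")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min == n_maj) return(list(features = features, labels = labels))
  if (n_min < 2) stop("SMOTE requires at least 2 minority observations")
  set.seed(as.integer(seed))
  min_rows <- features[labels == minority, , drop = FALSE]
  k_eff <- min(k, n_min - 1)
  d <- as.matrix(stats::dist(min_rows))
  diag(d) <- Inf
  nn_idx <- t(apply(d, 1, function(row) order(row)[seq_len(k_eff)]))
  n_new <- n_maj - n_min
  synth <- matrix(0, n_new, ncol(features))
  for (s in seq_len(n_new)) {
    i <- sample.int(n_min, 1)
    nn <- nn_idx[i, sample.int(k_eff, 1)]
    u <- stats::runif(1)
    synth[s, ] <- min_rows[i, ] + u * (min_rows[nn, ] - min_rows[i, ])
  }
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, n_new)))
}

# ---- feed-forward network ------------------------------------------------

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(n_in, hidden, n_out = 1L) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialisation for the rectifier layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, task) {
  A <- list(X)
  L <- length(par$W)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% par$W[[l]] + matrix(par$b[[l]], nrow(X),
                                        length(par$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L) relu(Z) else if (task == "classification") sigmoid(Z) else Z
  }
  A
}

mlp_loss <- function(par, X, y, task, l2) {
  out <- mlp_forward(par, X, task)[[length(par$W) + 1]][, 1]
  data_loss <- if (task == "classification") {
    p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((out - y)^2)
  }
  data_loss + l2 * sum(vapply(par$W, function(w) sum(w^2), numeric(1)))
}

mlp_grad <- function(par, X, y, task, l2) {
  L <- length(par$W)
  A <- mlp_forward(par, X, task)
  n <- nrow(X)
  out <- A[[L + 1]][, 1]
  # dL/dz_out: both BCE+sigmoid and MSE+identity reduce to (out - y) * c
  delta <- matrix((out - y) * (if (task == "regression") 2 else 1) / n, ncol = 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(A[[l]]) %*% delta + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train a feed-forward network
#'
#' Binary cross-entropy with sigmoid output (classification, targets are
#' `active`/`inactive` labels) or mean-squared error with linear output
#' (regression, targets already Min-Max scaled), plus an L2 penalty. Trains
#' full-batch Adam for at most `cfg$max_epochs` epochs with early stopping
#' on a `cfg$val_fraction` random validation split (best weights restored).
#' Fully deterministic given `cfg$seed`.
#'
#' @param features Scaled numeric matrix (>= 10 rows).
#' @param targets Numeric scaled targets (regression) or class labels
#'   (classification).
#' @param cfg A [model_config()].
#' @return An object of class `iri_mlp` with a [predict][predict.iri_mlp]
#'   method.
#' @export
train_model <- function(features, targets, cfg = model_config()) {
  X <- as.matrix(features)
  if (nrow(X) != length(targets)) stop("feature rows and targets differ in length")
  if (nrow(X) < 10) stop("need at least 10 training rows")
  y <- if (cfg$task == "classification") {
    as.numeric(targets == "active")
  } else {
    as.numeric(targets)
  }
  set.seed(cfg$seed)
  n <- nrow(X)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  par <- mlp_init(ncol(X), cfg$hidden_layers)
  m <- rapply(par, function(x) x * 0, how = "replace")
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, par = par, epoch = 0L)
  stale <- 0L
  history <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    g <- mlp_grad(par, Xtr, ytr, cfg$task, cfg$l2_sigma)
    for (part in c("W", "b")) {
      for (l in seq_along(par[[part]])) {
        m[[part]][[l]] <- b1 * m[[part]][[l]] + (1 - b1) * g[[part]][[l]]
        v[[part]][[l]] <- b2 * v[[part]][[l]] + (1 - b2) * g[[part]][[l]]^2
        mhat <- m[[part]][[l]] / (1 - b1^epoch)
        vhat <- v[[part]][[l]] / (1 - b2^epoch)
        par[[part]][[l]] <- par[[part]][[l]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- mlp_loss(par, Xval, yval, cfg$task, 0)
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, par = par, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$early_stop_patience) break
    }
  }
  structure(list(par = best$par, cfg = cfg, n_features = ncol(X),
                 best_epoch = best$epoch, epochs_run = length(history),
                 val_loss = best$loss, val_history = history),
            class = "iri_mlp")
}

#' Predict from a trained network
#'
#' @param object An `iri_mlp` fit.
#' @param newdata Feature matrix on the same scale as training.
#' @param type `"response"` (probability / scaled value) or `"class"`
#'   (classification only).
#' @param ... Unused.
#' @return Numeric vector, or character labels for `type = "class"`.
#' @export
predict.iri_mlp <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) stop("newdata has wrong number of features")
  out <- mlp_forward(object$par, X, object$cfg$task)[[length(object$par$W) + 1]][, 1]
  if (type == "class") {
    if (object$cfg$task != "classification") stop("type='class' needs a classifier")
    return(ifelse(out > object$cfg$prob_threshold, "active", "inactive"))
  }
  out
}

#' @export
print.iri_mlp <- function(x, ...) {
  cat("<iri_mlp> ", x$cfg$task, ", hidden [",
      paste(x$cfg$hidden_layers, collapse = ", "), "], best epoch ",
      x$best_epoch, "/", x$epochs_run, ", val loss ",
      format(x$val_loss, digits = 4), "\n", sep = "")
  invisible(x)
}

# Fold-local preprocessing + training + prediction for one LOO fold.
loo_fold <- function(X, mgs, i, cfg) {
  fold_cfg <- cfg
  fold_cfg$seed <- derive_seed(cfg$seed, i)
  Xtr <- X[-i, , drop = FALSE]
  scaler <- suppressWarnings(minmax_fit(Xtr))
  Xs <- minmax_apply(scaler, Xtr)
  Xi <- minmax_apply(scaler, X[i, , drop = FALSE])
  if (cfg$task == "classification") {
    lab <- label_activity(mgs[-i], cfg$activity_threshold_mgs)
    if (length(unique(lab)) == 2 && min(table(lab)) >= 2) {
      set.seed(fold_cfg$seed)
      bal <- smote_balance(Xs, lab, seed = derive_seed(fold_cfg$seed, 1L))
      Xs <- bal$features; lab <- bal$labels
    }
    fit <- train_model(Xs, lab, fold_cfg)
    prob <- predict(fit, Xi)
    c(prediction = prob)
  } else {
    yscaler <- suppressWarnings(minmax_fit(matrix(mgs[-i], ncol = 1)))
    ys <- minmax_apply(yscaler, matrix(mgs[-i], ncol = 1))[, 1]
    fit <- train_model(Xs, ys, fold_cfg)
    pred <- minmax_invert(yscaler, matrix(predict(fit, Xi), ncol = 1))[1, 1]
    c(prediction = pred)
  }
}

#' Leave-one-out cross validation for one representation
#'
#' For each compound, fits the full preprocessing + model pipeline on all
#' other compounds (Min-Max scaling, SMOTE balancing for classification,
#' target scaling for regression, network training with its validation
#' split) and predicts the held-out compound. No statistic of the held-out
#' compound enters any fold's preprocessing or training.
#'
#' @param compounds Compound tibble with `id` and `mgs_percent` (>= 10
#'   rows).
#' @param features Feature block: a data frame of numeric columns (optionally
#'   with an `id` column matching `compounds$id`) or a matrix, rows aligned
#'   with `compounds`.
#' @param cfg A [model_config()].
#' @return A tibble of class `iri_loo`: `id`, `observed` (%MGS),
#'   `prediction` (%MGS for regression, active-class probability for
#'   classification), and for classification `observed_label`,
#'   `predicted_label`.
#' @export
loo_cv <- function(compounds, features, cfg = model_config()) {
  if (nrow(compounds) < 10) stop("leave-one-out needs at least 10 compounds")
  X <- feature_matrix(features, compounds$id)
  mgs <- compounds$mgs_percent
  stopifnot(all(!is.na(mgs)))
  preds <- vapply(seq_len(nrow(X)), function(i) loo_fold(X, mgs, i, cfg),
                  numeric(1))
  out <- tibble::tibble(id = compounds$id, observed = mgs, prediction = preds)
  if (cfg$task == "classification") {
    out$observed_label <- label_activity(mgs, cfg$activity_threshold_mgs)
    out$predicted_label <- ifelse(preds > cfg$prob_threshold, "active", "inactive")
  }
  attr(out, "task") <- cfg$task
  class(out) <- c("iri_loo", class(out))
  out
}

#' Leave-one-out predictions for several representations
#'
#' Runs [loo_cv()] once per feature block with block-specific derived seeds
#' and collects the per-model predictions in one wide tibble ready for
#' ensemble combination and exhaustive subset search.
#'
#' @param compounds Compound tibble.
#' @param blocks Named list of feature blocks.
#' @param cfg A [model_config()].
#' @return A tibble of class `iri_loo_multi`: `id`, `observed`, one
#'   prediction column per block (probability or %MGS).
#' @export
loo_cv_blocks <- function(compounds, blocks, cfg = model_config()) {
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)),
            all(nzchar(names(blocks))))
  out <- tibble::tibble(id = compounds$id, observed = compounds$mgs_percent)
  for (b in seq_along(blocks)) {
    bcfg <- cfg
    bcfg$seed <- derive_seed(cfg$seed, 7000L + b)
    res <- loo_cv(compounds, blocks[[b]], bcfg)
    out[[names(blocks)[b]]] <- res$prediction
  }
  attr(out, "task") <- cfg$task
  attr(out, "threshold") <- cfg$activity_threshold_mgs
  attr(out, "prob_threshold") <- cfg$prob_threshold
  class(out) <- c("iri_loo_multi", class(out))
  out
}

# Coerce a feature block (tibble with optional id column, or matrix) to a
# numeric matrix aligned with `ids`.
feature_matrix <- function(features, ids = NULL) {
  if (is.matrix(features)) {
    X <- features
  } else {
    features <- as.data.frame(features)
    if ("id" %in% names(features)) {
      if (!is.null(ids)) {
        if (!all(ids %in% features$id)) stop("feature block is missing id(s)")
        features <- features[match(ids, features$id), , drop = FALSE]
      }
      features$id <- NULL
    }
    X <- as.matrix(features)
  }
  if (!is.numeric(X)) stop("feature block must be numeric")
  if (!all(is.finite(X))) stop("feature block contains non-finite values")
  if (!is.null(ids) && nrow(X) != length(ids)) {
    stop("feature block rows do not match compounds")
  }
  X
}
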