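# Severity classification under stratified 10-fold cross-validation.
#
# Three classifier families mirror the usual screening toolkit:
#   - "logistic": L2-regularized multinomial logistic regression (a
#     functional stand-in for boosted simple-logistic learners);
#   - "svm": linear SVM (polynomial kernel of exponent 1.0 is a linear
#     kernel), cost C = 1, squared-hinge primal, one-vs-rest;
#   - "mlp": a small dense network, hidden layers 50 and 25 with ReLU and
#     dropout 0.2 before the output layer, softmax output, Adam training.
# All training is deterministic given a seed.

#' Describe a classifier
#'
#' @param kind one of `"logistic"`, `"svm"`, `"mlp"`.
#' @param ... hyperparameter overrides: `lambda` (logistic ridge penalty,
#'   default 1e-3), `cost` (SVM C, default 1), `hidden` (MLP layer sizes,
#'   default `c(50, 25)`), `dropout` (default 0.2), `epochs` (default 200),
#'   `batch` (default 16), `lr` (default 1e-3).
#' @return a `classifier_spec` list, serializable with [jsonlite::toJSON()].
#' @export
classifier_spec <- function(kind = c("logistic", "svm", "mlp"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    logistic = list(lambda = 1e-3),
    svm = list(cost = 1),
    mlp = list(hidden = c(50L, 25L), dropout = 0.2, epochs = 200L,
               batch = 16L, lr = 1e-3))
  structure(c(list(kind = kind), utils::modifyList(defaults, list(...))),
            class = "classifier_spec")
}

#' Binary severity labels from a roster
#'
#' Label 1 when AHI is at or above the threshold, else 0. Thresholds 5, 15
#' and 30 are the severity-group boundaries.
#'
#' @param roster data.frame with an `ahi` column (see [read_roster()]).
#' @param threshold AHI cut-off (> 0).
#' @return factor with levels `"0"`, `"1"`.
#' @export
make_binary_labels <- function(roster, threshold) {
  if (threshold <= 0) stop("make_binary_labels: threshold must be > 0")
  factor(as.integer(roster$ahi >= threshold), levels = c("0", "1"))
}

# --- linear SVM (squared-hinge primal) -------------------------------------

.svm_linear_fit <- function(X, y, cost = 1) {
  p <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- 1 - y * (as.numeric(X %*% w) + b)
    h <- pmax(m, 0)
    0.5 * sum(w^2) + cost * sum(h^2)
  }
  grd <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- 1 - y * (as.numeric(X %*% w) + b)
    h <- pmax(m, 0)
    gw <- w - 2 * cost * as.numeric(crossprod(X, y * h))
    gb <- -2 * cost * sum(y * h)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1L), obj, grd, method = "BFGS",
                      control = list(maxit = 200L, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L])
}

# --- small MLP with dropout -------------------------------------------------

.mlp_fit <- function(X, y_idx, n_classes, hidden, dropout, epochs, batch, lr,
                     seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, hidden, n_classes)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1L]))
  B <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(B, function(b) b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), y_idx)] <- 1
  prev_loss <- Inf; stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      A <- list(X[idx, , drop = FALSE])
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        Z <- A[[l]] %*% W[[l]] + matrix(B[[l]], length(idx), sizes[l + 1L],
                                        byrow = TRUE)
        if (l < L) {
          H <- pmax(Z, 0)
          # inverted dropout on hidden activations feeding the next layer
          mk <- matrix(stats::rbinom(length(H), 1L, 1 - dropout) / (1 - dropout),
                       nrow(H), ncol(H))
          masks[[l]] <- mk
          A[[l + 1L]] <- H * mk
        } else {
          Zs <- Z - apply(Z, 1L, max)
          Pm <- exp(Zs) / rowSums(exp(Zs))
          A[[l + 1L]] <- Pm
        }
      }
      Pm <- A[[L + 1L]]
      ep_loss <- ep_loss - sum(log(pmax(Pm[Y[idx, , drop = FALSE] == 1], 1e-12)))
      D <- (Pm - Y[idx, , drop = FALSE]) / length(idx)
      for (l in L:1) {
        gW <- crossprod(A[[l]], D)
        gB <- colSums(D)
        if (l > 1L) {
          D <- (D %*% t(W[[l]])) * masks[[l - 1L]] * (A[[l]] > 0)
        }
        t_eff <- t + 1L
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
        vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t_eff)) /
          (sqrt(vW[[l]] / (1 - b2^t_eff)) + eps)
        B[[l]] <- B[[l]] - lr * (mB[[l]] / (1 - b1^t_eff)) /
          (sqrt(vB[[l]] / (1 - b2^t_eff)) + eps)
      }
      t <- t + 1L
    }
    if (prev_loss - ep_loss < 1e-5 * max(abs(prev_loss), 1)) {
      stall <- stall + 1L
      if (stall >= 20L) break  # training plateau
    } else stall <- 0L
    prev_loss <- ep_loss
  }
  list(W = W, B = B, sizes = sizes)
}

.mlp_predict_prob <- function(model, X) {
  A <- X
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- A %*% model$W[[l]] + matrix(model$B[[l]], nrow(A),
                                     ncol(model$W[[l]]), byrow = TRUE)
    A <- if (l < L) pmax(Z, 0) else {
      Zs <- Z - apply(Z, 1L, max)
      exp(Zs) / rowSums(exp(Zs))
    }
  }
  A
}

# --- unified training front-end --------------------------------------------

#' Train a severity classifier
#'
#' Standardizes features internally (statistics stored with the model) and
#' fits the classifier described by `spec`. Probability outputs always sum
#' to 1 per subject; for the SVM they are a softmax over the one-vs-rest
#' decision values (documented convention — margins are not calibrated
#' probabilities).
#'
#' @param spec a [classifier_spec()].
#' @param X subjects x features numeric matrix (finite values).
#' @param y class labels (factor or coercible; >= 2 classes present).
#' @param seed integer seed controlling any stochastic training.
#' @return an `sdb_classifier` with [predict()] support
#'   (`type = "class"` or `"prob"`).
#' @export
train_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("train_classifier: non-finite inputs")
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("train_classifier: need >= 2 classes")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- scale(X, mu, sdev)
  lev <- levels(y)
  model <- switch(spec$kind,
    logistic = {
      set.seed(seed)
      glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                     lambda = c(10, 1, 0.1, spec$lambda))
    },
    svm = lapply(lev, function(cl)
      .svm_linear_fit(Xs, ifelse(y == cl, 1, -1), spec$cost)),
    mlp = .mlp_fit(Xs, as.integer(y), nlevels(y), spec$hidden, spec$dropout,
                   spec$epochs, spec$batch, spec$lr, seed))
  structure(list(spec = spec, model = model, mu = mu, sd = sdev,
                 levels = lev, seed = seed),
            class = "sdb_classifier")
}

#' @param object an `sdb_classifier`.
#' @param newdata subjects x features matrix.
#' @param type `"class"` for labels, `"prob"` for a probability matrix.
#' @param ... unused.
#' @rdname train_classifier
#' @export
predict.sdb_classifier <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  X <- scale(as.matrix(newdata), object$mu, object$sd)
  prob <- switch(object$spec$kind,
    logistic = {
      pr <- predict(object$model, X, s = object$spec$lambda,
                    type = "response")
      matrix(pr[, , 1L], nrow(X), dimnames = list(NULL, dimnames(pr)[[2L]]))
    },
    svm = {
      dec <- vapply(object$model, function(m)
        as.numeric(X %*% m$w + m$b), numeric(nrow(X)))
      dec <- matrix(dec, nrow(X))
      e <- exp(dec - apply(dec, 1L, max))
      e / rowSums(e)
    },
    mlp = .mlp_predict_prob(object$model, X))
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

# --- cross-validation -------------------------------------------------------

.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated evaluation
#'
#' Stratified k-fold cross-validation (disjoint 9:1 train/test split per
#' fold at k = 10). Features are standardized inside [train_classifier()]
#' using training-fold statistics only. Discriminator selection can either
#' be fixed upfront (`feature_subset`, mirroring a once-on-all-data
#' procedure) or refit inside every training fold
#' (`refit_selection = TRUE`, the leakage-free mode); the two modes answer
#' different questions and both are exposed.
#'
#' @param table subjects x features matrix/data.frame.
#' @param labels class labels (factor).
#' @param spec a [classifier_spec()].
#' @param n_folds number of folds (default 10); must not exceed the
#'   smallest class count.
#' @param seed integer seed (folds, classifier randomness).
#' @param feature_subset character vector of columns to use (default all).
#' @param refit_selection refit [select_discriminators()] +
#'   [assemble_biomarker()] inside each training fold; qTM columns (if
#'   present) are always retained alongside the refit biomarker.
#' @param selection_alpha alpha for refit selection (default 0.05).
#' @param fold_assignment optional integer vector of precomputed fold ids
#'   (1..k) per subject, overriding the internal stratified assignment.
#' @return an `evaluation_report`: list with `confusion`, `accuracy`,
#'   `per_class` (sensitivity/specificity/AUC), `macro_auc`, `folds`,
#'   `seed`, `predicted`, `prob`.
#' @export
crossval_evaluate <- function(table, labels, spec = classifier_spec("logistic"),
                              n_folds = 10L, seed = 1L, feature_subset = NULL,
                              refit_selection = FALSE, selection_alpha = 0.05,
                              fold_assignment = NULL) {
  X <- as.matrix(table)
  y <- droplevels(factor(labels))
  if (is.null(fold_assignment) && min(table(y)) < n_folds)
    stop("crossval_evaluate: n_folds exceeds smallest class count")
  fold <- fold_assignment %||% .stratified_folds(y, n_folds, seed)
  if (length(fold) != length(y))
    stop("crossval_evaluate: fold assignment length mismatch")
  n_folds <- max(fold)
  for (f in seq_len(n_folds))
    if (nlevels(droplevels(y[fold != f])) < nlevels(y))
      stop("crossval_evaluate: class absent from training fold ", f)
  pred <- factor(rep(levels(y)[1L], length(y)), levels = levels(y))
  prob <- matrix(NA_real_, length(y), nlevels(y),
                 dimnames = list(NULL, levels(y)))
  if (!is.null(feature_subset)) {
    missing_cols <- setdiff(feature_subset, colnames(X))
    if (length(missing_cols))
      stop("crossval_evaluate: unknown features: ",
           paste(utils::head(missing_cols, 3L), collapse = ", "))
  }
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    cols <- feature_subset %||% colnames(X)
    if (refit_selection) {
      ds <- select_discriminators(X[tr, , drop = FALSE], y[tr],
                                  alpha = selection_alpha)
      bm <- suppressWarnings(assemble_biomarker(ds))
      qtm_cols <- grep("^qtm_", colnames(X), value = TRUE)
      cols <- unique(c(bm, qtm_cols))
      if (length(cols) == 0L) cols <- colnames(X)
    }
    mdl <- train_classifier(spec, X[tr, cols, drop = FALSE], y[tr],
                            seed = seed + f)
    prob[te, ] <- predict(mdl, X[te, cols, drop = FALSE], type = "prob")
    pred[te] <- predict(mdl, X[te, cols, drop = FALSE], type = "class")
  }
  rep <- compute_metrics(table(true = y, predicted = pred), prob, y)
  rep$folds <- fold
  rep$seed <- seed
  rep$predicted <- pred
  rep$prob <- prob
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.3f, macro AUC %s\n",
              x$accuracy,
              if (is.na(x$macro_auc)) "NA" else sprintf("%.3f", x$macro_auc)))
  print(x$confusion)
  invisible(x)
}

#' Classification metrics from a confusion matrix and scores
#'
#' One-vs-rest sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` per
#' class; ROC area by the rank (Mann-Whitney) statistic on the class'
#' probability scores; macro averages across classes. A class with zero
#' positives reports `NA` (missing), never 0.
#'
#' @param confusion square contingency table, true x predicted.
#' @param scores subjects x classes probability matrix (optional; AUC is
#'   `NA` without it).
#' @param labels true labels aligned with `scores` rows.
#' @return list with `confusion`, `accuracy`, `per_class` data.frame
#'   (`sensitivity`, `specificity`, `auc`), `macro_auc`.
#' @export
compute_metrics <- function(confusion, scores = NULL, labels = NULL) {
  cm <- unclass(as.matrix(confusion))   # plain matrix, serializable
  names(dimnames(cm)) <- NULL
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  classes <- rownames(cm)
  per <- data.frame(class = classes, sensitivity = NA_real_,
                    specificity = NA_real_, auc = NA_real_)
  for (i in seq_along(classes)) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp; tn <- n - tp - fn - fp
    per$sensitivity[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per$specificity[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    if (!is.null(scores) && !is.null(labels)) {
      pos <- labels == classes[i]
      if (any(pos) && any(!pos)) {
        r <- rank(scores[, classes[i]])
        np <- sum(pos); nn <- sum(!pos)
        per$auc[i] <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
      }
    }
  }
  list(confusion = cm, accuracy = acc, per_class = per,
       macro_auc = if (all(is.na(per$auc))) NA_real_ else
         mean(per$auc, na.rm = TRUE))
}
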