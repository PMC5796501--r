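# Severity-group discriminator selection and the acoustic biomarker.
#
# A feature is a discriminator for group G when, after passing a one-way
# ANOVA screen across the four severity groups, its Tukey HSD p-values are
# below alpha for all three pairs (G vs each other group). The acoustic
# biomarker is the ordered, deduplicated union of the four groups'
# discriminator sets. No multiple-testing correction is applied across
# features by default, reproducing the field's usual per-feature alpha;
# a Benjamini-Hochberg option is available.

#' One-way ANOVA screen across severity groups
#'
#' Classical fixed-effects one-way ANOVA, vectorised across feature columns.
#' Convention for degenerate columns: zero variance both within and between
#' groups gives `F = 0, p = 1`; zero within- but positive between-group
#' variance gives `F = Inf, p = 0` (flagged via the returned data).
#'
#' @param table numeric matrix or data.frame, subjects x features.
#' @param groups factor/character of group labels, one per subject; at least
#'   two groups with two subjects each.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return data.frame with `feature`, `F`, `p`, `pass`.
#' @export
anova_screen <- function(table, groups, alpha = 0.05) {
  X <- as.matrix(table)
  groups <- factor(groups)
  n <- nrow(X); k <- nlevels(groups)
  if (k < 2L) stop("anova_screen: need >= 2 groups")
  if (any(tabulate(groups) < 2L)) stop("anova_screen: need >= 2 subjects per group")
  G <- stats::model.matrix(~ groups - 1L)           # n x k indicator
  ng <- colSums(G)
  gm <- crossprod(G, X) / ng                         # k x p group means
  grand <- colMeans(X)
  ssb <- colSums(ng * (gm - rep(grand, each = k))^2)
  sst <- colSums(X^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (k - 1L)) / (ssw / (n - k))
  p <- stats::pf(Fv, k - 1L, n - k, lower.tail = FALSE)
  degen_all <- ssb < 1e-24 & ssw < 1e-24
  Fv[degen_all] <- 0; p[degen_all] <- 1
  sep <- ssw < 1e-24 & ssb >= 1e-24
  Fv[sep] <- Inf; p[sep] <- 0
  data.frame(feature = colnames(X) %||% paste0("V", seq_len(ncol(X))),
             F = Fv, p = p, pass = p < alpha, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tukey HSD pairwise p-values for one feature
#'
#' Tukey-Kramer studentized-range test on all group pairs, using the pooled
#' within-group variance; unequal group sizes are handled by the Kramer
#' adjustment. When the pooled variance is exactly zero the test is
#' degenerate: pairs with equal means report p = 1 and pairs with unequal
#' means p = 0, and the result carries attribute `degenerate = TRUE`.
#'
#' @param values numeric vector (one feature across subjects).
#' @param groups factor/character of group labels.
#' @param alpha retained for interface symmetry; not used in the p-values.
#' @return named numeric vector of pairwise p-values (`"A-B"` names), with
#'   attribute `means` (group means).
#' @export
tukey_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("tukey_pairwise: need >= 2 groups")
  ng <- tabulate(groups)
  if (any(ng < 2L)) stop("tukey_pairwise: need >= 2 subjects per group")
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  df <- n - k
  mse <- ssw / df
  pairs <- utils::combn(levels(groups), 2L)
  pnames <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  degenerate <- mse < 1e-24
  p <- vapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    dmean <- abs(gm[i1] - gm[i2])
    if (degenerate) return(if (dmean < 1e-12) 1 else 0)
    se <- sqrt(mse / 2 * (1 / ng[match(i1, levels(groups))] +
                            1 / ng[match(i2, levels(groups))]))
    stats::ptukey(dmean / se, nmeans = k, df = df, lower.tail = FALSE)
  }, numeric(1))
  out <- stats::setNames(p, pnames)
  attr(out, "means") <- gm
  attr(out, "degenerate") <- degenerate
  out
}

#' Select severity-group discriminators
#'
#' Features passing the ANOVA screen are submitted to Tukey HSD; feature `f`
#' enters group `G`'s discriminator set when its adjusted p-value is below
#' `alpha` for every pair `(G, other)`. A feature may appear in several
#' groups' sets, and sets may be empty.
#'
#' @param table subjects x features matrix/data.frame.
#' @param groups group labels (expects the four severity groups).
#' @param alpha per-test significance level (default 0.05).
#' @param require_anova screen by ANOVA before Tukey testing (default
#'   `TRUE`).
#' @param fdr apply Benjamini-Hochberg across features within the ANOVA
#'   screen (default `FALSE`, mirroring the uncorrected convention).
#' @return object of class `discriminator_sets`: list with `sets` (named
#'   list of feature-name vectors per group), `anova` (screen table) and
#'   `tukey` (matrix of pairwise p-values, features x pairs).
#' @export
select_discriminators <- function(table, groups, alpha = 0.05,
                                  require_anova = TRUE, fdr = FALSE) {
  X <- as.matrix(table)
  groups <- factor(groups)
  glev <- levels(groups)
  scr <- anova_screen(X, groups, alpha)
  pscr <- if (fdr) stats::p.adjust(scr$p, "BH") else scr$p
  tested <- if (require_anova) which(pscr < alpha) else seq_len(ncol(X))
  pairs <- utils::combn(glev, 2L)
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  tuk <- matrix(NA_real_, ncol(X), length(pair_names),
                dimnames = list(colnames(X), pair_names))
  for (j in tested) tuk[j, ] <- tukey_pairwise(X[, j], groups)
  sets <- stats::setNames(vector("list", length(glev)), glev)
  for (g in glev) {
    others <- setdiff(glev, g)
    cols <- vapply(others, function(o)
      which(pairs[1L, ] %in% c(g, o) & pairs[2L, ] %in% c(g, o)),
      integer(1))
    ok <- tested[apply(tuk[tested, cols, drop = FALSE] < alpha, 1L,
                       function(r) all(!is.na(r)) && all(r))]
    sets[[g]] <- colnames(X)[ok]
  }
  structure(list(sets = sets, anova = scr, tukey = tuk, alpha = alpha),
            class = "discriminator_sets")
}

#' @export
print.discriminator_sets <- function(x, ...) {
  cat("<discriminator_sets> alpha =", x$alpha, "\n")
  for (g in names(x$sets))
    cat(sprintf("  %-9s %d feature(s)\n", g, length(x$sets[[g]])))
  invisible(x)
}

#' Assemble the acoustic biomarker
#'
#' Stable-order deduplicated union of all groups' discriminator sets. An
#' empty union raises a warning (downstream classification then falls back
#' to all features).
#'
#' @param sets a `discriminator_sets` object, or a plain named list of
#'   feature-name vectors.
#' @return character vector of biomarker feature names.
#' @export
assemble_biomarker <- function(sets) {
  if (inherits(sets, "discriminator_sets")) sets <- sets$sets
  u <- unique(unlist(sets, use.names = FALSE))
  if (length(u) == 0L)
    warning("assemble_biomarker: empty union; no discriminating features")
  u
}

#' Rank features by linear-SVM weights (recursive feature elimination)
#'
#' Features are standardized, a linear one-vs-rest SVM is fitted, and
#' features are eliminated from the bottom of the summed-squared-weight
#' ranking (10% of the surviving set per round, at least one) until none
#' remain; elimination order, reversed, is the ranking. Duplicated columns
#' receive identical weights and are eliminated in column order (the
#' documented tie-break).
#'
#' @param table subjects x features matrix/data.frame.
#' @param labels class labels (>= 2 classes).
#' @param top_k how many leading features to return in `top`; capped at the
#'   number of features with a warning.
#' @param cost SVM cost parameter C (default 1).
#' @return list with `ranking` (all features, best first) and `top`.
#' @export
svm_rank_features <- function(table, labels, top_k = 50L, cost = 1) {
  X <- as.matrix(table)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("svm_rank_features: need >= 2 classes")
  p <- ncol(X)
  if (top_k > p) {
    warning("svm_rank_features: top_k exceeds feature count; returning all")
    top_k <- p
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- scale(X, mu, sdev)
  alive <- seq_len(p)
  eliminated <- integer(0)
  while (length(alive) > 0L) {
    W <- .svm_ovr_weights(Xs[, alive, drop = FALSE], labels, cost)
    score <- colSums(W^2)
    n_drop <- max(1L, floor(0.1 * length(alive)))
    # ties broken by column order: order() is stable on the index
    drop_local <- order(score)[seq_len(n_drop)]
    eliminated <- c(eliminated, alive[sort(drop_local)])
    alive <- alive[-sort(drop_local)]
  }
  ranking <- colnames(X)[rev(eliminated)]
  list(ranking = ranking, top = ranking[seq_len(top_k)])
}

# one-vs-rest linear SVM weight matrix (n_classes x p), no intercept column
.svm_ovr_weights <- function(X, labels, cost = 1) {
  lev <- levels(labels)
  W <- matrix(0, length(lev), ncol(X))
  for (i in seq_along(lev)) {
    y <- ifelse(labels == lev[i], 1, -1)
    fit <- .svm_linear_fit(X, y, cost)
    W[i, ] <- fit$w
  }
  W
}

# --- fixture: published discriminator table --------------------------------

#' Load the published discriminator-table fixture
#'
#' A machine-readable transcription of the reported severity-group
#' discriminators (62 normal, 7 moderate, 63 severe, 132 in total), with
#' index ranges expanded. Used for schema checks and entry counting; the
#' feature identities themselves are cohort-specific and are not an
#' evaluation target.
#'
#' @return data.frame with columns `group`, `stat` (mean/sd/min),
#'   `derivative` (0/1), `feature` (canonical schema token).
#' @export
load_discriminator_fixture <- function() {
  path <- system.file("extdata", "published_discriminators.csv",
                      package = "sdbscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Map fixture rows to subject-feature-vector names
#'
#' @param fixture data.frame as returned by [load_discriminator_fixture()].
#' @return character vector of schema names (`<feature>[_d1]_<stat>`).
#' @export
fixture_feature_names <- function(fixture = load_discriminator_fixture()) {
  paste0(fixture$feature, ifelse(fixture$derivative == 1L, "_d1", ""),
         "_", fixture$stat)
}
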