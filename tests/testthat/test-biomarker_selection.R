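# ANOVA screen, Tukey HSD, discriminator sets, biomarker, SVM ranking.

test_that("anova_screen handles identical, separated and degenerate groups", {
  g2 <- rep(c("a", "b"), each = 3)
  out <- anova_screen(cbind(f = c(1, 2, 3, 1, 2, 3)), g2)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)

  set.seed(2)
  sep <- c(rep(0, 4), rep(10, 4)) + stats::rnorm(8, sd = 1e-3)
  out2 <- anova_screen(cbind(f = sep), rep(c("a", "b"), each = 4))
  expect_lt(out2$p, 1e-6)

  # all-constant column: p = 1 by convention; constant-within/differing
  # -between: F = Inf, p = 0
  X <- cbind(flat = rep(2, 8), split = rep(c(0, 1), each = 4))
  out3 <- anova_screen(X, rep(c("a", "b"), each = 4))
  expect_equal(out3$p, c(1, 0))
  expect_equal(out3$F[2], Inf)
})

test_that("anova_screen agrees with the lm/anova reference route", {
  set.seed(14)
  tab <- make_feature_table(10, 12, seed = 14)
  mine <- anova_screen(tab$X, tab$groups)
  for (j in seq_len(ncol(tab$X))) {
    ref <- stats::anova(stats::lm(tab$X[, j] ~ tab$groups))
    expect_equal(mine$F[j], ref$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$p[j], ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("tukey_pairwise matches the reference implementation", {
  # identical groups: p ~ 1
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b", "c", "d"), each = 3)
  expect_true(all(tukey_pairwise(v, g) > 0.999))

  # one group shifted far out; the three null groups share identical
  # samples, so their pairwise mean differences are exactly zero
  set.seed(4)
  base_draw <- stats::rnorm(10)
  v2 <- rep(base_draw, 4)
  g2 <- rep(c("a", "b", "c", "d"), each = 10)
  v2[g2 == "c"] <- v2[g2 == "c"] + 10
  p2 <- tukey_pairwise(v2, g2)
  involved <- grepl("c", names(p2))
  expect_true(all(p2[involved] < 1e-4))
  expect_true(all(p2[!involved] > 0.9))

  # agreement with stats::TukeyHSD on random unbalanced datasets
  set.seed(90)
  for (i in 1:25) {
    sizes <- sample(5:12, 4, replace = TRUE)
    gg <- factor(rep(letters[1:4], sizes))
    vv <- stats::rnorm(sum(sizes)) + rep(stats::rnorm(4), sizes)
    mine <- tukey_pairwise(vv, gg)
    ref <- stats::TukeyHSD(stats::aov(vv ~ gg))$gg
    ref_p <- ref[, "p adj"]
    names(ref_p) <- rownames(ref)
    # stats orders pairs as "b-a"; flip to match
    lookup <- vapply(names(mine), function(nm) {
      parts <- strsplit(nm, "-")[[1]]
      ref_p[[paste(parts[2], parts[1], sep = "-")]]
    }, numeric(1))
    expect_equal(as.numeric(mine), unname(lookup), tolerance = 1e-6)
  }
})

test_that("discriminator selection recovers planted group effects", {
  tab <- make_feature_table(30, 20, seed = 6, shifts = list(
    list(feature = "f1", group = "normal", delta = 5),
    list(feature = "f2", group = "severe", delta = -5)
  ))
  # add a monotone feature separating every group from every other
  tab$X[, "f3"] <- stats::rnorm(120, mean = as.integer(tab$groups) * 8)
  ds <- select_discriminators(tab$X, tab$groups)
  expect_true("f1" %in% ds$sets$normal)
  expect_false("f1" %in% unlist(ds$sets[c("mild", "moderate", "severe")]))
  expect_true("f2" %in% ds$sets$severe)
  expect_true(all(vapply(ds$sets, function(s) "f3" %in% s, logical(1))))
  # identical-across-groups features stay out
  expect_false("f10" %in% unlist(ds$sets))

  # monotone affine transforms do not change membership
  tab2 <- tab
  tab2$X[, "f1"] <- 100 - 7 * tab2$X[, "f1"]
  ds2 <- select_discriminators(tab2$X, tab2$groups)
  expect_true("f1" %in% ds2$sets$normal)
  expect_equal(ds$tukey["f1", ], ds2$tukey["f1", ], tolerance = 1e-9)
})

test_that("biomarker union is a stable deduplicated union", {
  sets <- list(normal = c("A", "B"), mild = character(0),
               moderate = c("B", "C"), severe = character(0))
  expect_equal(assemble_biomarker(sets), c("A", "B", "C"))
  disjoint <- list(a = c("x", "y"), b = character(0),
                   c = c("p", "q", "r"), d = character(0))
  expect_length(assemble_biomarker(disjoint), 5L)
  expect_warning(empty <- assemble_biomarker(list(a = character(0))), "empty")
  expect_length(empty, 0L)
})

test_that("published fixture expands to the reported counts", {
  fix <- load_discriminator_fixture()
  counts <- table(fix$group)
  expect_equal(unname(counts[["normal"]]), 62L)
  expect_equal(unname(counts[["moderate"]]), 7L)
  expect_equal(unname(counts[["severe"]]), 63L)
  expect_equal(nrow(fix), 132L)
  expect_false("mild" %in% fix$group)   # mild set is empty
  expect_equal(anyDuplicated(fix), 0L)
})

test_that("null data yields discriminator sets far below alpha", {
  # requiring all three Tukey pairs simultaneously makes per-group
  # false discovery much rarer than alpha
  set.seed(77)
  hits <- 0L; total <- 0L
  for (i in 1:5) {
    tab <- make_feature_table(15, 40, seed = 700 + i)
    ds <- select_discriminators(tab$X, tab$groups)
    hits <- hits + length(unique(unlist(ds$sets)))
    total <- total + ncol(tab$X)
  }
  expect_lt(hits / total, 0.05 / 2)
})

test_that("SVM ranking surfaces informative features", {
  set.seed(19)
  wins <- 0L
  for (i in 1:20) {
    X <- matrix(stats::rnorm(60 * 22), 60, 22,
                dimnames = list(NULL, paste0("f", 1:22)))
    y <- factor(rep(c("lo", "hi"), each = 30))
    X[y == "hi", 1] <- X[y == "hi", 1] + 4
    X[y == "hi", 2] <- X[y == "hi", 2] - 4
    rk <- svm_rank_features(X, y, top_k = 2)
    if (setequal(rk$top, c("f1", "f2"))) wins <- wins + 1L
  }
  expect_gte(wins, 18L)

  # top_k = all -> identity subset; oversize top_k warns
  X <- matrix(stats::rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("a", "b"), each = 20))
  rk2 <- svm_rank_features(X, y, top_k = 5)
  expect_setequal(rk2$top, colnames(X))
  expect_warning(svm_rank_features(X, y, top_k = 9), "exceeds")

  # duplicated column: identical weights, adjacent ranks by column order
  Xd <- cbind(X, f1dup = X[, "f1"])
  Xd[y == "b", c("f1", "f1dup")] <- Xd[y == "b", c("f1", "f1dup")] + 5
  rkd <- svm_rank_features(Xd, y, top_k = 2)
  expect_setequal(rkd$top, c("f1", "f1dup"))
})
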