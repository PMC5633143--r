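test_that("NIPALS PLS matches the Krylov-subspace closed form", {
  set.seed(42)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- c(0, 1, 0, 1, 1, 0)
  for (A in 1:3) {
    m <- fit_pls(X, y, A)
    b <- krylov_pls1_coef(scale(X), y - mean(y), A)
    expect_lt(max(abs(coef(m) - b)), 1e-8)
  }
  # training reconstruction: yhat from T and q equals the predict() path
  m2 <- fit_pls(X, y, 2)
  expect_equal(predict(m2, X),
               as.vector(m2$y_mean + m2$T %*% m2$q), tolerance = 1e-10)
  # score orthogonality and unit-norm weights
  G <- crossprod(m2$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_equal(unname(colSums(m2$W^2)), rep(1, 2), tolerance = 1e-12)
  expect_gte(m2$R2Y, 0); expect_lte(m2$R2Y, 1)
})

test_that("PLS handles perfect predictors and the A = 0 edge", {
  set.seed(7)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- rep_len(0:1, 10)
  yc <- y - mean(y)
  # other columns orthogonalized against y, so the lone predictor carries it
  for (j in c(1, 3, 4)) X[, j] <- residuals(lm(X[, j] ~ yc))
  X[, 2] <- y * 2 + 1  # exactly proportional to the coded response
  m <- fit_pls(X, y, 1)
  expect_equal(m$R2Y, 1, tolerance = 1e-10)
  expect_equal(which.max(abs(m$W[, 1])), 2L, ignore_attr = TRUE)
  m0 <- fit_pls(X, y, 0)
  expect_equal(predict(m0, X), rep(mean(y), 10))
})

test_that("PLS predictions agree with mixOmics on a shared fixture", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("V", 1:5)))
  y <- rep(c(0, 1), 6)
  mo <- mixOmics::pls(X, y, ncomp = 2, scale = TRUE, mode = "regression")
  pr <- predict(mo, X)$predict[, , 2]
  expect_lt(max(abs(pr - predict(fit_pls(X, y, 2), X))), 1e-8)
})

test_that("fold assignment is balanced, round-robin by default, stratified on request", {
  f <- assign_folds(20, 7)
  expect_equal(unname(sort(table(f), decreasing = TRUE)),
               c(3L, 3L, 3L, 3L, 3L, 3L, 2L), ignore_attr = TRUE)
  expect_equal(assign_folds(14, 7), rep(1:7, 2))
  labs <- rep(c("a", "b"), c(11, 9))
  fs <- assign_folds(20, 7, scheme = "stratified", labels = labs, seed = 3)
  tab <- table(fs, labs)
  expect_true(all(abs(tab[, "a"] / rowSums(tab) - 11 / 20) * rowSums(tab) <= 1))
  expect_error(assign_folds(5, 7))
})

test_that("cross-validation assembles out-of-fold predictions without leakage", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("V", 1:6)))
  y <- rep(0:1, each = 10)
  folds <- assign_folds(20, 7)
  cv <- cross_validate(X, y, 2, folds)
  expect_length(cv$ypredcv, 20)
  # predictions invariant to row order given fixed fold labels
  perm <- sample(20)
  cv2 <- cross_validate(X[perm, ], y[perm], 2, folds[perm])
  expect_equal(cv2$ypredcv, cv$ypredcv[perm], tolerance = 1e-10)
  # strong separation yields high Q2
  Xs <- X; Xs[, 1] <- y * 2 + rnorm(20, sd = 0.3)
  expect_gt(cross_validate(Xs, y, 2, folds)$Q2, 0.5)
  # null relation: Q2 non-positive in expectation
  set.seed(19)
  q2 <- replicate(60, {
    Xn <- matrix(rnorm(20 * 6), 20, 6)
    colnames(Xn) <- paste0("V", 1:6)
    cross_validate(Xn, sample(y), 2, folds)$Q2
  })
  expect_lt(mean(q2), 0)
})

test_that("VIP normalization and fixtures match the direct formula", {
  set.seed(23)
  # sum of squared VIP equals p on every fitted model
  for (r in 1:5) {
    n <- sample(8:20, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- rep_len(0:1, n)
    m <- fit_pls(X, y, min(3, p, n - 1))
    expect_equal(sum(vip(m)^2), p, tolerance = 1e-8)
  }
  # p = 1 forces VIP = 1
  X1 <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "only"))
  expect_equal(unname(vip(fit_pls(X1, rep_len(0:1, 10), 1))), 1, tolerance = 1e-12)
  # direct evaluation of the formula on a 4-variable, 2-component fixture
  X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- rep_len(c(0, 1), 10)
  m <- fit_pls(X, y, 2)
  direct <- sqrt(4 * as.vector(m$W^2 %*% m$SSa) / sum(m$SSa))
  expect_equal(unname(vip(m)), direct, tolerance = 1e-12)
})

test_that("jackknife CIs equal the hand-computed form on stored submodels", {
  set.seed(31)
  X <- matrix(rnorm(21 * 5), 21, 5, dimnames = list(NULL, paste0("V", 1:5)))
  X[, 1] <- X[, 1] + rep(c(0, 1.5), c(10, 11))
  y <- rep(c(0, 1), c(10, 11))
  folds <- assign_folds(21, 7)
  jk <- jackknife_vip_ci(X, y, 2, folds)
  subs <- attr(jk, "submodels")
  k <- nrow(subs)
  se <- sqrt(((k - 1) / k) * colSums(sweep(subs, 2, colMeans(subs))^2))
  full <- vip(fit_pls(X, y, 2))
  expect_equal(jk$se, unname(se), tolerance = 1e-12)
  expect_equal(jk$lower, unname(full - qt(0.975, k - 1) * se), tolerance = 1e-12)
  expect_true(all(jk$lower <= jk$vip & jk$vip <= jk$upper))
  # duplicated columns get identical VIP and CI
  Xd <- cbind(X, V1copy = X[, 1])
  jkd <- jackknife_vip_ci(Xd, y, 2, folds)
  expect_equal(jkd[jkd$variable == "V1", -1], jkd[jkd$variable == "V1copy", -1],
               ignore_attr = TRUE, tolerance = 1e-10)
  # a noiseless, perfectly determined response: SE is exactly zero for p = 1
  # (VIP identically 1) and CI width is small once fold-to-fold scaling
  # variation fades (n = 140)
  X1 <- matrix(rnorm(21), 21, 1, dimnames = list(NULL, "only"))
  jk1 <- jackknife_vip_ci(X1, as.vector(2 * X1[, 1]), 1, folds)
  expect_equal(jk1$se, 0)
  Xp <- matrix(rnorm(140 * 3), 140, 3, dimnames = list(NULL, paste0("V", 1:3)))
  yp <- as.vector(Xp %*% c(1, 0.5, -0.25))
  jkp <- jackknife_vip_ci(Xp, yp, 2, assign_folds(140, 7))
  expect_lt(max(jkp$upper - jkp$lower), 1)
  expect_true(all(jkp$lower > 0))
  # and narrower than under a heavily noise-corrupted response
  jkn <- jackknife_vip_ci(Xp, yp + rnorm(140, sd = 4), 2, assign_folds(140, 7))
  expect_lt(max(jkp$upper - jkp$lower), max(jkn$upper - jkn$lower))
})

test_that("iterative VIP selection terminates, is idempotent and guards degenerate input", {
  set.seed(55)
  X <- cbind(matrix(rnorm(20 * 2, rep(c(0, 2), each = 10)), 20, 2),
             matrix(rnorm(20 * 8), 20, 8))
  colnames(X) <- c("inf1", "inf2", paste0("null", 1:8))
  y <- rep(0:1, each = 10)
  sel <- suppressWarnings(select_variables(X, y))
  expect_lte(sel$iterations, 25)
  expect_true(all(c("inf1", "inf2") %in% sel$variables) || !is.null(sel$guard))
  if (is.null(sel$guard)) {
    expect_true(all(sel$vip$vip >= 0.8 & sel$vip$lower > 0))
  }
  # strictly shrinking retained sets
  sizes <- vapply(sel$trace, function(it) length(it$retained), numeric(1))
  expect_true(all(diff(c(sizes, length(sel$variables))) < 0))
  # idempotence: rerunning on the final set changes nothing
  if (is.null(sel$guard) && length(sel$variables) >= 3) {
    sel2 <- suppressWarnings(select_variables(X[, sel$variables, drop = FALSE], y))
    if (is.null(sel2$guard)) {
      expect_identical(sel2$variables, sel$variables)
      expect_equal(sel2$iterations, 0)
    }
  }
  # all-null input fires a guard and keeps at least two variables
  Xn <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("V", 1:10)))
  sn <- suppressWarnings(select_variables(Xn, y))
  expect_false(is.null(sn$guard))
  expect_gte(length(sn$variables), 2)
})

test_that("component choice caps at one for univariate or pure-noise problems", {
  set.seed(61)
  X1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "only"))
  y <- rep(0:1, 10)
  expect_equal(choose_components(X1, y), 1)
  a_null <- replicate(20, {
    Xn <- matrix(rnorm(20 * 5), 20, 5)
    colnames(Xn) <- paste0("V", 1:5)
    choose_components(Xn, sample(y))
  })
  expect_gte(mean(a_null == 1), 0.8)
  # two informative directions masked by y-orthogonal shared variance need a
  # second component
  a_two <- replicate(40, {
    n <- 24
    z1 <- rnorm(n); z2 <- rnorm(n); f <- rnorm(n); g <- rnorm(n)
    Xo <- cbind(z1 + 2 * f, z1 - 2 * f, z2 + 2 * g, z2 - 2 * g) +
      matrix(rnorm(n * 4, sd = 0.2), n, 4)
    colnames(Xo) <- paste0("V", 1:4)
    choose_components(Xo, as.numeric(z1 + z2 > 0))
  })
  expect_gte(mean(a_two >= 2), 0.8)
})

test_that("ROC from cross-validated predictions: trapezoid, ties and cutoffs", {
  r <- roc_from_cv(c(1, 0.5, 0.5, 0.5), c("P", "P", "N", "N"), "P")
  expect_equal(r$auc, 0.75)  # two tied pairs at 0.5: half credit each
  r2 <- roc_from_cv(c(0.9, 0.8, 0.8, 0.1), c("P", "P", "N", "N"), "P")
  expect_equal(r2$auc, 0.875)
  expect_equal(r2$auc_mw, 0.875)
  expect_equal(roc_from_cv(c(1, 1, 0, 0), rep(c("P", "N"), each = 2), "P")$auc, 1)
  expect_equal(roc_from_cv(rep(0.3, 6), rep(c("P", "N"), 3), "P")$auc, 0.5)
  # monotone curve, matching Mann-Whitney on random fixtures
  set.seed(71)
  for (i in 1:5) {
    sc <- round(rnorm(30), 1)  # rounding forces ties
    lb <- sample(c("a", "b"), 30, replace = TRUE, prob = c(.4, .6))
    if (length(unique(lb)) < 2) next
    rr <- roc_from_cv(sc, lb, "b")
    expect_lt(abs(rr$auc - rr$auc_mw), 1e-10)
    expect_true(all(diff(rr$tpr) >= 0) && all(diff(rr$fpr) >= 0))
  }
  skip_if_not_installed("pROC")
  sc <- rnorm(40); lb <- rep(c("a", "b"), 20)
  expect_equal(roc_from_cv(sc, lb, "b")$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("a", "b"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  expect_error(roc_from_cv(c(1, 2), c("P", "P"), "P"), "both classes")
})
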