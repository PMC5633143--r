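#' Fit a PLS-DA model by NIPALS
#'
#' Single-response NIPALS partial least squares: the class membership is coded
#' 0/1 and mean-centered, X is autoscaled (unless `scale. = FALSE`, in which
#' case it must already be centered/scaled). Components are extracted by the
#' usual weight/score/loading updates with X and y deflation; a component
#' whose score variance is negligible truncates the model with a warning.
#'
#' @param X numeric matrix (samples x variables).
#' @param y response: numeric 0/1 vector or a two-level factor (second level
#'   coded 1).
#' @param A number of latent components (`A <= min(n - 1, p)`).
#' @param scale. autoscale X internally (default) and store the parameters
#'   for prediction.
#' @param tol threshold on relative score variance below which components are
#'   considered exhausted.
#' @return object of class `pls_model` with weights `W` (unit-norm columns),
#'   loadings `P`, scores `T`, y-loadings `q`, per-component explained
#'   y-variance `SSa`, training `R2Y`, the scaling parameters and the y mean.
#' @export
fit_pls <- function(X, y, A, scale. = TRUE, tol = 1e-12) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.character(y)) stop("y must be a 0/1 numeric vector or a factor")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, A >= 0, A <= min(n - 1, p))
  scaling <- NULL
  if (scale.) {
    scaling <- uv_scale(X)
    Xs <- scaling$scaled
  } else Xs <- X
  y_mean <- mean(y)
  yc <- y - y_mean
  ss_y <- sum(yc^2)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  SSa <- numeric(0)
  Xd <- Xs; yd <- yc
  ss_t0 <- sum(Xs^2)
  a <- 0
  while (a < A) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < tol * max(ss_t0, 1)) break
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - q_ * t_
    W <- cbind(W, w); P <- cbind(P, p_); Tm <- cbind(Tm, t_)
    q <- c(q, q_); SSa <- c(SSa, q_^2 * tt)
    a <- a + 1
  }
  if (a < A) warning(sprintf("X exhausted after %d component(s); A truncated from %d", a, A))
  vn <- colnames(X) %||% paste0("V", seq_len(p))
  rownames(W) <- rownames(P) <- vn
  structure(list(A = a, W = W, P = P, T = Tm, q = q, SSa = SSa,
                 R2Y = if (ss_y > 0) sum(SSa) / ss_y else 0,
                 y_mean = y_mean, scaling = scaling, var_names = vn,
                 n = n, p = p),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), %d x %d, R2Y = %.3f\n",
              x$A, x$n, x$p, x$R2Y))
  invisible(x)
}

#' Regression coefficients of a fitted PLS model (on the scaled X)
#'
#' @param object a `pls_model`.
#' @param ... unused.
#' @return coefficient vector such that `yhat = y_mean + Xs %*% b`.
#' @export
coef.pls_model <- function(object, ...) {
  if (object$A == 0) return(stats::setNames(rep(0, object$p), object$var_names))
  b <- object$W %*% solve(crossprod(object$P, object$W), object$q)
  stats::setNames(as.vector(b), object$var_names)
}

#' Predict class scores for new samples
#'
#' Applies the stored scaling and returns predictions on the 0/1 coding scale
#' of the training response. With `A = 0` the prediction is the training mean.
#'
#' @param object a `pls_model`.
#' @param newdata matrix of new rows (same variables as training).
#' @param ... unused.
#' @return numeric vector of predicted scores.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    newdata <- newdata[, object$var_names, drop = FALSE]
  }
  Xs <- if (!is.null(object$scaling)) uv_apply(object$scaling, newdata) else newdata
  as.vector(object$y_mean + Xs %*% coef(object))
}

#' Assign cross-validation folds
#'
#' Default scheme is the deterministic round-robin in sample order (venetian
#' blinds): sample i goes to fold `((i - 1) mod k) + 1`, so fold sizes differ
#' by at most one. The stratified alternative shuffles within each class under
#' a seed and deals classes round-robin, keeping per-fold class ratios within
#' one sample of the global ratio.
#'
#' @param n number of samples (`n >= k`).
#' @param k number of folds.
#' @param scheme `"round_robin"` or `"stratified"`.
#' @param labels class labels, required for the stratified scheme.
#' @param seed seed for the stratified shuffle.
#' @return integer fold labels of length `n`.
#' @export
assign_folds <- function(n, k = 7, scheme = c("round_robin", "stratified"),
                         labels = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= k)
  if (scheme == "round_robin") return(((seq_len(n) - 1L) %% k) + 1L)
  stopifnot(!is.null(labels), length(labels) == n)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  nxt <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- ((nxt + seq_along(idx) - 1L) %% k) + 1L
    nxt <- nxt + length(idx)
  }
  folds
}

drop_zero_variance <- function(X) {
  s <- apply(X, 2, sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    warning("dropping zero-variance column(s) in a training fold: ",
            paste(colnames(X)[bad], collapse = ", "))
    X <- X[, -bad, drop = FALSE]
  }
  X
}

#' Cross-validated predictions and Q2
#'
#' Out-of-fold predictions (Y-predcv) assembled over k folds. Scaling is
#' refit inside every training fold, so no information leaks from held-out
#' samples. Q2 = 1 - PRESS / SS_tot with SS_tot about the full-sample mean.
#'
#' @param X feature matrix (unscaled).
#' @param y 0/1 response (or two-level factor).
#' @param A number of components for every fold model.
#' @param folds integer fold labels (see [assign_folds()]).
#' @return list of class `cv_result`: `ypredcv`, `Q2`, `folds`, `A`.
#' @export
cross_validate <- function(X, y, A, folds = assign_folds(nrow(X))) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.numeric(y) - 1
  n <- nrow(X)
  stopifnot(length(folds) == n, length(y) == n)
  ypred <- numeric(n)
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    Xtr <- drop_zero_variance(X[tr, , drop = FALSE])
    m <- fit_pls(Xtr, y[tr], A = min(A, length(tr) - 1, ncol(Xtr)))
    ypred[te] <- predict(m, X[te, colnames(Xtr), drop = FALSE])
  }
  press <- sum((y - ypred)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(ypredcv = ypred, Q2 = 1 - press / ss_tot, folds = folds,
                 A = A),
            class = "cv_result")
}

#' Choose the number of PLS components by cross-validation
#'
#' Starts at one component and adds components while Q2 improves by more than
#' `gain`, up to `min(cap, n - 2, p)`. Returns at least one component.
#'
#' @param X feature matrix.
#' @param y 0/1 response.
#' @param folds fold labels.
#' @param gain minimum Q2 improvement to accept another component.
#' @param cap hard cap on components.
#' @return selected number of components.
#' @export
choose_components <- function(X, y, folds = assign_folds(nrow(X)),
                              gain = 0.01, cap = 5) {
  X <- as.matrix(X)
  amax <- max(1, min(cap, nrow(X) - 2, ncol(X)))
  best_a <- 1
  best_q2 <- cross_validate(X, y, 1, folds)$Q2
  a <- 1
  while (a < amax) {
    a <- a + 1
    q2 <- cross_validate(X, y, a, folds)$Q2
    if (q2 > best_q2 + gain) {
      best_a <- a; best_q2 <- q2
    } else break
  }
  best_a
}
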