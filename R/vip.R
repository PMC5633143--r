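#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a ), where w_a are the
#' unit-norm NIPALS weight vectors and SS_a the y-variance explained by
#' component a. The mean squared VIP over variables is exactly 1
#' (sum of VIP^2 equals p).
#'
#' @param model a fitted `pls_model` with at least one component.
#' @return named vector of VIP values.
#' @export
vip <- function(model) {
  if (model$A < 1) stop("VIP needs a model with at least one component")
  ss <- model$SSa
  if (sum(ss) <= 0) stop("no explained y-variance; VIP undefined")
  w2 <- model$W^2  # columns already unit norm
  stats::setNames(sqrt(model$p * as.vector(w2 %*% ss) / sum(ss)),
                  model$var_names)
}

#' Jackknife confidence intervals for VIP
#'
#' Recomputes the VIP vector on each leave-one-fold-out submodel and forms
#' the jackknife standard error SE_j = sqrt(((k - 1) / k) *
#' sum_i (VIP_ij - mean_i VIP_ij)^2); the confidence interval is VIP_full
#' +/- t_{1-(1-level)/2, k-1} * SE_j. A submodel that fails to fit is skipped
#' with a warning (k reduced accordingly).
#'
#' @param X feature matrix (unscaled).
#' @param y 0/1 response (or two-level factor).
#' @param A number of components.
#' @param folds integer fold labels (>= 3 folds).
#' @param level confidence level.
#' @return data frame of class `vip_result`: `variable`, `vip`, `se`,
#'   `lower`, `upper`, `above_threshold` (VIP >= 0.8), `ci_excludes_zero`;
#'   the submodel VIP matrix is kept in attribute `"submodels"`.
#' @export
jackknife_vip_ci <- function(X, y, A, folds = assign_folds(nrow(X)),
                             level = 0.95) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.numeric(y) - 1
  uf <- sort(unique(folds))
  if (length(uf) < 3) stop("jackknife needs at least 3 folds")
  full <- fit_pls(X, y, A)
  v_full <- vip(full)
  subs <- matrix(NA_real_, length(uf), ncol(X),
                 dimnames = list(paste0("fold", uf), colnames(X)))
  ok <- logical(length(uf))
  for (i in seq_along(uf)) {
    tr <- which(folds != uf[i])
    fit <- tryCatch(
      fit_pls(X[tr, , drop = FALSE], y[tr], min(A, length(tr) - 1, ncol(X))),
      error = function(e) NULL)
    if (is.null(fit) || fit$A < 1) {
      warning("jackknife submodel for fold ", uf[i], " failed; fold skipped")
      next
    }
    subs[i, ] <- vip(fit)
    ok[i] <- TRUE
  }
  k <- sum(ok)
  if (k < 3) stop("fewer than 3 usable jackknife submodels")
  vs <- subs[ok, , drop = FALSE]
  se <- sqrt(((k - 1) / k) * colSums(sweep(vs, 2, colMeans(vs))^2))
  tq <- qt(1 - (1 - level) / 2, df = k - 1)
  out <- data.frame(variable = names(v_full), vip = unname(v_full),
                    se = unname(se),
                    lower = unname(v_full - tq * se),
                    upper = unname(v_full + tq * se),
                    stringsAsFactors = FALSE)
  out$above_threshold <- out$vip >= 0.8
  out$ci_excludes_zero <- out$lower > 0
  attr(out, "submodels") <- vs
  attr(out, "k") <- k
  class(out) <- c("vip_result", "data.frame")
  out
}

#' Iterative VIP-based variable selection
#'
#' Repeats { fit PLS-DA, cross-validate, compute VIP with jackknife CI, drop
#' every variable with VIP below the threshold or a CI overlapping zero }
#' until all retained variables pass both rules, or a guard fires: fewer than
#' `min_vars` variables would remain, or `max_iter` iterations. The retained
#' set shrinks strictly while the loop runs, so termination is guaranteed.
#'
#' @param X feature matrix (unscaled).
#' @param y 0/1 response (or two-level factor).
#' @param A fixed number of components, or `NULL` to re-select by
#'   [choose_components()] at every iteration.
#' @param vip_threshold VIP retention threshold.
#' @param k number of cross-validation folds.
#' @param level jackknife confidence level.
#' @param max_iter iteration guard.
#' @param min_vars smallest admissible retained set.
#' @return list of class `selection_trace`: `variables` (final set), `model`
#'   (final fit), `cv` (final `cv_result`), `vip` (final `vip_result`),
#'   `trace` (per-iteration records), `guard` (`NULL`, or the guard reason).
#' @export
select_variables <- function(X, y, A = NULL, vip_threshold = 0.8, k = 7,
                             level = 0.95, max_iter = 25, min_vars = 2) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.factor(y)) y <- as.numeric(y) - 1
  stopifnot(ncol(X) >= 3)
  vars <- colnames(X)
  trace <- list()
  guard <- NULL
  iter <- 0
  repeat {
    Xi <- X[, vars, drop = FALSE]
    folds <- assign_folds(nrow(Xi), k)
    Ai <- A %||% choose_components(Xi, y, folds)
    cv <- cross_validate(Xi, y, Ai, folds)
    jk <- jackknife_vip_ci(Xi, y, Ai, folds, level = level)
    fail <- !(jk$vip >= vip_threshold & jk$lower > 0)
    if (!any(fail)) break
    keep <- vars[!fail]
    if (length(keep) < min_vars) {
      guard <- "dropping failing variables would leave fewer than min_vars"
      break
    }
    iter <- iter + 1
    trace[[iter]] <- list(
      iteration = iter, A = Ai, Q2 = cv$Q2, retained = vars,
      dropped = data.frame(
        variable = jk$variable[fail],
        reason = ifelse(jk$vip[fail] < vip_threshold,
                        ifelse(jk$lower[fail] <= 0,
                               "VIP < threshold and CI overlaps 0",
                               "VIP < threshold"),
                        "CI overlaps 0"),
        stringsAsFactors = FALSE))
    vars <- keep
    if (iter >= max_iter) {
      guard <- "maximum number of iterations reached"
      break
    }
  }
  Xf <- X[, vars, drop = FALSE]
  folds <- assign_folds(nrow(Xf), k)
  Af <- A %||% choose_components(Xf, y, folds)
  model <- fit_pls(Xf, y, Af)
  cv <- cross_validate(Xf, y, Af, folds)
  jk <- jackknife_vip_ci(Xf, y, Af, folds, level = level)
  structure(list(variables = vars, model = model, cv = cv, vip = jk,
                 trace = trace, guard = guard, iterations = iter),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("VIP selection: %d iteration(s), %d variable(s) retained, Q2 = %.3f\n",
              x$iterations, length(x$variables), x$cv$Q2))
  if (!is.null(x$guard)) cat("  guard:", x$guard, "\n")
  invisible(x)
}
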