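#' Percentage difference between two groups
#'
#' PD = 100 * (mean_left - mean_right) / mean_left, computed "left to right"
#' in the order the comparison is written, with the left group mean as
#' denominator.
#'
#' @param left_values,right_values numeric vectors of group observations.
#' @return percentage difference (%).
#' @export
#' @examples
#' percentage_difference(c(2, 2), c(1, 1))  # 50
percentage_difference <- function(left_values, right_values) {
  stopifnot(length(left_values) > 0, length(right_values) > 0)
  ml <- mean(left_values)
  if (ml == 0) stop("left group mean is zero; PD undefined")
  100 * (ml - mean(right_values)) / ml
}

#' Signed relative standard deviation
#'
#' RSD = 100 * sd / mean with the n-1 standard deviation; the sign follows
#' the mean, so groups with negative mean integrals report negative RSDs.
#'
#' @param values numeric vector (length >= 2).
#' @return RSD (%).
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean; RSD undefined")
  100 * sd(values) / m
}

#' Two-sample pooled-variance Student t test
#'
#' Two-sided test with the classical pooled variance (not Welch). Degenerate
#' input with zero pooled variance and equal means returns t = 0, p = 1; zero
#' pooled variance with unequal means returns t = +/-Inf, p = 0.
#'
#' @param a_values,b_values numeric vectors (each length >= 2).
#' @param alpha significance level for the flag.
#' @param welch use the Welch (unequal-variance) form instead.
#' @return list with `t`, `df`, `p`, `significant`.
#' @export
student_t <- function(a_values, b_values, alpha = 0.05, welch = FALSE) {
  na <- length(a_values); nb <- length(b_values)
  stopifnot(na >= 2, nb >= 2)
  dm <- mean(a_values) - mean(b_values)
  if (welch) {
    va <- var(a_values) / na; vb <- var(b_values) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a_values) + (nb - 1) * var(b_values)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (se == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t <- dm / se
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, significant = p < alpha)
}

#' Univariate report for one compartment
#'
#' Mirrors the study's summary-table layout: for every metabolite, the
#' percentage difference over the three ordered comparisons (BDG vs RG,
#' RG vs UDG, BDG vs UDG), the signed RSD per group, and the pooled-variance
#' Student t test p-value per comparison with a p < 0.05 significance flag.
#'
#' @param ft a `feature_table` with a `group` column.
#' @param comparisons list of ordered group pairs; defaults to the study's
#'   three.
#' @param alpha significance level.
#' @return data frame of class `univariate_table`, one row per metabolite.
#' @export
build_univariate_report <- function(ft, comparisons = diet_comparisons(),
                                    alpha = 0.05) {
  groups <- unique(unlist(comparisons))
  if (!all(groups %in% ft$group)) {
    stop("unknown group label(s): ",
         paste(setdiff(groups, ft$group), collapse = ", "))
  }
  X <- feature_matrix(ft)
  mets <- colnames(X)
  out <- data.frame(metabolite = mets, stringsAsFactors = FALSE)
  for (cmp in comparisons) {
    tag <- paste0(tolower(cmp[1]), "_", tolower(cmp[2]))
    a <- X[ft$group == cmp[1], , drop = FALSE]
    b <- X[ft$group == cmp[2], , drop = FALSE]
    pd <- p <- tt <- numeric(length(mets))
    for (j in seq_along(mets)) {
      pd[j] <- percentage_difference(a[, j], b[, j])
      res <- student_t(a[, j], b[, j], alpha = alpha)
      p[j] <- res$p; tt[j] <- res$t
    }
    out[[paste0("pd_", tag)]] <- pd
    out[[paste0("t_", tag)]] <- tt
    out[[paste0("p_", tag)]] <- p
    out[[paste0("sig_", tag)]] <- p < alpha
  }
  for (g in groups) {
    out[[paste0("rsd_", tolower(g))]] <-
      apply(X[ft$group == g, , drop = FALSE], 2, rsd)
  }
  attr(out, "compartment") <- attr(ft, "compartment")
  class(out) <- c("univariate_table", "data.frame")
  out
}

#' Write a univariate report in the printed-table layout
#'
#' Three PD columns (stars on p < 0.05) followed by three per-group RSD
#' columns, one row per metabolite.
#'
#' @param report a `univariate_table`.
#' @param path output CSV path.
#' @param digits rounding for display.
#' @return `path`, invisibly.
#' @export
write_univariate_report <- function(report, path, digits = 1) {
  star <- function(pd, sig) paste0(formatC(round(pd, digits), format = "f",
                                           digits = digits),
                                   ifelse(sig, "*", ""))
  out <- data.frame(
    Metabolite = report$metabolite,
    `PD BDG vs RG` = star(report$pd_bdg_rg, report$sig_bdg_rg),
    `PD RG vs UDG` = star(report$pd_rg_udg, report$sig_rg_udg),
    `PD BDG vs UDG` = star(report$pd_bdg_udg, report$sig_bdg_udg),
    `RSD BDG` = round(report$rsd_bdg, digits),
    `RSD RG` = round(report$rsd_rg, digits),
    `RSD UDG` = round(report$rsd_udg, digits),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
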