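#' Cohort design
#'
#' Describes a three-group dietary cohort: ordered group labels, group sizes
#' and unique animal identifiers shared across the serum, urine and tissue
#' compartments. The default mirrors the study layout: a balanced-diet group
#' (BDG, 11 pigs), a regression group (RG, 8 pigs, Western diet later replaced
#' by a balanced one) and an unbalanced Western-diet group (UDG, 9 pigs).
#'
#' @param group_names ordered character vector of group labels.
#' @param group_sizes integer vector of group sizes, same length/order as
#'   `group_names`.
#' @param animal_ids optional character vector of unique identifiers; defaults
#'   to `P01`, `P02`, ... assigned to groups in block order.
#' @return an object of class `cohort_design`: a list with `groups` (per-animal
#'   data frame), `group_names` and `group_sizes`.
#' @export
#' @examples
#' d <- cohort_design()
#' table(d$groups$group)
cohort_design <- function(group_names = c("BDG", "RG", "UDG"),
                          group_sizes = c(11L, 8L, 9L),
                          animal_ids = NULL) {
  stopifnot(length(group_names) == length(group_sizes),
            !anyDuplicated(group_names), all(group_sizes >= 1))
  group_sizes <- as.integer(group_sizes)
  n <- sum(group_sizes)
  if (is.null(animal_ids)) animal_ids <- sprintf("P%02d", seq_len(n))
  if (length(animal_ids) != n) {
    stop("sum(group_sizes) must equal the number of animal_ids")
  }
  if (anyDuplicated(animal_ids)) stop("animal_ids must be unique")
  groups <- data.frame(
    animal_id = animal_ids,
    group = factor(rep(group_names, group_sizes), levels = group_names),
    stringsAsFactors = FALSE
  )
  structure(list(groups = groups, group_names = group_names,
                 group_sizes = stats::setNames(group_sizes, group_names)),
            class = "cohort_design")
}

#' Default study design (28 animals: 11 BDG, 8 RG, 9 UDG)
#'
#' @return a `cohort_design` with deterministic animal identifiers.
#' @export
default_design <- function() cohort_design()

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort design:", sum(x$group_sizes), "animals\n")
  print(x$group_sizes)
  invisible(x)
}

#' Clinical covariate specifications
#'
#' End-of-study clinical variables with per-group Gaussian mean and standard
#' deviation: body weight, three ultrasound subcutaneous-fat depths, the serum
#' lipid panel (TG, TC, HDL-C, LDL-C), glucose and insulin. All ten variables
#' are physically nonnegative, so sampling truncates at zero.
#'
#' @return data frame with columns `variable`, `unit`, `group`, `mean`, `sd`.
#' @export
clinical_specs <- function() {
  vars <- c("body_weight", "lumbar_fat", "neck_fat", "shoulder_fat",
            "TG", "TC", "HDL_C", "LDL_C", "glucose", "insulin")
  units <- c("kg", "mm", "cm", "cm", "mmol/l", "mmol/l", "mmol/l", "mmol/l",
             "mg/dl", "ug/ml")
  # per-group end-of-study mean and sd, order BDG, RG, UDG
  m <- rbind(
    body_weight  = c(246,  245,  260),
    lumbar_fat   = c(13.6, 12,   14.6),
    neck_fat     = c(12.5, 12.4, 16),
    shoulder_fat = c(11.6, 11.4, 14.4),
    TG           = c(0.32, 0.49, 0.53),
    TC           = c(2.1,  1.9,  2.02),
    HDL_C        = c(0.75, 0.65, 0.88),
    LDL_C        = c(1.09, 1.18, 1.17),
    glucose      = c(94.6, 103.8, 102.5),
    insulin      = c(45.7, 79.4, 52.8)
  )
  s <- rbind(
    body_weight  = c(27.5, 16.5, 21),
    lumbar_fat   = c(3,    2.5,  2.5),
    neck_fat     = c(2.5,  2,    1.6),
    shoulder_fat = c(2.4,  2,    1.8),
    TG           = c(0.2,  0.21, 0.34),
    TC           = c(0.45, 0.51, 0.48),
    HDL_C        = c(0.13, 0.1,  0.34),
    LDL_C        = c(0.24, 0.2,  0.17),
    glucose      = c(13.7, 26.1, 27.4),
    insulin      = c(14.65, 52.9, 19.7)
  )
  grp <- c("BDG", "RG", "UDG")
  data.frame(
    variable = rep(vars, each = 3L),
    unit = rep(units, each = 3L),
    group = rep(grp, times = length(vars)),
    mean = as.vector(t(m)),
    sd = as.vector(t(s)),
    stringsAsFactors = FALSE
  )
}

#' Sample end-of-study clinical covariates
#'
#' Gaussian draws per (variable, group) pair, truncated at zero by rejection
#' (all packaged variables are nonnegative quantities).
#'
#' @param design a `cohort_design`.
#' @param specs specification table as returned by [clinical_specs()].
#' @param seed optional integer seed; `NULL` continues the current RNG stream.
#' @return data frame: `animal_id`, `group`, one column per clinical variable.
#' @export
sample_clinical <- function(design, specs = clinical_specs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- design$groups
  vars <- unique(specs$variable)
  out <- data.frame(animal_id = g$animal_id, group = as.character(g$group),
                    stringsAsFactors = FALSE)
  for (v in vars) {
    col <- numeric(nrow(g))
    for (grp in design$group_names) {
      row <- specs[specs$variable == v & specs$group == grp, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("missing clinical spec for variable '%s', group '%s'", v, grp))
      }
      idx <- which(g$group == grp)
      x <- rnorm(length(idx), row$mean, row$sd)
      while (any(x < 0)) {  # truncate at zero: redraw negatives
        bad <- x < 0
        x[bad] <- rnorm(sum(bad), row$mean, row$sd)
      }
      col[idx] <- x
    }
    out[[v]] <- col
  }
  out
}
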