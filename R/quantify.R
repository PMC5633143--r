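#' Integrate library windows into a feature table
#'
#' The relative level of each metabolite is the trapezoidal integral of the
#' spectrum over its library window, with no baseline subtraction inside the
#' window. Negative integrals (noise dipping below zero) are propagated.
#'
#' @param spectra a `spectrum_set`.
#' @param library a `metabolite_library` for the same compartment.
#' @return a `feature_table`: data frame with `animal_id`, `group`, then one
#'   column per metabolite; attribute `"compartment"`.
#' @export
integrate_windows <- function(spectra, library) {
  ppm <- spectra$ppm
  if (any(library$ppm_low < min(ppm) | library$ppm_high > max(ppm))) {
    stop("integration window outside the axis range")
  }
  n <- nrow(spectra$intensities)
  vals <- matrix(NA_real_, n, nrow(library),
                 dimnames = list(NULL, library$name))
  for (j in seq_len(nrow(library))) {
    idx <- which(ppm >= library$ppm_low[j] & ppm <= library$ppm_high[j])
    if (length(idx) < 2) stop("window too narrow for the axis: ", library$name[j])
    for (i in seq_len(n)) {
      vals[i, j] <- pracma::trapz(ppm[idx], spectra$intensities[i, idx])
    }
  }
  ft <- data.frame(animal_id = spectra$sample_ids,
                   group = spectra$groups %||% rep(NA_character_, n),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  attr(ft, "compartment") <- spectra$compartment
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Extract the numeric feature matrix of a feature table
#'
#' @param ft a `feature_table` (or any data frame whose non-feature columns
#'   are `animal_id` and `group`).
#' @return numeric matrix with animal ids as rownames.
#' @export
feature_matrix <- function(ft) {
  cols <- setdiff(names(ft), c("animal_id", "group"))
  m <- as.matrix(ft[, cols, drop = FALSE])
  rownames(m) <- ft$animal_id
  m
}

#' Unit-variance (autoscaling) of a feature matrix
#'
#' Mean-centers each column and divides it by its sample standard deviation
#' (n - 1 denominator), the scaling applied before every model fit so that
#' all variables enter with equal weight. The returned parameters allow the
#' identical transform to be applied to held-out rows.
#'
#' @param x numeric matrix (samples x variables).
#' @return list of class `uv_scaling`: `scaled` matrix, `center`, `scale`.
#' @export
uv_scale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  bad <- which(scl == 0 | !is.finite(scl))
  if (length(bad)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[bad] %||% bad, collapse = ", "))
  }
  scaled <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(scaled = scaled, center = ctr, scale = scl),
            class = "uv_scaling")
}

#' Apply stored unit-variance scaling parameters to new rows
#'
#' @param scaling a `uv_scaling` object.
#' @param x new matrix with the same columns.
#' @return scaled matrix.
#' @export
uv_apply <- function(scaling, x) {
  x <- as.matrix(x)
  sweep(sweep(x[, names(scaling$center), drop = FALSE], 2, scaling$center),
        2, scaling$scale, "/")
}

#' Write a feature table to CSV
#'
#' @param ft a `feature_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  write.csv(ft, path, row.names = FALSE)
  invisible(path)
}
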