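#' Spectrum set container
#'
#' A cohort of intensity vectors on one shared, strictly ascending ppm axis.
#' On-disk spectra follow the NMR display convention (descending ppm); in
#' memory the axis is always ascending.
#'
#' @param ppm strictly monotone numeric axis (stored ascending).
#' @param intensities samples x points matrix.
#' @param sample_ids character vector, one per row of `intensities`.
#' @param groups optional character vector of group labels.
#' @param compartment compartment tag.
#' @param frequency_mhz nominal spectrometer frequency.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensities, sample_ids, groups = NULL,
                         compartment = NA_character_, frequency_mhz = 600.58) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1L)
  stopifnot(length(ppm) >= 2, ncol(intensities) == length(ppm),
            nrow(intensities) == length(sample_ids))
  d <- diff(ppm)
  if (all(d < 0)) {  # descending input: co-reverse
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  } else if (!all(d > 0)) {
    stop("ppm axis must be strictly monotone")
  }
  structure(list(ppm = ppm, intensities = intensities,
                 sample_ids = as.character(sample_ids),
                 groups = if (is.null(groups)) NULL else as.character(groups),
                 compartment = compartment, frequency_mhz = frequency_mhz),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra x %d points (%.3f..%.3f ppm), compartment %s\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm),
              x$compartment))
  invisible(x)
}

#' Read a cohort of spectra from a manifest
#'
#' Loads the two-column (ppm, intensity) sample files listed in a cohort
#' manifest for one compartment. All samples must share one axis; a grid
#' differing from the first sample's by less than half the point spacing is
#' interpolated onto it, larger mismatches are an error. Descending on-disk
#' axes are reversed to the ascending in-memory convention.
#'
#' @param manifest path to a manifest JSON written by [write_cohort()] (or any
#'   conforming export).
#' @param compartment which compartment to read.
#' @return a `spectrum_set` in manifest sample order.
#' @export
read_spectra <- function(manifest, compartment = c("serum", "urine", "tissue")) {
  compartment <- match.arg(compartment)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  sec <- man$compartments[[compartment]]
  if (is.null(sec)) stop("manifest has no compartment '", compartment, "'")
  files <- file.path(base, sec$files)
  ids <- man$design$animal_ids
  ref_ppm <- NULL
  Y <- NULL
  for (i in seq_along(files)) {
    if (!file.exists(files[i])) {
      stop(sprintf("missing spectrum file for sample %s: %s", ids[i], files[i]))
    }
    tab <- read.table(files[i], header = TRUE)
    ppm <- tab[[1]]; y <- tab[[2]]
    if (all(diff(ppm) < 0)) { ppm <- rev(ppm); y <- rev(y) }
    if (any(diff(ppm) <= 0)) stop("non-monotone ppm axis in ", files[i])
    if (is.null(ref_ppm)) {
      ref_ppm <- ppm
      Y <- matrix(NA_real_, length(files), length(ppm))
    } else if (length(ppm) != length(ref_ppm) ||
               max(abs(ppm - ref_ppm)) > 0.5 * (ref_ppm[2] - ref_ppm[1])) {
      stop("ppm axis of ", files[i], " deviates beyond tolerance from the first sample")
    } else if (any(ppm != ref_ppm)) {
      y <- approx(ppm, y, xout = ref_ppm, rule = 2)$y
    }
    Y[i, ] <- y
  }
  spectrum_set(ref_ppm, Y, ids, man$design$groups, compartment,
               frequency_mhz = man$frequency_mhz %||% 600.58)
}

#' Reference spectra to the compartment anchor resonance
#'
#' Translates each spectrum by an integer number of points so that the maximum
#' intensity within the anchor search window sits at the nominal anchor
#' position (alpha-glucose 5.225 ppm for serum, TSP 0.000 ppm for urine and
#' tissue).
#'
#' @param spectra a `spectrum_set`.
#' @param compartment compartment used to pick the anchor; defaults to the
#'   set's own tag.
#' @param anchor override anchor position (ppm).
#' @param search_halfwidth half-width of the anchor search window (ppm).
#' @return the referenced `spectrum_set`, with per-sample applied shifts
#'   (points) in attribute `"shifts"`.
#' @export
reference_to_anchor <- function(spectra, compartment = spectra$compartment,
                                anchor = NULL, search_halfwidth = 0.1) {
  anchor <- anchor %||% anchor_ppm(compartment)
  ppm <- spectra$ppm
  dx <- ppm[2] - ppm[1]
  win <- which(ppm >= anchor - search_halfwidth & ppm <= anchor + search_halfwidth)
  if (length(win) < 3) stop("anchor search window lies outside the axis")
  i_nominal <- win[which.min(abs(ppm[win] - anchor))]
  shifts <- integer(nrow(spectra$intensities))
  for (i in seq_len(nrow(spectra$intensities))) {
    seg <- spectra$intensities[i, win]
    if (max(seg) == min(seg)) {
      stop("flat anchor search window for sample ", spectra$sample_ids[i])
    }
    i_max <- win[which.max(seg)]
    shifts[i] <- i_nominal - i_max
    spectra$intensities[i, ] <- shift_points(spectra$intensities[i, ], shifts[i])
  }
  attr(spectra, "shifts") <- stats::setNames(shifts, spectra$sample_ids)
  spectra
}

# Correlation-maximizing integer lag of x against target within +/- max_shift.
best_segment_lag <- function(x, target, max_shift) {
  n <- length(x)
  ext <- c(rep(x[1L], max_shift), x, rep(x[n], max_shift))
  lags <- -max_shift:max_shift
  cc <- vapply(lags, function(lag) {
    # segment shifted by `lag` points (replicated edges outside)
    sum(ext[(max_shift + 1L - lag):(max_shift + n - lag)] * target)
  }, numeric(1))
  top <- which(cc >= max(cc) - 1e-12 * max(abs(cc), 1))
  lags[top[which.min(abs(lags[top]))]]  # ties resolve to the smallest |lag|
}

#' Segment-wise integer-shift alignment (icoshift-style)
#'
#' Splits the axis into segments and rigidly shifts each segment of each
#' sample by the integer point offset that maximizes its cross-correlation
#' with the point-wise median spectrum. Vacated points are filled with the
#' segment edge value. The procedure is two-pass: the median target is
#' recomputed once from the first-pass result.
#'
#' @param spectra a `spectrum_set` with at least two samples.
#' @param segment_boundaries internal boundary positions (ppm); `NULL` treats
#'   the whole axis as a single segment. The convenience helper
#'   [library_segments()] derives boundaries from an integration library.
#' @param max_shift maximum absolute shift (points).
#' @param passes number of passes (target recomputed between passes).
#' @return list with elements `spectra` (aligned set) and `result`, a data
#'   frame of cumulative per-sample, per-segment shifts.
#' @export
segment_align <- function(spectra, segment_boundaries = NULL, max_shift = 10L,
                          passes = 2L) {
  Y <- spectra$intensities
  if (nrow(Y) < 2) stop("alignment needs at least two samples")
  ppm <- spectra$ppm
  max_shift <- as.integer(max_shift)
  bounds <- sort(segment_boundaries)
  cuts <- c(1L, vapply(bounds, function(b) which.min(abs(ppm - b)), 1L),
            length(ppm) + 1L)
  cuts <- unique(cuts)
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1] - 1L
  if (any(ends - starts + 1L < 2L * max_shift + 1L)) {
    stop("every segment must be wider than 2*max_shift + 1 points")
  }
  total <- matrix(0L, nrow(Y), length(starts))
  for (pass in seq_len(passes)) {
    target <- col_medians(Y)
    for (s in seq_along(starts)) {
      idx <- starts[s]:ends[s]
      tseg <- target[idx]
      if (max(tseg) == min(tseg)) next  # featureless target segment
      for (i in seq_len(nrow(Y))) {
        lag <- best_segment_lag(Y[i, idx], tseg, max_shift)
        if (lag != 0L) {
          Y[i, idx] <- shift_points(Y[i, idx], lag)
          total[i, s] <- total[i, s] + lag
        }
      }
    }
  }
  spectra$intensities <- Y
  res <- data.frame(
    sample_id = rep(spectra$sample_ids, times = length(starts)),
    segment = rep(seq_along(starts), each = nrow(Y)),
    ppm_low = rep(ppm[starts], each = nrow(Y)),
    ppm_high = rep(ppm[ends], each = nrow(Y)),
    shift = as.vector(total),
    stringsAsFactors = FALSE
  )
  list(spectra = spectra, result = res)
}

#' Default PQN exclusion regions
#'
#' The residual water region (4.7-5.1 ppm) and a window around the referencing
#' anchor are excluded from quotient computation; the anchor mimics an
#' internal standard whose intensity does not track dilution.
#'
#' @param compartment compartment tag.
#' @param anchor_halfwidth half-width of the anchor exclusion (ppm).
#' @return two-column matrix of (low, high) ppm intervals.
#' @export
default_exclusions <- function(compartment, anchor_halfwidth = 0.1) {
  a <- anchor_ppm(compartment)
  rbind(water = c(4.7, 5.1),
        anchor = c(a - anchor_halfwidth, a + anchor_halfwidth))
}

#' Probabilistic quotient normalization
#'
#' Estimates a per-sample dilution factor as the median, over informative
#' axis points, of the quotient between the sample and a reference spectrum
#' (the point-wise median spectrum of the set, or a supplied reference), then
#' divides each sample by its factor. Informative points are those where the
#' reference exceeds a noise floor, outside the exclusion regions.
#'
#' @param spectra a `spectrum_set` with at least two samples.
#' @param exclusion_regions two-column matrix of (low, high) ppm intervals
#'   excluded from quotient computation.
#' @param reference optional reference spectrum (numeric vector on the same
#'   axis); defaults to the point-wise median spectrum.
#' @param noise_floor intensity threshold for informative points; `NULL` uses
#'   `median(reference) + 5 * mad(reference)`.
#' @return list with `spectra` (normalized set), `result` (data frame of
#'   per-sample factors) and `reference`.
#' @export
pqn_normalize <- function(spectra, exclusion_regions = NULL, reference = NULL,
                          noise_floor = NULL) {
  Y <- spectra$intensities
  if (nrow(Y) < 2 && is.null(reference)) {
    stop("PQN needs at least two samples (or an explicit reference)")
  }
  if (is.null(exclusion_regions) && !is.na(spectra$compartment)) {
    exclusion_regions <- default_exclusions(spectra$compartment)
  }
  ref <- reference %||% col_medians(Y)
  keep <- rep(TRUE, length(spectra$ppm))
  if (!is.null(exclusion_regions)) {
    for (r in seq_len(nrow(exclusion_regions))) {
      keep <- keep & !(spectra$ppm >= exclusion_regions[r, 1] &
                       spectra$ppm <= exclusion_regions[r, 2])
    }
  }
  floor_ <- noise_floor %||% (median(ref) + 5 * mad(ref))
  pts <- which(keep & ref > floor_)
  if (length(pts) == 0) stop("reference spectrum has no points above the noise floor")
  factors <- vapply(seq_len(nrow(Y)),
                    function(i) median(Y[i, pts] / ref[pts]), numeric(1))
  if (any(factors <= 0)) stop("nonpositive PQN quotient factor")
  spectra$intensities <- Y / factors
  list(spectra = spectra,
       result = data.frame(sample_id = spectra$sample_ids, factor = factors,
                           stringsAsFactors = FALSE),
       reference = ref)
}
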