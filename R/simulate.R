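#' Simulation parameters for the spectral forward model
#'
#' Defaults emulate a 600.58 MHz acquisition on a desk-scale axis: 2^14 points
#' over -1..11 ppm (the acquired 64k/20 ppm grid scaled down), Lorentzian
#' singlets of 0.004 ppm full width at half maximum, per-metabolite chemical
#' shift jitter, an integer global referencing error per sample, instrument
#' noise at 1% of the unit-concentration peak height, and log-normal dilution
#' factors (CV 15% for serum/urine, 5% for tissue extracts).
#'
#' @param points number of axis points.
#' @param ppm_range axis range (ppm, ascending).
#' @param fwhm Lorentzian full width at half maximum (ppm).
#' @param noise_sd Gaussian noise standard deviation (intensity units);
#'   `NULL` uses 1% of the height of a unit-concentration peak.
#' @param shift_jitter_sd per-metabolite, per-sample chemical-shift jitter sd
#'   (ppm).
#' @param global_shift_sd per-sample referencing error sd (points).
#' @param dilution_cv named CV of the log-normal dilution factor per
#'   compartment.
#' @param anchor_height concentration-equivalent amplitude of the reference
#'   (anchor) resonance; unaffected by dilution and jitter.
#' @param tail_cut Lorentzians are evaluated within `tail_cut` ppm of their
#'   center (the neglected tail mass is < 0.2% at the default).
#' @param base_level default latent concentration of every metabolite
#'   (arbitrary units).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(points = 2^14, ppm_range = c(-1, 11), fwhm = 0.004,
                       noise_sd = NULL, shift_jitter_sd = 0.002,
                       global_shift_sd = 3,
                       dilution_cv = c(serum = 0.15, urine = 0.15, tissue = 0.05),
                       anchor_height = 5, tail_cut = 0.75, base_level = 1) {
  stopifnot(points >= 2, ppm_range[1] < ppm_range[2], fwhm > 0)
  if (is.null(noise_sd)) noise_sd <- 0.01 * 2 / (pi * fwhm)
  structure(list(points = as.integer(points), ppm_range = ppm_range,
                 fwhm = fwhm, noise_sd = noise_sd,
                 shift_jitter_sd = shift_jitter_sd,
                 global_shift_sd = global_shift_sd, dilution_cv = dilution_cv,
                 anchor_height = anchor_height, tail_cut = tail_cut,
                 base_level = base_level, frequency_mhz = 600.58),
            class = "sim_params")
}

ppm_axis <- function(sim) seq(sim$ppm_range[1], sim$ppm_range[2],
                              length.out = sim$points)

# Axis indices within tail_cut of a peak center (binary search, ascending ppm).
lorentz_span <- function(ppm, ctr, tail_cut) {
  i1 <- findInterval(ctr - tail_cut, ppm) + 1L
  i2 <- findInterval(ctr + tail_cut, ppm)
  if (i2 < i1) integer(0) else i1:i2
}

#' Log-normal draws with a prescribed arithmetic mean and CV
#'
#' @param n number of draws.
#' @param mean target arithmetic mean (> 0).
#' @param cv coefficient of variation (sd/mean); 0 gives the degenerate
#'   constant distribution.
#' @return numeric vector of strictly positive draws.
#' @keywords internal
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample latent metabolite concentrations for a cohort
#'
#' For metabolite m in group g, concentrations are log-normal with arithmetic
#' mean `base * multiplier(m, g)` and coefficient of variation `|RSD(m, g)|/100`.
#' This is the ground truth behind the synthetic spectra.
#'
#' @param design a `cohort_design`.
#' @param effects an `effect_spec` table (see [calibrate_effects()]).
#' @param base_levels named base concentrations per metabolite, or a single
#'   value recycled; defaults to 1.
#' @param seed optional integer seed; `NULL` continues the current RNG stream.
#' @return samples x metabolites matrix (rownames = animal ids) with
#'   attributes `compartment` and `group`.
#' @export
sample_concentrations <- function(design, effects, base_levels = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mets <- effects$metabolite
  if (length(base_levels) == 1L && is.null(names(base_levels))) {
    base_levels <- stats::setNames(rep(base_levels, length(mets)), mets)
  }
  if (any(base_levels[mets] <= 0) || anyNA(base_levels[mets])) {
    stop("every metabolite needs a positive base level")
  }
  g <- design$groups
  out <- matrix(NA_real_, nrow(g), length(mets),
                dimnames = list(g$animal_id, mets))
  mult_cols <- c(BDG = "mult_bdg", RG = "mult_rg", UDG = "mult_udg")
  rsd_cols <- c(BDG = "rsd_bdg", RG = "rsd_rg", UDG = "rsd_udg")
  for (j in seq_along(mets)) {
    for (grp in design$group_names) {
      idx <- which(g$group == grp)
      mu <- base_levels[[mets[j]]] * effects[[mult_cols[[grp]]]][j]
      cv <- abs(effects[[rsd_cols[[grp]]]][j]) / 100
      out[idx, j] <- rlnorm_mean_cv(length(idx), mu, cv)
    }
  }
  attr(out, "compartment") <- effects$compartment[1]
  attr(out, "group") <- as.character(g$group)
  out
}

#' Synthesize one 1H NMR spectrum from latent concentrations
#'
#' Forward model: intensity = dilution * sum_m c_m * Lorentzian(peak_m +
#' jitter_m, fwhm) + reference resonance + Gaussian noise. Each Lorentzian has
#' unit area per unit concentration, so window integrals are proportional to
#' concentration. The reference (anchor) resonance, when requested, is added
#' with fixed amplitude, no jitter and no dilution — it mimics an internal
#' standard and carries the per-sample referencing error only.
#'
#' @param conc named numeric vector of concentrations.
#' @param library a `metabolite_library` with `peak_ppm` for every metabolite.
#' @param ppm ascending axis (ppm).
#' @param fwhm Lorentzian full width at half maximum (ppm).
#' @param noise_sd Gaussian noise sd; 0 for noiseless spectra.
#' @param shift_jitter_sd per-metabolite jitter sd (ppm); 0 disables.
#' @param dilution positive multiplicative dilution factor.
#' @param anchor position (ppm) of the reference resonance, or `NULL`.
#' @param anchor_height amplitude (concentration equivalents) of the anchor.
#' @param global_shift rigid translation applied to all resonances (ppm).
#' @param tail_cut evaluation half-range of each Lorentzian (ppm).
#' @param seed optional integer seed.
#' @return numeric intensity vector along `ppm`.
#' @export
synthesize_spectrum <- function(conc, library, ppm, fwhm = 0.004,
                                noise_sd = 0, shift_jitter_sd = 0,
                                dilution = 1, anchor = NULL, anchor_height = 5,
                                global_shift = 0, tail_cut = 0.75,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dilution <= 0) stop("dilution_factor must be positive")
  if (any(library$peak_ppm < min(ppm) | library$peak_ppm > max(ppm))) {
    stop("every library peak must lie inside the ppm axis")
  }
  gam <- fwhm / 2
  y <- numeric(length(ppm))
  jit <- if (shift_jitter_sd > 0) rnorm(nrow(library), 0, shift_jitter_sd)
         else numeric(nrow(library))
  for (i in seq_len(nrow(library))) {
    ci <- conc[[library$name[i]]]
    if (is.null(ci) || is.na(ci)) stop("missing concentration for ", library$name[i])
    if (ci == 0) next
    ctr <- library$peak_ppm[i] + jit[i] + global_shift
    idx <- lorentz_span(ppm, ctr, tail_cut)
    y[idx] <- y[idx] + ci * (gam / pi) / ((ppm[idx] - ctr)^2 + gam^2)
  }
  y <- dilution * y
  if (!is.null(anchor)) {
    ctr <- anchor + global_shift
    idx <- lorentz_span(ppm, ctr, tail_cut)
    y[idx] <- y[idx] + anchor_height * (gam / pi) / ((ppm[idx] - ctr)^2 + gam^2)
  }
  if (noise_sd > 0) y <- y + rnorm(length(ppm), 0, noise_sd)
  y
}

simulate_compartment <- function(design, effects, library, sim, seed = NULL,
                                 anchored = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  comp <- effects$compartment[1]
  ppm <- ppm_axis(sim)
  dx <- ppm[2] - ppm[1]
  conc <- sample_concentrations(design, effects, base_levels = sim$base_level)
  n <- nrow(conc)
  dil <- rlnorm_mean_cv(n, 1, unname(sim$dilution_cv[[comp]]))
  gshift <- round(rnorm(n, 0, sim$global_shift_sd))
  Y <- matrix(0, n, length(ppm))
  for (i in seq_len(n)) {
    Y[i, ] <- synthesize_spectrum(
      conc[i, ], library, ppm, fwhm = sim$fwhm, noise_sd = sim$noise_sd,
      shift_jitter_sd = sim$shift_jitter_sd, dilution = dil[i],
      anchor = if (anchored) anchor_ppm(comp) else NULL,
      anchor_height = sim$anchor_height, global_shift = gshift[i] * dx,
      tail_cut = sim$tail_cut)
  }
  ss <- spectrum_set(ppm, Y, design$groups$animal_id,
                     as.character(design$groups$group), comp,
                     frequency_mhz = sim$frequency_mhz)
  list(spectra = ss, concentrations = conc,
       dilution = stats::setNames(dil, design$groups$animal_id),
       global_shift_points = stats::setNames(gshift, design$groups$animal_id))
}

#' Generate a full synthetic cohort
#'
#' Simulates the three spectral compartments (serum, urine, tissue) and the
#' clinical covariate table for one cohort, retaining the latent ground truth
#' (concentration tables, dilution factors, referencing errors) for recovery
#' testing.
#'
#' @param design a `cohort_design`.
#' @param effects named list of `effect_spec` tables for `serum`, `urine`,
#'   `tissue`; defaults to the packaged calibrated libraries.
#' @param clinical clinical specification table (see [clinical_specs()]).
#' @param sim a `sim_params` list.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param compartments compartments to simulate.
#' @return list of class `nmr_cohort` with elements `spectra`,
#'   `concentrations`, `dilution`, `global_shift_points` (each a per-
#'   compartment list), `clinical`, `design`, `sim`, `seed`.
#' @export
generate_cohort <- function(design = default_design(),
                            effects = list(serum = default_effects("serum"),
                                           urine = default_effects("urine"),
                                           tissue = default_effects("tissue")),
                            clinical = clinical_specs(), sim = sim_params(),
                            seed = 1,
                            compartments = c("serum", "urine", "tissue")) {
  set.seed(seed)
  out <- list(spectra = list(), concentrations = list(), dilution = list(),
              global_shift_points = list())
  for (comp in compartments) {
    res <- simulate_compartment(design, effects[[comp]],
                                metabolite_library(comp), sim)
    out$spectra[[comp]] <- res$spectra
    out$concentrations[[comp]] <- res$concentrations
    out$dilution[[comp]] <- res$dilution
    out$global_shift_points[[comp]] <- res$global_shift_points
  }
  out$clinical <- sample_clinical(design, clinical)
  out$design <- design
  out$sim <- sim
  out$seed <- seed
  flagged <- unlist(lapply(effects, function(e) e$metabolite[e$flagged]))
  out$flags <- list(
    capped_or_clamped = unname(flagged),
    urine_rsd_bdg_rg_duplicated = TRUE  # printed urine RSDs duplicate BDG/RG
  )
  class(out) <- "nmr_cohort"
  out
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat("Synthetic NMR cohort:", nrow(x$design$groups), "animals, seed", x$seed, "\n")
  for (comp in names(x$spectra)) {
    cat(sprintf("  %-7s %d spectra x %d points, %d metabolites\n", comp,
                nrow(x$spectra[[comp]]$intensities),
                length(x$spectra[[comp]]$ppm),
                ncol(x$concentrations[[comp]])))
  }
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-sample two-column spectra (ppm descending, per NMR display
#' convention), ground-truth concentration and clinical CSVs, and a JSON
#' manifest with relative paths, the design, the seed and the generator flags.
#'
#' @param cohort an `nmr_cohort`.
#' @param dir output directory (created if needed).
#' @return path to the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    design = list(group_names = cohort$design$group_names,
                  group_sizes = unname(cohort$design$group_sizes),
                  animal_ids = cohort$design$groups$animal_id,
                  groups = as.character(cohort$design$groups$group)),
    seed = cohort$seed,
    frequency_mhz = cohort$sim$frequency_mhz,
    points = cohort$sim$points,
    ppm_range = cohort$sim$ppm_range,
    flags = cohort$flags,
    compartments = list()
  )
  for (comp in names(cohort$spectra)) {
    ss <- cohort$spectra[[comp]]
    files <- character(length(ss$sample_ids))
    sub <- file.path(dir, comp)
    dir.create(sub, showWarnings = FALSE)
    ord <- rev(seq_along(ss$ppm))  # descending ppm on disk
    for (i in seq_along(ss$sample_ids)) {
      files[i] <- file.path(comp, paste0(ss$sample_ids[i], ".tsv"))
      df <- data.frame(ppm = sprintf("%.6f", ss$ppm[ord]),
                       intensity = sprintf("%.12e", ss$intensities[i, ord]))
      write.table(df, file.path(dir, files[i]), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    truth <- file.path(comp, "truth_concentrations.csv")
    tr <- data.frame(animal_id = rownames(cohort$concentrations[[comp]]),
                     cohort$concentrations[[comp]], check.names = FALSE)
    write.csv(tr, file.path(dir, truth), row.names = FALSE)
    manifest$compartments[[comp]] <- list(
      files = files, truth = truth,
      dilution = unname(cohort$dilution[[comp]]),
      anchor_ppm = anchor_ppm(comp))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest$clinical <- "clinical.csv"
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
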