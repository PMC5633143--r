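#' Printed group statistics used to calibrate the generator
#'
#' Per-compartment percentage differences (PD, left-to-right over the ordered
#' comparisons BDG vs RG, RG vs UDG, BDG vs UDG) and per-group relative
#' standard deviations (RSD, %) for the metabolites reported as significant or
#' VIP-selected in the source study. These are the calibration surface of the
#' synthetic cohort generator.
#'
#' Note: the urine table prints identical RSD values for the BDG and RG
#' columns; they are used as printed and flagged downstream.
#'
#' @param compartment one of `"serum"`, `"urine"`, `"tissue"`.
#' @return data frame: `metabolite`, `pd_bdg_rg`, `pd_rg_udg`, `pd_bdg_udg`,
#'   `rsd_bdg`, `rsd_rg`, `rsd_udg`.
#' @export
printed_group_statistics <- function(compartment = c("serum", "urine", "tissue")) {
  compartment <- match.arg(compartment)
  tab <- switch(compartment,
    serum = rbind(
      # metabolite        PD B/R  PD R/U  PD B/U  RSD B  RSD R  RSD U
      Leucine    = c(-22.5,   2.4, -20.2, 11.1,  8.7,  8.8),
      Valine     = c(-24.0,   3.6, -20.5, 15.3, 11.5, 11.3),
      Isoleucine = c(-19.6,   8.7, -11.0, 11.6, 12.1, 11.6),
      Alanine    = c( 28.3, -19.1,   9.3, 14.7, 21.9, 14.3),
      Acetone    = c(-29.3, -17.7, -46.4, 17.4, 25.5, 29.3),
      Pyruvate   = c( 26.0,  -7.0,  19.0, 15.0, 36.2, 20.4),
      Betaine    = c( -2.1,  32.0,  30.0, 17.6, 17.7, 19.0)),
    urine = rbind(
      Unk_1                   = c( 55.6,  -1.8, 54.0, 41.8, 41.8,  16.9),
      DMA                     = c( 41.1, -21.5, 20.0, 61.4, 61.4,  13.6),
      NN_Dimethylglycine      = c( 51.9, -47.3,  4.8, 63.9, 63.9,  22.7),
      Creatinine              = c( 48.4, -24.8, 24.4, 70.2, 70.2,  20.1),
      Unk_4                   = c( 60.8,  -2.5, 58.5, 42.6, 42.6,  24.3),
      Unk_5                   = c( 60.8,  -2.5, 58.5, 35.2, 35.2,  24.4),
      N_Phenylacetylglutamine = c( 73.5,  -8.2, 66.3, 49.2, 49.2,  19.3),
      Hippurate               = c( 45.0,  26.8, 69.7, 78.9, 78.9,  35.5),
      Unk_6                   = c( -6.2,  91.8, 86.9, 66.6, 66.6, 111.7)),
    tissue = rbind(
      L1              = c(-114.0,  57.9,  -67.3,   76.8,   67.1,   64.1),
      Leucine         = c(-135.0,  74.2,  -81.2,   94.2,   45.8,   38.9),
      Valine          = c(-202.3, 125.3, -210.1, -6032.5,  76.6,  235.4),
      Isoleucine      = c( 151.0, -149.0,    4.6,  -47.1, -656.7, -104.7),
      Lactate         = c( -20.6,  -5.9,  -26.4,   13.7,   13.8,   19.1),
      L3              = c( -98.3,  47.5,  -57.6,   53.5,   55.3,   49.2),
      Methionine      = c( -56.9,  -2.9,  -59.5,   29.9,   25.2,   32.1),
      L4              = c(-118.3,  63.0,  -68.0,   96.1,   60.4,   72.2),
      Creatine        = c( -27.6,   5.3,  -22.4,   11.1,   16.5,   19.8),
      Glucose         = c( -48.4,  14.1,  -34.9,   21.8,   54.8,   17.2),
      Methylhistidine = c( -30.3, -14.1,  -44.0,   21.9,   15.3,   28.6),
      IMP             = c( -41.9,   8.1,  -34.1,   17.4,   54.1,   14.3))
  )
  out <- data.frame(metabolite = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("metabolite", "pd_bdg_rg", "pd_rg_udg", "pd_bdg_udg",
                  "rsd_bdg", "rsd_rg", "rsd_udg")
  out
}

#' Invert a percentage difference into a right-group mean multiplier
#'
#' Under the left-anchored convention PD = 100 (m_L - m_R) / m_L with the
#' left (BDG) mean anchored at 1, the right-group multiplier is 1 - PD/100.
#' PD = 100 is rejected (zero multiplier); PD > 100 would imply a negative
#' mean, which the positive-valued log-normal generator cannot represent, so
#' the multiplier is clamped at `floor` and flagged by the caller.
#'
#' @param pd percentage difference (left vs right).
#' @param floor smallest admissible multiplier for PD > 100.
#' @return positive multiplier.
#' @export
pd_to_multiplier <- function(pd, floor = 0.05) {
  stopifnot(is.finite(pd))
  if (pd == 100) stop("PD = 100 implies a zero group mean (degenerate multiplier)")
  m <- 1 - pd / 100
  if (m < 0) m <- floor
  m
}

#' Calibrate generative effect specifications from printed group statistics
#'
#' Anchors the BDG multiplier at 1.0 and solves the RG and UDG multipliers
#' from the two BDG-anchored PD columns (the three pairwise PDs are printed to
#' one decimal and mutually slightly inconsistent; the direct BDG-anchored
#' columns minimize propagated rounding, so the RG-vs-UDG column is not used).
#' Metabolites of the library absent from the printed tables are treated as
#' null (multiplier 1.0 in every group) with the default RSD. RSD magnitudes
#' above `rsd_cap` (printed negative/extreme tissue values reflecting
#' near-zero baseline-corrected means) are capped and flagged.
#'
#' @param pd_table data frame with `metabolite`, `pd_bdg_rg`, `pd_bdg_udg`
#'   (and, unused for calibration, `pd_rg_udg`).
#' @param rsd_table data frame with `metabolite`, `rsd_bdg`, `rsd_rg`,
#'   `rsd_udg`; may be the same object as `pd_table`.
#' @param compartment compartment tag.
#' @param metabolites optional character vector of all library metabolites;
#'   those missing from the tables get null effects.
#' @param default_rsd within-group RSD (%) assigned to null metabolites.
#' @param rsd_cap cap on |RSD| (%).
#' @return data frame of class `effect_spec`: one row per metabolite with
#'   multipliers `mult_bdg` (1.0), `mult_rg`, `mult_udg`, RSDs `rsd_bdg`,
#'   `rsd_rg`, `rsd_udg`, and a logical `flagged` with a `note`.
#' @export
calibrate_effects <- function(pd_table, rsd_table = pd_table,
                              compartment = c("serum", "urine", "tissue"),
                              metabolites = NULL, default_rsd = 15,
                              rsd_cap = 200) {
  compartment <- match.arg(compartment)
  stopifnot(all(c("metabolite", "pd_bdg_rg", "pd_bdg_udg") %in% names(pd_table)))
  mets <- metabolites %||% pd_table$metabolite
  res <- data.frame(metabolite = mets, compartment = compartment,
                    mult_bdg = 1.0, mult_rg = 1.0, mult_udg = 1.0,
                    rsd_bdg = default_rsd, rsd_rg = default_rsd,
                    rsd_udg = default_rsd, flagged = FALSE, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pd_table))) {
    m <- pd_table$metabolite[i]
    j <- match(m, res$metabolite)
    if (is.na(j)) next
    res$mult_rg[j] <- pd_to_multiplier(pd_table$pd_bdg_rg[i])
    res$mult_udg[j] <- pd_to_multiplier(pd_table$pd_bdg_udg[i])
    if (pd_table$pd_bdg_rg[i] > 100 || pd_table$pd_bdg_udg[i] > 100) {
      res$flagged[j] <- TRUE
      res$note[j] <- "PD > 100 implies a negative mean; multiplier clamped"
    }
    k <- match(m, rsd_table$metabolite)
    if (!is.na(k)) {
      for (col in c("rsd_bdg", "rsd_rg", "rsd_udg")) {
        r <- rsd_table[[col]][k]
        if (abs(r) > rsd_cap) {
          r <- sign(r) * rsd_cap
          res$flagged[j] <- TRUE
          res$note[j] <- paste0(res$note[j],
            if (nzchar(res$note[j])) "; " else "", "|RSD| capped at ", rsd_cap)
        }
        res[[col]][j] <- r
      }
    }
  }
  class(res) <- c("effect_spec", "data.frame")
  res
}

#' Default calibrated effect library for a compartment
#'
#' Convenience wrapper: [calibrate_effects()] applied to the packaged printed
#' statistics over the full packaged metabolite library of the compartment.
#'
#' @inheritParams calibrate_effects
#' @return an `effect_spec` data frame covering the whole library.
#' @export
default_effects <- function(compartment = c("serum", "urine", "tissue"),
                            default_rsd = 15) {
  compartment <- match.arg(compartment)
  calibrate_effects(printed_group_statistics(compartment),
                    compartment = compartment,
                    metabolites = metabolite_library(compartment)$name,
                    default_rsd = default_rsd)
}
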