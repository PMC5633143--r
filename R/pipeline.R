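#' Default end-to-end configuration
#'
#' Every tunable of the pipeline in one nested list, overridable piecewise and
#' echoed into the provenance record of [run_study()]. Can be serialized to /
#' loaded from YAML.
#'
#' @param ... named overrides merged over the defaults (top level only).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    design = list(group_names = c("BDG", "RG", "UDG"),
                  group_sizes = c(11L, 8L, 9L)),
    sim = sim_params(),
    preprocess = list(max_shift = 10L, passes = 2L, anchor_halfwidth = 0.1),
    analysis = list(folds = 7L, vip_threshold = 0.8, ncomp = NULL,
                    jackknife_level = 0.95, max_iter = 25L)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Load a configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] fields.
#' @return configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  modify <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  modify(cfg, user)
}

#' Preprocess one compartment: reference, align, normalize
#'
#' The full preprocessing chain of the analysis: anchor referencing,
#' segment-wise integer alignment (segments at library-window midpoints),
#' and probabilistic quotient normalization.
#'
#' @param spectra a `spectrum_set`.
#' @param library the compartment's `metabolite_library` (drives alignment
#'   segmentation).
#' @param max_shift alignment shift bound (points); `NULL` uses 10 points,
#'   reduced if the grid makes the narrowest segment too small.
#' @param passes alignment passes.
#' @return list: `spectra` (processed set), `alignment`, `normalization`.
#' @export
preprocess_spectra <- function(spectra, library = metabolite_library(spectra$compartment),
                               max_shift = NULL, passes = 2L) {
  ss <- reference_to_anchor(spectra)
  segs <- library_segments(library)
  if (is.null(max_shift)) {
    dx <- ss$ppm[2] - ss$ppm[1]
    min_seg <- min(diff(c(min(ss$ppm), segs, max(ss$ppm)))) / dx
    max_shift <- max(1L, min(10L, as.integer((min_seg - 2) %/% 2)))
  }
  al <- segment_align(ss, segs, max_shift = max_shift, passes = passes)
  pq <- pqn_normalize(al$spectra)
  list(spectra = pq$spectra, alignment = al$result, normalization = pq$result)
}

#' Simulate and quantify one compartment of one cohort
#'
#' Convenience wrapper running the forward model and the full recovery chain
#' (simulate spectra, reference, align, PQN-normalize, integrate) for a single
#' compartment, returning the feature table together with the ground truth.
#'
#' @param compartment compartment name.
#' @param seed cohort seed.
#' @param design cohort design.
#' @param effects effect specification (defaults to the packaged calibrated
#'   library).
#' @param sim simulation parameters.
#' @return list: `features` (a `feature_table`), `truth` (concentration
#'   matrix), `dilution` (true factors), `normalization` (estimated factors).
#' @export
simulate_and_quantify <- function(compartment, seed,
                                  design = default_design(),
                                  effects = default_effects(compartment),
                                  sim = sim_params()) {
  set.seed(seed)
  lib <- metabolite_library(compartment)
  res <- simulate_compartment(design, effects, lib, sim)
  pp <- preprocess_spectra(res$spectra, lib)
  list(features = integrate_windows(pp$spectra, lib),
       truth = res$concentrations, dilution = res$dilution,
       normalization = pp$normalization)
}

#' Fuse compartment feature tables with the clinical block
#'
#' Inner-joins the serum, urine and tissue feature tables and the clinical
#' covariates on animal id (only animals present in every block are retained,
#' matching the paired design). Metabolite columns are suffixed `_S`, `_U`,
#' `_T` by compartment; clinical variables keep their plain names.
#'
#' @param serum_ft,urine_ft,tissue_ft compartment `feature_table`s.
#' @param clinical clinical covariate data frame (`animal_id`, `group`,
#'   variables).
#' @return fused `feature_table` with attribute `"blocks"` mapping each
#'   column to its source block.
#' @export
fuse <- function(serum_ft, urine_ft, tissue_ft, clinical) {
  blocks <- list(serum = serum_ft, urine = urine_ft, tissue = tissue_ft,
                 clinical = clinical)
  suffix <- c(compartment_suffix, clinical = "")
  out <- NULL
  origin <- character(0)
  for (nm in names(blocks)) {
    b <- as.data.frame(blocks[[nm]])
    vars <- setdiff(names(b), c("animal_id", "group"))
    names(b)[match(vars, names(b))] <- paste0(vars, suffix[[nm]])
    origin <- c(origin,
                stats::setNames(rep(nm, length(vars)), paste0(vars, suffix[[nm]])))
    out <- if (is.null(out)) b else
      merge(out, b[, c("animal_id", setdiff(names(b), c("animal_id", "group")))],
            by = "animal_id", sort = FALSE)
  }
  if (nrow(out) == 0) stop("no animal is present in every block")
  class(out) <- c("feature_table", "data.frame")
  attr(out, "compartment") <- "fused"
  attr(out, "blocks") <- origin
  out
}

#' Run one two-group comparison through selection, CV and ROC
#'
#' Subsets the table to the two (ordered) groups, codes the right-hand group
#' as the positive class (1), runs the iterative VIP selection loop, and
#' evaluates the final model by ROC/AUC on its 7-fold cross-validated
#' predictions (Y-predcv).
#'
#' @param tbl a `feature_table` (single block or fused) with a `group` column.
#' @param groupA,groupB ordered group labels (left, right).
#' @param config analysis configuration (see [default_config()]`$analysis`).
#' @return list of class `comparison_report`: `comparison`, `selection`,
#'   `roc`, `auc`, `q2`, `n`.
#' @export
run_comparison <- function(tbl, groupA, groupB,
                           config = default_config()$analysis) {
  sub <- tbl[tbl$group %in% c(groupA, groupB), , drop = FALSE]
  nA <- sum(sub$group == groupA); nB <- sum(sub$group == groupB)
  if (nA < 4 || nB < 4) stop("each group needs at least 4 samples")
  X <- feature_matrix(sub)
  y <- as.integer(sub$group == groupB)
  sel <- select_variables(X, y, A = config$ncomp,
                          vip_threshold = config$vip_threshold,
                          k = config$folds, level = config$jackknife_level,
                          max_iter = config$max_iter)
  roc <- roc_from_cv(sel$cv$ypredcv, sub$group, positive_class = groupB)
  structure(list(comparison = paste(groupA, "vs", groupB),
                 selection = sel, roc = roc, auc = roc$auc, q2 = sel$cv$Q2,
                 n = c(nA, nB)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s: AUC = %.3f, Q2 = %.3f, %d variable(s) retained\n",
              x$comparison, x$auc, x$q2, length(x$selection$variables)))
  invisible(x)
}

#' Run the full study end to end
#'
#' Simulates (or ingests) a cohort, preprocesses and quantifies all three
#' compartments, writes per-compartment univariate reports, and runs the
#' three ordered comparisons (BDG vs RG, RG vs UDG, BDG vs UDG) on each
#' single block and on the fused serum + urine + tissue + clinical matrix.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir optional output directory; when given, CSV/JSON reports and
#'   a master index are written.
#' @param cohort optional pre-generated `nmr_cohort` (simulated when `NULL`).
#' @return list of class `study_result`: `features` (per block), `univariate`
#'   (per compartment), `comparisons` (nested: block -> comparison ->
#'   `comparison_report`), `fused`, `cohort`, `config`.
#' @export
run_study <- function(config = default_config(), outdir = NULL,
                      cohort = NULL) {
  design <- cohort_design(config$design$group_names, config$design$group_sizes)
  if (is.null(cohort)) {
    cohort <- generate_cohort(design, sim = config$sim, seed = config$seed)
  }
  comps <- names(cohort$spectra)
  features <- univ <- list()
  for (comp in comps) {
    lib <- metabolite_library(comp)
    pp <- preprocess_spectra(cohort$spectra[[comp]], lib,
                             max_shift = config$preprocess$max_shift,
                             passes = config$preprocess$passes)
    features[[comp]] <- integrate_windows(pp$spectra, lib)
    univ[[comp]] <- build_univariate_report(features[[comp]])
  }
  fused <- fuse(features$serum, features$urine, features$tissue,
                cohort$clinical)
  blocks <- c(features, list(fused = fused))
  comparisons <- list()
  for (bl in names(blocks)) {
    comparisons[[bl]] <- list()
    for (cmp in diet_comparisons()) {
      key <- paste(cmp[1], "vs", cmp[2])
      comparisons[[bl]][[key]] <-
        run_comparison(blocks[[bl]], cmp[1], cmp[2], config$analysis)
    }
  }
  out <- structure(list(features = features, univariate = univ,
                        comparisons = comparisons, fused = fused,
                        cohort = cohort, config = config),
                   class = "study_result")
  if (!is.null(outdir)) write_study(out, outdir)
  out
}

write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (comp in names(study$univariate)) {
    p <- file.path(outdir, paste0("univariate_", comp, ".csv"))
    write_univariate_report(study$univariate[[comp]], p)
    paths <- c(paths, p)
  }
  for (bl in names(study$comparisons)) {
    for (key in names(study$comparisons[[bl]])) {
      rep_ <- study$comparisons[[bl]][[key]]
      p <- file.path(outdir, sprintf("model_%s_%s.json", bl,
                                     gsub(" ", "_", key)))
      jsonlite::write_json(list(
        block = bl, comparison = rep_$comparison, auc = rep_$auc,
        q2 = rep_$q2, n = rep_$n,
        variables = rep_$selection$variables,
        guard = rep_$selection$guard,
        iterations = rep_$selection$iterations,
        vip = rep_$selection$vip[, c("variable", "vip", "lower", "upper")],
        roc = roc_points(rep_$roc),
        sensitivity = rep_$roc$sensitivity,
        specificity = rep_$roc$specificity
      ), p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
      paths <- c(paths, p)
    }
  }
  index <- list(seed = study$config$seed,
                files = data.frame(file = basename(paths),
                                   md5 = unname(tools::md5sum(paths))))
  jsonlite::write_json(index, file.path(outdir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
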