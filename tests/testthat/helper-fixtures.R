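# Shared fixtures: everything is generated in code at test time.

shift_points <- nmrfusion:::shift_points

# Desk-scale simulation grid for unit tests (coarser than the analysis
# default); alignment shift bounds scaled with it.
quick_sim <- function(...) sim_params(points = 2^12, ...)
quick_max_shift <- 4L

# A small three-group design for smoke tests.
quick_design <- function(n = 4L) cohort_design(group_sizes = c(n, n, n))

# A minimal two-metabolite library on well-separated singlets.
toy_library <- function() {
  lib <- data.frame(
    name = c("A", "B"),
    compartment = "serum",
    peak_ppm = c(2.0, 6.0),
    ppm_low = c(1.9, 5.9),
    ppm_high = c(2.1, 6.1),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}

# Closed-form fraction of a unit-area Lorentzian (fwhm = 2*gamma) captured in
# a symmetric window of half-width w around its center.
lorentz_window_fraction <- function(w, fwhm) (2 / pi) * atan(2 * w / fwhm)

# Independent PLS1 oracle: after A components, the NIPALS regression vector on
# centered/scaled data equals the Krylov-subspace least-squares solution
# b = K (K' S K)^{-1} K' s with s = X'y, S = X'X, K = [s, Ss, ..., S^(A-1) s].
krylov_pls1_coef <- function(Xs, yc, A) {
  s <- crossprod(Xs, yc)
  S <- crossprod(Xs)
  K <- s
  for (a in seq_len(A - 1)) K <- cbind(K, S %*% K[, a])
  as.vector(K %*% solve(t(K) %*% S %*% K, t(K) %*% s))
}
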