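test_that("write-then-read round trip preserves spectra and conventions", {
  sim <- quick_sim()
  co <- generate_cohort(quick_design(3L), sim = sim, seed = 4,
                        compartments = "serum")
  dir <- file.path(tempdir(), "roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- write_cohort(co, dir)
  ss <- read_spectra(man, "serum")
  expect_lt(max(abs(ss$intensities - co$spectra$serum$intensities)), 1e-9)
  expect_true(all(diff(ss$ppm) > 0))  # ascending in memory, descending on disk
  expect_identical(ss$sample_ids, co$design$groups$animal_id)
  # a missing file errors naming the sample
  file.remove(file.path(dir, "serum", paste0(ss$sample_ids[2], ".tsv")))
  expect_error(read_spectra(man, "serum"), ss$sample_ids[2])
})

test_that("descending axes are co-reversed on construction", {
  ppm <- seq(5, 1, length.out = 50)
  y <- seq_len(50)
  ss <- spectrum_set(ppm, y, "s1")
  expect_true(all(diff(ss$ppm) > 0))
  expect_equal(ss$intensities[1, ], rev(y))
  expect_error(spectrum_set(c(1, 3, 2), c(0, 0, 0), "s1"), "monotone")
})

test_that("anchor referencing recovers integer translations exactly", {
  sim <- quick_sim()
  ppm <- seq(-1, 11, length.out = sim$points)
  lib <- metabolite_library("serum")
  conc <- stats::setNames(rep(1, nrow(lib)), lib$name)
  y <- synthesize_spectrum(conc, lib, ppm, anchor = 5.225, anchor_height = 5)
  ss0 <- spectrum_set(ppm, rbind(y, y), c("a", "b"), compartment = "serum")
  r0 <- reference_to_anchor(ss0)
  expect_equal(unname(attr(r0, "shifts")), c(0L, 0L))  # already anchored
  # translate one sample by +7 points: shift -7 recovered, spectrum restored
  ss1 <- ss0
  ss1$intensities[2, ] <- shift_points(y, 7L)
  r1 <- reference_to_anchor(ss1)
  expect_equal(unname(attr(r1, "shifts")[2]), -7L)
  core <- 10:(sim$points - 10)
  expect_equal(r1$intensities[2, core], y[core])
  # urine/tissue anchor at 0 ppm, serum at 5.225
  expect_equal(anchor_ppm("serum"), 5.225)
  expect_equal(anchor_ppm("urine"), 0.0)
  expect_error(reference_to_anchor(
    spectrum_set(ppm, matrix(0, 1, length(ppm)), "s", compartment = "serum")),
    "flat")
})

test_that("segment alignment recovers constructed integer shifts and is idempotent", {
  sim <- quick_sim()
  ppm <- seq(-1, 11, length.out = sim$points)
  lib <- toy_library()
  y <- synthesize_spectrum(c(A = 1, B = 1), lib, ppm)
  Y <- rbind(y, y, y)
  ss <- spectrum_set(ppm, Y, c("a", "b", "c"), compartment = "serum")
  al0 <- segment_align(ss, segment_boundaries = 4, max_shift = quick_max_shift)
  expect_true(all(al0$result$shift == 0))  # identical spectra: nothing moves
  # jitter one sample by +3 points inside the second segment only
  seg2 <- which(ppm >= 4)
  Y2 <- Y
  Y2[2, seg2] <- shift_points(Y[2, seg2], 3L)
  ss2 <- spectrum_set(ppm, Y2, c("a", "b", "c"), compartment = "serum")
  al2 <- segment_align(ss2, segment_boundaries = 4, max_shift = quick_max_shift)
  sh <- al2$result
  expect_equal(sh$shift[sh$sample_id == "b" & sh$segment == 2], -3L)
  expect_equal(al2$spectra$intensities[2, ], y, tolerance = 1e-12)
  # idempotence: aligning the aligned set yields all-zero shifts
  al3 <- segment_align(al2$spectra, segment_boundaries = 4,
                       max_shift = quick_max_shift)
  expect_true(all(al3$result$shift == 0))
  expect_error(segment_align(ss, segment_boundaries = 4, max_shift = 3000),
               "wider")
})

test_that("alignment collapses simulated chemical-shift jitter", {
  # jitter sd = 3 points on this grid; shift bound covers > 3 sd
  sim <- sim_params(points = 2^13, shift_jitter_sd = 3 * 12 / (2^13 - 1),
                    noise_sd = 0, global_shift_sd = 0)
  set.seed(21)
  res <- nmrfusion:::simulate_compartment(quick_design(6L),
                                          default_effects("serum"),
                                          metabolite_library("serum"), sim)
  lib <- metabolite_library("serum")
  al <- segment_align(res$spectra, library_segments(lib), max_shift = 10L)
  ppm <- al$spectra$ppm
  spreads <- vapply(seq_len(nrow(lib)), function(j) {
    w <- which(ppm >= lib$ppm_low[j] & ppm <= lib$ppm_high[j])
    apex <- apply(al$spectra$intensities[, w], 1, which.max)
    diff(range(apex))
  }, numeric(1))
  expect_gte(mean(spreads <= 1), 0.95)
})

test_that("PQN factors scale as constructed and normalization is scale-equivariant", {
  sim <- quick_sim()
  ppm <- seq(-1, 11, length.out = sim$points)
  y <- synthesize_spectrum(c(A = 1, B = 2), toy_library(), ppm)
  ss <- spectrum_set(ppm, rbind(y, 2 * y), c("a", "b"), compartment = "urine")
  pq <- pqn_normalize(ss)
  expect_equal(pq$result$factor[2] / pq$result$factor[1], 2, tolerance = 1e-10)
  expect_equal(pq$spectra$intensities[1, ], pq$spectra$intensities[2, ],
               tolerance = 1e-10)
  # global rescaling of all samples changes outputs only by the global scale:
  # quotient factors are relative to the cohort reference, hence invariant
  ssc <- ss
  ssc$intensities <- 5 * ss$intensities
  pqc <- pqn_normalize(ssc)
  expect_equal(pqc$result$factor, pq$result$factor, tolerance = 1e-10)
  expect_equal(pqc$spectra$intensities, 5 * pq$spectra$intensities,
               tolerance = 1e-10, ignore_attr = TRUE)
  # the reference spectrum normalized against itself has factor exactly 1
  pq1 <- pqn_normalize(ss, reference = y)
  expect_equal(pq1$result$factor[1], 1)
})

test_that("PQN recovers seeded log-normal dilution factors", {
  r <- simulate_and_quantify("serum", seed = 31, sim = quick_sim())
  expect_gte(cor(r$dilution, r$normalization$factor), 0.95)
})

test_that("referencing and alignment commute with a global integer translation", {
  sim <- quick_sim()
  set.seed(41)
  res <- nmrfusion:::simulate_compartment(quick_design(3L),
                                          default_effects("urine"),
                                          metabolite_library("urine"), sim)
  ss <- res$spectra
  sst <- ss
  for (i in seq_len(nrow(sst$intensities))) {
    sst$intensities[i, ] <- shift_points(sst$intensities[i, ], 5L)
  }
  a <- reference_to_anchor(ss)
  b <- reference_to_anchor(sst)
  core <- 20:(sim$points - 20)
  expect_equal(a$intensities[, core], b$intensities[, core], tolerance = 1e-12)
  expect_equal(attr(b, "shifts") - attr(a, "shifts"),
               stats::setNames(rep(-5L, length(ss$sample_ids)), ss$sample_ids))
})
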