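# RT correction, library matching boundaries, isomer collapse.

make_pm <- function(rt, mz, intens = NULL, n_samples = 2) {
  n <- length(rt)
  if (is.null(intens)) {
    intens <- matrix(100, n, n_samples)
  }
  colnames(intens) <- paste0("s", seq_len(ncol(intens)))
  rownames(intens) <- paste0("p", seq_len(n))
  peak_matrix(data.frame(peak_id = paste0("p", seq_len(n)), rt_min = rt,
                         mz = mz),
              intens,
              data.frame(sample_id = colnames(intens),
                         organ = "root", condition = "P_replete",
                         genotype = "WT",
                         replicate = seq_len(ncol(intens))))
}

test_that("rt_map interpolates linearly and extrapolates by offset", {
  f <- rt_map(data.frame(observed_rt = c(5, 10),
                         reference_rt = c(5.1, 10.1)))
  expect_equal(f(7.5), 7.6)      # hand-derived interpolation
  expect_equal(f(4.0), 4.1)      # constant-offset extrapolation (low)
  expect_equal(f(12.0), 12.1)    # constant-offset extrapolation (high)
  expect_equal(f(c(5, 10)), c(5.1, 10.1))  # markers map exactly
})

test_that("identity markers leave the matrix unchanged; correction is
           idempotent on aligned data", {
  pm <- make_pm(c(2, 8, 15), c(500, 700, 900))
  mk <- data.frame(observed_rt = c(1.5, 16), reference_rt = c(1.5, 16))
  out <- correct_rt(pm, mk)
  expect_equal(out$peaks$rt_min, pm$peaks$rt_min)
  expect_equal(correct_rt(out, mk)$peaks$rt_min, out$peaks$rt_min)
})

test_that("rt_map validates marker count and monotonicity", {
  expect_error(rt_map(data.frame(observed_rt = 5, reference_rt = 5)),
               "at least 2")
  expect_error(rt_map(data.frame(observed_rt = c(5, 5),
                                 reference_rt = c(5, 6))),
               "strictly increasing")
  expect_error(rt_map(data.frame(observed_rt = c(5, 6),
                                 reference_rt = c(6, 5))),
               "strictly increasing")
})

test_that("matching honors inclusive ppm and RT boundaries", {
  lib <- build_library("PC", 34, 2, 7.0, rt_tolerance_min = 0.2)
  mz0 <- lib$theoretical_mz
  # at 9.99 ppm / RT dev 0.199: matched; at 0.201 min: out
  pm <- make_pm(c(7.0, 7.199, 7.201), mz0 * c(1 + 9.99e-6, 1, 1))
  ann <- match_library(pm, lib)
  expect_setequal(ann$peak_id, c("p1", "p2"))
  expect_equal(max(ann$ppm_error), 9.99, tolerance = 1e-6)
  # just past the ppm edge: unmatched (the bounds are <=, so the printed
  # 10 ppm itself is still inside)
  pm2 <- make_pm(7.0, mz0 * (1 + 10.01e-6))
  expect_identical(nrow(match_library(pm2, lib)), 0L)
  expect_identical(nrow(match_library(make_pm(7.0, 700),
                                      build_library("PC", 34, 2, 7.0,
                                        theoretical_mz = 700))), 1L)
})

test_that("a peak annotates at most one species, best ppm first", {
  # two entries close in m/z; the peak sits nearer the second
  lib <- build_library(c("PC", "PC"), c(34, 34), c(2, 2), c(7.0, 7.05),
                       theoretical_mz = c(700.000, 700.004))
  lib$species <- c("PC A", "PC B")
  pm <- make_pm(7.02, 700.003)
  ann <- match_library(pm, lib)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$species, "PC B")
})

test_that("library rt tolerances outside the window are rejected, not
           clamped", {
  lib <- default_library()
  lib$rt_tolerance_min[3] <- 0.30
  pm <- make_pm(7, 700)
  expect_error(match_library(pm, lib), "0.05, 0.2")
})

test_that("isomer collapse sums intensity and conserves the total", {
  lib <- build_library("DGDG", 34, 3, 8.2)
  ints <- matrix(c(100, 40, 50, 20), 2, 2, byrow = FALSE)
  pm <- make_pm(c(8.18, 8.24), rep(lib$theoretical_mz, 2), ints)
  ann <- match_library(pm, lib)
  expect_identical(nrow(ann), 2L)
  am <- collapse_isomers(pm, ann)
  expect_identical(nrow(am$rows), 1L)
  expect_equal(unname(am$intensities[1, ]), c(140, 70))
  # conservation: matched intensity in = species intensity out
  expect_equal(sum(am$intensities), sum(ints))
})

test_that("zero-noise annotation has recall and precision 1;
           decoys never annotate; totals are conserved", {
  gen <- noiseless_dataset(seed = 21)
  am <- annotate_peaks(gen$peaks, default_library(),
                       markers = gen$truth$markers)
  pmapp <- gen$truth$peak_map
  lipid_ids <- pmapp$peak_id[pmapp$kind == "lipid"]
  expect_setequal(am$provenance$peak_id, lipid_ids)   # recall & precision
  truth_sp <- pmapp$species[match(am$provenance$peak_id, pmapp$peak_id)]
  expect_identical(am$provenance$species, truth_sp)   # correct identities
  idx <- match(lipid_ids, gen$peaks$peaks$peak_id)
  expect_equal(sum(am$intensities),
               sum(gen$peaks$intensities[idx, ]))     # conservation
})

test_that("matching is invariant under sample-column permutation", {
  gen <- noiseless_dataset(seed = 13)
  pm <- gen$peaks
  perm <- rev(seq_len(ncol(pm$intensities)))
  pm2 <- peak_matrix(pm$peaks, pm$intensities[, perm],
                     pm$samples[perm, ])
  a1 <- match_library(correct_rt(pm, gen$truth$markers), default_library())
  a2 <- match_library(correct_rt(pm2, gen$truth$markers), default_library())
  expect_identical(a1, a2)
})

test_that("annotation under default drift requires RT correction", {
  # drift up to 0.1 min pushes peaks to the edge of the default tolerance;
  # with markers the full lipid complement must be recovered
  gen <- generate_peak_matrix(tiny_design(), remodeling_profile("root"),
                              default_library(),
                              generator_config(seed = 15))
  am <- annotate_peaks(gen$peaks, default_library(),
                       markers = gen$truth$markers)
  n_lipid <- sum(gen$truth$peak_map$kind == "lipid")
  expect_identical(nrow(am$provenance), as.integer(n_lipid))
})
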