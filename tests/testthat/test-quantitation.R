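test_that("standard curves are recovered exactly from points on a line", {
  cq <- 40 - log2(10) * (3:7)
  curve <- fitStandardCurve(10^(3:7), cq)
  expect_equal(curve@slope, -log2(10), tolerance = 1e-12)
  expect_equal(curve@intercept, 40, tolerance = 1e-10)
  expect_equal(curve@r_squared, 1)
  expect_equal(curveEfficiency(curve), 1, tolerance = 1e-12)  # 100% efficiency
  expect_error(fitStandardCurve(c(1e4, 1e4), c(30, 30.1)),
               "insufficient calibration")
})

test_that("Cq inversion applies the full volumetric scaling chain", {
  curve <- fitStandardCurve(10^(3:7), 40 - log2(10) * (3:7))
  expect_equal(quantifyCopies(40, curve), 1, tolerance = 1e-9)
  expect_equal(quantifyCopies(40 + curve@slope, curve), 10, tolerance = 1e-9)
  # 1e3 copies in reaction, 100x dilution, 0.05 g stool -> 2e6 copies/g
  cq3 <- 40 - log2(10) * 3
  expect_equal(quantifyCopies(cq3, curve, dilution_factor = 100,
                              stool_mass_g = 0.05), 2e6, tolerance = 1e-9)
  expect_true(is.na(quantifyCopies(NA_real_, curve)))
  expect_error(quantifyCopies(30, curve, stool_mass_g = 0), "> 0")
})

test_that("relative abundances normalize counts and reject empty samples", {
  expect_equal(unname(relativeAbundances(c(a = 30, b = 70))), c(0.3, 0.7))
  expect_equal(unname(relativeAbundances(c(a = 100))), 1)
  m <- matrix(c(1, 1, 1, 1, 2, 2), 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  ra <- relativeAbundances(m)
  expect_equal(colSums(ra), c(s1 = 1, s2 = 1, s3 = 1), tolerance = 1e-12)
  m[, 2] <- 0
  expect_error(relativeAbundances(m), "empty sample")
})

test_that("concentration estimation divides copy-weighted totals by copy number", {
  res <- estimateConcentrations(
    matrix(c(50, 50), 2, dimnames = list(c("E. coli", "x"), "s1")),
    total_16s_per_g = 2e9, copy_numbers = c("E. coli" = 10, x = 10))
  expect_equal(res$concentration["E. coli", "s1"], 1e8)  # 0.5 * 2e9 / 10
  # zero fraction -> non-detected, value 0 pre-imputation
  res0 <- estimateConcentrations(
    matrix(c(100, 0), 2, dimnames = list(c("a", "b"), "s1")),
    total_16s_per_g = 1e9, copy_numbers = c(a = 5, b = 5))
  expect_false(res0$detected["b", "s1"])
  expect_equal(res0$concentration["b", "s1"], 0)
  # uniform fractions and equal copy numbers -> equal concentrations
  resu <- estimateConcentrations(
    matrix(rep(25, 4), 4, dimnames = list(letters[1:4], "s1")),
    total_16s_per_g = 1e9, copy_numbers = setNames(rep(4, 4), letters[1:4]))
  expect_equal(unname(diff(range(resu$concentration))), 0)
  expect_error(estimateConcentrations(
    matrix(1, 1, dimnames = list("a", "s1")), 1e9, c(b = 5)),
    "no 16S copy number.*a")
})

test_that("copy-weighted concentrations conserve the measured total", {
  set.seed(7)
  counts <- matrix(rpois(50, 200), 5,
                   dimnames = list(paste0("sp", 1:5), paste0("s", 1:10)))
  cn <- setNames(sample(3:10, 5), rownames(counts))
  totals <- runif(10, 1e8, 1e10)
  res <- estimateConcentrations(counts, totals, cn)
  recon <- colSums(res$concentration * cn)
  expect_equal(unname(recon), totals, tolerance = 1e-12)
})

test_that("copy-number bias is corrected: unequal reads, equal estimates", {
  xm <- matrix(c(1e8, 1e8), 2, 1, dimnames = list(c("a", "b"), NULL))
  model <- matchingModel(xm, copies = c(10L, 5L))
  se <- observeCommunity(makeTrajectory(xm), model,
                         observationSettings(read_depth = Inf, qpcr_cv = 0,
                                             detection_limit = 0, seed = 1))
  counts <- SummarizedExperiment::assay(se, "counts")
  expect_gt(counts["a", 1], counts["b", 1])   # biased reads
  se <- estimateConcentrations(se)
  conc <- SummarizedExperiment::assay(se, "concentration")
  expect_equal(conc["a", 1], conc["b", 1], tolerance = 1e-12)  # equal cells
  expect_equal(conc["a", 1], 1e8, tolerance = 1e-12)
})

test_that("noiseless estimation round-trips the simulator truth", {
  mod <- defaultConsortium(list(
    phages = emptyPhageTable(),
    amp_efficiency = setNames(rep(1, 10), phagedyn:::consortiumNames())))
  sc <- Scenario(speciesNames(mod), sampling_days = c(1.1, 8.1, 16.1),
                 n_mice = 2L)
  se <- observeCommunity(simulateCommunity(mod, sc), mod,
                         observationSettings(read_depth = Inf, qpcr_cv = 0,
                                             detection_limit = 0, seed = 1))
  se <- estimateConcentrations(se)
  conc <- SummarizedExperiment::assay(se, "concentration")
  tru <- SummarizedExperiment::assay(se, "truth")
  expect_lt(max(abs(conc - tru) / pmax(tru, 1)), 1e-6)
})

test_that("imputation fills non-detects with the per-species dataset minimum", {
  conc <- matrix(c(5.3e2, 8e3, 0, 1e6,
                   2e6,   3e6, 4e6, 5e6), 2, byrow = TRUE,
                 dimnames = list(c("E. faecalis", "other"), paste0("s", 1:4)))
  det <- conc > 0
  res <- imputeNondetects(list(concentration = conc, detected = det))
  # the E. faecalis dataset minimum (5.3e2 bacteria/g) fills its non-detect
  expect_equal(res$concentration["E. faecalis", "s3"], 5.3e2)
  expect_true(res$imputed["E. faecalis", "s3"])
  expect_equal(res$concentration[det], conc[det])   # detected untouched
  expect_true(all(res$concentration >= conc))       # monotone
  again <- imputeNondetects(res)
  expect_equal(again$concentration, res$concentration)  # idempotent
  expect_false(any(again$imputed & res$detected))
  # two non-detects in different samples receive the same minimum
  conc2 <- conc; conc2["E. faecalis", c(2, 3)] <- 0
  res2 <- imputeNondetects(list(concentration = conc2, detected = conc2 > 0))
  expect_equal(unname(res2$concentration["E. faecalis", c(2, 3)]),
               rep(min(conc2["E. faecalis", conc2["E. faecalis", ] > 0]), 2))
  # never-detected species is an explicit error
  conc3 <- conc; conc3["other", ] <- 0
  expect_error(imputeNondetects(list(concentration = conc3,
                                     detected = conc3 > 0)),
               "never detected.*other")
})

test_that("imputation leaves fully detected datasets unchanged", {
  conc <- matrix(runif(6, 1e3, 1e6), 2,
                 dimnames = list(c("a", "b"), paste0("s", 1:3)))
  res <- imputeNondetects(list(concentration = conc,
                               detected = conc > 0))
  expect_equal(res$concentration, conc)
  expect_false(any(res$imputed))
})

test_that("phage quantitation uses per-phage curves and propagates non-detects", {
  curve <- defaultStandardCurve()
  tab <- data.frame(sample_id = c("s1", "s2", "s3"),
                    assay = c("T4", "T4", "VD13"),
                    cq = c(curve@intercept, NA, curve@intercept - log2(10) * 5))
  prof <- quantifyPhage(tab, list(T4 = curve, VD13 = curve))
  expect_equal(prof$est_phage_per_g[1], 1, tolerance = 1e-9)
  expect_true(is.na(prof$est_phage_per_g[2]))
  expect_equal(prof$est_phage_per_g[3], 1e5, tolerance = 1e-9)
  expect_error(quantifyPhage(tab, list(T4 = curve)), "no standard curve")
})
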