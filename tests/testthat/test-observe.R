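twoSpeciesSetup <- function(copies = c(10L, 5L), amp = c(1, 1),
                            x = c(1e8, 1e8)) {
  xm <- matrix(x, 2, 1, dimnames = list(c("a", "b"), NULL))
  list(traj = makeTrajectory(xm), model = matchingModel(xm, copies, amp))
}

test_that("read fractions follow concentration x copy number x efficiency", {
  s <- twoSpeciesSetup()
  se <- observeCommunity(s$traj, s$model,
                         observationSettings(read_depth = Inf, qpcr_cv = 0,
                                             detection_limit = 0, seed = 1))
  counts <- SummarizedExperiment::assay(se, "counts")
  expect_equal(unname(counts[, 1] / sum(counts[, 1])), c(2/3, 1/3))
  # amplification bias shifts fractions the same way
  s2 <- twoSpeciesSetup(copies = c(5L, 5L), amp = c(1, 0.5))
  se2 <- observeCommunity(s2$traj, s2$model,
                          observationSettings(read_depth = Inf, qpcr_cv = 0,
                                              detection_limit = 0, seed = 1))
  counts2 <- SummarizedExperiment::assay(se2, "counts")
  expect_equal(unname(counts2[, 1] / sum(counts2[, 1])), c(2/3, 1/3))
})

test_that("noiseless qPCR total equals the copy-weighted community sum", {
  s <- twoSpeciesSetup()
  se <- observeCommunity(s$traj, s$model,
                         observationSettings(qpcr_cv = 0, detection_limit = 0,
                                             seed = 1))
  expect_equal(se$total_16s_per_g, 1e8 * 10 + 1e8 * 5)
})

test_that("observation is reproducible for a fixed seed and varies across seeds", {
  s <- twoSpeciesSetup()
  st <- observationSettings(seed = 42)
  se1 <- observeCommunity(s$traj, s$model, st)
  se2 <- observeCommunity(s$traj, s$model, st)
  expect_identical(SummarizedExperiment::assay(se1, "counts"),
                   SummarizedExperiment::assay(se2, "counts"))
  expect_identical(se1$total_16s_per_g, se2$total_16s_per_g)
  se3 <- observeCommunity(s$traj, s$model, observationSettings(seed = 43))
  expect_false(identical(SummarizedExperiment::assay(se1, "counts"),
                         SummarizedExperiment::assay(se3, "counts")))
})

test_that("observed read fractions stay within 3 binomial SDs of expectation", {
  xm <- matrix(c(5e8, 1e8, 1e7, 1e6), 4, 1,
               dimnames = list(paste0("s", 1:4), NULL))
  traj <- makeTrajectory(xm)
  model <- matchingModel(xm, copies = c(3L, 6L, 9L, 12L))
  w <- xm[, 1] * c(3, 6, 9, 12)
  p <- w / sum(w)
  depth <- 1e6
  # 80 fraction/seed comparisons at a 3-sigma band: allow the expected
  # handful of statistical exceedances, never a systematic bias
  violations <- 0L
  for (seed in 1:20) {
    se <- observeCommunity(traj, model,
                           observationSettings(read_depth = depth, seed = seed))
    f <- SummarizedExperiment::assay(se, "counts")[, 1] / depth
    violations <- violations +
      sum(abs(f - p) > 3 * sqrt(p * (1 - p) / depth) + 1e-12)
  }
  expect_lte(violations, 2L)
})

test_that("detection limits and degenerate samples are handled", {
  s <- twoSpeciesSetup(x = c(10, 10))   # total 16S = 150 copies/g
  se <- observeCommunity(s$traj, s$model,
                         observationSettings(qpcr_cv = 0,
                                             detection_limit = 1e3, seed = 1))
  expect_true(is.na(se$total_16s_per_g))
  empty <- makeTrajectory(matrix(0, 2, 1,
                                 dimnames = list(c("a", "b"), NULL)))
  expect_error(observeCommunity(empty, s$model, observationSettings(seed = 1)),
               "degenerate")
})

test_that("dropout cohorts emit no row for the omitted species", {
  mod <- defaultConsortium(list(phages = emptyPhageTable()))
  sc <- Scenario(setdiff(speciesNames(mod), "E. coli"),
                 sampling_days = c(1, 16.1), n_mice = 2L)
  traj <- simulateCommunity(mod, sc)
  se <- observeCommunity(traj, mod, observationSettings(seed = 1))
  expect_equal(nrow(se), 9L)
  expect_false("E. coli" %in% rownames(se))
  expect_equal(unique(se$cohort), "dropout:E. coli")
})

test_that("metabolite emission tracks producers and leaves background flat", {
  xm <- matrix(c(1e8, 1e7), 1, 2, dimnames = list("C. sporogenes", NULL))
  traj <- makeTrajectory(xm, times = c(1, 2))
  linkage <- data.frame(
    compound = c("tryptamine", "background"),
    producer = c("C. sporogenes", NA), yield = c(1, NA),
    baseline = c(NA, 500), pathway_class = "amino acid")
  met <- emitMetabolites(traj, linkage, noise_cv = 0, seed = 1)
  expect_equal(unname(met["tryptamine", ]), c(1e8, 1e7))  # 10x knockdown
  expect_equal(unname(met["background", ]), c(500, 500))
  expect_identical(met, emitMetabolites(traj, linkage, noise_cv = 0, seed = 1))
  linkage$yield[1] <- -1
  expect_error(emitMetabolites(traj, linkage, noise_cv = 0, seed = 1),
               "negative yield")
})

test_that("colony assay reports the resistant fraction and its sensitivity limit", {
  xm <- matrix(c(1e5, 0), 2, 1, dimnames = list(c("ef", "other"), NULL))
  rm_ <- xm * 0
  traj <- makeTrajectory(xm, resistant = rm_)
  a <- colonyAssay(traj, "ef", day = 1, n_colonies = 64L, seed = 1)
  expect_equal(a$fraction, 0)
  expect_equal(a$detection_limit, 1 / 64)   # the 1.6% sensitivity
  all_res <- makeTrajectory(xm * 0, resistant = xm)
  expect_equal(colonyAssay(all_res, "ef", 1, seed = 1)$fraction, 1)
  expect_error(colonyAssay(traj, "other", 1, seed = 1), "no growth")
})
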