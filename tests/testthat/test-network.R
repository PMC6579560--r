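cohortSE <- function(values, mice = 1:2) {
  conc <- matrix(rep(values, length(mice)), length(values),
                 dimnames = list(names(values), NULL))
  makeConcSE(conc, mouse = mice, day = rep(16.1, length(mice)))
}

test_that("dropout comparisons become signed, weighted influence edges", {
  full <- cohortSE(c(a = 1e7, b = 1e8, c = 1e6))
  drop_a <- cohortSE(c(b = 1e6, c = 1e7))   # b down 100x, c up 10x
  nw <- inferNetwork(list(a = drop_a), full, min_weight = 0.1)
  e <- networkEdges(nw)
  expect_equal(nrow(e), 2L)
  eb <- e[e$target == "b", ]
  expect_equal(eb$sign, "promotion")   # removal of a reduced b
  expect_equal(eb$weight, 2)
  ec <- e[e$target == "c", ]
  expect_equal(ec$sign, "repression")  # removal of a increased b
  expect_equal(ec$weight, 1)
  # identical cohorts -> no edges above any positive threshold
  nw0 <- inferNetwork(list(a = cohortSE(c(b = 1e8, c = 1e6))), full,
                      min_weight = 1e-6)
  expect_equal(nrow(networkEdges(nw0)), 0L)
  # a cohort omitting two species is malformed
  drop_two <- cohortSE(c(c = 1e6))
  expect_error(inferNetwork(list(a = drop_two), full), "malformed cohort")
})

test_that("conflation unions edges and keeps both influences on shared targets", {
  mk <- function(src, sign, targets, w = 1)
    new("InteractionNetwork",
        edges = data.frame(source = src, target = targets, sign = sign,
                           weight = w),
        reference_day = 16.1, min_weight = 0.1)
  five <- c("Am", "Bo", "Bv", "Pd", "Pm")
  ef <- mk("E. faecalis", "promotion", five)
  bf <- mk("B. fragilis", "repression", five)
  both <- conflateNetworks(list(ef, bf))
  e <- networkEdges(both)
  expect_equal(nrow(e), 10L)
  for (t in five) {
    signs <- sort(e$sign[e$target == t])
    expect_equal(signs, c("promotion", "repression"))
  }
  empty <- new("InteractionNetwork",
               edges = data.frame(source = character(), target = character(),
                                  sign = character(), weight = numeric()),
               reference_day = 16.1, min_weight = 0.1)
  expect_equal(networkEdges(conflateNetworks(list(empty, ef))),
               networkEdges(ef))
  expect_error(conflateNetworks(list(ef, ef)), "conflict")
})

test_that("predicted responses sum capped signed edge contributions", {
  nw <- new("InteractionNetwork",
            edges = data.frame(
              source = c("a", "b", "a"), target = c("t", "t", "u"),
              sign = c("promotion", "repression", "promotion"),
              weight = c(1, 1, 3)),
            reference_day = 16.1, min_weight = 0)
  # lone promotion edge: target predicted to fall by the knockdown amount
  expect_equal(predictResponse(nw, c(a = 2))[["u"]], -2)
  # contributions are capped by the edge weight
  single <- new("InteractionNetwork",
                edges = data.frame(source = "a", target = "t",
                                   sign = "promotion", weight = 2),
                reference_day = 16.1, min_weight = 0)
  expect_equal(predictResponse(single, c(a = 5))[["t"]], -2)
  # equal opposite influences nullify
  expect_equal(predictResponse(nw, c(a = 1, b = 1))[["t"]], 0)
  expect_equal(unname(predictResponse(nw, c(a = 0, b = 0))), c(0, 0))
  expect_error(predictResponse(nw, c(a = -1)), ">= 0")
  expect_error(predictResponse(nw, c(zz = 1)), "not in network")
})

test_that("predicted responses are additive in knockdowns and odd under sign flip", {
  set.seed(3)
  edges <- data.frame(
    source = rep(c("a", "b"), each = 3),
    target = rep(c("t1", "t2", "t3"), 2),
    sign = sample(c("promotion", "repression"), 6, replace = TRUE),
    weight = runif(6, 0.2, 2))
  nw <- new("InteractionNetwork", edges = edges, reference_day = 16.1,
            min_weight = 0)
  kd_a <- c(a = 0.7); kd_b <- c(b = 1.3)
  both <- predictResponse(nw, c(kd_a, kd_b))
  expect_equal(both, predictResponse(nw, kd_a) + predictResponse(nw, kd_b))
  flipped <- edges
  flipped$sign <- ifelse(edges$sign == "promotion", "repression", "promotion")
  nwf <- new("InteractionNetwork", edges = flipped, reference_day = 16.1,
             min_weight = 0)
  expect_equal(predictResponse(nwf, c(kd_a, kd_b)), -both)
})

test_that("sign recovery counts matches against ground truth", {
  nw <- new("InteractionNetwork",
            edges = data.frame(source = rep("a", 4),
                               target = c("t1", "t2", "t3", "t4"),
                               sign = c("promotion", "promotion",
                                        "repression", "repression"),
                               weight = 1),
            reference_day = 16.1, min_weight = 0)
  truth <- data.frame(source = "a", target = c("t1", "t2", "t3", "t4"),
                      true_sign = c("promotion", "repression", "promotion",
                                    "repression"))
  rep_ <- evaluateSignRecovery(nw, truth)
  expect_equal(rep_$sign_agreement, 0.5)
  expect_equal(rep_$n_edges_evaluated, 4L)
  truth$true_sign <- nw@edges$sign
  expect_equal(evaluateSignRecovery(nw, truth)$sign_agreement, 1)
  empty <- new("InteractionNetwork",
               edges = data.frame(source = character(), target = character(),
                                  sign = character(), weight = numeric()),
               reference_day = 16.1, min_weight = 0)
  er <- evaluateSignRecovery(empty, truth)
  expect_equal(er$n_edges_evaluated, 0L)
  expect_true(is.nan(er$sign_agreement))
})

test_that("noiseless dropout inference matches steady-state influence signs", {
  mod <- nullificationModel(phages = FALSE)
  st <- observationSettings(read_depth = Inf, qpcr_cv = 0,
                            detection_limit = 0, seed = 1)
  quant <- function(included) {
    sc <- Scenario(included, sampling_days = c(10, 16.1), n_mice = 2L)
    se <- observeCommunity(simulateCommunity(mod, sc), mod, st)
    imputeNondetects(estimateConcentrations(se))
  }
  full <- quant(speciesNames(mod))
  drops <- list(promoter = quant(c("repressor", "target")),
                repressor = quant(c("promoter", "target")))
  nw <- inferNetwork(drops, full, day = 16.1, min_weight = 0.05)
  truth <- steadyStateInfluence(mod, c("promoter", "repressor"))
  ev <- evaluateSignRecovery(nw, truth)
  expect_gt(ev$n_edges_evaluated, 0L)
  expect_equal(ev$sign_agreement, 1)
  e <- networkEdges(nw)
  expect_equal(e$sign[e$source == "promoter" & e$target == "target"],
               "promotion")
  expect_equal(e$sign[e$source == "repressor" & e$target == "target"],
               "repression")
})
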