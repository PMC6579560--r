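# Fixture builders shared across the test files. Everything is generated
# in code; no data files.

# single-species logistic community: equilibrium at -r/a
logisticModel <- function(r = 1, a = -1e-9, inoculum = 2e7,
                          phages = emptyPhageTable()) {
  sp <- data.frame(name = "solo", growth_rate = r, copies_16s = 10L,
                   inoculum = inoculum, amp_efficiency = 1)
  GLVModel(sp, matrix(a, 1, 1), phages)
}

# n non-interacting logistic species
decoupledModel <- function(r, a, inoculum = 2e7) {
  n <- length(r)
  sp <- data.frame(name = paste0("sp", seq_len(n)), growth_rate = r,
                   copies_16s = 5L, inoculum = inoculum,
                   amp_efficiency = 1)
  GLVModel(sp, diag(a, n))
}

# hand-built trajectory (bypasses the integrator)
makeTrajectory <- function(x, times = seq_len(ncol(x)), resistant = NULL,
                           phage = NULL, n_mice = 1L) {
  sc <- Scenario(rownames(x), sampling_days = times, n_mice = n_mice)
  if (is.null(resistant)) resistant <- x * 0
  if (is.null(phage)) phage <- matrix(0, 0, ncol(x))
  new("CommunityTrajectory", times = as.numeric(times), susceptible = x,
      resistant = resistant, phage = phage, scenario = sc)
}

# minimal model matching a hand-built trajectory's species
matchingModel <- function(x, copies = rep(5L, nrow(x)),
                          amp = rep(1, nrow(x))) {
  n <- nrow(x)
  sp <- data.frame(name = rownames(x), growth_rate = 1,
                   copies_16s = copies, inoculum = 1e7,
                   amp_efficiency = amp)
  GLVModel(sp, diag(-1e-9, n))
}

# SummarizedExperiment with a concentration assay, for the analysis modules
makeConcSE <- function(conc, mouse, day) {
  cd <- S4Vectors::DataFrame(
    sample_id = sprintf("m%d_d%s", mouse, formatC(day, format = "fg")),
    mouse = mouse, day = day)
  colnames(conc) <- cd$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = conc), colData = cd)
}

# SummarizedExperiment with a counts assay, for the stability module
makeCountSE <- function(counts, mouse, day) {
  cd <- S4Vectors::DataFrame(
    sample_id = sprintf("m%d_d%s", mouse, formatC(day, format = "fg")),
    mouse = mouse, day = day)
  colnames(counts) <- cd$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

# independent brute-force Bray-Curtis (the printed formula, written naively)
bruteBray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + (x[i] + y[i])
  }
  unname(num / den)
}

# independent brute-force BH step-up
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# default-consortium trajectories are expensive enough to share
cachedDefaultTrajectory <- local({
  traj <- NULL
  function() {
    if (is.null(traj)) {
      mod <- defaultConsortium()
      traj <<- simulateCommunity(mod, defaultScenario(mod))
    }
    traj
  }
})

# fresh scratch directory under the session tempdir (cleaned up on exit)
freshTempDir <- function() {
  d <- tempfile("phagedyn_test_")
  dir.create(d)
  d
}
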