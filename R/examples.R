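#' Constructed three-species nullification community
#'
#' A minimal community for studying counteracting influences: a promoter
#' and a repressor exert opposite-sign net influences of equal magnitude
#' (\code{strength}, as a fraction of the target's baseline rate) on a
#' common target species, and each influencer carries an identical lytic
#' phage dosed at \code{dose_day}. Knocking down both influencers
#' simultaneously removes equal amounts of promotion and repression, so
#' the target's response nullifies, while either single knockdown moves
#' the target appreciably.
#'
#' @param strength dimensionless influence magnitude (default 0.5).
#' @param dose_day phage dose day (default 16.1).
#' @param phages include the two phages (set FALSE for the phage-free
#'   model used in steady-state comparisons).
#' @return a [GLVModel-class] with species \code{promoter},
#'   \code{repressor}, \code{target}.
#' @export
nullificationModel <- function(strength = 0.5, dose_day = 16.1,
                               phages = TRUE) {
  nm <- c("promoter", "repressor", "target")
  xstar <- c(promoter = 1e8, repressor = 1e8, target = 1e7)
  r0 <- c(1, 1, 1)
  s <- matrix(0, 3, 3, dimnames = list(nm, nm))
  s["target", "promoter"] <- strength
  s["target", "repressor"] <- -strength
  A <- s * (r0 / rep(xstar, each = 3))
  diag(A) <- -r0 / xstar
  species <- data.frame(name = nm, growth_rate = as.numeric(-A %*% xstar),
                        copies_16s = 5L, inoculum = 2e7,
                        amp_efficiency = 1)
  ph <- if (phages) data.frame(
    name = c("phiP", "phiR"), target = c("promoter", "repressor"),
    kill_rate = 2e-9, burst = 25, decay = 0.15, mutation_rate = 1e-9,
    resistance_cost = 0.1, dose = 2e6, dose_day = dose_day)
  else emptyPhageTable()
  GLVModel(species, A, ph)
}
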