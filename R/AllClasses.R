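#' @import methods
#' @importFrom stats rbinom rmultinom rnorm rlnorm runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Ground-truth phage--bacteria community model
#'
#' A generalized Lotka-Volterra (gLV) community with lytic phage predation.
#' Bacterial species grow per-capita at \eqn{r_i + \sum_j a_{ij} x_j}, where
#' \eqn{a_{ij}} is the effect of species \eqn{j} on species \eqn{i} (per
#' (cfu/g) per day) and \eqn{x_j} is the total (susceptible + resistant)
#' concentration of species \eqn{j}. Each phage kills its susceptible target
#' by mass action, replicates with a burst size, decays first-order, and is
#' dosed as an instantaneous addition at its dose day.
#'
#' @slot species data.frame with one row per species and columns
#'   \code{name}, \code{growth_rate} (per day), \code{copies_16s} (16S rRNA
#'   gene copies per genome, integer >= 1), \code{inoculum} (cfu per gavage
#'   dose), \code{amp_efficiency} (relative universal-16S qPCR amplification
#'   factor in [0, 1]).
#' @slot interactions square numeric matrix \eqn{a_{ij}} with dimnames equal
#'   to the species names; entry (i, j) is the effect of species j on the
#'   per-capita growth of species i.
#' @slot phages data.frame with one row per phage and columns \code{name},
#'   \code{target} (a species name), \code{kill_rate} (per (pfu/g) per day),
#'   \code{burst} (progeny per lysed cell), \code{decay} (per day),
#'   \code{mutation_rate} (per-division resistance probability),
#'   \code{resistance_cost} (fractional growth-rate reduction in [0, 1)),
#'   \code{dose} (pfu), \code{dose_day} (decimal day). May have zero rows.
#'
#' @seealso [GLVModel()], [defaultConsortium()], [simulateCommunity()]
#' @export
setClass("GLVModel",
  representation(species = "data.frame",
                 interactions = "matrix",
                 phages = "data.frame"))

setValidity("GLVModel", function(object) {
  sp <- object@species
  need <- c("name", "growth_rate", "copies_16s", "inoculum", "amp_efficiency")
  if (!all(need %in% names(sp)))
    return(paste("species table must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp) < 1L) return("at least one species required")
  if (anyDuplicated(sp$name)) return("duplicated species names")
  if (any(sp$copies_16s < 1)) return("copies_16s must be >= 1")
  if (any(sp$inoculum < 0)) return("inoculum must be >= 0")
  if (any(sp$amp_efficiency < 0 | sp$amp_efficiency > 1))
    return("amp_efficiency must lie in [0, 1]")
  A <- object@interactions
  if (nrow(A) != ncol(A)) return("interaction matrix must be square")
  if (nrow(A) != nrow(sp))
    return("interaction matrix side must equal the number of species")
  if (is.null(rownames(A)) || !identical(rownames(A), sp$name) ||
      !identical(colnames(A), sp$name))
    return("interaction matrix dimnames must equal the species names, in order")
  ph <- object@phages
  pneed <- c("name", "target", "kill_rate", "burst", "decay",
             "mutation_rate", "resistance_cost", "dose", "dose_day")
  if (!all(pneed %in% names(ph)))
    return(paste("phage table must have columns:", paste(pneed, collapse = ", ")))
  if (nrow(ph) > 0L) {
    if (anyDuplicated(ph$name)) return("duplicated phage names")
    bad <- setdiff(ph$target, sp$name)
    if (length(bad))
      return(paste("phage targets not in the consortium:", paste(bad, collapse = ", ")))
    if (any(ph$kill_rate < 0) || any(ph$burst < 0) || any(ph$decay < 0))
      return("kill_rate, burst and decay must be >= 0")
    if (any(ph$mutation_rate < 0 | ph$mutation_rate > 1))
      return("mutation_rate must lie in [0, 1]")
    if (any(ph$resistance_cost < 0 | ph$resistance_cost >= 1))
      return("resistance_cost must lie in [0, 1)")
  }
  TRUE
})

#' Experimental scenario: which species, which mice, which sampling days
#'
#' @slot included_species character vector of species colonized at
#'   \code{colonization_day}; a 9-member subset of a 10-member consortium is
#'   a dropout cohort.
#' @slot colonization_day decimal day of the bacterial gavage.
#' @slot sampling_days strictly increasing decimal days of stool collection.
#' @slot duration total simulated days.
#' @slot n_mice number of mice in the cohort.
#' @slot mouse_seed_offsets integer offsets added to the master seed to give
#'   each mouse its own observation-noise stream.
#'
#' @seealso [Scenario()], [defaultScenario()]
#' @export
setClass("Scenario",
  representation(included_species = "character",
                 colonization_day = "numeric",
                 sampling_days = "numeric",
                 duration = "numeric",
                 n_mice = "integer",
                 mouse_seed_offsets = "integer"))

setValidity("Scenario", function(object) {
  if (length(object@included_species) < 1L)
    return("included_species must be non-empty")
  d <- object@sampling_days
  if (length(d) < 1L || any(diff(d) <= 0))
    return("sampling_days must be strictly increasing")
  if (object@n_mice < 1L) return("n_mice must be >= 1")
  if (length(object@mouse_seed_offsets) != object@n_mice)
    return("mouse_seed_offsets must have one entry per mouse")
  if (object@duration < max(d)) return("duration must cover the sampling days")
  TRUE
})

#' Ground-truth trajectory of a simulated community
#'
#' Concentrations evaluated at the scenario's sampling days. Rows of the
#' bacterial matrices are species (all model species; species excluded from
#' the scenario are identically zero), columns are time points.
#'
#' @slot times decimal days (the scenario sampling grid).
#' @slot susceptible species x time matrix of phage-susceptible cfu/g.
#' @slot resistant species x time matrix of phage-resistant cfu/g.
#' @slot phage phage x time matrix of pfu/g (zero rows if no phages).
#' @slot scenario the [Scenario-class] that produced the trajectory.
#' @export
setClass("CommunityTrajectory",
  representation(times = "numeric",
                 susceptible = "matrix",
                 resistant = "matrix",
                 phage = "matrix",
                 scenario = "Scenario"))

setValidity("CommunityTrajectory", function(object) {
  nt <- length(object@times)
  if (ncol(object@susceptible) != nt || ncol(object@resistant) != nt)
    return("bacterial matrices must have one column per time point")
  if (nrow(object@phage) > 0L && ncol(object@phage) != nt)
    return("phage matrix must have one column per time point")
  if (!identical(dim(object@susceptible), dim(object@resistant)))
    return("susceptible and resistant matrices must have identical shape")
  vals <- c(object@susceptible, object@resistant, object@phage)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("all concentrations must be finite and >= 0")
  TRUE
})

#' @describeIn CommunityTrajectory-class constructor from concentration
#'   matrices (useful for observation-layer studies that do not need the
#'   integrator).
#' @param susceptible species x time matrix of susceptible cfu/g.
#' @param times decimal days, one per column.
#' @param resistant optional species x time matrix (default all zero).
#' @param phage optional phage x time matrix (default none).
#' @param n_mice number of mice for downstream observation.
#' @export
CommunityTrajectory <- function(susceptible, times = seq_len(ncol(susceptible)),
                                resistant = susceptible * 0,
                                phage = matrix(0, 0, ncol(susceptible)),
                                n_mice = 1L) {
  sc <- Scenario(rownames(susceptible), sampling_days = times,
                 n_mice = n_mice)
  new("CommunityTrajectory", times = as.numeric(times),
      susceptible = susceptible, resistant = resistant, phage = phage,
      scenario = sc)
}

#' qPCR standard curve
#'
#' Linear fit Cq = intercept + slope * log10(copies). Slope is negative; a
#' slope of -log2(10) = -3.3219 corresponds to perfect per-cycle doubling
#' (100\% amplification efficiency, E = 10^(-1/slope) - 1).
#'
#' @slot slope Cq per log10(copies), < 0.
#' @slot intercept Cq at 1 copy.
#' @slot r_squared coefficient of determination of the fit.
#' @slot n_points number of calibration points used.
#' @seealso [fitStandardCurve()], [quantifyCopies()]
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 r_squared = "numeric", n_points = "integer"))

setValidity("StandardCurve", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope >= 0)
    return("slope must be a single negative number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (object@r_squared < 0 || object@r_squared > 1 + 1e-12)
    return("r_squared must lie in [0, 1]")
  TRUE
})

#' Hypothesized interbacterial influence network
#'
#' Signed, weighted net-influence edges inferred from dropout-versus-full
#' colonization comparisons. The edge source is the dropped-out species;
#' promotion means its removal reduced the target, repression means its
#' removal increased the target. Weights are |log10 fold change|, so each
#' edge is an upper limit on what a phage knockdown of the source can do to
#' the target. These are net (direct + mediated) influences, not direct
#' interaction coefficients.
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} ("promotion" or "repression") and \code{weight} (>= 0).
#' @slot reference_day decimal day of the compared samples.
#' @slot min_weight weight threshold below which edges were omitted.
#' @seealso [inferNetwork()], [predictResponse()]
#' @export
setClass("InteractionNetwork",
  representation(edges = "data.frame",
                 reference_day = "numeric",
                 min_weight = "numeric"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  need <- c("source", "target", "sign", "weight")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) > 0L) {
    if (any(e$source == e$target)) return("self-edges are not allowed")
    if (any(e$weight < 0)) return("edge weights must be >= 0")
    if (!all(e$sign %in% c("promotion", "repression")))
      return('edge sign must be "promotion" or "repression"')
    if (anyDuplicated(e[, c("source", "target")]))
      return("at most one edge per (source, target) pair")
  }
  TRUE
})
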