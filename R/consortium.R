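#' Construct a GLVModel
#'
#' Low-level constructor; most users start from [defaultConsortium()].
#'
#' @param species data.frame of species parameters (see [GLVModel-class]).
#' @param interactions square interaction matrix with species names as
#'   dimnames (dimnames are added from \code{species$name} if missing).
#' @param phages data.frame of phage parameters; defaults to no phages.
#' @return a validated [GLVModel-class] object.
#' @examples
#' sp <- data.frame(name = "E. coli", growth_rate = 1, copies_16s = 10,
#'                  inoculum = 2e7, amp_efficiency = 1)
#' GLVModel(sp, matrix(-1e-9, 1, 1))
#' @export
GLVModel <- function(species, interactions, phages = emptyPhageTable()) {
  species <- as.data.frame(species)
  interactions <- as.matrix(interactions)
  if (is.null(rownames(interactions)))
    dimnames(interactions) <- list(species$name, species$name)
  new("GLVModel", species = species, interactions = interactions,
      phages = as.data.frame(phages))
}

#' @rdname GLVModel
#' @export
emptyPhageTable <- function() {
  data.frame(name = character(), target = character(), kill_rate = numeric(),
             burst = numeric(), decay = numeric(), mutation_rate = numeric(),
             resistance_cost = numeric(), dose = numeric(),
             dose_day = numeric())
}

#' Construct a Scenario
#'
#' @param included_species species colonized at \code{colonization_day}.
#' @param sampling_days strictly increasing decimal days of stool sampling.
#' @param colonization_day decimal day of the bacterial gavage (default 0).
#' @param duration total simulated days (default: last sampling day).
#' @param n_mice number of mice in the cohort.
#' @param mouse_seed_offsets per-mouse integer offsets added to the master
#'   seed for observation noise (default \code{0:(n_mice-1)}).
#' @return a validated [Scenario-class] object.
#' @export
Scenario <- function(included_species, sampling_days, colonization_day = 0,
                     duration = max(sampling_days), n_mice = 5L,
                     mouse_seed_offsets = seq_len(n_mice) - 1L) {
  new("Scenario", included_species = included_species,
      colonization_day = colonization_day,
      sampling_days = as.numeric(sampling_days),
      duration = duration, n_mice = as.integer(n_mice),
      mouse_seed_offsets = as.integer(mouse_seed_offsets))
}

# Canonical ten-member consortium, in fixed order.
consortiumNames <- function() {
  c("A. muciniphila", "B. fragilis", "B. ovatus", "B. vulgatus",
    "C. sporogenes", "E. faecalis", "E. coli", "K. oxytoca",
    "P. distasonis", "P. mirabilis")
}

#' Stool collection grids of the longitudinal and dropout experiments
#'
#' Decimal days of stool sampling: 41 time points over 43.1 days for the
#' longitudinal phage-perturbation cohort (phage doses at days 16.1 and
#' 30.1), and 6 time points to day 16.1 for the dropout cohorts.
#' @return numeric vector of decimal days.
#' @export
longitudinalSamplingDays <- function() {
  c(0.3, 0.5, 1.1, 1.3, 2.2, 2.3, 3.1, 5.1, 7.1, 8.1, 9.0, 11.0, 13.3,
    14.1, 15.1, 16.1, 16.3, 17.1, 17.3, 18.1, 18.3, 19.1, 21.1, 23.1,
    25.1, 27.1, 28.1, 29.1, 30.4, 30.5, 31.1, 31.3, 32.1, 32.3, 33.3,
    35.1, 37.1, 39.1, 40.1, 42.1, 43.1)
}

#' @rdname longitudinalSamplingDays
#' @export
dropoutSamplingDays <- function() c(0.3, 1.1, 3.1, 7.1, 11.1, 16.1)

#' Default ten-species consortium with four lytic phages
#'
#' Builds the ground-truth community model: ten human gut commensals
#' spanning Firmicutes, Bacteroidetes, Proteobacteria and Verrucomicrobia,
#' with rrnDB 16S copy numbers (A. muciniphila 3, B. fragilis 6, B. ovatus
#' 5, B. vulgatus 7, C. sporogenes 9, E. faecalis 4, E. coli 10, K. oxytoca
#' 8, P. distasonis 7, P. mirabilis 7), gavage inocula of 2e6 cfu
#' (A. muciniphila, P. mirabilis) or 2e7 cfu (all others), and four lytic
#' phages dosed at 2e6 pfu each: T4 (E. coli) and F1 (C. sporogenes) at day
#' 16.1, VD13 (E. faecalis) and B40-8 (B. fragilis) at day 30.1.
#'
#' The interaction matrix is parameterized around a target coexistence
#' equilibrium \eqn{x^*} (total about 1e9 cfu/g): off-diagonal entries are
#' \eqn{a_{ij} = s_{ij} r^0_i / x^*_j} with dimensionless influence
#' strengths \eqn{s_{ij}}, diagonals \eqn{a_{ii} = -r^0_i / x^*_i}, and
#' growth rates \eqn{r = -A x^*}, so \eqn{x^*} is exactly the phage-free
#' equilibrium. The sign structure of \eqn{s} (E. coli promoting
#' B. fragilis and repressing B. vulgatus, P. distasonis and P. mirabilis;
#' C. sporogenes promoting P. distasonis and P. mirabilis; B. fragilis
#' repressing and E. faecalis promoting the same five low-abundance
#' species) is the ground truth against which dropout-based network
#' inference is validated.
#'
#' @param overrides named list of replacements. Per-species numeric fields
#'   (\code{growth_rate}, \code{copies_16s}, \code{inoculum},
#'   \code{amp_efficiency}) take named vectors replacing only the named
#'   species; \code{interactions} a full replacement matrix; \code{phages}
#'   a replacement phage table (or \code{emptyPhageTable()} to remove all
#'   phages); \code{equilibrium} a named vector of target equilibrium
#'   concentrations; \code{influence} a full replacement of the
#'   dimensionless strength matrix. Unknown keys are an error.
#' @return a [GLVModel-class].
#' @examples
#' mod <- defaultConsortium()
#' speciesTable(mod)[speciesTable(mod)$name == "E. coli", "copies_16s"]
#' nophage <- defaultConsortium(list(phages = emptyPhageTable()))
#' @export
defaultConsortium <- function(overrides = list()) {
  known <- c("growth_rate", "copies_16s", "inoculum", "amp_efficiency",
             "interactions", "phages", "equilibrium", "influence")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stopNamed("unknown override parameter(s): %s (known: %s)",
              paste(bad, collapse = ", "), paste(known, collapse = ", "))

  nm <- consortiumNames()
  n <- length(nm)
  species <- data.frame(
    name = nm,
    growth_rate = NA_real_,
    copies_16s = c(3L, 6L, 5L, 7L, 9L, 4L, 10L, 8L, 7L, 7L),
    inoculum = ifelse(nm %in% c("A. muciniphila", "P. mirabilis"), 2e6, 2e7),
    # universal-16S qPCR amplification bias; P. distasonis is poorly
    # amplified by the universal primers
    amp_efficiency = ifelse(nm == "P. distasonis", 0.2, 1))

  # target coexistence equilibrium (cfu/g), total ~1.1e9
  xstar <- c("A. muciniphila" = 2e8, "B. fragilis" = 1e7, "B. ovatus" = 3e8,
             "B. vulgatus" = 5e6, "C. sporogenes" = 1e8, "E. faecalis" = 1e5,
             "E. coli" = 2e8, "K. oxytoca" = 2e8, "P. distasonis" = 3e6,
             "P. mirabilis" = 2e6)
  if (!is.null(overrides$equilibrium)) {
    repl <- overrides$equilibrium
    checkSpeciesNames(names(repl), nm, "equilibrium")
    xstar[names(repl)] <- repl
  }

  # baseline per-capita rates setting the self-limitation scale
  r0 <- c(0.8, 0.7, 0.9, 0.9, 1.0, 0.8, 1.2, 1.0, 0.7, 0.9)
  names(r0) <- nm

  # dimensionless net influence strengths s[i, j]: effect of species j on
  # species i, as a fraction of r0_i lost/gained when j is at equilibrium
  s <- matrix(0, n, n, dimnames = list(nm, nm))
  s["B. fragilis",    "E. coli"] <-  0.6
  s["B. vulgatus",    "E. coli"] <- -1.5
  s["P. distasonis",  "E. coli"] <- -0.6
  s["A. muciniphila", "E. coli"] <- -0.6
  s["P. mirabilis",   "E. coli"] <- -0.8
  s["B. ovatus",      "E. coli"] <- -0.5
  s["P. distasonis",  "C. sporogenes"] <-  0.8
  s["P. mirabilis",   "C. sporogenes"] <-  0.4
  s["A. muciniphila", "C. sporogenes"] <- -0.4
  lowfive <- c("A. muciniphila", "B. ovatus", "B. vulgatus",
               "P. distasonis", "P. mirabilis")
  s[lowfive, "B. fragilis"] <- -0.5
  s[lowfive, "E. faecalis"] <-  0.5
  if (!is.null(overrides$influence)) s <- overrides$influence

  A <- s * (r0 / rep(xstar, each = n))   # a_ij = s_ij * r0_i / xstar_j
  diag(A) <- -r0 / xstar
  if (!is.null(overrides$interactions)) A <- overrides$interactions
  species$growth_rate <- as.numeric(-A %*% xstar)

  phages <- data.frame(
    name = c("T4", "F1", "VD13", "B40-8"),
    target = c("E. coli", "C. sporogenes", "E. faecalis", "B. fragilis"),
    # burst*kill sets the phage amplification rate on the pre-dose target
    # (fast for T4, slow for F1) and decay the post-knockdown persistence
    kill_rate = c(2e-9, 2e-9, 8e-7, 3e-8),
    burst = c(25, 15, 15, 15),
    decay = c(0.15, 0.6, 0.15, 0.15),
    # F1/VD13 resistance emerges quickly (transient C. sporogenes
    # knockdown; E. faecalis resistant-subpopulation takeover); T4 and
    # B40-8 resistance is rare (durable knockdowns)
    mutation_rate = c(1e-9, 1e-4, 3e-3, 1e-8),
    resistance_cost = c(0.1, 0.05, 0.05, 0.1),
    dose = rep(2e6, 4),
    dose_day = c(16.1, 16.1, 30.1, 30.1))

  for (field in c("growth_rate", "copies_16s", "inoculum", "amp_efficiency")) {
    if (!is.null(overrides[[field]])) {
      repl <- overrides[[field]]
      checkSpeciesNames(names(repl), nm, field)
      species[[field]][match(names(repl), nm)] <- repl
    }
  }
  if (!is.null(overrides$phages)) phages <- overrides$phages

  GLVModel(species, A, phages)
}

checkSpeciesNames <- function(given, known, what) {
  if (is.null(given) || any(!nzchar(given)))
    stopNamed("override '%s' must be a named vector of species values", what)
  bad <- setdiff(given, known)
  if (length(bad))
    stopNamed("override '%s' names unknown species: %s", what,
              paste(bad, collapse = ", "))
}

#' Default experimental scenarios
#'
#' \code{defaultScenario()} is the longitudinal phage-perturbation design:
#' all species colonized at day 0, five mice, 41 stool samples to day 43.1.
#' \code{dropoutScenario()} is a nine-member dropout cohort: one species
#' omitted, five mice, six stool samples to day 16.1.
#'
#' @param model a [GLVModel-class].
#' @param n_mice mice per cohort.
#' @param omit species name omitted from the dropout consortium.
#' @return a [Scenario-class].
#' @export
defaultScenario <- function(model, n_mice = 5L) {
  Scenario(speciesNames(model), longitudinalSamplingDays(), n_mice = n_mice)
}

#' @rdname defaultScenario
#' @export
dropoutScenario <- function(model, omit, n_mice = 5L) {
  nm <- speciesNames(model)
  if (!omit %in% nm) stopNamed("unknown species to omit: %s", omit)
  Scenario(setdiff(nm, omit), dropoutSamplingDays(), n_mice = n_mice)
}
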