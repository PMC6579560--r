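#' Observation-model settings
#'
#' Parameters of the noisy measurement layer applied to a ground-truth
#' trajectory: 16S amplicon sequencing (multinomial reads weighted by true
#' concentration x 16S copy number x amplification efficiency),
#' universal-16S qPCR (lognormal multiplicative noise with mean 1 and the
#' given coefficient of variation), phage-specific qPCR (one genome per
#' particle), per-sample stool mass, and a detection limit below which
#' qPCR values are reported as non-detected.
#'
#' @param read_depth reads per sample; \code{Inf} emits the infinite-depth
#'   expectation (expected fractions scaled to 1e6 pseudo-reads).
#' @param qpcr_cv lognormal coefficient of variation of qPCR measurements.
#' @param detection_limit copies/g below which a qPCR value is non-detected.
#' @param stool_mass_mean,stool_mass_cv lognormal per-sample stool mass (g).
#' @param dilution_factor template dilution applied before qPCR.
#' @param seed master seed; per-mouse streams are seed + mouse offset.
#' @return a list of class \code{"ObservationSettings"}.
#' @export
observationSettings <- function(read_depth = 5e4, qpcr_cv = 0.25,
                                detection_limit = 1e3,
                                stool_mass_mean = 0.05, stool_mass_cv = 0.2,
                                dilution_factor = 100, seed = 1L) {
  if (read_depth < 1) stopNamed("read_depth must be >= 1")
  if (qpcr_cv < 0) stopNamed("qpcr_cv must be >= 0")
  if (detection_limit < 0) stopNamed("detection_limit must be >= 0")
  structure(list(read_depth = read_depth, qpcr_cv = qpcr_cv,
                 detection_limit = detection_limit,
                 stool_mass_mean = stool_mass_mean,
                 stool_mass_cv = stool_mass_cv,
                 dilution_factor = dilution_factor, seed = seed),
            class = "ObservationSettings")
}

#' Emit noisy observed tables from a ground-truth trajectory
#'
#' Per sample (one mouse at one sampling day), sequencing reads are drawn
#' multinomially with probabilities proportional to
#' \eqn{x_i n_i e_i} (true concentration x 16S copies per genome x
#' amplification efficiency); the universal-16S qPCR total is
#' \eqn{(\sum_i x_i n_i e_i) \cdot LN(1, cv)} copies/g and each phage qPCR
#' value is \eqn{P_p \cdot LN(1, cv)} genomes/g (one genome per particle).
#' qPCR values below the detection limit are reported as NA (non-detected).
#' Only species included in the trajectory's scenario are emitted (a
#' dropout cohort's count table has no row for the omitted species).
#' Output is reproducible for a fixed seed; each mouse uses the stream
#' seed + mouse_seed_offset.
#'
#' @param traj a [CommunityTrajectory-class].
#' @param model the [GLVModel-class] that produced it.
#' @param settings an [observationSettings()] list.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   \code{counts} (reads; expected fractional reads when
#'   \code{read_depth = Inf}) and \code{truth} (true cfu/g), rowData
#'   \code{copies_16s} and \code{amp_efficiency}, and colData
#'   \code{sample_id}, \code{mouse}, \code{day}, \code{cohort},
#'   \code{stool_mass_g}, \code{dilution}, \code{total_16s_per_g} and one
#'   \code{phage_<name>_per_g} column per phage.
#' @export
observeCommunity <- function(traj, model, settings = observationSettings()) {
  if (is.null(settings$seed)) stopNamed("settings$seed must be set")
  sc <- traj@scenario
  nm <- speciesNames(model)
  inc <- intersect(nm, sc@included_species)
  sp <- speciesTable(model)
  idx <- match(inc, nm)
  x <- abundances(traj, "total")[idx, , drop = FALSE]
  P <- abundances(traj, "phage")
  weight_per_cell <- sp$copies_16s[idx] * sp$amp_efficiency[idx]

  days <- trajectoryTimes(traj)
  n_mice <- sc@n_mice
  samples <- expand.grid(day_i = seq_along(days), mouse = seq_len(n_mice))
  ns <- nrow(samples)

  counts <- matrix(0, length(inc), ns, dimnames = list(inc, NULL))
  truth <- matrix(0, length(inc), ns, dimnames = list(inc, NULL))
  total <- numeric(ns)
  mass <- numeric(ns)
  phmat <- matrix(NA_real_, nrow(P), ns)

  cohort <- if (length(inc) == length(nm)) "full" else
    paste0("dropout:", setdiff(nm, inc)[1L])

  for (m in seq_len(n_mice)) {
    sel <- which(samples$mouse == m)
    withSeed(settings$seed + sc@mouse_seed_offsets[m], {
      for (k in seq_along(sel)) {
        j <- sel[k]
        ti <- samples$day_i[j]
        xi <- x[, ti]
        truth[, j] <- xi
        w <- xi * weight_per_cell
        if (sum(w) <= 0) {
          if (settings$read_depth > 0)
            stopNamed("degenerate sample: zero total community for mouse %d at day %.1f",
                      m, days[ti])
        } else if (is.finite(settings$read_depth)) {
          counts[, j] <- drop(rmultinom(1, size = settings$read_depth,
                                        prob = w / sum(w)))
        } else {
          counts[, j] <- 1e6 * w / sum(w)
        }
        tot <- sum(w) * lnFactor(1, settings$qpcr_cv)
        total[j] <- if (tot >= settings$detection_limit) tot else NA_real_
        if (nrow(P) > 0L) {
          pv <- P[, ti] * lnFactor(nrow(P), settings$qpcr_cv)
          pv[pv < settings$detection_limit] <- NA_real_
          phmat[, j] <- pv
        }
        mass[j] <- settings$stool_mass_mean *
          lnFactor(1, settings$stool_mass_cv)
      }
    })
  }

  cd <- S4Vectors::DataFrame(
    sample_id = sprintf("m%d_d%s", samples$mouse, formatC(days[samples$day_i],
                                                          format = "fg")),
    mouse = samples$mouse,
    day = days[samples$day_i],
    cohort = cohort,
    stool_mass_g = mass,
    dilution = settings$dilution_factor,
    total_16s_per_g = total)
  if (nrow(P) > 0L)
    for (p in seq_len(nrow(P)))
      cd[[paste0("phage_", rownames(P)[p], "_per_g")]] <- phmat[p, ]
  colnames(counts) <- colnames(truth) <- cd$sample_id
  rd <- S4Vectors::DataFrame(copies_16s = sp$copies_16s[idx],
                             amp_efficiency = sp$amp_efficiency[idx],
                             row.names = inc)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, truth = truth),
    rowData = rd, colData = cd)
}

#' Default metabolite--producer linkage
#'
#' Compound-to-producer map used by [emitMetabolites()]. Tryptamine is
#' uniquely produced by C. sporogenes (tryptophan decarboxylation) and
#' tyramine by E. faecalis (tyrosine decarboxylation), the consortium's
#' sole lactic acid bacterium; a handful of further compounds are linked to
#' other members, and the remainder are unlinked host/background compounds
#' with constant expected level.
#'
#' @param n_unlinked number of unlinked background compounds.
#' @param yield arbitrary-units yield per producer cfu/g.
#' @param baseline expected level of unlinked compounds.
#' @return data.frame with columns \code{compound}, \code{producer} (NA for
#'   unlinked), \code{yield}, \code{baseline}, \code{pathway_class}.
#' @export
defaultMetaboliteLinkage <- function(n_unlinked = 40L, yield = 1e-5,
                                     baseline = 1e3) {
  linked <- data.frame(
    compound = c("tryptamine", "tyramine", "mucin-glycan product",
                 "propionate analog"),
    producer = c("C. sporogenes", "E. faecalis", "A. muciniphila",
                 "B. ovatus"),
    yield = yield, baseline = NA_real_,
    pathway_class = c("amino acid", "amino acid", "carbohydrate", "lipid"))
  unlinked <- data.frame(
    compound = sprintf("background_%03d", seq_len(n_unlinked)),
    producer = NA_character_, yield = NA_real_, baseline = baseline,
    pathway_class = rep(c("amino acid", "lipid", "carbohydrate",
                          "nucleotide", "xenobiotics"),
                        length.out = n_unlinked))
  rbind(linked, unlinked)
}

#' Emit a noisy metabolite table from a trajectory
#'
#' Linked compounds track their producer: expected level =
#' yield x producer concentration; unlinked compounds have a constant
#' expected baseline. Every level is multiplied by lognormal noise with
#' mean 1 and coefficient of variation \code{noise_cv}, independently per
#' compound, mouse and day.
#'
#' @param traj a [CommunityTrajectory-class].
#' @param linkage data.frame as returned by [defaultMetaboliteLinkage()].
#' @param noise_cv lognormal coefficient of variation.
#' @param seed master seed (per-mouse streams as in [observeCommunity()]).
#' @return matrix compounds x samples (same sample naming as
#'   [observeCommunity()]), with the pathway classes in
#'   \code{attr(, "pathway_class")}.
#' @export
emitMetabolites <- function(traj, linkage = defaultMetaboliteLinkage(),
                            noise_cv = 0.3, seed = 1L) {
  linked <- !is.na(linkage$producer)
  if (any(linkage$yield[linked] < 0)) stopNamed("negative yield")
  sc <- traj@scenario
  x <- abundances(traj, "total")
  bad <- setdiff(linkage$producer[linked], rownames(x))
  if (length(bad))
    stopNamed("linkage producers not in the model: %s",
              paste(bad, collapse = ", "))
  days <- trajectoryTimes(traj)
  nc <- nrow(linkage)
  # expected level per compound x day
  mu <- matrix(rep(linkage$baseline, length(days)), nc)
  mu[linked, ] <- linkage$yield[linked] *
    x[linkage$producer[linked], , drop = FALSE]

  out <- NULL
  ids <- NULL
  for (m in seq_len(sc@n_mice)) {
    block <- withSeed(seed + sc@mouse_seed_offsets[m],
                      mu * matrix(lnFactor(nc * length(days), noise_cv), nc))
    out <- cbind(out, block)
    ids <- c(ids, sprintf("m%d_d%s", m, formatC(days, format = "fg")))
  }
  dimnames(out) <- list(linkage$compound, ids)
  attr(out, "pathway_class") <- setNames(linkage$pathway_class,
                                         linkage$compound)
  out
}

#' In vitro colony resistance assay
#'
#' Emulates picking colonies of one species from a stool sample and
#' cross-streaking them against its phage: each of \code{n_colonies}
#' colonies is resistant with probability m/(s+m), the true resistant
#' fraction at the assayed day. The limit of sensitivity is 1/n_colonies
#' (1.6\% for the default 64 colonies).
#'
#' @param traj a [CommunityTrajectory-class].
#' @param species assayed species name.
#' @param day assayed sampling day (matched within 0.05 d).
#' @param n_colonies number of colonies screened.
#' @param seed RNG seed.
#' @return list with \code{fraction} (observed resistant fraction),
#'   \code{n_resistant}, \code{n_colonies}, \code{detection_limit} and
#'   \code{true_fraction}.
#' @export
colonyAssay <- function(traj, species, day, n_colonies = 64L, seed = 1L) {
  if (n_colonies < 1L) stopNamed("n_colonies must be >= 1")
  if (!species %in% rownames(traj@susceptible))
    stopNamed("species %s not in trajectory", species)
  ti <- matchDay(trajectoryTimes(traj), day, tol = 0.05)
  if (is.na(ti)) stopNamed("no sample within 0.05 d of day %.2f", day)
  s <- traj@susceptible[species, ti]
  m <- traj@resistant[species, ti]
  if (s + m <= 0)
    stopNamed("no growth: %s absent at day %.2f", species, day)
  p <- m / (s + m)
  k <- withSeed(seed, rbinom(1, n_colonies, p))
  list(fraction = k / n_colonies, n_resistant = k, n_colonies = n_colonies,
       detection_limit = 1 / n_colonies, true_fraction = p)
}
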