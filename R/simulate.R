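#' Simulate ground-truth community dynamics
#'
#' Integrates the gLV + mass-action lysis system. For each species
#' \eqn{i} with susceptible concentration \eqn{s_i}, resistant concentration
#' \eqn{m_i} and total \eqn{x_i = s_i + m_i}, and each phage \eqn{p} with
#' concentration \eqn{P_p}:
#' \deqn{ds_i/dt = s_i g_i - \sum_p k_p s_i P_p [target_p = i] - \mu_i s_i (g_i)_+}
#' \deqn{dm_i/dt = m_i (r_i (1 - c_i) + \sum_j a_{ij} x_j) + \mu_i s_i (g_i)_+}
#' \deqn{dP_p/dt = \beta_p k_p s_{target(p)} P_p - w_p P_p}
#' with per-capita gLV growth \eqn{g_i = r_i + \sum_j a_{ij} x_j}. The
#' mutation flux is growth-coupled: a fraction \eqn{\mu_i} of divisions of
#' the susceptible pool produce resistant cells (only when the gLV growth
#' term is positive), and resistance carries a fractional growth-rate cost
#' \eqn{c_i}. Phage (and bacterial) doses are instantaneous additions at
#' the dose day. Integration uses lsoda (stiff-capable) with relative
#' tolerance 1e-8 and absolute tolerance 1e-3 cfu/g; states are clipped at
#' zero. The result is deterministic given model and scenario.
#'
#' @param model a [GLVModel-class].
#' @param scenario a [Scenario-class]; species not included start at zero
#'   and remain identically zero.
#' @return a [CommunityTrajectory-class] evaluated at the scenario's
#'   sampling days.
#' @examples
#' mod <- defaultConsortium(list(phages = emptyPhageTable()))
#' sc <- Scenario(speciesNames(mod), sampling_days = c(1, 5, 20), n_mice = 1L)
#' traj <- simulateCommunity(mod, sc)
#' abundances(traj)[, 3]
#' @export
simulateCommunity <- function(model, scenario) {
  nm <- speciesNames(model)
  bad <- setdiff(scenario@included_species, nm)
  if (length(bad))
    stopNamed("scenario includes species not in the model: %s",
              paste(bad, collapse = ", "))
  n <- length(nm)
  ph <- phageTable(model)
  np <- nrow(ph)

  r <- speciesTable(model)$growth_rate
  A <- interactionMatrix(model)
  target_idx <- match(ph$target, nm)
  # per-species mutation rate / cost, pooled over phages targeting it
  mu <- numeric(n); cost <- numeric(n)
  if (np > 0L) {
    for (p in seq_len(np)) {
      i <- target_idx[p]
      mu[i] <- mu[i] + ph$mutation_rate[p]
      cost[i] <- max(cost[i], ph$resistance_cost[p])
    }
  }

  y0 <- c(ifelse(nm %in% scenario@included_species,
                 speciesTable(model)$inoculum, 0),
          rep(0, n), rep(0, np))
  names(y0) <- stateNames(nm, ph$name)

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    s <- y[seq_len(n)]
    m <- y[n + seq_len(n)]
    x <- s + m
    glv <- drop(A %*% x)
    g <- r + glv
    gplus <- pmax(g, 0)
    kill <- numeric(n)
    dP <- numeric(np)
    if (np > 0L) {
      P <- y[2L * n + seq_len(np)]
      for (p in seq_len(np)) {
        i <- target_idx[p]
        kill[i] <- kill[i] + ph$kill_rate[p] * P[p]
        dP[p] <- ph$burst[p] * ph$kill_rate[p] * s[i] * P[p] - ph$decay[p] * P[p]
      }
    }
    flux <- mu * s * gplus
    ds <- s * g - s * kill - flux
    dm <- m * (r * (1 - cost) + glv) + flux
    list(c(ds, dm, dP))
  }

  t0 <- scenario@colonization_day
  times <- sort(unique(c(t0, scenario@sampling_days, scenario@duration)))
  events <- NULL
  if (np > 0L) {
    edat <- data.frame(var = paste0("phage.", ph$name), time = ph$dose_day,
                       value = ph$dose, method = "add")
    # only events inside the integration window
    edat <- edat[edat$time >= t0 & edat$time <= max(times), , drop = FALSE]
    if (nrow(edat) > 0L) {
      events <- list(data = edat)
      times <- sort(unique(c(times, edat$time)))
    }
  }

  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-3, events = events)
  if (any(!is.finite(out)))
    stopNamed("integration failed (non-finite state) near day %.2f",
              out[which(!stats::complete.cases(out))[1L], "time"])
  keep <- match(scenario@sampling_days, out[, "time"])
  vals <- pmax(out[keep, -1L, drop = FALSE], 0)
  new("CommunityTrajectory",
      times = scenario@sampling_days,
      susceptible = matrix(t(vals[, seq_len(n), drop = FALSE]), n,
                           dimnames = list(nm, NULL)),
      resistant = matrix(t(vals[, n + seq_len(n), drop = FALSE]), n,
                         dimnames = list(nm, NULL)),
      phage = if (np > 0L)
        matrix(t(vals[, 2L * n + seq_len(np), drop = FALSE]), np,
               dimnames = list(ph$name, NULL))
      else matrix(0, 0, length(scenario@sampling_days)),
      scenario = scenario)
}

stateNames <- function(species, phages) {
  c(paste0("s.", species), paste0("m.", species),
    if (length(phages)) paste0("phage.", phages))
}

#' Phage-free gLV equilibrium of a (sub)community
#'
#' Integrates the phage-free gLV restricted to \code{included} to a long
#' horizon and reports the equilibrium. Convergence is declared when the
#' largest relative change over the final fifth of the horizon and the
#' largest per-capita growth rate of a surviving species are both below
#' \code{tol}; otherwise the result is flagged non-convergent (oscillatory
#' or divergent systems are reported, never silently returned).
#'
#' @param model a [GLVModel-class] (phages, if any, are ignored).
#' @param included species subset to colonize (default: all).
#' @param horizon integration time, days.
#' @param tol convergence tolerance.
#' @return list with \code{concentrations} (named vector over all model
#'   species; excluded species are 0), \code{converged} (logical) and
#'   \code{residual} (largest relative drift observed).
#' @examples
#' mod <- defaultConsortium()
#' eq <- steadyState(mod)
#' stopifnot(eq$converged)
#' @export
steadyState <- function(model, included = speciesNames(model),
                        horizon = 2000, tol = 1e-6) {
  nophage <- GLVModel(speciesTable(model), interactionMatrix(model))
  sc <- Scenario(included, sampling_days = c(horizon * 0.8, horizon * 0.9,
                                             horizon),
                 duration = horizon, n_mice = 1L)
  traj <- simulateCommunity(nophage, sc)
  x <- abundances(traj)
  xend <- x[, 3L]
  scale <- pmax(xend, 1)   # cfu/g; treat < 1 cfu/g as extinct
  drift <- max(abs(xend - x[, 1L]) / scale)
  g <- speciesTable(model)$growth_rate + drop(interactionMatrix(model) %*% xend)
  alive <- xend > 1
  pc <- if (any(alive)) max(abs(g[alive])) else 0
  residual <- max(drift, pc)
  list(concentrations = setNames(ifelse(xend > 1, xend, 0),
                                 speciesNames(model)),
       converged = residual < tol,
       residual = residual)
}

#' Ground-truth net influence from steady-state dropouts
#'
#' For each source species, compares the phage-free equilibrium of the
#' community without that species to the full-community equilibrium and
#' returns per-target log10 ratios. The sign of each ratio defines the
#' ground-truth net influence of the source on the target (negative ratio:
#' the source promotes the target), which dropout-based network inference
#' is expected to recover.
#'
#' @param model a [GLVModel-class].
#' @param sources species whose dropout equilibria are computed.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{log10_ratio} (dropout over full equilibrium) and
#'   \code{true_sign} ("promotion" or "repression"; NA where the ratio is
#'   zero or a concentration vanished).
#' @export
steadyStateInfluence <- function(model, sources) {
  full <- steadyState(model)
  if (!full$converged)
    stopNamed("full community did not reach equilibrium (residual %.3g)",
              full$residual)
  res <- NULL
  for (src in sources) {
    drop_eq <- steadyState(model, setdiff(speciesNames(model), src))
    if (!drop_eq$converged)
      stopNamed("dropout of %s did not reach equilibrium (residual %.3g)",
                src, drop_eq$residual)
    targets <- setdiff(speciesNames(model), src)
    ratio <- log10(drop_eq$concentrations[targets] /
                     full$concentrations[targets])
    res <- rbind(res, data.frame(
      source = src, target = targets, log10_ratio = as.numeric(ratio),
      true_sign = ifelse(is.finite(ratio) & ratio != 0,
                         ifelse(ratio < 0, "promotion", "repression"),
                         NA_character_),
      row.names = NULL))
  }
  res
}
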