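#' Per-mouse log10 fold changes after a perturbation
#'
#' For each mouse, each post-perturbation sample is compared to that
#' mouse's reference sample: the latest sample collected at or before
#' perturbation_day - 0.5 days ("1 day prior" on a decimal-day sampling
#' grid that has no sample at exactly -1.0 for every mouse). Values are
#' log10(concentration at t / concentration at reference); concentrations
#' must be imputed first (no zeros).
#'
#' @param se a \code{SummarizedExperiment} with an imputed
#'   \code{concentration} assay and colData \code{mouse}, \code{day}.
#' @param perturbation_day decimal day of the perturbation.
#' @param ref_offset reference rule: latest sample with
#'   day <= perturbation_day - ref_offset (default 0.5).
#' @return tidy data.frame: \code{species}, \code{mouse}, \code{day},
#'   \code{elapsed} (day - perturbation_day), \code{log10_fc}.
#' @export
foldChange <- function(se, perturbation_day, ref_offset = 0.5) {
  conc <- SummarizedExperiment::assay(se, "concentration")
  cd <- SummarizedExperiment::colData(se)
  out <- NULL
  for (m in unique(cd$mouse)) {
    sel <- which(cd$mouse == m)
    days <- cd$day[sel]
    ref_ok <- which(days <= perturbation_day - ref_offset + 1e-9)
    if (!length(ref_ok))
      stopNamed("mouse %s has no reference sample before day %.1f",
                m, perturbation_day)
    ref <- sel[ref_ok[which.max(days[ref_ok])]]
    post <- sel[days > perturbation_day]
    if (!length(post)) next
    lfc <- log10(conc[, post, drop = FALSE] / conc[, ref])
    out <- rbind(out, data.frame(
      species = rep(rownames(conc), length(post)),
      mouse = m,
      day = rep(cd$day[post], each = nrow(conc)),
      elapsed = rep(cd$day[post] - perturbation_day, each = nrow(conc)),
      log10_fc = as.numeric(lfc), row.names = NULL))
  }
  out
}

#' Dropout-versus-full colonization fold change
#'
#' Per remaining species, log10 of the ratio of the dropout cohort's
#' cross-mouse mean concentration to the full cohort's, at matched
#' sampling days (nearest sample within a tolerance window). The omitted
#' species is excluded from the output; species absent from both cohorts
#' are dropped with a note.
#'
#' @param dropout_se,full_se \code{SummarizedExperiment}s with imputed
#'   \code{concentration} assays.
#' @param day decimal day compared (default 16.1, end of colonization).
#' @param tol day-matching tolerance (default 0.5).
#' @param mode cross-mouse mean: "geometric" (default, matching log-scale
#'   presentation of ratio quantities) or "arithmetic".
#' @return data.frame \code{species}, \code{log10_fc}, \code{n_dropout},
#'   \code{n_full}.
#' @export
dropoutFoldChange <- function(dropout_se, full_se, day = 16.1, tol = 0.5,
                              mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  shared <- intersect(rownames(dropout_se), rownames(full_se))
  lost <- setdiff(rownames(full_se), c(shared, rownames(dropout_se)))
  if (!length(shared)) stopNamed("cohorts share no species")
  centre <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    conc <- SummarizedExperiment::assay(se, "concentration")
    sel <- integer(0)
    for (m in unique(cd$mouse)) {
      msel <- which(cd$mouse == m)
      i <- matchDay(cd$day[msel], day, tol)
      if (!is.na(i)) sel <- c(sel, msel[i])
    }
    if (!length(sel))
      stopNamed("no samples within %.2f d of day %.2f", tol, day)
    fun <- if (mode == "geometric") geomean else mean
    list(centre = apply(conc[shared, sel, drop = FALSE], 1L, fun),
         n = length(sel))
  }
  d <- centre(dropout_se); f <- centre(full_se)
  data.frame(species = shared,
             log10_fc = as.numeric(log10(d$centre / f$centre)),
             n_dropout = d$n, n_full = f$n, row.names = NULL)
}

#' Aggregate per-mouse values into a center and spread
#'
#' @param x per-mouse values.
#' @param mode "arithmetic" mean or "geometric" mean (requires all values
#'   positive; spread is computed on the log10 scale and reported as a
#'   log10 spread).
#' @param error "SD" or "SEM" (SD / sqrt(n)).
#' @return list with \code{center}, \code{spread}, \code{n} (single values
#'   get spread 0).
#' @examples
#' aggregateValues(c(1, 2, 3), "arithmetic", "SEM")
#' aggregateValues(c(1e2, 1e4), "geometric")$center   # 1e3
#' @export
aggregateValues <- function(x, mode = c("arithmetic", "geometric"),
                            error = c("SD", "SEM")) {
  mode <- match.arg(mode)
  error <- match.arg(error)
  if (!length(x)) stopNamed("need at least one value")
  n <- length(x)
  if (mode == "geometric") {
    if (any(x <= 0))
      stopNamed("geometric aggregation requires all values > 0")
    lx <- log10(x)
    sp <- if (n > 1L) sd(lx) else 0
    if (error == "SEM") sp <- sp / sqrt(n)
    list(center = 10^mean(lx), spread = sp, n = n)
  } else {
    sp <- if (n > 1L) sd(x) else 0
    if (error == "SEM") sp <- sp / sqrt(n)
    list(center = mean(x), spread = sp, n = n)
  }
}

#' Aggregate a fold-change series across mice
#'
#' Applies [aggregateValues()] per species and elapsed time to the tidy
#' output of [foldChange()].
#'
#' @param fc data.frame from [foldChange()].
#' @inheritParams aggregateValues
#' @return data.frame \code{species}, \code{elapsed}, \code{center},
#'   \code{spread}, \code{n}.
#' @export
aggregateFoldChange <- function(fc, mode = "arithmetic", error = "SEM") {
  keys <- unique(fc[, c("species", "elapsed")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    v <- fc$log10_fc[fc$species == keys$species[i] &
                       fc$elapsed == keys$elapsed[i]]
    a <- aggregateValues(v, mode, error)
    data.frame(species = keys$species[i], elapsed = keys$elapsed[i],
               center = a$center, spread = a$spread, n = a$n)
  })
  do.call(rbind, res)
}
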