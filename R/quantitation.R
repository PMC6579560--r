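#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq = intercept + slope * log10(copies) from
#' calibration points (standards of known copy number included on every
#' assay plate).
#'
#' @param copies known copy numbers of the standards (> 0).
#' @param cq measured Cq values.
#' @return a [StandardCurve-class].
#' @examples
#' cv <- fitStandardCurve(10^(3:7), 40 - 3.3219 * (3:7))
#' curveEfficiency(cv)   # 1 = perfect per-cycle doubling
#' @export
fitStandardCurve <- function(copies, cq) {
  if (length(copies) != length(cq)) stopNamed("copies and cq lengths differ")
  ok <- is.finite(copies) & is.finite(cq)
  copies <- copies[ok]; cq <- cq[ok]
  if (any(copies <= 0)) stopNamed("standard copy numbers must be > 0")
  if (length(unique(copies)) < 2L)
    stopNamed("insufficient calibration: need >= 2 distinct copy levels")
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stopNamed("calibration did not yield a negative slope (slope = %.3g)",
              slope)
  r2 <- if (stats::var(cq) == 0) 1 else
    max(0, min(1, 1 - sum(stats::resid(fit)^2) / sum((cq - mean(cq))^2)))
  new("StandardCurve", slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = r2, n_points = length(cq))
}

#' @rdname fitStandardCurve
#' @param curve a [StandardCurve-class].
#' @return \code{curveEfficiency()}: the per-cycle amplification efficiency
#'   E = 10^(-1/slope) - 1 (1 corresponds to 100\%).
#' @export
curveEfficiency <- function(curve) 10^(-1 / curve@slope) - 1

#' Convert a Cq value to copies per gram of stool
#'
#' Inverts the standard curve (copies in reaction = 10^((cq - intercept) /
#' slope)) and applies the volumetric scaling chain: template dilution,
#' extract-to-template volume ratio, and stool mass. Non-detect Cq values
#' (NA) propagate as NA.
#'
#' @param cq Cq value(s); NA = non-detect.
#' @param curve a [StandardCurve-class].
#' @param dilution_factor fold dilution of the template before qPCR.
#' @param extract_volume,template_volume extraction eluate volume and
#'   template volume per reaction (same units); their ratio scales copies
#'   per reaction up to copies per extract.
#' @param stool_mass_g mass of stool extracted, grams.
#' @return copies per gram of stool.
#' @examples
#' cv <- fitStandardCurve(10^(3:7), 40 - 3.3219 * (3:7))
#' quantifyCopies(40 - 3.3219 * 3, cv)   # 1000 copies
#' @export
quantifyCopies <- function(cq, curve, dilution_factor = 1,
                           extract_volume = 1, template_volume = 1,
                           stool_mass_g = 1) {
  if (any(c(dilution_factor, extract_volume, template_volume,
            stool_mass_g) <= 0))
    stopNamed("dilution, volumes and stool mass must all be > 0")
  copies_rxn <- 10^((cq - curve@intercept) / curve@slope)
  copies_rxn * dilution_factor * (extract_volume / template_volume) /
    stool_mass_g
}

#' Relative 16S read fractions
#'
#' @param counts per-species reads: a named vector (one sample) or a
#'   species x samples matrix.
#' @return fractions summing to 1 per sample.
#' @export
relativeAbundances <- function(counts) {
  if (is.matrix(counts)) {
    tot <- colSums(counts)
    if (any(tot <= 0))
      stopNamed("empty sample(s): %s",
                paste(colnames(counts)[tot <= 0], collapse = ", "))
    return(sweep(counts, 2L, tot, "/"))
  }
  tot <- sum(counts)
  if (tot <= 0) stopNamed("empty sample: total reads must be > 0")
  counts / tot
}

#' Estimate absolute bacterial concentrations
#'
#' The core estimation step: each species' concentration per gram of stool
#' is its relative 16S read fraction times the qPCR-measured total 16S
#' copies per gram, divided by its 16S copies per genome:
#' \deqn{c_i = f_i \cdot T / n_i.}
#' Zero-fraction species (and all species of a sample whose total qPCR was
#' a non-detect) are recorded as non-detected, candidates for imputation by
#' [imputeNondetects()]. Amplification-efficiency bias is deliberately not
#' corrected here; the observation model can inject it so its effect on
#' estimates is measurable.
#'
#' @param x a species x samples count matrix, or a
#'   \code{SummarizedExperiment} from [observeCommunity()] /
#'   [readStudyTables()] (uses assay \code{counts}, colData
#'   \code{total_16s_per_g} and rowData \code{copies_16s}).
#' @param total_16s_per_g per-sample total 16S copies/g (matrix input only).
#' @param copy_numbers named vector of 16S copies per genome covering every
#'   species in \code{x} (matrix input only).
#' @return for matrix input, a list with matrices \code{concentration}
#'   (est. bacteria per g stool) and \code{detected}; for a
#'   SummarizedExperiment, the same object with assays
#'   \code{concentration} and \code{detected} added.
#' @examples
#' estimateConcentrations(matrix(c(50, 50), 2, dimnames = list(c("a", "b"), "s1")),
#'                        total_16s_per_g = 2e9, copy_numbers = c(a = 10, b = 5))
#' @export
estimateConcentrations <- function(x, total_16s_per_g = NULL,
                                   copy_numbers = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    res <- estimateConcentrations(
      SummarizedExperiment::assay(x, "counts"),
      x$total_16s_per_g,
      setNames(SummarizedExperiment::rowData(x)$copies_16s, rownames(x)))
    SummarizedExperiment::assays(x)$concentration <- res$concentration
    SummarizedExperiment::assays(x)$detected <- res$detected
    return(x)
  }
  counts <- as.matrix(x)
  missing_cn <- setdiff(rownames(counts), names(copy_numbers))
  if (length(missing_cn))
    stopNamed("no 16S copy number for species: %s",
              paste(missing_cn, collapse = ", "))
  if (length(total_16s_per_g) == 1L)
    total_16s_per_g <- rep(total_16s_per_g, ncol(counts))
  if (length(total_16s_per_g) != ncol(counts))
    stopNamed("need one total_16s_per_g value per sample")
  frac <- relativeAbundances(counts)
  n_i <- copy_numbers[rownames(counts)]
  conc <- sweep(frac, 2L, total_16s_per_g, "*") / n_i
  detected <- frac > 0 & !is.na(conc)
  conc[is.na(conc)] <- NA_real_
  list(concentration = conc, detected = detected)
}

#' Impute non-detected concentrations with per-species dataset minima
#'
#' Every non-detected entry of a species is replaced by the lowest
#' concentration at which that species was detected anywhere in the
#' dataset (one experiment: a time series or one dropout cohort; minima
#' are not pooled across experiments). Detected values are untouched, so
#' the operation never lowers a value and is idempotent.
#'
#' @param x a \code{SummarizedExperiment} carrying assays
#'   \code{concentration} and \code{detected} (from
#'   [estimateConcentrations()]), or a list with those two matrices.
#' @return the input with non-detects filled in and an \code{imputed}
#'   logical matrix/assay added.
#' @export
imputeNondetects <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    res <- imputeNondetects(list(
      concentration = SummarizedExperiment::assay(x, "concentration"),
      detected = SummarizedExperiment::assay(x, "detected")))
    SummarizedExperiment::assays(x)$concentration <- res$concentration
    SummarizedExperiment::assays(x)$imputed <- res$imputed
    return(x)
  }
  conc <- x$concentration
  det <- x$detected
  imputed <- !det
  if (any(imputed)) {
    never <- rownames(conc)[rowSums(det) == 0L]
    if (length(never))
      stopNamed("cannot impute species never detected in the dataset: %s",
                paste(never, collapse = ", "))
    mins <- vapply(seq_len(nrow(conc)), function(i)
      min(conc[i, det[i, ]]), numeric(1))
    for (i in seq_len(nrow(conc)))
      conc[i, imputed[i, ]] <- mins[i]
  }
  list(concentration = conc, detected = det, imputed = imputed)
}

#' Quantify phages from phage-specific qPCR
#'
#' Each phage is quantified against its own phage-specific standard curve
#' via [quantifyCopies()]; results are estimated phage per gram of stool.
#'
#' @param cq_table data.frame with columns \code{sample_id}, \code{assay}
#'   (phage name) and \code{cq} (NA = non-detect).
#' @param curves named list of [StandardCurve-class], one per phage assay.
#' @param dilution_factor,extract_volume,template_volume,stool_mass_g
#'   scaling chain passed to [quantifyCopies()]; \code{stool_mass_g} may be
#'   a named vector by sample_id.
#' @return data.frame \code{sample_id}, \code{phage},
#'   \code{est_phage_per_g} (NA for non-detects).
#' @export
quantifyPhage <- function(cq_table, curves, dilution_factor = 1,
                          extract_volume = 1, template_volume = 1,
                          stool_mass_g = 1) {
  missing_cv <- setdiff(unique(cq_table$assay), names(curves))
  if (length(missing_cv))
    stopNamed("no standard curve for phage assay(s): %s",
              paste(missing_cv, collapse = ", "))
  mass <- if (length(stool_mass_g) > 1L)
    stool_mass_g[cq_table$sample_id] else rep(stool_mass_g, nrow(cq_table))
  out <- vapply(seq_len(nrow(cq_table)), function(i)
    quantifyCopies(cq_table$cq[i], curves[[cq_table$assay[i]]],
                   dilution_factor, extract_volume, template_volume,
                   mass[i]),
    numeric(1))
  data.frame(sample_id = cq_table$sample_id, phage = cq_table$assay,
             est_phage_per_g = out)
}
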