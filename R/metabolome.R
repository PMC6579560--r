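#' Normalize metabolite levels to pre-perturbation reference samples
#'
#' Per compound and mouse, fold change = level in the post sample divided
#' by level in that mouse's designated pre (reference) sample, collected
#' immediately prior to the perturbation. A compound must be detected
#' (present, > 0) in both members of a pair to contribute; otherwise the
#' pair's fold change is NA, so no ratios are fabricated from non-detects.
#'
#' @param mat compounds x samples matrix (NA or 0 = non-detected).
#' @param pairing data.frame with columns \code{post}, \code{pre} (sample
#'   column names) and \code{mouse}.
#' @return compounds x pairs fold-change matrix, columns named by mouse.
#' @export
normalizeToReference <- function(mat, pairing) {
  need <- c("post", "pre", "mouse")
  if (!all(need %in% names(pairing)))
    stopNamed("pairing must have columns: %s", paste(need, collapse = ", "))
  missing_s <- setdiff(c(pairing$post, pairing$pre), colnames(mat))
  if (length(missing_s))
    stopNamed("unpaired sample(s) absent from the table: %s",
              paste(missing_s, collapse = ", "))
  post <- mat[, pairing$post, drop = FALSE]
  pre <- mat[, pairing$pre, drop = FALSE]
  fc <- post / pre
  fc[!is.finite(fc) | post <= 0 | pre <= 0] <- NA_real_
  colnames(fc) <- as.character(pairing$mouse)
  fc
}

#' Per-compound differential test with BH false-discovery-rate control
#'
#' For each compound with fold changes from at least \code{min_n} mice, a
#' two-sided one-sample t-test of the log2 fold changes against 0 (paired
#' design; \code{test = "welch"} gives a Welch two-sample test of log2
#' levels for unpaired designs such as germfree versus colonized, with
#' \code{mat2} as the second group). p values are Benjamini-Hochberg
#' adjusted across all tested compounds; compounds with degenerate
#' (all-constant) input are flagged untestable and excluded from the BH
#' family (a compound constant at fold change exactly 1 gets p = 1).
#'
#' @param fc compounds x mice fold-change matrix (from
#'   [normalizeToReference()]), or log-scale level matrix for
#'   \code{test = "welch"}.
#' @param alpha FDR level for the significance flag.
#' @param test "t" (one-sample on log2 fold changes) or "welch".
#' @param mat2 second-group matrix (welch only).
#' @param min_n minimum mice per compound (default 2).
#' @return data.frame: \code{compound}, \code{mean_fold_change},
#'   \code{log2_fc}, \code{p_value}, \code{p_adjusted},
#'   \code{significant}, \code{direction} ("up"/"down"/"none"),
#'   \code{n}, \code{untestable}.
#' @export
differentialAbundance <- function(fc, alpha = 0.05,
                                  test = c("t", "welch"), mat2 = NULL,
                                  min_n = 2L) {
  test <- match.arg(test)
  if (test == "welch" && is.null(mat2))
    stopNamed("welch test requires mat2 (second group)")
  compounds <- rownames(fc)
  res <- data.frame(compound = compounds, mean_fold_change = NA_real_,
                    log2_fc = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, significant = FALSE,
                    direction = "none", n = 0L, untestable = FALSE,
                    row.names = NULL)
  for (i in seq_along(compounds)) {
    if (test == "t") {
      v <- fc[i, ]
      v <- v[is.finite(v) & v > 0]
      lv <- log2(v)
      res$n[i] <- length(lv)
      if (length(lv) < min_n) { res$untestable[i] <- TRUE; next }
      res$mean_fold_change[i] <- mean(v)
      res$log2_fc[i] <- mean(lv)
      if (sd(lv) == 0) {
        if (all(lv == 0)) res$p_value[i] <- 1 else res$untestable[i] <- TRUE
        next
      }
      res$p_value[i] <- stats::t.test(lv, mu = 0)$p.value
    } else {
      a <- fc[i, ]; b <- mat2[i, ]
      a <- a[is.finite(a) & a > 0]; b <- b[is.finite(b) & b > 0]
      res$n[i] <- min(length(a), length(b))
      if (length(a) < min_n || length(b) < min_n) {
        res$untestable[i] <- TRUE; next
      }
      res$mean_fold_change[i] <- mean(a) / mean(b)
      res$log2_fc[i] <- mean(log2(a)) - mean(log2(b))
      if (sd(log2(a)) == 0 && sd(log2(b)) == 0) {
        if (res$log2_fc[i] == 0) res$p_value[i] <- 1
        else res$untestable[i] <- TRUE
        next
      }
      res$p_value[i] <- stats::t.test(log2(a), log2(b))$p.value
    }
  }
  tested <- !is.na(res$p_value)
  res$p_adjusted[tested] <- stats::p.adjust(res$p_value[tested],
                                            method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res$direction[res$significant & res$log2_fc > 0] <- "up"
  res$direction[res$significant & res$log2_fc < 0] <- "down"
  res
}

#' Presence call from germfree samples
#'
#' A compound is called present if detected (> 0 and not NA) in at least
#' \code{min_detected} of the samples (the default reproduces a
#' 4-of-5-mice cutoff).
#'
#' @param mat compounds x samples matrix of germfree measurements.
#' @param min_detected minimum samples with detection.
#' @return named logical vector per compound.
#' @export
presenceFilter <- function(mat, min_detected = 4L) {
  if (min_detected > ncol(mat))
    stopNamed("min_detected (%d) exceeds the number of samples (%d)",
              min_detected, ncol(mat))
  detected <- !is.na(mat) & mat > 0
  rowSums(detected) >= min_detected
}

#' Volcano summary counts
#'
#' @param dt a [differentialAbundance()] table.
#' @return list: \code{n_total} (tested compounds), \code{n_significant},
#'   \code{n_up}, \code{n_down}, and fractions \code{frac_significant},
#'   \code{frac_up}, \code{frac_down} of the tested total.
#' @export
volcanoSummary <- function(dt) {
  if (!nrow(dt)) stopNamed("empty differential table")
  tested <- dt[!dt$untestable & !is.na(dt$p_value), , drop = FALSE]
  n <- nrow(tested)
  up <- sum(tested$direction == "up")
  down <- sum(tested$direction == "down")
  list(n_total = n, n_significant = sum(tested$significant),
       n_up = up, n_down = down,
       frac_significant = if (n) sum(tested$significant) / n else 0,
       frac_up = if (n) up / n else 0,
       frac_down = if (n) down / n else 0)
}

#' Hierarchical-clustering row/column ordering for log2 heatmaps
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of a log2 fold-change matrix, as used to order compounds and
#' conditions in clustered heatmaps. Deterministic for fixed input; ties
#' are broken by input order (hclust's convention).
#'
#' @param mat finite numeric matrix (compounds x conditions).
#' @param linkage agglomeration method passed to \code{hclust}.
#' @param cluster_cols also cluster columns (needs >= 2 columns).
#' @return list with \code{row_order}, \code{col_order},
#'   \code{row_hclust}, \code{col_hclust} (NULL where trivial).
#' @export
clusterOrder <- function(mat, linkage = "average", cluster_cols = TRUE) {
  if (any(!is.finite(mat)))
    stopNamed("matrix must be finite (handle non-detects first)")
  ro <- seq_len(nrow(mat)); rh <- NULL
  if (nrow(mat) > 1L) {
    rh <- stats::hclust(stats::dist(mat), method = linkage)
    ro <- rh$order
  }
  co <- seq_len(ncol(mat)); ch <- NULL
  if (cluster_cols && ncol(mat) > 1L) {
    ch <- stats::hclust(stats::dist(t(mat)), method = linkage)
    co <- ch$order
  }
  list(row_order = ro, col_order = co, row_hclust = rh, col_hclust = ch)
}

#' Run the full metabolome differential analysis on a deposited-style table
#'
#' Convenience wrapper for an externally supplied compounds x samples TSV
#' (compound_id in the first column): pairs post/pre samples, normalizes,
#' tests with BH correction and summarizes. Intended for re-analysis of a
#' locally available untargeted-metabolomics deposit.
#'
#' @param path TSV path (compounds as rows, samples as columns).
#' @param pairing data.frame with \code{post}, \code{pre}, \code{mouse}.
#' @param alpha FDR level.
#' @return list with the differential table and its [volcanoSummary()].
#' @export
analyzeDepositTable <- function(path, pairing, alpha = 0.05) {
  if (!file.exists(path)) stopNamed("metabolite table not found: %s", path)
  tab <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  fc <- normalizeToReference(mat, pairing)
  dt <- differentialAbundance(fc, alpha = alpha)
  list(differential = dt, summary = volcanoSummary(dt))
}
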