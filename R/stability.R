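#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} in [0, 1]
#' (0 = identical, 1 = disjoint support). For compositions normalized to
#' sum to 1 the denominator is exactly 2, so the value equals
#' \eqn{\frac{1}{2}\sum_i |x_i - y_i|}. Computed through
#' \code{vegan::vegdist}. Bray-Curtis is not a metric (the triangle
#' inequality can fail), so no metric properties beyond symmetry should be
#' assumed.
#'
#' @param x,y non-negative abundance vectors over the same species.
#' @return dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5))   # 0.5
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stopNamed("profiles differ in length")
  if (any(x < 0) || any(y < 0)) stopNamed("abundances must be >= 0")
  if (sum(x) + sum(y) == 0)
    stopNamed("undefined dissimilarity: both profiles are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

# relative-abundance compositions per sample from the counts assay
compositions <- function(se) {
  relativeAbundances(SummarizedExperiment::assay(se, "counts"))
}

#' Between-mouse dissimilarity at one time point
#'
#' Bray-Curtis dissimilarity on relative abundances for every unordered
#' pair of mice sampled at the given day (community synchrony across
#' animals; decreasing values indicate a more reproducible, stable
#' community).
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay and
#'   colData \code{mouse}, \code{day}.
#' @param day sampling day (matched within \code{tol}, per mouse).
#' @param tol day-matching tolerance.
#' @return data.frame \code{day}, \code{mouse_a}, \code{mouse_b},
#'   \code{dissimilarity}; zero rows (with a message) if fewer than two
#'   mice were sampled.
#' @export
dissimilarityBetweenMice <- function(se, day, tol = 0.05) {
  cd <- SummarizedExperiment::colData(se)
  comp <- compositions(se)
  sel <- integer(0)
  for (m in unique(cd$mouse)) {
    msel <- which(cd$mouse == m)
    i <- matchDay(cd$day[msel], day, tol)
    if (!is.na(i)) sel <- c(sel, msel[i])
  }
  if (length(sel) < 2L) {
    message(sprintf("fewer than 2 mice sampled at day %.1f", day))
    return(data.frame(day = numeric(), mouse_a = integer(),
                      mouse_b = integer(), dissimilarity = numeric()))
  }
  pairs <- utils::combn(seq_along(sel), 2L)
  data.frame(
    day = day,
    mouse_a = cd$mouse[sel][pairs[1L, ]],
    mouse_b = cd$mouse[sel][pairs[2L, ]],
    dissimilarity = apply(pairs, 2L, function(p)
      brayCurtis(comp[, sel[p[1L]]], comp[, sel[p[2L]]])))
}

#' Within-mouse dissimilarity between adjacent time points
#'
#' Bray-Curtis dissimilarity on relative abundances between each sample of
#' one mouse and its previous available sample ("t - 1" is the previous
#' sample on the irregular grid, not calendar day minus one). Decreasing
#' values after a perturbation indicate reduced deviation from steady
#' state.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay.
#' @param mouse mouse id.
#' @return data.frame \code{mouse}, \code{day_prev}, \code{day},
#'   \code{dissimilarity}; zero rows (with a message) for a single time
#'   point.
#' @export
dissimilarityOverTime <- function(se, mouse) {
  cd <- SummarizedExperiment::colData(se)
  comp <- compositions(se)
  sel <- which(cd$mouse == mouse)
  sel <- sel[order(cd$day[sel])]
  if (length(sel) < 2L) {
    message(sprintf("mouse %s has fewer than 2 time points", mouse))
    return(data.frame(mouse = integer(), day_prev = numeric(),
                      day = numeric(), dissimilarity = numeric()))
  }
  data.frame(
    mouse = mouse,
    day_prev = cd$day[sel[-length(sel)]],
    day = cd$day[sel[-1L]],
    dissimilarity = vapply(seq_len(length(sel) - 1L), function(k)
      brayCurtis(comp[, sel[k]], comp[, sel[k + 1L]]), numeric(1)))
}
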