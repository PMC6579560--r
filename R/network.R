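#' Infer the interbacterial influence network from dropout cohorts
#'
#' For each dropped-out species i and each remaining species j, the log10
#' fold change \eqn{\Delta} between the dropout cohort and the full
#' consortium at the reference day defines an edge i -> j: promotion if
#' \eqn{\Delta < 0} (removing i reduced j), repression if
#' \eqn{\Delta > 0}, with weight \eqn{|\Delta|}. Edges below
#' \code{min_weight} are omitted (0 draws every computed edge). Because a
#' dropout is the maximal possible knockdown, edge weights are upper
#' limits on what phage predation of the source can do to the target, and
#' the network measures net (direct + mediated) influence.
#'
#' @param dropouts named list of dropout-cohort
#'   \code{SummarizedExperiment}s; names are the omitted species. Each
#'   cohort must omit exactly one species of the full consortium.
#' @param full_se full-consortium \code{SummarizedExperiment}.
#' @param day reference day (default 16.1).
#' @param min_weight minimum |log10 fold change| to keep an edge.
#' @param tol,mode passed to [dropoutFoldChange()].
#' @return an [InteractionNetwork-class].
#' @export
inferNetwork <- function(dropouts, full_se, day = 16.1, min_weight = 0.1,
                         tol = 0.5, mode = "geometric") {
  if (is.null(names(dropouts)) || any(!nzchar(names(dropouts))))
    stopNamed("dropouts must be a named list (names = omitted species)")
  edges <- NULL
  for (src in names(dropouts)) {
    omitted <- setdiff(rownames(full_se), rownames(dropouts[[src]]))
    if (!identical(omitted, src))
      stopNamed("malformed cohort '%s': omits [%s], expected exactly [%s]",
                src, paste(omitted, collapse = ", "), src)
    dfc <- dropoutFoldChange(dropouts[[src]], full_se, day, tol, mode)
    keep <- abs(dfc$log10_fc) >= min_weight & dfc$species != src
    if (any(keep))
      edges <- rbind(edges, data.frame(
        source = src, target = dfc$species[keep],
        sign = ifelse(dfc$log10_fc[keep] < 0, "promotion", "repression"),
        weight = abs(dfc$log10_fc[keep]), row.names = NULL))
  }
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric())
  new("InteractionNetwork", edges = edges, reference_day = day,
      min_weight = min_weight)
}

#' Conflate several influence networks
#'
#' Union of edges, e.g. combining the two sources of one phage set
#' (simultaneously dosed phages) into a single network. Shared targets
#' keep both sources' edges; there is no cancellation at the edge level.
#' The same (source, target) pair appearing in two inputs is a conflict
#' error.
#'
#' @param networks list of [InteractionNetwork-class] objects.
#' @return an [InteractionNetwork-class].
#' @export
conflateNetworks <- function(networks) {
  if (!length(networks)) stopNamed("need at least one network")
  edges <- do.call(rbind, lapply(networks, networkEdges))
  if (anyDuplicated(edges[, c("source", "target")])) {
    d <- edges[duplicated(edges[, c("source", "target")]), , drop = FALSE]
    stopNamed("conflict: duplicate edge(s) across networks: %s",
              paste(sprintf("%s->%s", d$source, d$target), collapse = ", "))
  }
  new("InteractionNetwork", edges = edges,
      reference_day = networks[[1L]]@reference_day,
      min_weight = min(vapply(networks, function(nw) nw@min_weight,
                              numeric(1))))
}

#' Predict community response to knockdowns of network sources
#'
#' Heuristic formalization of reasoning on the influence network: knocking
#' down source i by \code{knockdown[i]} log10 units removes that much of
#' its influence, so each target j receives, per knocked-down source, a
#' contribution of -min(weight(i->j), knockdown_i) for a promotion edge
#' (loss of promotion: target predicted to fall) or
#' +min(weight(i->j), knockdown_i) for a repression edge (loss of
#' repression: target predicted to rise). Contributions are capped by the
#' knockdown magnitude because the dropout-derived weight is an upper
#' limit. Opposite-sign influences of equal magnitude cancel
#' ("nullification"). Scores are additive in knockdowns and odd under a
#' global sign flip of the edges; they are validated only for sign and
#' nullification behavior, not as quantitative fold-change predictions.
#'
#' @param network an [InteractionNetwork-class].
#' @param knockdown named numeric vector of log10 knockdown magnitudes
#'   (>= 0), names = source species.
#' @return named numeric vector of signed response scores for every
#'   network target not itself knocked down.
#' @examples
#' nw <- new("InteractionNetwork",
#'   edges = data.frame(source = "a", target = "b",
#'                      sign = "promotion", weight = 2),
#'   reference_day = 16.1, min_weight = 0)
#' predictResponse(nw, c(a = 2))   # b predicted to fall by up to 2 logs
#' @export
predictResponse <- function(network, knockdown) {
  if (any(knockdown < 0)) stopNamed("knockdown magnitudes must be >= 0")
  e <- networkEdges(network)
  missing_src <- setdiff(names(knockdown), e$source)
  if (length(missing_src))
    stopNamed("knockdown source(s) not in network: %s",
              paste(missing_src, collapse = ", "))
  targets <- setdiff(unique(e$target), names(knockdown))
  score <- setNames(numeric(length(targets)), targets)
  for (src in names(knockdown)) {
    sel <- e[e$source == src & e$target %in% targets, , drop = FALSE]
    if (!nrow(sel)) next
    contrib <- pmin(sel$weight, knockdown[[src]]) *
      ifelse(sel$sign == "promotion", -1, 1)
    score[sel$target] <- score[sel$target] + contrib
  }
  score
}

#' Compare inferred edge signs to ground truth
#'
#' @param network an [InteractionNetwork-class].
#' @param truth data.frame with columns \code{source}, \code{target},
#'   \code{true_sign} ("promotion"/"repression"), e.g. from
#'   [steadyStateInfluence()].
#' @return list with \code{n_edges_evaluated}, \code{sign_agreement}
#'   (matching / evaluated; NaN for an empty network), \code{per_edge}
#'   table and \code{n_excluded} (edges absent from the truth).
#' @export
evaluateSignRecovery <- function(network, truth) {
  e <- networkEdges(network)
  if (!nrow(e))
    return(list(n_edges_evaluated = 0L, sign_agreement = NaN,
                per_edge = data.frame(), n_excluded = 0L))
  key <- paste(e$source, e$target, sep = "\r")
  tkey <- paste(truth$source, truth$target, sep = "\r")
  hit <- match(key, tkey)
  excluded <- is.na(hit) | is.na(truth$true_sign[hit])
  per <- data.frame(source = e$source, target = e$target,
                    inferred_sign = e$sign,
                    true_sign = truth$true_sign[hit],
                    weight = e$weight)[!excluded, , drop = FALSE]
  n_eval <- nrow(per)
  list(n_edges_evaluated = n_eval,
       sign_agreement = if (n_eval) mean(per$inferred_sign == per$true_sign)
                        else NaN,
       per_edge = per,
       n_excluded = sum(excluded))
}

#' Export a network as an edge-list table
#'
#' @param network an [InteractionNetwork-class].
#' @param path optional TSV path; when given the table is written there.
#' @return the edge-list data.frame, invisibly when written.
#' @export
networkToTable <- function(network, path = NULL) {
  e <- networkEdges(network)
  if (!is.null(path)) {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(e))
  }
  e
}
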