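# Accessor generics and show methods for the core classes.

#' @rdname GLVModel-class
#' @param object,x a \code{GLVModel}, \code{Scenario},
#'   \code{CommunityTrajectory}, \code{StandardCurve} or
#'   \code{InteractionNetwork} as appropriate.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname GLVModel-class
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname GLVModel-class
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname GLVModel-class
#' @export
setGeneric("phageTable", function(x) standardGeneric("phageTable"))

#' @rdname CommunityTrajectory-class
#' @export
setGeneric("trajectoryTimes", function(x) standardGeneric("trajectoryTimes"))

#' @rdname CommunityTrajectory-class
#' @param compartment which concentrations to return: total bacteria
#'   (susceptible + resistant), one bacterial compartment, or phage.
#' @export
setGeneric("abundances", function(x, compartment = c("total", "susceptible",
                                                     "resistant", "phage"))
  standardGeneric("abundances"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn GLVModel-class species names, in model order.
#' @export
setMethod("speciesNames", "GLVModel", function(x) x@species$name)

#' @describeIn GLVModel-class the species parameter table.
#' @export
setMethod("speciesTable", "GLVModel", function(x) x@species)

#' @describeIn GLVModel-class the gLV interaction matrix \eqn{a_{ij}}.
#' @export
setMethod("interactionMatrix", "GLVModel", function(x) x@interactions)

#' @describeIn GLVModel-class the phage parameter table.
#' @export
setMethod("phageTable", "GLVModel", function(x) x@phages)

#' @describeIn CommunityTrajectory-class sampling days of the trajectory.
#' @export
setMethod("trajectoryTimes", "CommunityTrajectory", function(x) x@times)

#' @describeIn CommunityTrajectory-class concentration matrix
#'   (rows = species or phages, columns = time points).
#' @export
setMethod("abundances", "CommunityTrajectory", function(x, compartment =
    c("total", "susceptible", "resistant", "phage")) {
  compartment <- match.arg(compartment)
  switch(compartment,
         total = x@susceptible + x@resistant,
         susceptible = x@susceptible,
         resistant = x@resistant,
         phage = x@phage)
})

#' @describeIn InteractionNetwork-class the edge table.
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname GLVModel-class
#' @export
setMethod("show", "GLVModel", function(object) {
  cat("GLVModel with", nrow(object@species), "species and",
      nrow(object@phages), "phages\n")
  cat("  species:", paste(object@species$name, collapse = ", "), "\n")
  if (nrow(object@phages) > 0L)
    cat("  phages: ",
        paste(sprintf("%s->%s (day %.1f)", object@phages$name,
                      object@phages$target, object@phages$dose_day),
              collapse = ", "), "\n")
})

#' @rdname Scenario-class
#' @export
setMethod("show", "Scenario", function(object) {
  cat("Scenario:", length(object@included_species), "species,",
      object@n_mice, "mice,", length(object@sampling_days),
      "sampling days over", object@duration, "days\n")
})

#' @rdname CommunityTrajectory-class
#' @export
setMethod("show", "CommunityTrajectory", function(object) {
  cat("CommunityTrajectory:", nrow(object@susceptible), "species,",
      nrow(object@phage), "phages,", length(object@times), "time points",
      sprintf("(day %.1f to %.1f)\n", min(object@times), max(object@times)))
})

#' @rdname StandardCurve-class
#' @export
setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: Cq = %.4f %+.4f * log10(copies)  (r2 = %.4f, E = %.1f%%)\n",
              object@intercept, object@slope, object@r_squared,
              100 * curveEfficiency(object)))
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("show", "InteractionNetwork", function(object) {
  e <- object@edges
  cat("InteractionNetwork:", nrow(e), "edges",
      sprintf("(%d promotion, %d repression) at day %.1f, min weight %.2f\n",
              sum(e$sign == "promotion"), sum(e$sign == "repression"),
              object@reference_day, object@min_weight))
})
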