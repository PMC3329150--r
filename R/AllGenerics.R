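## Generics and accessors. Slot access goes through these everywhere.

#' @rdname MetabolicNetwork-class
#' @param object,x a MetabolicNetwork (or other object as documented)
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("stoichiometryMatrix",
           function(object) standardGeneric("stoichiometryMatrix"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("objectiveId", function(object) standardGeneric("objectiveId"))
#' @rdname MetabolicNetwork-class
#' @param value replacement value
#' @export
setGeneric("objectiveId<-",
           function(object, value) standardGeneric("objectiveId<-"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("fluxBounds", function(object) standardGeneric("fluxBounds"))
#' @rdname MetabolicNetwork-class
#' @param ids reaction ids to modify
#' @param lower,upper replacement bounds (recycled)
#' @export
setGeneric("setFluxBounds", function(object, ids, lower = NULL, upper = NULL)
  standardGeneric("setFluxBounds"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname MetabolicNetwork-class
#' @export
setGeneric("isExchange", function(object) standardGeneric("isExchange"))

#' @rdname FluxDistribution-class
#' @param object object to access
#' @export
setGeneric("fluxValues", function(object) standardGeneric("fluxValues"))
#' @rdname FluxDistribution-class
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname FluxDistribution-class
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname FvaResult-class
#' @param object object to access
#' @export
setGeneric("fvaRanges", function(object) standardGeneric("fvaRanges"))

setMethod("reactionIds", "MetabolicNetwork", function(object)
  object@reactions$id)
setMethod("metaboliteIds", "MetabolicNetwork", function(object)
  object@metabolites$id)
setMethod("nReactions", "MetabolicNetwork", function(object)
  nrow(object@reactions))
setMethod("nMetabolites", "MetabolicNetwork", function(object)
  nrow(object@metabolites))
setMethod("stoichiometryMatrix", "MetabolicNetwork", function(object)
  object@stoichiometry)
setMethod("objectiveId", "MetabolicNetwork", function(object)
  object@objective)
setMethod("objectiveId<-", "MetabolicNetwork", function(object, value) {
  stopifnot(is.character(value), length(value) == 1)
  if (!is.na(value) && !(value %in% object@reactions$id))
    stop("objective reaction not in model: ", value)
  object@objective <- value
  object
})
setMethod("fluxBounds", "MetabolicNetwork", function(object) {
  b <- cbind(lower = object@reactions$lower_bound,
             upper = object@reactions$upper_bound)
  rownames(b) <- object@reactions$id
  b
})
setMethod("setFluxBounds", "MetabolicNetwork",
  function(object, ids, lower = NULL, upper = NULL) {
    idx <- match(ids, object@reactions$id)
    if (anyNA(idx))
      stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
    if (!is.null(lower)) object@reactions$lower_bound[idx] <- lower
    if (!is.null(upper)) object@reactions$upper_bound[idx] <- upper
    validObject(object)
    object
  })
setMethod("gprRules", "MetabolicNetwork", function(object) {
  g <- object@reactions$gpr
  names(g) <- object@reactions$id
  g
})
setMethod("geneIds", "MetabolicNetwork", function(object) {
  g <- unique(unlist(lapply(object@reactions$gpr, gprGenes)))
  sort(g)
})
setMethod("isExchange", "MetabolicNetwork", function(object) {
  e <- object@reactions$is_exchange
  names(e) <- object@reactions$id
  e
})

setMethod("fluxValues", "FluxDistribution", function(object) object@values)
setMethod("objectiveValue", "FluxDistribution", function(object)
  object@objectiveValue)
setMethod("solverStatus", "FluxDistribution", function(object) object@status)
setMethod("fluxValues", "TpdFitResult", function(object)
  object@flux@values)

setMethod("fvaRanges", "FvaResult", function(object) object@ranges)

setMethod("show", "MetabolicNetwork", function(object) {
  cnt <- reactionCounts(object)
  cat("MetabolicNetwork:", cnt["total"], "reactions (",
      cnt["metabolic"], "metabolic/transport,", cnt["exchange"],
      "exchange ),", nMetabolites(object), "metabolites,",
      length(geneIds(object)), "genes\n")
  cat("  objective:", object@objective, "\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, "), objective =",
      format(object@objectiveValue, digits = 6), "\n")
  nz <- sum(abs(object@values) > 1e-9)
  cat("  ", length(object@values), "reactions,", nz, "carrying flux\n")
})

setMethod("show", "FvaResult", function(object) {
  cat("FvaResult over", nrow(object@ranges), "reactions\n")
  sp <- object@ranges[, "max"] - object@ranges[, "min"]
  cat("  mean span:", format(mean(sp), digits = 5),
      " max span:", format(max(sp), digits = 5), "\n")
})

setMethod("show", "EnergyParameters", function(object) {
  cat("EnergyParameters: GAR =", format(object@gar, digits = 5),
      "mmol ATP g-1 AFDW (slope), NGAR =", format(object@ngar, digits = 5),
      "mmol g-1 AFDW h-1\n")
})

setMethod("show", "PhppGrid", function(object) {
  nr <- length(setdiff(unique(as.vector(object@regionId)), 0L))
  cat("PhppGrid:", length(object@psii), "x", length(object@psi),
      "photon grid (mode:", object@mode, "),", nr, "regions\n")
  for (r in names(object@limitation))
    cat("  region", r, ":", object@limitation[r], "\n")
})

setMethod("show", "TpdFitResult", function(object) {
  cat("TpdFitResult: evidence score", object@evidenceScore,
      "( flux norm", format(object@fluxNorm, digits = 5), ")\n")
})

setMethod("show", "DarkFixationResult", function(object) {
  cat("DarkFixationResult:\n")
  cat("  N2 / glycogen :", format(object@n2PerGlycogen, digits = 4), "\n")
  cat("  H2 / glycogen :", format(object@h2PerGlycogen, digits = 4), "\n")
  cat("  O2 / N2       :", format(object@o2PerN2, digits = 4), "\n")
})
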