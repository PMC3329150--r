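#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t colSums rowSums
NULL

## Central S4 containers for constraint-based models of phototrophic
## metabolism.  A MetabolicNetwork holds the stoichiometric matrix S
## (metabolites x reactions), per-reaction capacity bounds, gene-protein-
## reaction (GPR) boolean rules, and the identifier of the objective
## (usually the biomass drain).  All fluxes are in mmol g-1 AFDW h-1;
## biomass flux is in h-1.

#' MetabolicNetwork class
#'
#' A stoichiometric metabolic model: reactions with flux bounds and GPR
#' rules, metabolites with optional elemental formulas, and a sparse
#' stoichiometry matrix (rows = metabolites, columns = reactions).
#' Steady-state flux distributions v satisfy S v = 0 with
#' lower_bound <= v <= upper_bound per reaction.
#'
#' @slot reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem`, `is_exchange`.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`.
#' @slot stoichiometry sparse `Matrix` (metabolites x reactions).
#' @slot objective character, the id of the objective reaction (may be
#'   `NA_character_` for a model with no declared objective).
#' @slot compartments character vector of compartment identifiers.
#' @export
setClass("MetabolicNetwork",
  representation(
    reactions = "data.frame",
    metabolites = "data.frame",
    stoichiometry = "Matrix",
    objective = "character",
    compartments = "character"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character()
  rxn <- object@reactions
  met <- object@metabolites
  S <- object@stoichiometry
  need <- c("id", "name", "lower_bound", "upper_bound", "gpr", "subsystem",
            "is_exchange")
  if (!all(need %in% names(rxn)))
    msgs <- c(msgs, paste("reactions lacks columns:",
                          paste(setdiff(need, names(rxn)), collapse = ", ")))
  if (!all(c("id", "compartment") %in% names(met)))
    msgs <- c(msgs, "metabolites needs columns id, compartment")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "stoichiometry dimensions do not match reaction/metabolite tables")
  if (nrow(S) > 0 && !identical(rownames(S), met$id))
    msgs <- c(msgs, "stoichiometry rownames must equal metabolite ids")
  if (ncol(S) > 0 && !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "stoichiometry colnames must equal reaction ids")
  if (nrow(rxn) > 0 && any(rxn$lower_bound > rxn$upper_bound + 1e-12))
    msgs <- c(msgs, "some reactions have lower_bound > upper_bound")
  if (!is.na(object@objective) && !(object@objective %in% rxn$id))
    msgs <- c(msgs, paste("objective reaction not in model:", object@objective))
  if (length(msgs)) msgs else TRUE
})

#' FluxDistribution class
#'
#' A single steady-state flux vector with its objective value and solver
#' status. Values are named by reaction id.
#'
#' @slot values named numeric vector of fluxes (mmol g-1 AFDW h-1).
#' @slot objectiveValue numeric, value of the objective at this solution.
#' @slot status character, one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxDistribution",
  representation(values = "numeric", objectiveValue = "numeric",
                 status = "character"))

setValidity("FluxDistribution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded", "maxit"))
    return("status must be optimal/infeasible/unbounded/maxit")
  if (object@status == "optimal" && is.null(names(object@values)))
    return("optimal flux values must be named by reaction id")
  TRUE
})

#' FvaResult class
#'
#' Per-reaction flux ranges from flux variability analysis, together with
#' the constraint context used to compute them.
#'
#' @slot ranges numeric matrix with columns `min`, `max`; rownames are
#'   reaction ids.
#' @slot context list describing the constraints under which the ranges
#'   were computed.
#' @export
setClass("FvaResult",
  representation(ranges = "matrix", context = "list"))

setValidity("FvaResult", function(object) {
  r <- object@ranges
  if (!all(c("min", "max") %in% colnames(r)))
    return("ranges needs columns min and max")
  if (is.null(rownames(r))) return("ranges must have reaction-id rownames")
  bad <- r[, "min"] > r[, "max"] + 1e-6
  if (any(bad))
    return(paste("min > max for:", paste(rownames(r)[bad], collapse = ", ")))
  TRUE
})

#' BiomassComposition class
#'
#' Macromolecular composition of biomass as mass fractions of ash-free dry
#' weight. Fractions must be nonnegative and close to closure (sum within
#' 0.95 to 1.05, tolerating measurement error).
#'
#' @slot fractions named numeric vector of mass fractions (g per g AFDW).
#' @slot aminoAcidProfile optional named numeric vector of residue mole
#'   fractions (may be empty).
#' @export
setClass("BiomassComposition",
  representation(fractions = "numeric", aminoAcidProfile = "numeric"))

setValidity("BiomassComposition", function(object) {
  f <- object@fractions
  if (is.null(names(f)) || !length(f)) return("fractions must be named and non-empty")
  if (any(f < 0)) return("fractions must be nonnegative")
  s <- sum(f)
  if (s < 0.95 || s > 1.05)
    return(sprintf("fractions sum to %.3f; must lie in [0.95, 1.05]", s))
  TRUE
})

#' EnergyParameters class
#'
#' Growth-associated (GAR) and non-growth-associated (NGAR) ATP
#' requirements. GAR is stored in mmol ATP per g AFDW so that GAR x growth
#' rate has flux units; as the slope of the ATP-hydrolysis vs growth-rate
#' regression it is printed in mmol g-1 AFDW h-1 per h-1. NGAR is the
#' maintenance ATP flux in mmol g-1 AFDW h-1.
#'
#' @slot gar numeric >= 0.
#' @slot ngar numeric >= 0.
#' @export
setClass("EnergyParameters", representation(gar = "numeric", ngar = "numeric"))

setValidity("EnergyParameters", function(object) {
  if (length(object@gar) != 1 || length(object@ngar) != 1)
    return("gar and ngar must be scalars")
  if (object@gar < 0 || object@ngar < 0) return("gar and ngar must be >= 0")
  TRUE
})

#' ExpressionEvidence class
#'
#' Gene-level expression evidence: a set of genes whose proteins were
#' detected and per-gene log2 mRNA levels, with a threshold below which a
#' gene counts as lowly expressed.
#'
#' @slot proteinDetected character vector of gene ids.
#' @slot mrnaLog2 named numeric vector of log2 mRNA levels.
#' @slot mrnaThreshold numeric scalar (log2 scale).
#' @export
setClass("ExpressionEvidence",
  representation(proteinDetected = "character", mrnaLog2 = "numeric",
                 mrnaThreshold = "numeric"))

setValidity("ExpressionEvidence", function(object) {
  if (!is.finite(object@mrnaThreshold)) return("mrnaThreshold must be finite")
  TRUE
})

#' ReactionEvidenceSets class
#'
#' Reaction-level evidence sets for expression-constrained flux fitting:
#' R_E (measured-flux reactions, constrained to their values), R_H
#' (protein-detected, flux favored), R_L (undetected and low-mRNA, flux
#' disfavored), and the activity threshold epsilon.
#'
#' @slot rE named numeric vector: reaction id -> measured flux.
#' @slot rH character vector of reaction ids.
#' @slot rL character vector of reaction ids.
#' @slot epsilon numeric > 0, flux above which a reaction counts as active.
#' @export
setClass("ReactionEvidenceSets",
  representation(rE = "numeric", rH = "character", rL = "character",
                 epsilon = "numeric"))

setValidity("ReactionEvidenceSets", function(object) {
  if (length(intersect(object@rH, object@rL)))
    return("rH and rL must be disjoint")
  if (length(intersect(names(object@rE), c(object@rH, object@rL))))
    return("measured reactions must be excluded from rH and rL")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  TRUE
})

#' TpdFitResult class
#'
#' Result of the evidence-integration fit: a flux distribution that
#' maximizes agreement with transcriptome/proteome evidence and, among
#' score-optimal solutions, minimizes the sum of squared fluxes. Binaries
#' x/y mark active-negative/active-positive for R_H reactions; z marks
#' enforced inactivity for R_L reactions.
#'
#' @slot flux a [FluxDistribution-class].
#' @slot x,y,z named integer vectors of optimal binary indicators.
#' @slot evidenceScore numeric, number of satisfied evidence statements.
#' @slot fluxNorm numeric, sum of squared fluxes of the returned solution.
#' @export
setClass("TpdFitResult",
  representation(flux = "FluxDistribution", x = "integer", y = "integer",
                 z = "integer", evidenceScore = "numeric",
                 fluxNorm = "numeric"))

#' PhppGrid class
#'
#' A phenotypic phase plane over PSII and PSI photon-uptake fluxes: the
#' optimal growth surface, an integer region labelling (regions are
#' delineated by which photon constraints have positive marginal value),
#' and a per-region limitation diagnosis.
#'
#' @slot psii,psi numeric axes (photon uptake, mmol g-1 AFDW h-1).
#' @slot growth numeric matrix (length(psii) x length(psi)), h-1.
#' @slot regionId integer matrix of the same shape; 0 marks infeasible or
#'   zero-growth cells, boundary cells carry the lower adjacent region id.
#' @slot limitation named character vector: region id -> one of
#'   "reductant_limited", "energy_limited", "mixed", "neither".
#' @slot mode character, "fixed" or "upper_bound" photon constraints.
#' @export
setClass("PhppGrid",
  representation(psii = "numeric", psi = "numeric", growth = "matrix",
                 regionId = "matrix", limitation = "character",
                 mode = "character"))

setValidity("PhppGrid", function(object) {
  if (!identical(dim(object@growth), dim(object@regionId)))
    return("growth and regionId must have identical dimensions")
  if (!all(dim(object@growth) == c(length(object@psii), length(object@psi))))
    return("growth matrix dimensions must match axes")
  if (any(object@growth < -1e-9, na.rm = TRUE))
    return("growth must be nonnegative")
  TRUE
})

#' DarkFixationResult class
#'
#' Yields and electron-transport fluxes for dark nitrogen fixation fueled
#' by glycogen catabolism, with cyanophycin production as the objective.
#'
#' @slot n2PerGlycogen,h2PerGlycogen,o2PerN2 numeric yield ratios (mol/mol).
#' @slot cyanophycinFlux numeric, optimal cyanophycin production flux.
#' @slot pathwayFluxes named numeric vector of representative fluxes
#'   through COX/QOX/Mehler/NDH/FdPq at the optimum.
#' @export
setClass("DarkFixationResult",
  representation(n2PerGlycogen = "numeric", h2PerGlycogen = "numeric",
                 o2PerN2 = "numeric", cyanophycinFlux = "numeric",
                 pathwayFluxes = "numeric"))
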