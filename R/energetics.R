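## ATP-requirement estimation (GAR/NGAR), dark nitrogen-fixation
## energetics, and photon-flux unit conversion.

#' Estimate growth- and non-growth-associated ATP requirements
#'
#' For each batch observation the growth rate and both photon uptakes are
#' fixed to their measured values and the maintenance ATP-hydrolysis flux
#' is maximized by LP. Ordinary least squares of maximal ATP hydrolysis
#' against growth rate gives the slope (GAR) and intercept (NGAR).
#' The network's biomass equation should carry polymerization-only ATP
#' costs (no GAR folded in) during estimation.
#'
#' @param network a [MetabolicNetwork-class].
#' @param batches data.frame with columns `uptake_630` (PSII photons),
#'   `uptake_680` (PSI photons) and `growth` (h-1); at least two batches
#'   with distinct growth rates.
#' @param maintenanceId ATP-hydrolysis reaction id (default `"ATPM"`).
#' @param psiiId,psiId photon exchange ids.
#' @return an [EnergyParameters-class]; the per-batch maximal ATP
#'   hydrolysis fluxes are attached as attribute `"fit"`.
#' @export
estimateAtpRequirements <- function(network, batches,
                                    maintenanceId = "ATPM",
                                    psiiId = "EX_photon_psii",
                                    psiId = "EX_photon_psi") {
  stopifnot(all(c("uptake_630", "uptake_680", "growth") %in% names(batches)))
  if (nrow(batches) < 2 || length(unique(round(batches$growth, 12))) < 2)
    stop("need at least two batches with distinct growth rates")
  if (!maintenanceId %in% network@reactions$id)
    stop("network lacks maintenance reaction ", maintenanceId)
  atpm <- numeric(nrow(batches))
  for (i in seq_len(nrow(batches))) {
    cts <- list(
      list(reaction = psiiId, fixed = batches$uptake_630[i]),
      list(reaction = psiId, fixed = batches$uptake_680[i]),
      list(reaction = network@objective, fixed = batches$growth[i]),
      list(reaction = maintenanceId, lb = 0, ub = BIG_BOUND))
    fb <- solveFba(network, cts, objective = maintenanceId)
    if (fb@status != "optimal")
      stop("batch ", i, " (uptakes ", batches$uptake_630[i], "/",
           batches$uptake_680[i], ", growth ", batches$growth[i],
           ") is infeasible under the model")
    atpm[i] <- fb@objectiveValue
  }
  fit <- stats::lm(atpm ~ growth, data = cbind(batches, atpm = atpm))
  gar <- unname(stats::coef(fit)[2])
  ngar <- unname(stats::coef(fit)[1])
  if (gar < 0)
    stop("fitted GAR is negative (", format(gar), "); batch data are not ",
         "consistent with an ATP-limited growth model")
  if (ngar < 0) {
    warning("fitted NGAR is negative (", format(ngar), "); clamped to 0")
    ngar <- 0
  }
  out <- new("EnergyParameters", gar = gar, ngar = ngar)
  attr(out, "fit") <- data.frame(growth = batches$growth, atpm = atpm)
  out
}

#' Install energy parameters into a network
#'
#' NGAR becomes the lower bound of the maintenance ATP-hydrolysis flux;
#' GAR is folded into the biomass equation's ATP hydrolysis term
#' (ATP + H2O consumed, ADP + Pi + H returned, all scaled per unit
#' growth). The network's biomass equation must carry polymerization-only
#' ATP before this call (apply once).
#'
#' @param network a [MetabolicNetwork-class].
#' @param params an [EnergyParameters-class].
#' @param maintenanceId ATP-hydrolysis reaction id.
#' @param atpSpecies role -> metabolite id map as in
#'   [buildBiomassEquation()].
#' @return the modified [MetabolicNetwork-class].
#' @export
applyEnergyParameters <- function(network, params, maintenanceId = "ATPM",
    atpSpecies = c(atp = "atp_c", adp = "adp_c", pi = "pi_c",
                   h2o = "h2o_c", h = "h_c")) {
  stopifnot(is(params, "EnergyParameters"))
  if (!maintenanceId %in% network@reactions$id)
    stop("network lacks maintenance reaction ", maintenanceId)
  if (is.na(network@objective))
    stop("network has no biomass/objective reaction")
  net <- setFluxBounds(network, maintenanceId, lower = params@ngar)
  if (params@gar > 0) {
    S <- net@stoichiometry
    bio <- net@objective
    sgn <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
    for (role in names(sgn)) {
      sp <- atpSpecies[[role]]
      if (!sp %in% rownames(S))
        stop("metabolite ", sp, " not in network; cannot fold GAR")
      S[sp, bio] <- S[sp, bio] + sgn[[role]] * params@gar
    }
    net@stoichiometry <- S
  }
  validObject(net)
  net
}

#' Dark nitrogen-fixation analysis
#'
#' Simulates dark N2-fixing conditions: photon uptakes fixed to zero,
#' combined-nitrogen uptake closed, glycogen supplied through a bounded
#' demand-style source reaction, and cyanophycin production maximized.
#' Yields are computed from the nitrogenase flux (N2), the net H2
#' exchange, and O2 uptake at a flux-norm-minimal optimum; N stored in
#' cyanophycin is reported alongside for comparison.
#'
#' @param network a [MetabolicNetwork-class] (e.g. [makeToyNetwork()]).
#' @param glycogenFluxCap glycogen supply cap (default 0.171
#'   mmol g-1 AFDW h-1).
#' @param removeHydrogenases drop the three hydrogenase reactions
#'   (bidirectional NADH/NADPH and uptake) before simulating, so that
#'   nitrogenase-produced H2 is not recycled.
#' @param ngar maintenance ATP flux; `NULL` keeps the network's bound.
#' @param hydrogenaseIds,glycogenSourceId,cyanophycinSinkId,nitrogenaseId,maintenanceId
#'   reaction ids (toy defaults).
#' @return a [DarkFixationResult-class].
#' @export
darkN2Fixation <- function(network, glycogenFluxCap = 0.171,
                           removeHydrogenases = TRUE, ngar = NULL,
                           hydrogenaseIds = c("HDH_1", "HDH_2", "UPHYDR"),
                           glycogenSourceId = "DM_glycogen",
                           cyanophycinSinkId = "DM_cyanophycin",
                           nitrogenaseId = "NIF",
                           maintenanceId = "ATPM") {
  stopifnot(glycogenFluxCap >= 0)
  net <- network
  if (removeHydrogenases) {
    present <- intersect(hydrogenaseIds, net@reactions$id)
    if (length(present)) net <- deleteReactions(net, present)
  }
  cts <- c(photonConstraints(0, 0, "fixed"),
           list(list(reaction = "EX_nh4", lb = 0, ub = BIG_BOUND),
                list(reaction = glycogenSourceId, lb = 0,
                     ub = glycogenFluxCap),
                list(reaction = cyanophycinSinkId, lb = 0, ub = BIG_BOUND),
                list(reaction = net@objective, fixed = 0)))
  if (!is.null(ngar))
    cts <- c(cts, list(list(reaction = maintenanceId, lb = ngar,
                            ub = BIG_BOUND)))
  fb <- solveFba(net, cts, objective = cyanophycinSinkId)
  if (fb@status != "optimal")
    stop("dark N2-fixation problem infeasible (NGAR too high for the ",
         "glycogen supply?)")
  cph <- fb@objectiveValue
  mn <- minimizeFluxNorm(net, cph, cts, objective = cyanophycinSinkId)
  v <- if (mn@status == "optimal") fluxValues(mn) else fluxValues(fb)
  gly <- v[glycogenSourceId]
  nif <- if (nitrogenaseId %in% names(v)) v[nitrogenaseId] else 0
  h2net <- if ("EX_h2" %in% names(v)) v["EX_h2"] else 0
  o2in <- if ("EX_o2" %in% names(v)) -v["EX_o2"] else 0
  yield <- function(x) if (gly > 1e-9) unname(x / gly) else 0
  path <- v[intersect(c("COX", "QOX", "MEHLER_NADPH", "MEHLER_FD", "NDH1",
                        "NDH2", "FDPQ"), names(v))]
  out <- new("DarkFixationResult",
             n2PerGlycogen = yield(nif),
             h2PerGlycogen = yield(max(h2net, 0)),
             o2PerN2 = if (nif > 1e-9) unname(o2in / nif) else 0,
             cyanophycinFlux = unname(cph),
             pathwayFluxes = path)
  attr(out, "cyanophycinNPerGlycogen") <- yield(cph)  # 1 N per monomer
  attr(out, "flux") <- v
  out
}

#' Convert photon consumption to biomass-specific flux
#'
#' Multiplies a light consumption rate (umol photon m-2 s-1) by the
#' illuminated culture surface area (m2) and divides by the biomass
#' (g AFDW), converting umol to mmol and seconds to hours.
#'
#' @param consumptionRate umol photon m-2 s-1 (>= 0).
#' @param area m2 (> 0).
#' @param biomass g AFDW (> 0).
#' @return photon uptake flux in mmol g-1 AFDW h-1.
#' @examples
#' photonFluxFromIrradiance(1, 1, 3.6)  # 1.0
#' @export
photonFluxFromIrradiance <- function(consumptionRate, area, biomass) {
  if (biomass <= 0) stop("biomass must be positive")
  if (area <= 0) stop("area must be positive")
  if (any(consumptionRate < 0)) stop("consumption rate must be >= 0")
  consumptionRate * area * 3600 / 1000 / biomass
}
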