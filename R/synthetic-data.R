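## Synthetic data generation: a toy phototroph network reproducing the
## topology of cyanobacterial photosynthetic + respiratory electron
## transport, expression evidence correlated with a known flux state, and
## batch series generated from known ATP-requirement parameters.
##
## The toy tracks electrons on a two-electron basis. Carriers use
## pseudo-element formulas (Pq, Pc, Fdx, Ndp, Ncd, Adn, Po) chosen so
## every internal reaction is elementally and charge balanced; photons are
## massless species without formulas (exempt from the balance audit).

#' Default toy-network specification
#'
#' Proton stoichiometries are textbook-like integers on a two-electron
#' basis: PSII deposits 2 H+ into the lumen, cytochrome b6f 4 (Q-cycle),
#' NDH-1 pumps 4, COX pumps 2; the quinol oxidase (QOX) and NDH-2 pump
#' none, so COX/NDH-1 outrank QOX/NDH-2 energetically. The ATP synthase
#' couples 4 lumen protons per ATP. These defaults give the toy a
#' three-region phenotypic phase plane on the 0-60 photon grid.
#'
#' @param protonPerPsii,protonPerCytb6f,protonPerNdh1,protonPerCox lumen
#'   protons translocated per 2 electrons.
#' @param atpPerProton ATP synthase coupling (ATP per lumen proton;
#'   default 1/4).
#' @param include named logical list of feature flags: `cyclic_fdpq`,
#'   `ndh2`, `qox`, `mehler`, `nitrogenase`, `hydrogenases`, `glycogen`,
#'   `cyanophycin`.
#' @param gar growth-associated ATP requirement folded into the biomass
#'   equation (mmol ATP per g AFDW; default 544).
#' @param ngar maintenance ATP flux installed as the lower bound of the
#'   ATP-hydrolysis reaction (mmol g-1 AFDW h-1; default 2.8).
#' @return list of generator settings.
#' @export
toyNetworkSpec <- function(protonPerPsii = 2, protonPerCytb6f = 4,
                           protonPerNdh1 = 4, protonPerCox = 2,
                           atpPerProton = 0.25,
                           include = list(), gar = 544, ngar = 2.8) {
  inc <- list(cyclic_fdpq = TRUE, ndh2 = TRUE, qox = TRUE, mehler = TRUE,
              nitrogenase = TRUE, hydrogenases = TRUE, glycogen = TRUE,
              cyanophycin = TRUE)
  inc[names(include)] <- include
  stopifnot(protonPerPsii > 0, protonPerCytb6f >= 2, protonPerNdh1 >= 0,
            protonPerCox >= 0, atpPerProton > 0)
  list(protonPerPsii = protonPerPsii, protonPerCytb6f = protonPerCytb6f,
       protonPerNdh1 = protonPerNdh1, protonPerCox = protonPerCox,
       atpPerProton = atpPerProton, include = inc, gar = gar, ngar = ngar)
}

#' Toy biomass composition and monomer tables
#'
#' Mass fractions emulate light-limited chemostat biomass (protein-rich,
#' about 3% cyanophycin) and ammonium-limited biomass (carbohydrate about
#' half of dry weight, no cyanophycin). Monomer coefficients are mmol
#' precursor per g macromolecule, with polymerization ATP cost included
#' (ADP/Pi/H returned).
#'
#' @param condition `"light_limited"` or `"ammonium_limited"`.
#' @return a [BiomassComposition-class].
#' @export
toyBiomassComposition <- function(condition = c("light_limited",
                                                "ammonium_limited")) {
  condition <- match.arg(condition)
  f <- switch(condition,
    light_limited = c(protein = 0.55, carbohydrate = 0.25, lipid = 0.10,
                      nucleic_acid = 0.05, cyanophycin = 0.03,
                      pigment = 0.02),
    ammonium_limited = c(protein = 0.30, carbohydrate = 0.48, lipid = 0.12,
                         nucleic_acid = 0.05, cyanophycin = 0.00,
                         pigment = 0.02))
  new("BiomassComposition", fractions = f, aminoAcidProfile = numeric())
}

#' @rdname toyBiomassComposition
#' @export
toyMonomerTable <- function() {
  poly <- function(cx = 0, nh4 = 0, cph = 0, atp = 0) {
    out <- c(cx_c = cx, nh4_c = nh4, cph_c = cph,
             atp_c = atp, h2o_c = atp, adp_c = -atp, pi_c = -atp,
             h_c = -atp)
    out[out != 0 | names(out) %in% c("cx_c")]
  }
  list(protein = poly(cx = 45, nh4 = 12, atp = 14),
       carbohydrate = poly(cx = 37, atp = 6),
       lipid = poly(cx = 55, atp = 8),
       nucleic_acid = poly(cx = 30, nh4 = 12, atp = 12),
       cyanophycin = c(cph_c = 13.3),
       pigment = poly(cx = 50, nh4 = 2, atp = 10))
}

#' Generate the toy phototroph network
#'
#' Builds a small (about 30-reaction) stoichiometric model with the
#' canonical cyanobacterial electron-transport topology: PSII -> Pq ->
#' cytochrome b6f -> Pc -> PSI -> Fd -> FNR -> NADPH, ferredoxin-dependent
#' cyclic flow (FdPq), NDH-1/2, terminal oxidases COX and QOX, Mehler
#' reactions, ATP synthase, nitrogenase with obligate H2 co-production,
#' bidirectional and uptake hydrogenases, lumped CO2 fixation, and
#' glycogen/cyanophycin storage. Biomass is assembled from the toy
#' composition via [buildBiomassEquation()].
#'
#' @param spec a [toyNetworkSpec()] list.
#' @param composition biomass composition (default light-limited).
#' @return a [MetabolicNetwork-class] supporting photoautotrophic growth.
#' @export
makeToyNetwork <- function(spec = toyNetworkSpec(),
                           composition = toyBiomassComposition()) {
  inc <- spec$include
  kAtp <- round(1 / spec$atpPerProton)
  p2 <- spec$protonPerPsii; p6 <- spec$protonPerCytb6f
  pn <- spec$protonPerNdh1; pc <- spec$protonPerCox
  rx <- list()
  add <- function(id, stoich, lb = 0, ub = BIG_BOUND, gpr = "",
                  subsystem = "", name = id) {
    rx[[id]] <<- list(id = id, name = name, stoich = stoich,
                      lower_bound = lb, upper_bound = ub, gpr = gpr,
                      subsystem = subsystem)
  }
  ## exchanges: photons are sources (flux = uptake, positive); all other
  ## exchanges are written metabolite -> (secretion positive)
  add("EX_photon_psii", c(photon_psii = 1), 0, BIG_BOUND,
      subsystem = "Exchange")
  add("EX_photon_psi", c(photon_psi = 1), 0, BIG_BOUND,
      subsystem = "Exchange")
  for (m in c("h2o_c", "h_c", "o2_c", "co2_c", "nh4_c", "n2_c"))
    add(paste0("EX_", sub("_c$", "", m)), stats::setNames(-1, m),
        -BIG_BOUND, BIG_BOUND, subsystem = "Exchange")
  add("EX_h2", c(h2_c = -1), 0, BIG_BOUND, subsystem = "Exchange")

  ETC <- "Electron transport"
  add("PSII", c(photon_psii = -2, h2o_c = -1, pq_c = -1, h_c = -p2,
                o2_c = 0.5, pqh2_c = 1, h_l = p2),
      gpr = "gPsbA and gPsbD", subsystem = ETC,
      name = "Photosystem II")
  add("CYTB6F", c(pqh2_c = -1, pcox_c = -2, h_c = -(p6 - 2),
                  pq_c = 1, pcred_c = 2, h_l = p6),
      gpr = "gPetB and gPetD", subsystem = ETC, name = "Cytochrome b6f")
  add("PSI", c(photon_psi = -2, pcred_c = -2, fdox_c = -2,
               pcox_c = 2, fdred_c = 2),
      gpr = "gPsaA and gPsaB", subsystem = ETC, name = "Photosystem I")
  add("FNR", c(fdred_c = -2, nadp_c = -1, h_c = -1, fdox_c = 2,
               nadph_c = 1), lb = -BIG_BOUND,
      gpr = "gPetH", subsystem = ETC, name = "Ferredoxin-NADP+ reductase")
  if (inc$cyclic_fdpq)
    add("FDPQ", c(fdred_c = -2, pq_c = -1, h_c = -2, fdox_c = 2,
                  pqh2_c = 1),
        gpr = "gPgr5", subsystem = ETC, name = "Fd-dependent cyclic flow")
  add("NDH1", c(nadh_c = -1, pq_c = -1, h_c = -(1 + pn), nad_c = 1,
                pqh2_c = 1, h_l = pn),
      gpr = "gNdhA and gNdhB", subsystem = ETC,
      name = "NADH dehydrogenase type 1")
  if (inc$ndh2)
    add("NDH2", c(nadh_c = -1, pq_c = -1, h_c = -1, nad_c = 1, pqh2_c = 1),
        gpr = "gNdbA", subsystem = ETC, name = "NADH dehydrogenase type 2")
  add("COX", c(pcred_c = -2, o2_c = -0.5, h_c = -(2 + pc), pcox_c = 2,
               h2o_c = 1, h_l = pc),
      gpr = "gCtaC and gCtaD", subsystem = ETC,
      name = "Cytochrome c oxidase")
  if (inc$qox)
    add("QOX", c(pqh2_c = -1, o2_c = -0.5, pq_c = 1, h2o_c = 1),
        gpr = "gCydA or gCydB", subsystem = ETC, name = "Quinol oxidase")
  if (inc$mehler) {
    add("MEHLER_NADPH", c(nadph_c = -1, o2_c = -0.5, h_c = -1, nadp_c = 1,
                          h2o_c = 1),
        gpr = "gFlv1 and gFlv3", subsystem = ETC,
        name = "Mehler reaction (NADPH)")
    add("MEHLER_FD", c(fdred_c = -2, o2_c = -0.5, h_c = -2, fdox_c = 2,
                       h2o_c = 1),
        gpr = "gFlv2 and gFlv4", subsystem = ETC,
        name = "Mehler reaction (ferredoxin)")
  }
  add("ATPASE", c(adp_c = -1, pi_c = -1, h_l = -kAtp, atp_c = 1,
                  h2o_c = 1, h_c = kAtp - 1),
      gpr = "gAtpA and gAtpB", subsystem = ETC, name = "ATP synthase")
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      lb = spec$ngar, ub = BIG_BOUND, subsystem = "Maintenance",
      name = "ATP maintenance hydrolysis")

  CM <- "Central metabolism"
  add("CBB", c(co2_c = -1, atp_c = -3, nadph_c = -2, h2o_c = -2,
               cx_c = 1, adp_c = 3, pi_c = 3, nadp_c = 2, h_c = 1),
      gpr = "gRbcL and gRbcS", subsystem = CM,
      name = "CO2 fixation (lumped Calvin cycle)")
  if (inc$glycogen) {
    add("GLYSYN", c(cx_c = -6, atp_c = -1, glycogen_c = 1, adp_c = 1,
                    pi_c = 1, h_c = 1),
        gpr = "gGlgA", subsystem = CM, name = "Glycogen synthesis")
    add("GLYHYD", c(glycogen_c = -1, h2o_c = -1, cx_c = 6),
        gpr = "gGlgP", subsystem = CM, name = "Glycogen hydrolysis")
    add("GLYCAT", c(glycogen_c = -1, nad_c = -6, nadp_c = -6, adp_c = -4,
                    pi_c = -4, h2o_c = -3, co2_c = 6, nadh_c = 6,
                    nadph_c = 6, atp_c = 4, h_c = 8),
        gpr = "gCatA and gCatB", subsystem = CM,
        name = "Glycogen catabolism (lumped glycolysis/PPP/TCA)")
    add("DM_glycogen", c(glycogen_c = 1), 0, 0, subsystem = "Demand",
        name = "Glycogen source (dark simulations)")
  }
  if (inc$cyanophycin) {
    add("CPHSYN", c(cx_c = -2, nh4_c = -1, atp_c = -2, h2o_c = -1,
                    cph_c = 1, adp_c = 2, pi_c = 2, h_c = 3),
        gpr = "gCphA", subsystem = CM, name = "Cyanophycin synthesis")
    add("DM_cyanophycin", c(cph_c = -1), 0, 0, subsystem = "Demand",
        name = "Cyanophycin sink (dark simulations)")
  }
  if (inc$nitrogenase)
    add("NIF", c(n2_c = -1, fdred_c = -8, atp_c = -16, h2o_c = -16,
                 nh4_c = 2, h2_c = 1, fdox_c = 8, adp_c = 16, pi_c = 16,
                 h_c = 6),
        gpr = "gNifH and gNifD and gNifK", subsystem = "Nitrogen",
        name = "Nitrogenase")
  if (inc$hydrogenases) {
    add("HDH_1", c(nadh_c = -1, h_c = -1, nad_c = 1, h2_c = 1),
        lb = -BIG_BOUND, gpr = "gHoxH", subsystem = "Hydrogen",
        name = "Bidirectional hydrogenase (NADH)")
    add("HDH_2", c(nadph_c = -1, h_c = -1, nadp_c = 1, h2_c = 1),
        lb = -BIG_BOUND, gpr = "gHoxY", subsystem = "Hydrogen",
        name = "Bidirectional hydrogenase (NADPH)")
    add("UPHYDR", c(h2_c = -1, fdox_c = -2, fdred_c = 2, h_c = 2),
        gpr = "gHupL and gHupS", subsystem = "Hydrogen",
        name = "Uptake hydrogenase")
  }

  comp <- composition
  if (!inc$cyanophycin && comp@fractions["cyanophycin"] > 0) {
    f <- comp@fractions
    f["protein"] <- f["protein"] + f["cyanophycin"]
    f["cyanophycin"] <- 0
    comp <- new("BiomassComposition", fractions = f,
                aminoAcidProfile = comp@aminoAcidProfile)
  }
  bio <- buildBiomassEquation(comp, toyMonomerTable(), gar = spec$gar)
  rx[[bio$id]] <- bio

  metInfo <- data.frame(
    id = c("photon_psii", "photon_psi", "h_c", "h_l", "h2o_c", "o2_c",
           "co2_c", "n2_c", "h2_c", "nh4_c", "pq_c", "pqh2_c", "pcox_c",
           "pcred_c", "fdox_c", "fdred_c", "nadp_c", "nadph_c", "nad_c",
           "nadh_c", "adp_c", "atp_c", "pi_c", "cx_c", "glycogen_c",
           "cph_c"),
    compartment = c("e", "e", "c", "l", rep("c", 22)),
    formula = c(NA, NA, "H", "H", "H2O", "O2", "CO2", "N2", "H2", "NH4",
                "Pq", "PqH2", "Pc", "Pc", "Fdx", "Fdx", "Ndp", "NdpH",
                "Ncd", "NcdH", "Adn", "AdnPoO3", "PoO4H", "CH2O",
                "C6H10O5", "C2H5NO"),
    charge = c(NA, NA, 1, 1, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 0, 1, 0,
               1, 0, -3, -4, -2, 0, 0, 0),
    stringsAsFactors = FALSE)
  metInfo <- metInfo[metInfo$id %in%
                       unique(unlist(lapply(rx, function(r) names(r$stoich)))), ]
  net <- makeNetwork(unname(rx), metaboliteInfo = metInfo,
                     objective = "BIOMASS",
                     compartments = c("c", "l", "e"))
  ## viability: photoautotrophic growth must be possible with both photon
  ## exchanges open
  g <- solveFba(net, photonConstraints(30, 30, mode = "upper_bound"))
  if (g@status != "optimal" || g@objectiveValue <= 1e-9)
    stop("unviable toy specification: no path from photons to biomass ",
         "with the chosen feature flags")
  net
}

#' Photon-uptake constraints
#'
#' Builds the constraint list fixing (or upper-bounding) the PSII and PSI
#' photon uptake fluxes. Uptake values are positive, in
#' mmol photon g-1 AFDW h-1.
#'
#' @param psii,psi photon uptake values (>= 0).
#' @param mode `"fixed"` (both uptakes forced, as in phase-plane
#'   construction) or `"upper_bound"`.
#' @param psiiId,psiId exchange reaction ids.
#' @return constraint list for [solveFba()] and friends.
#' @export
photonConstraints <- function(psii, psi, mode = c("fixed", "upper_bound"),
                              psiiId = "EX_photon_psii",
                              psiId = "EX_photon_psi") {
  mode <- match.arg(mode)
  stopifnot(psii >= 0, psi >= 0)
  if (mode == "fixed")
    list(list(reaction = psiiId, fixed = psii),
         list(reaction = psiId, fixed = psi))
  else
    list(list(reaction = psiiId, lb = 0, ub = psii),
         list(reaction = psiId, lb = 0, ub = psi))
}

#' Simulate expression evidence from a known flux state
#'
#' Genes supporting at least one active reaction (|flux| above
#' `activeTol`) are detected with probability `detectProbActive`; genes of
#' inactive reactions with `detectProbInactive`. log2 mRNA levels are
#' drawn from normals centered at `mrnaMeanActive` / `mrnaMeanInactive`.
#' Bit-reproducible under `seed`.
#'
#' @param network a [MetabolicNetwork-class].
#' @param trueFlux a [FluxDistribution-class] on the same network.
#' @param detectProbActive,detectProbInactive detection probabilities.
#' @param mrnaMeanActive,mrnaMeanInactive,mrnaSd log2-scale parameters.
#' @param mrnaThreshold low-expression cutoff stored in the result.
#' @param activeTol flux magnitude above which a reaction counts active.
#' @param seed integer RNG seed.
#' @return an [ExpressionEvidence-class].
#' @export
simulateExpression <- function(network, trueFlux,
                               detectProbActive = 0.9,
                               detectProbInactive = 0.05,
                               mrnaMeanActive = 10, mrnaMeanInactive = 5,
                               mrnaSd = 1, mrnaThreshold = 8,
                               activeTol = 1e-6, seed = 1) {
  stopifnot(is(trueFlux, "FluxDistribution"),
            detectProbActive >= 0, detectProbActive <= 1,
            detectProbInactive >= 0, detectProbInactive <= 1, mrnaSd >= 0)
  v <- fluxValues(trueFlux)
  rules <- gprRules(network)
  geneActive <- list()
  for (rid in names(rules)) {
    gs <- gprGenes(rules[rid])
    if (!length(gs)) next
    act <- abs(v[rid]) > activeTol
    for (g in gs)
      geneActive[[g]] <- isTRUE(geneActive[[g]]) || act
  }
  genes <- sort(names(geneActive))
  active <- vapply(genes, function(g) isTRUE(geneActive[[g]]), logical(1))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  res <- withr_seed({
    det <- stats::runif(length(genes)) <
      ifelse(active, detectProbActive, detectProbInactive)
    mrna <- stats::rnorm(length(genes),
                         mean = ifelse(active, mrnaMeanActive,
                                       mrnaMeanInactive),
                         sd = mrnaSd)
    list(det = det, mrna = mrna)
  })
  new("ExpressionEvidence",
      proteinDetected = genes[res$det],
      mrnaLog2 = stats::setNames(res$mrna, genes),
      mrnaThreshold = mrnaThreshold)
}

#' Simulate batch photobioreactor observations
#'
#' For each photon-uptake pair the growth rate is computed by FBA on a
#' network carrying the true GAR/NGAR, then multiplicative Gaussian noise
#' with coefficient of variation `noiseCv` is applied. Infeasible photon
#' pairs are skipped with a warning. Columns mirror the batch-table
#' layout: uptake at 630 nm drives PSII, at 680 nm PSI.
#'
#' @param network a network whose biomass carries the true GAR and whose
#'   maintenance bound is the true NGAR (e.g. from [makeToyNetwork()]).
#' @param photonGrid two-column matrix of (PSII, PSI) uptakes.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @return data.frame with columns `batch`, `uptake_630`, `uptake_680`,
#'   `growth`.
#' @export
simulateBatches <- function(network, photonGrid, noiseCv = 0, seed = 1) {
  stopifnot(ncol(photonGrid) == 2, nrow(photonGrid) >= 2, noiseCv >= 0)
  out <- list()
  set.seed(seed)
  zs <- stats::rnorm(nrow(photonGrid))
  for (i in seq_len(nrow(photonGrid))) {
    fb <- solveFba(network, photonConstraints(photonGrid[i, 1],
                                              photonGrid[i, 2]))
    if (fb@status != "optimal") {
      warning("photon pair (", photonGrid[i, 1], ", ", photonGrid[i, 2],
              ") infeasible; skipped")
      next
    }
    mu <- fb@objectiveValue * (1 + noiseCv * zs[i])
    out[[length(out) + 1L]] <- data.frame(
      batch = i, uptake_630 = photonGrid[i, 1],
      uptake_680 = photonGrid[i, 2], growth = max(mu, 0))
  }
  do.call(rbind, out)
}

#' Default batch photon grid for ATP-requirement studies
#'
#' Photon-uptake pairs lying in the dual-limited (energy-sensitive) region
#' of the toy phase plane, where the maximal ATP-hydrolysis flux varies
#' linearly with growth rate and the GAR/NGAR regression is identifiable.
#' PSI uptake is set to 0.7 of PSII uptake.
#'
#' @param n number of batches (>= 2).
#' @param psiiRange PSII photon-uptake range.
#' @return two-column matrix of (PSII, PSI) uptakes.
#' @export
toyBatchGrid <- function(n = 8, psiiRange = c(20, 55)) {
  psii <- seq(psiiRange[1], psiiRange[2], length.out = n)
  cbind(psii = psii, psi = 0.7 * psii)
}
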