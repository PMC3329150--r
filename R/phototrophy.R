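## Photon-resolved analyses: phenotypic phase planes over PSII/PSI photon
## uptake, limitation diagnosis via artificial energy/reductant reactions,
## region-wise flux variability, and electron-transport scenario scans.

## marginal value of each photon constraint at a grid point by forward
## finite differences. The LP value function is piecewise linear in the
## photon uptakes, so a fixed small probe step returns the exact
## right-derivative and labels are stable under grid refinement (duals at
## phase-plane vertices are systematically degenerate, so the probe is
## the primary mechanism).
photonMarginals <- function(network, psii, psi, mode, probe = 0.25,
                            dualTol = 1e-6) {
  fb <- solveFba(network, photonConstraints(psii, psi, mode))
  if (fb@status != "optimal") return(c(NA_real_, NA_real_))
  g0 <- fb@objectiveValue
  g2 <- solveFba(network, photonConstraints(psii + probe, psi, mode))
  g1 <- solveFba(network, photonConstraints(psii, psi + probe, mode))
  d2 <- if (g2@status == "optimal") (g2@objectiveValue - g0) / probe else NA
  d1 <- if (g1@status == "optimal") (g1@objectiveValue - g0) / probe else NA
  c(psii = d2, psi = d1)
}

#' Compute a phenotypic phase plane over photon uptakes
#'
#' For every grid point the growth rate is the FBA optimum under the given
#' photon regime. Regions are delineated by the pattern of positive
#' marginal value of the two photon constraints (region 1: only PSII
#' limiting; region 3: only PSI limiting; region 2: both). Cells where
#' growth is zero or infeasible get region 0. Each region is diagnosed as
#' reductant- or energy-limited via [diagnoseLimitation()] at an interior
#' point.
#'
#' @param network a [MetabolicNetwork-class] with distinct PSII and PSI
#'   photon exchange reactions.
#' @param psiiRange,psiRange numeric length-2 ranges (mmol g-1 AFDW h-1).
#' @param step grid step (> 0).
#' @param mode `"fixed"` photon uptakes (default, phase-plane convention)
#'   or `"upper_bound"`.
#' @param dualTol tolerance for calling a marginal value positive.
#' @return a [PhppGrid-class].
#' @export
computePhpp <- function(network, psiiRange = c(0, 60), psiRange = c(0, 60),
                        step = 5, mode = c("fixed", "upper_bound"),
                        dualTol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(step > 0)
  for (rid in c("EX_photon_psii", "EX_photon_psi"))
    if (!rid %in% network@reactions$id)
      stop("network lacks photon exchange reaction ", rid)
  ax2 <- seq(psiiRange[1], psiiRange[2], by = step)
  ax1 <- seq(psiRange[1], psiRange[2], by = step)
  growth <- matrix(0, length(ax2), length(ax1))
  lim2 <- lim1 <- matrix(NA_real_, length(ax2), length(ax1))
  for (i in seq_along(ax2)) for (j in seq_along(ax1)) {
    fb <- solveFba(network, photonConstraints(ax2[i], ax1[j], mode))
    g <- if (fb@status == "optimal") max(fb@objectiveValue, 0) else 0
    growth[i, j] <- g
    if (g > dualTol) {
      m <- photonMarginals(network, ax2[i], ax1[j], mode,
                           dualTol = dualTol)
      lim2[i, j] <- m[1]; lim1[i, j] <- m[2]
    }
  }
  region <- matrix(0L, length(ax2), length(ax1))
  for (i in seq_along(ax2)) for (j in seq_along(ax1)) {
    if (growth[i, j] <= dualTol) next
    p2pos <- isTRUE(lim2[i, j] > dualTol)
    p1pos <- isTRUE(lim1[i, j] > dualTol)
    region[i, j] <- if (p2pos && p1pos) 2L else if (p2pos) 1L
                    else if (p1pos) 3L else 0L
  }
  ## diagnose limitation per region at an interior representative point
  regs <- sort(setdiff(unique(as.vector(region)), 0L))
  limitation <- character(0)
  for (r in regs) {
    cells <- which(region == r, arr.ind = TRUE)
    ## pick the cell closest to the region centroid
    cen <- colMeans(cells)
    k <- which.min((cells[, 1] - cen[1])^2 + (cells[, 2] - cen[2])^2)
    limitation[as.character(r)] <- diagnoseLimitation(
      network, psii = ax2[cells[k, 1]], psi = ax1[cells[k, 2]], mode = mode)
  }
  new("PhppGrid", psii = ax2, psi = ax1, growth = growth,
      regionId = region, limitation = limitation, mode = mode)
}

#' Diagnose growth limitation at a photon regime
#'
#' Adds, separately, a small-capacity artificial ATP-generating reaction
#' (ADP + Pi + H -> ATP + H2O) and an artificial NADPH-generating reaction
#' (NADP + H -> NADPH), and labels the regime by which addition strictly
#' increases the optimal growth rate: only ATP -> `"energy_limited"`,
#' only NADPH -> `"reductant_limited"`, both -> `"mixed"`, neither ->
#' `"neither"` (e.g. carbon-limited).
#'
#' @param network a [MetabolicNetwork-class].
#' @param psii,psi photon uptakes.
#' @param mode photon constraint mode.
#' @param delta capacity of the artificial reactions (default 0.1
#'   mmol g-1 AFDW h-1).
#' @param tol strict-increase threshold on growth (default 1e-8 h-1).
#' @param species named ids of adp/atp/pi/h2o/h/nadp/nadph metabolites
#'   (defaults match the toy network).
#' @return character label.
#' @export
diagnoseLimitation <- function(network, psii, psi,
                               mode = c("fixed", "upper_bound"),
                               delta = 0.1, tol = 1e-8,
                               species = c(adp = "adp_c", atp = "atp_c",
                                           pi = "pi_c", h2o = "h2o_c",
                                           h = "h_c", nadp = "nadp_c",
                                           nadph = "nadph_c")) {
  mode <- match.arg(mode)
  cts <- photonConstraints(psii, psi, mode)
  base <- solveFba(network, cts)
  if (base@status != "optimal")
    stop("photon regime infeasible; cannot diagnose limitation")
  atpRx <- list(id = "ART_ATP", stoich = stats::setNames(
    c(-1, -1, -1, 1, 1),
    unname(species[c("adp", "pi", "h", "atp", "h2o")])),
    lower_bound = 0, upper_bound = delta)
  nadphRx <- list(id = "ART_NADPH", stoich = stats::setNames(
    c(-1, -1, 1), unname(species[c("nadp", "h", "nadph")])),
    lower_bound = 0, upper_bound = delta)
  gain <- function(rx) {
    net2 <- addReaction(network, rx)
    fb <- solveFba(net2, cts)
    if (fb@status != "optimal") return(0)
    fb@objectiveValue - base@objectiveValue
  }
  atpGain <- gain(atpRx) > tol
  nadphGain <- gain(nadphRx) > tol
  if (atpGain && nadphGain) "mixed"
  else if (atpGain) "energy_limited"
  else if (nadphGain) "reductant_limited"
  else "neither"
}

#' Region-wise flux variability over a phase plane (PhPP FVA)
#'
#' For sampled points of a region, growth is fixed to its maximum at that
#' point and FVA is run over the target reactions. A reaction is `active`
#' in the region if its min and max flux share a sign and exclude zero at
#' every sampled point, `blocked` if its range is [0,0] at every point,
#' and `optional` otherwise.
#'
#' @param network a [MetabolicNetwork-class].
#' @param grid a [PhppGrid-class].
#' @param regionIds regions to analyze (default: all nonzero).
#' @param reactions reaction ids to classify (default: all non-exchange).
#' @param sampleDensity maximum points sampled per region (default 25,
#'   i.e. a 5x5-equivalent sample).
#' @param zeroTol zero tolerance on ranges.
#' @return named list: region id -> named character vector of labels.
#' @export
phppFva <- function(network, grid, regionIds = NULL, reactions = NULL,
                    sampleDensity = 25, zeroTol = 1e-9) {
  stopifnot(is(grid, "PhppGrid"))
  reactions <- reactions %||%
    network@reactions$id[!network@reactions$is_exchange]
  regionIds <- regionIds %||% sort(setdiff(unique(as.vector(grid@regionId)), 0L))
  out <- list()
  for (r in regionIds) {
    cells <- which(grid@regionId == r, arr.ind = TRUE)
    if (nrow(cells) == 0) stop("region ", r, " is empty")
    if (nrow(cells) == 1)
      warning("region ", r, " contains a single grid point")
    take <- unique(round(seq(1, nrow(cells),
                             length.out = min(sampleDensity, nrow(cells)))))
    lab <- NULL
    for (k in take) {
      p2 <- grid@psii[cells[k, 1]]; p1 <- grid@psi[cells[k, 2]]
      cts <- photonConstraints(p2, p1, grid@mode)
      fva <- runFva(network, cts, reactions = reactions,
                    fixObjective = "max")
      rg <- fvaRanges(fva)
      ptLab <- ifelse(rg[, "min"] > zeroTol | rg[, "max"] < -zeroTol,
                      "active",
               ifelse(abs(rg[, "min"]) <= zeroTol &
                      abs(rg[, "max"]) <= zeroTol, "blocked", "optional"))
      if (is.null(lab)) lab <- ptLab
      else {
        ## aggregate: active only if active everywhere; blocked only if
        ## blocked everywhere; anything mixed is optional
        lab <- ifelse(lab == ptLab, lab, "optional")
      }
    }
    out[[as.character(r)]] <- lab
  }
  out
}

#' Electron-transport scenario scan
#'
#' Removes named reaction sets (e.g. cyclic photosynthesis routes,
#' alternative reductant sinks), fixes the PSII photon uptake, and scans
#' PSI photon uptake values, reporting maximal growth and the secreted
#' products at a flux-norm-minimal optimum.
#'
#' @param network a [MetabolicNetwork-class].
#' @param removedSets named list of reaction-id vectors to delete; ids not
#'   present in the model are ignored with a message.
#' @param psiiFixed fixed PSII photon uptake.
#' @param psiValues PSI photon uptake values to scan.
#' @param secretionExclude exchange ids never reported as products
#'   (inorganic exchanges by default).
#' @return data.frame with columns `scenario`, `psi`, `growth`,
#'   `feasible` (the photon regime admits a steady state), `grows`
#'   (growth above 1e-9), `secreted` (comma-separated exchange ids).
#' @export
scenarioScan <- function(network, removedSets, psiiFixed, psiValues,
                         secretionExclude = c("EX_h2o", "EX_h", "EX_o2",
                                              "EX_co2")) {
  res <- list()
  for (nm in names(removedSets)) {
    ids <- removedSets[[nm]]
    known <- intersect(ids, network@reactions$id)
    if (length(setdiff(ids, known)))
      message("scenario ", nm, ": ignoring absent reaction(s) ",
              paste(setdiff(ids, known), collapse = ", "))
    net2 <- if (length(known)) deleteReactions(network, known) else network
    anyGrowth <- FALSE
    for (p1 in psiValues) {
      cts <- photonConstraints(psiiFixed, p1, "fixed")
      fb <- solveFba(net2, cts)
      feasible <- fb@status == "optimal"
      grows <- feasible && fb@objectiveValue > 1e-9
      secreted <- ""
      if (grows) {
        anyGrowth <- TRUE
        mn <- minimizeFluxNorm(net2, fb@objectiveValue, cts)
        if (mn@status == "optimal") {
          v <- fluxValues(mn)
          ex <- network@reactions$id[network@reactions$is_exchange]
          ex <- setdiff(intersect(ex, names(v)),
                        c(secretionExclude, "EX_photon_psii",
                          "EX_photon_psi"))
          pos <- ex[v[ex] > 1e-6]
          secreted <- paste(pos, collapse = ",")
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        scenario = nm, psi = p1,
        growth = if (grows) fb@objectiveValue else 0,
        feasible = feasible, grows = grows, secreted = secreted,
        stringsAsFactors = FALSE)
    }
    if (!anyGrowth)
      message("scenario ", nm, ": no growth at any scanned PSI value")
  }
  do.call(rbind, res)
}
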