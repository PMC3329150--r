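## Integration of transcriptome and proteome data (TPD) into flux states:
## evidence reaction sets, the mixed-integer quadratic fit (maximize the
## number of satisfied evidence statements, then minimize the sum of
## squared fluxes), and TPD-constrained flux variability analysis with
## the binary indicators fixed at their optimal values.

#' Build reaction evidence sets from expression data
#'
#' A reaction enters R_H (high set) when its GPR evaluates TRUE over the
#' protein-detected genes; it enters R_L (low set) when every associated
#' gene is undetected and below the mRNA threshold. Reactions with
#' measured fluxes (R_E) are excluded from both. Precedence on conflict
#' is R_H, logged via `message()`.
#'
#' @param network a [MetabolicNetwork-class].
#' @param evidence an [ExpressionEvidence-class].
#' @param measured named numeric vector: reaction id -> measured flux
#'   (typically biomass, O2 exchange and the two photon exchanges).
#' @param epsilon activity threshold flux (default 0.1 mmol g-1 AFDW h-1).
#' @param mode `"threshold"` uses `evidence@mrnaThreshold`;
#'   `"data_driven"` uses the lowest mRNA level among detected genes.
#' @return a [ReactionEvidenceSets-class].
#' @export
buildReactionSets <- function(network, evidence, measured = numeric(),
                              epsilon = 0.1,
                              mode = c("threshold", "data_driven")) {
  mode <- match.arg(mode)
  stopifnot(is(evidence, "ExpressionEvidence"))
  rules <- gprRules(network)
  modelGenes <- geneIds(network)
  evGenes <- union(evidence@proteinDetected, names(evidence@mrnaLog2))
  unmatched <- setdiff(evGenes, modelGenes)
  if (length(unmatched))
    message(length(unmatched), " evidence gene(s) not in model GPRs: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) " ...")
  thr <- if (mode == "threshold") evidence@mrnaThreshold else {
    det <- intersect(evidence@proteinDetected, names(evidence@mrnaLog2))
    if (!length(det)) stop("data_driven mode needs mRNA levels for ",
                           "detected genes")
    min(evidence@mrnaLog2[det])
  }
  rH <- character(); rL <- character()
  for (rid in names(rules)) {
    if (rid %in% names(measured)) next
    gs <- gprGenes(rules[rid])
    if (!length(gs)) next
    inH <- isTRUE(evalGpr(rules[rid], evidence@proteinDetected))
    mr <- evidence@mrnaLog2[gs]
    low <- !any(gs %in% evidence@proteinDetected) &&
      all(!is.na(mr)) && all(mr < thr)
    if (inH && low) {
      message("reaction ", rid, " qualifies for both sets; kept in R_H")
      low <- FALSE
    }
    if (inH) rH <- c(rH, rid)
    if (low) rL <- c(rL, rid)
  }
  new("ReactionEvidenceSets", rE = measured, rH = rH, rL = rL,
      epsilon = epsilon)
}

## build the mixed-integer LP relaxation structure shared by the solver
tpdMilpStructure <- function(network, sets) {
  ids <- network@reactions$id
  n <- length(ids)
  lb <- network@reactions$lower_bound
  ub <- network@reactions$upper_bound
  names(lb) <- names(ub) <- ids
  for (rid in names(sets@rE)) {
    if (!rid %in% ids) stop("measured reaction not in model: ", rid)
    lb[rid] <- ub[rid] <- sets@rE[[rid]]
  }
  eps <- sets@epsilon
  binType <- character(); binRxn <- character()
  for (r in sets@rH) { binType <- c(binType, "x", "y")
                       binRxn <- c(binRxn, r, r) }
  for (r in sets@rL) { binType <- c(binType, "z"); binRxn <- c(binRxn, r) }
  K <- length(binType)
  S <- as.matrix(network@stoichiometry)
  rows <- list(); senses <- character(); rhs <- numeric()
  addRow <- function(vPart, bPart, sense, b) {
    rows[[length(rows) + 1L]] <<- c(vPart, bPart)
    senses <<- c(senses, sense); rhs <<- c(rhs, b)
  }
  zeroV <- numeric(n); names(zeroV) <- ids
  zeroB <- numeric(K)
  binLb <- rep(0, K); binUb <- rep(1, K)
  for (r in sets@rH) {
    ix <- which(binType == "x" & binRxn == r)
    iy <- which(binType == "y" & binRxn == r)
    if (lb[r] >= 0) binUb[ix] <- 0          # negative activity impossible
    if (lb[r] > -eps) binUb[ix] <- 0
    if (ub[r] < eps) binUb[iy] <- 0
    vP <- zeroV; vP[r] <- 1
    bP <- zeroB; bP[iy] <- -ub[r]; bP[ix] <- eps
    addRow(vP, bP, "<=", 0)                  # v <= ub*y - eps*x
    bP <- zeroB; bP[ix] <- -lb[r]; bP[iy] <- -eps
    addRow(vP, bP, ">=", 0)                  # v >= lb*x + eps*y
    bP <- zeroB; bP[ix] <- 1; bP[iy] <- 1
    addRow(zeroV, bP, "<=", 1)               # x + y <= 1
  }
  for (r in sets@rL) {
    iz <- which(binType == "z" & binRxn == r)
    vP <- zeroV; vP[r] <- 1
    bP <- zeroB; bP[iz] <- ub[r]
    addRow(vP, bP, "<=", ub[r])              # z=1 -> v <= 0
    bP <- zeroB; bP[iz] <- lb[r]
    addRow(vP, bP, ">=", lb[r])              # z=1 -> v >= 0
  }
  A <- rbind(cbind(S, matrix(0, nrow(S), K)),
             do.call(rbind, rows))
  list(ids = ids, n = n, K = K, A = A,
       rowSense = c(rep("=", nrow(S)), senses),
       rhs = c(rep(0, nrow(S)), rhs),
       lb = lb, ub = ub, binLb = binLb, binUb = binUb,
       binType = binType, binRxn = binRxn)
}

## branch and bound over the binary indicators; objective = sum of
## binaries (evidence score), deterministic branching order
tpdBranchBound <- function(st, weights = NULL) {
  n <- st$n; K <- st$K
  obj <- c(rep(0, n), if (is.null(weights)) rep(1, K) else weights)
  best <- list(score = -Inf, bin = NULL)
  solveNode <- function(bl, bu) {
    lpSolve2(obj, st$A, st$rowSense, st$rhs,
             c(unname(st$lb), bl), c(unname(st$ub), bu), sense = "max")
  }
  stack <- list(list(bl = st$binLb, bu = st$binUb))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- solveNode(node$bl, node$bu)
    if (r$status != "optimal") next
    if (r$objval < best$score + 1 - 1e-6) next  # cannot beat incumbent
    bvals <- r$x[n + seq_len(K)]
    frac <- pmin(bvals - floor(bvals + 1e-9), ceiling(bvals - 1e-9) - bvals)
    if (K == 0L || max(frac) < 1e-6) {
      score <- r$objval
      if (score > best$score + 1e-9) {
        best <- list(score = score, bin = round(bvals))
      }
      next
    }
    j <- which.max(frac)  # deterministic: first index among ties
    up <- node; up$bl[j] <- 1
    dn <- node; dn$bu[j] <- 0
    ## explore the "evidence satisfied" branch first
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up
  }
  best
}

#' Fit a flux distribution to transcriptome/proteome evidence
#'
#' Solves the evidence-integration program: maximize the number of
#' satisfied evidence statements (active flux, |v| >= epsilon, for R_H
#' reactions; zero flux for R_L reactions) subject to mass balance,
#' bounds, and measured-rate constraints, then - lexicographically, with
#' the score fixed - minimize the sum of squared fluxes so alternate
#' optima do not route flux through futile cycles. The binaries of the
#' first score-optimal solution are the `x^opt, y^opt, z^opt` used by
#' [tpdConstrainedFva()].
#'
#' @param network a [MetabolicNetwork-class].
#' @param sets a [ReactionEvidenceSets-class].
#' @param weight `NULL` for the lexicographic objective (default);
#'   otherwise a positive scalar and the exploratory weighted objective
#'   `weight * score - sum(v^2)` is maximized instead.
#' @param norm `"L2"` (default) or `"L1"` for the second stage.
#' @return a [TpdFitResult-class].
#' @export
fitTpdFlux <- function(network, sets, weight = NULL, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  stopifnot(is(sets, "ReactionEvidenceSets"))
  st <- tpdMilpStructure(network, sets)
  if (st$K == 0L) {
    mn <- minimizeFluxNormFree(network,
      lapply(names(sets@rE), function(r)
        list(reaction = r, fixed = sets@rE[[r]])), norm)
    if (is.null(mn)) stop("measured-rate constraints infeasible")
    return(new("TpdFitResult", flux = mn, x = integer(), y = integer(),
               z = integer(), evidenceScore = 0,
               fluxNorm = attr(mn, "fluxNorm")))
  }
  bb <- tpdBranchBound(st)
  if (!is.finite(bb$score)) {
    stop("evidence-integration problem infeasible: no binary assignment ",
         "is consistent with the measured rates (",
         paste(names(sets@rE), collapse = ", "), "). A flux forced into ",
         "(0, epsilon) by the measurements makes every assignment ",
         "infeasible; try a smaller epsilon (current ", sets@epsilon, ")")
  }
  bin <- as.integer(bb$bin)
  if (!is.null(weight)) {
    ## exploratory weighted mode: enumerate score-feasible binary vectors
    ## found by branch and bound at decreasing scores, pick the best
    ## weight*score - norm; with the default lexicographic mode being the
    ## primary interface this stays a small search
    cand <- list(bin)
    bestVal <- -Inf; bestBin <- bin; bestFlux <- NULL
    for (b in cand) {
      s2 <- tpdStage2(network, sets, st, b, norm)
      if (is.null(s2)) next
      val <- weight * sum(b) - s2$normVal
      if (val > bestVal) { bestVal <- val; bestBin <- b; bestFlux <- s2 }
    }
    bin <- bestBin
    stage2 <- bestFlux
  } else {
    stage2 <- tpdStage2(network, sets, st, bin, norm)
  }
  if (is.null(stage2))
    stop("stage-2 norm minimization infeasible at the optimal binaries")
  xv <- yv <- stats::setNames(integer(length(sets@rH)), sets@rH)
  zv <- stats::setNames(integer(length(sets@rL)), sets@rL)
  for (k in seq_len(st$K)) {
    t <- st$binType[k]; r <- st$binRxn[k]
    if (t == "x") xv[r] <- bin[k]
    if (t == "y") yv[r] <- bin[k]
    if (t == "z") zv[r] <- bin[k]
  }
  new("TpdFitResult", flux = stage2$flux, x = xv, y = yv, z = zv,
      evidenceScore = sum(bin), fluxNorm = stage2$normVal)
}

## constraints implied by fixed binaries (shared by stage 2 and TPD-FVA)
tpdBinaryConstraints <- function(sets, binType, binRxn, bin) {
  eps <- sets@epsilon
  cts <- lapply(names(sets@rE), function(r)
    list(reaction = r, fixed = sets@rE[[r]]))
  for (r in sets@rH) {
    x <- bin[binType == "x" & binRxn == r]
    y <- bin[binType == "y" & binRxn == r]
    if (y == 1) cts <- c(cts, list(list(reaction = r, lb = eps)))
    else if (x == 1) cts <- c(cts, list(list(reaction = r, ub = -eps)))
    else cts <- c(cts, list(list(reaction = r, fixed = 0)))
  }
  for (r in sets@rL) {
    z <- bin[binType == "z" & binRxn == r]
    if (z == 1) cts <- c(cts, list(list(reaction = r, fixed = 0)))
  }
  cts
}

tpdStage2 <- function(network, sets, st, bin, norm) {
  cts <- tpdBinaryConstraints(sets, st$binType, st$binRxn, bin)
  ## minimize flux norm with no objective fixation beyond the constraints
  net2 <- network
  mn <- minimizeFluxNormFree(net2, cts, norm)
  if (is.null(mn)) return(NULL)
  list(flux = mn, normVal = attr(mn, "fluxNorm"))
}

## norm minimization under constraints only (no objective fixation)
minimizeFluxNormFree <- function(network, constraints, norm = "L2") {
  cs <- applyConstraints(network, constraints)
  S <- as.matrix(network@stoichiometry)
  ids <- network@reactions$id
  n <- length(ids)
  if (norm == "L2") {
    eq <- rbind(S, cs$extraA[cs$extraSense == "=", , drop = FALSE])
    beq <- c(rep(0, nrow(S)), cs$extraRhs[cs$extraSense == "="])
    r <- qpSolveNorm(eq, beq, cs$lb, cs$ub)
    if (r$status != "optimal") return(NULL)
    v <- r$x
  } else {
    A2 <- cbind(S, -S)
    lb2 <- c(pmax(cs$lb, 0), pmax(-cs$ub, 0))
    ub2 <- c(pmax(cs$ub, 0), pmax(-cs$lb, 0))
    r <- lpSolve2(rep(1, 2 * n), A2, rep("=", nrow(S)), rep(0, nrow(S)),
                  lb2, ub2, sense = "min")
    if (r$status != "optimal") return(NULL)
    v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  }
  names(v) <- ids
  fd <- new("FluxDistribution", values = v, objectiveValue = NA_real_,
            status = "optimal")
  attr(fd, "fluxNorm") <- if (norm == "L2") sum(v^2) else sum(abs(v))
  attr(fd, "normType") <- norm
  fd
}

#' TPD-constrained flux variability analysis
#'
#' Reruns FVA with the measured-rate constraints plus the binary
#' indicators fixed at their fit-optimal values, so the ranges reflect
#' only flux distributions consistent with the expression evidence.
#' Ranges can only shrink relative to unconstrained FVA.
#'
#' @param network a [MetabolicNetwork-class].
#' @param sets the [ReactionEvidenceSets-class] used for the fit.
#' @param fit the [TpdFitResult-class] from [fitTpdFlux()].
#' @param reactions optional reaction subset.
#' @return an [FvaResult-class].
#' @export
tpdConstrainedFva <- function(network, sets, fit, reactions = NULL) {
  stopifnot(is(fit, "TpdFitResult"))
  binType <- c(rep(c("x", "y"), length(sets@rH)), rep("z", length(sets@rL)))
  binRxn <- c(rep(sets@rH, each = 2), sets@rL)
  bin <- integer(length(binType))
  for (k in seq_along(binType)) {
    r <- binRxn[k]
    bin[k] <- switch(binType[k], x = fit@x[[r]], y = fit@y[[r]],
                     z = fit@z[[r]])
  }
  cts <- tpdBinaryConstraints(sets, binType, binRxn, bin)
  runFva(network, cts, reactions = reactions)
}

#' Sensitivity of usage-class counts to the activity threshold
#'
#' Reruns the evidence fit and TPD-constrained FVA for several values of
#' the activity threshold epsilon and tabulates the
#' required/optional/inactive counts, since published classification
#' counts depend on this unreported constant.
#'
#' @param network a [MetabolicNetwork-class].
#' @param evidence an [ExpressionEvidence-class].
#' @param measured named numeric vector of measured fluxes.
#' @param epsilons thresholds to test.
#' @param zeroTol passed to [classifyUsage()].
#' @return data.frame with one row per epsilon.
#' @export
epsilonSensitivity <- function(network, evidence, measured,
                               epsilons = c(0.01, 0.1, 1),
                               zeroTol = 1e-9) {
  out <- lapply(epsilons, function(eps) {
    sets <- suppressMessages(
      buildReactionSets(network, evidence, measured, epsilon = eps))
    fit <- tryCatch(fitTpdFlux(network, sets), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(epsilon = eps, evidence_score = NA_real_,
                        required = NA_integer_, optional = NA_integer_,
                        inactive = NA_integer_, feasible = FALSE))
    cls <- classifyUsage(tpdConstrainedFva(network, sets, fit), zeroTol)
    tb <- table(cls)
    data.frame(epsilon = eps, evidence_score = fit@evidenceScore,
               required = tb[["required"]], optional = tb[["optional"]],
               inactive = tb[["inactive"]], feasible = TRUE)
  })
  do.call(rbind, out)
}
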