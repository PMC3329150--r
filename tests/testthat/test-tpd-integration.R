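## Evidence reaction sets and the mixed-integer evidence-integration fit.

## chemostat-like measured rates reused across tests
toyMeasured <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      net <- toyNet()
      cts <- photonConstraints(20, 14)
      mu <- objectiveValue(solveFba(net, cts))
      mn <- minimizeFluxNorm(net, mu, cts)
      m <<- list(
        meas = c(BIOMASS = mu, EX_o2 = unname(fluxValues(mn)["EX_o2"]),
                 EX_photon_psii = 20, EX_photon_psi = 14),
        truth = mn)
    }
    m
  }
})

test_that("evidence sets respect AND semantics and set exclusions", {
  net <- toyNet()
  ## PSII needs gPsbA AND gPsbD: detecting one subunit is not enough
  ev1 <- new("ExpressionEvidence", proteinDetected = "gPsbA",
             mrnaLog2 = numeric(), mrnaThreshold = 8)
  sets1 <- suppressMessages(buildReactionSets(net, ev1))
  expect_false("PSII" %in% sets1@rH)
  ev2 <- new("ExpressionEvidence", proteinDetected = c("gPsbA", "gPsbD"),
             mrnaLog2 = numeric(), mrnaThreshold = 8)
  sets2 <- suppressMessages(buildReactionSets(net, ev2))
  expect_true("PSII" %in% sets2@rH)
  ## an isozyme pair needs only one detection
  ev3 <- new("ExpressionEvidence", proteinDetected = "gCydA",
             mrnaLog2 = numeric(), mrnaThreshold = 8)
  expect_true("QOX" %in% suppressMessages(buildReactionSets(net, ev3))@rH)
  ## measured reactions never enter either set
  mu <- toyMeasured()
  sets4 <- suppressMessages(buildReactionSets(net, ev2, mu$meas))
  expect_false("BIOMASS" %in% c(sets4@rH, sets4@rL))
})

test_that("undetected genes below the mRNA threshold populate the low set", {
  net <- toyNet()
  genes <- geneIds(net)
  ev <- new("ExpressionEvidence", proteinDetected = character(),
            mrnaLog2 = stats::setNames(rep(4, length(genes)), genes),
            mrnaThreshold = 8)
  sets <- suppressMessages(buildReactionSets(net, ev))
  expect_length(sets@rH, 0)
  geneAssoc <- names(gprRules(net))[nzchar(gprRules(net))]
  expect_setequal(sets@rL, geneAssoc)
  ## data-driven threshold: lowest mRNA among detected proteins
  ev2 <- new("ExpressionEvidence",
             proteinDetected = c("gPsbA", "gPsbD"),
             mrnaLog2 = stats::setNames(c(6, 7, rep(4, length(genes) - 2)),
                                        c("gPsbA", "gPsbD",
                                          setdiff(genes, c("gPsbA", "gPsbD")))),
             mrnaThreshold = 8)
  sets2 <- suppressMessages(buildReactionSets(net, ev2,
                                              mode = "data_driven"))
  ## threshold is 6, so genes at 4 are low but nothing at >= 6 is
  expect_true(all(vapply(sets2@rL, function(r)
    all(ev2@mrnaLog2[cyanoflux:::gprGenes(gprRules(net)[[r]])] < 6),
    logical(1))))
})

test_that("with no evidence the fit reduces to flux-norm minimization", {
  net <- toyNet()
  mu <- toyMeasured()
  sets <- toyEvidenceSets(character(), character(), mu$meas)
  fit <- fitTpdFlux(net, sets)
  expect_equal(fit@evidenceScore, 0)
  expect_equal(fluxValues(fit), fluxValues(mu$truth), tolerance = 1e-5)
})

test_that("the lexicographic fit matches exhaustive binary enumeration", {
  net <- toyNet()
  mu <- toyMeasured()
  ## small, deliberately conflicting evidence: QOX and the Mehler
  ## reactions are claimed active although the optimum keeps them off
  sets <- toyEvidenceSets(
    rH = c("CBB", "COX", "QOX", "MEHLER_NADPH"),
    rL = c("FDPQ", "NDH2", "CPHSYN", "GLYHYD"),
    rE = mu$meas, epsilon = 0.01)
  fit <- fitTpdFlux(net, sets)
  oracle <- tpdExhaustiveOracle(net, sets)
  expect_equal(fit@evidenceScore, oracle$score)
  expect_equal(fit@fluxNorm, oracle$norm, tolerance = 1e-4)
  ## returned binaries satisfy the indicator semantics
  v <- fluxValues(fit)
  for (r in sets@rH) {
    if (fit@y[[r]] == 1) expect_gte(v[[r]], sets@epsilon - 1e-7)
    if (fit@x[[r]] == 1) expect_lte(v[[r]], -sets@epsilon + 1e-7)
    if (fit@x[[r]] + fit@y[[r]] == 0) expect_lt(abs(v[[r]]), 1e-7)
  }
  for (r in sets@rL) if (fit@z[[r]] == 1) expect_lt(abs(v[[r]]), 1e-7)
})

test_that("TPD constraints only shrink ranges and raise required counts", {
  net <- toyNet()
  mu <- toyMeasured()
  ev <- simulateExpression(net, mu$truth, seed = 3)
  sets <- suppressMessages(buildReactionSets(net, ev, mu$meas,
                                             epsilon = 0.01))
  fit <- fitTpdFlux(net, sets)
  fvaT <- tpdConstrainedFva(net, sets, fit)
  fva0 <- runFva(net, lapply(names(mu$meas), function(r)
    list(reaction = r, fixed = mu$meas[[r]])))
  r0 <- fvaRanges(fva0); rT <- fvaRanges(fvaT)[rownames(r0), ]
  expect_true(all(rT[, "min"] >= r0[, "min"] - 1e-6))
  expect_true(all(rT[, "max"] <= r0[, "max"] + 1e-6))
  c0 <- table(classifyUsage(fva0)); cT <- table(classifyUsage(fvaT))
  expect_gte(cT[["required"]], c0[["required"]])
  expect_lte(cT[["optional"]], c0[["optional"]])
  ## enforced-zero reactions have the [0,0] range
  for (r in sets@rL) if (fit@z[[r]] == 1)
    expect_equal(unname(rT[r, ]), c(0, 0), tolerance = 1e-8)
})

test_that("synthetic evidence from a planted state is recovered", {
  net <- toyNet()
  mu <- toyMeasured()
  ev <- simulateExpression(net, mu$truth, detectProbActive = 0.9,
                           detectProbInactive = 0.05, seed = 5)
  sets <- suppressMessages(buildReactionSets(net, ev, mu$meas,
                                             epsilon = 0.01))
  fit <- fitTpdFlux(net, sets)
  vTrue <- fluxValues(mu$truth)
  vFit <- fluxValues(fit)
  gene <- names(gprRules(net))[nzchar(gprRules(net))]
  trueActive <- gene[abs(vTrue[gene]) > 1e-6]
  fitActive <- gene[abs(vFit[gene]) > 1e-6]
  jac <- length(intersect(trueActive, fitActive)) /
    length(union(trueActive, fitActive))
  expect_gte(jac, 0.8)
})

test_that("evidence-set construction from generated data matches truth at high fidelity", {
  net <- toyNet()
  mu <- toyMeasured()
  ev <- simulateExpression(net, mu$truth, detectProbActive = 1,
                           detectProbInactive = 0, mrnaSd = 0, seed = 1)
  sets <- suppressMessages(buildReactionSets(net, ev, mu$meas,
                                             epsilon = 0.01))
  vTrue <- fluxValues(mu$truth)
  gene <- setdiff(names(gprRules(net))[nzchar(gprRules(net))],
                  names(mu$meas))
  activeTruth <- gene[abs(vTrue[gene]) > 1e-6]
  inactiveTruth <- setdiff(gene, activeTruth)
  ## perfect detection: every truly active reaction is in R_H; inactive
  ## reactions are in R_L unless they share genes with active ones
  expect_true(all(activeTruth %in% sets@rH))
  expect_true(all(sets@rL %in% inactiveTruth))
})

test_that("the epsilon sensitivity report flags infeasible thresholds", {
  net <- toyNet()
  mu <- toyMeasured()
  ev <- simulateExpression(net, mu$truth, seed = 3)
  rep <- epsilonSensitivity(net, ev, mu$meas, epsilons = c(0.01, 0.1))
  expect_equal(nrow(rep), 2L)
  expect_true(rep$feasible[1])
  ## an epsilon above the smallest growth-coupled flux is unsatisfiable
  ## under the hard x=y=0 => v=0 semantics
  expect_false(rep$feasible[2])
})
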