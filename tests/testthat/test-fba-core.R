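## FBA, flux-norm minimization, FVA, classification, spans.

test_that("FBA on the branched network matches the vertex-enumeration oracle", {
  net <- branchNet()
  fb <- solveFba(net)
  oracle <- bruteForceLpMax(net)
  expect_identical(solverStatus(fb), "optimal")
  expect_equal(objectiveValue(fb), oracle$objval, tolerance = 1e-8)
  expect_equal(objectiveValue(fb), 7)  # 3 via yield-2 route + 1 via yield-1
})

test_that("infeasible and unbounded problems surface in the status", {
  net <- chainNet(5)
  fb <- solveFba(net, list(list(reaction = "EX_C", fixed = 10)))
  expect_identical(solverStatus(fb), "infeasible")
  expect_true(is.na(objectiveValue(fb)))
  unb <- makeNetwork(list(
    list(id = "EX_A", stoich = c(A = 1), lower_bound = 0,
         upper_bound = Inf),
    list(id = "EX_A2", stoich = c(A = -1), lower_bound = 0,
         upper_bound = Inf)), objective = "EX_A2")
  expect_identical(solverStatus(solveFba(unb)), "unbounded")
})

test_that("a linear chain with fixed supply pins every flux (FVA [5,5])", {
  net <- chainNet(5)
  fva <- runFva(net, reactions = c("EX_A", "R1", "R2", "EX_C"))
  expect_equal(unname(fvaRanges(fva)[, "min"]), rep(5, 4), tolerance = 1e-7)
  expect_equal(unname(fvaRanges(fva)[, "max"]), rep(5, 4), tolerance = 1e-7)
})

test_that("a reaction downstream of a closed exchange is blocked", {
  fva <- runFva(chainNet(5), reactions = "R3")
  expect_equal(unname(fvaRanges(fva)["R3", ]), c(0, 0), tolerance = 1e-9)
  expect_identical(as.character(classifyUsage(fva)), "inactive")
})

test_that("usage classification partitions ranges correctly", {
  rg <- matrix(c(2, 5, -3, 4, 0, 0, 1e-12, 1e-12, -4, -1), ncol = 2,
               byrow = TRUE, dimnames = list(paste0("r", 1:5),
                                             c("min", "max")))
  cls <- classifyUsage(new("FvaResult", ranges = rg, context = list()))
  expect_identical(as.character(cls),
                   c("required", "optional", "inactive", "inactive",
                     "required"))
  expect_equal(sum(table(cls)), 5L)  # exhaustive and exclusive
})

test_that("every FBA optimum lies within FVA ranges under the same constraints", {
  net <- toyNet()
  for (ph in list(c(20, 14), c(10, 30))) {
    cts <- photonConstraints(ph[1], ph[2])
    fb <- solveFba(net, cts)
    fva <- runFva(net, cts, fixObjective = "max")
    rg <- fvaRanges(fva)
    v <- fluxValues(fb)
    expect_true(all(v >= rg[names(v), "min"] - 1e-6))
    expect_true(all(v <= rg[names(v), "max"] + 1e-6))
  }
})

test_that("flux-norm minimization kills futile cycles and preserves the optimum", {
  net <- cycleNet()
  fb <- solveFba(net)
  mn <- minimizeFluxNorm(net, objectiveValue(fb))
  v <- fluxValues(mn)
  expect_equal(unname(v["CYC1"]), 0, tolerance = 1e-7)
  expect_equal(unname(v["CYC2"]), 0, tolerance = 1e-7)
  expect_equal(unname(v["EX_B"]), objectiveValue(fb), tolerance = 1e-7)
  ## L1 fallback gives the same support on this loop-free optimum
  m1 <- minimizeFluxNorm(net, objectiveValue(fb), norm = "L1")
  expect_equal(fluxValues(m1)[abs(fluxValues(m1)) > 1e-7],
               v[abs(v) > 1e-7], tolerance = 1e-6)
})

test_that("minimum-norm solution matches a dense QP oracle on a tiny instance", {
  ## chain with fixed supply: fluxes are fully determined, so the QP
  ## optimum equals the unique feasible point
  net <- chainNet(4)
  mn <- minimizeFluxNorm(net, 4)
  expect_equal(unname(fluxValues(mn)[c("EX_A", "R1", "R2", "EX_C")]),
               rep(4, 4), tolerance = 1e-7)
  expect_equal(attr(mn, "fluxNorm"), 4 * 16, tolerance = 1e-6)
})

test_that("zero objective with no maintenance gives the all-zero flux vector", {
  net <- toyNetNoGar()
  mn <- minimizeFluxNorm(net, 0, photonConstraints(0, 0))
  expect_identical(solverStatus(mn), "optimal")
  expect_lt(max(abs(fluxValues(mn))), 1e-7)
})

test_that("deleting reactions never increases the optimal objective", {
  net <- toyNet()
  cts <- photonConstraints(20, 14)
  base <- objectiveValue(solveFba(net, cts))
  for (drop in list("QOX", c("HDH_1", "HDH_2", "UPHYDR"), "FDPQ")) {
    less <- solveFba(deleteReactions(net, drop), cts)
    if (solverStatus(less) == "optimal")
      expect_lte(objectiveValue(less), base + 1e-8)
  }
})

test_that("the LP is homogeneous: scaling bounds and rates scales the optimum", {
  net <- toyNet()
  k <- 2.5
  ids <- reactionIds(net)
  b <- fluxBounds(net)
  scaled <- setFluxBounds(net, ids, lower = k * b[, "lower"],
                          upper = k * b[, "upper"])
  mu1 <- objectiveValue(solveFba(net, photonConstraints(20, 14)))
  mu2 <- objectiveValue(solveFba(scaled, photonConstraints(k * 20, k * 14)))
  expect_equal(mu2, k * mu1, tolerance = 1e-6)
})

test_that("flux spans match the brute-force oracle on the branched network", {
  net <- branchNet()
  cts <- list(list(reaction = "EX_P", fixed = 5))
  fva <- runFva(net, cts, reactions = c("HIGH", "LOW"))
  ## oracle: enumerate vertices maximizing/minimizing each flux
  for (r in c("HIGH", "LOW")) {
    hi <- bruteForceLpMax(net, objective = r, constraints = cts)
    expect_equal(fvaRanges(fva)[r, "max"], hi$objval, tolerance = 1e-7)
  }
  sm <- fluxSpanSummary(fva)
  expect_true(all(sm$spans >= 0))
  expect_equal(sm$meanSpan, mean(sm$spans))
  expect_error(fluxSpanSummary(fva, character(0)), "empty")
})

test_that("FVA errors name the offending reaction when infeasible", {
  net <- chainNet(5)
  expect_error(runFva(net, list(list(reaction = "EX_C", fixed = 10)),
                      reactions = "R1"), "R1")
})

test_that("the FVA report has the documented tab-separated layout", {
  net <- chainNet(5)
  fva <- runFva(net, reactions = c("R1", "R3"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  out <- writeFvaReport(fva, tf)
  tab <- utils::read.delim(tf)
  expect_named(tab, c("reaction", "min", "max", "span", "class"))
  expect_equal(tab$class, c("required", "inactive"))
})
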