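## Phenotypic phase planes, limitation diagnosis, region-wise FVA,
## electron-transport scenarios.

phppGrid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- computePhpp(toyNet(), c(0, 60), c(0, 60),
                                      step = 10)
    g
  }
})

test_that("the toy phase plane has exactly three regions", {
  grid <- phppGrid()
  regions <- sort(setdiff(unique(as.vector(grid@regionId)), 0L))
  expect_identical(regions, c(1L, 2L, 3L))
  ## single-photosystem-limited regions flank the dual-limited band
  expect_true(any(grid@regionId == 2L))
  expect_gte(sum(grid@regionId == 1L), 2)
  expect_gte(sum(grid@regionId == 3L), 2)
})

test_that("no water-splitting flux means no growth (PSII = 0)", {
  grid <- phppGrid()
  expect_lt(max(grid@growth[1, ]), 1e-8)   # psii = 0 row
  expect_lt(max(grid@growth[, 1]), 1e-8)   # psi = 0 likewise: no NADPH
})

test_that("growth is monotone and concave along axes in upper-bound mode", {
  net <- toyNet()
  gub <- computePhpp(net, c(0, 60), c(0, 60), step = 15,
                     mode = "upper_bound")
  G <- gub@growth
  for (i in seq_len(nrow(G))) {
    expect_true(all(diff(G[i, ]) >= -1e-8))
    if (ncol(G) > 2) expect_true(all(diff(diff(G[i, ])) <= 1e-7))
  }
  for (j in seq_len(ncol(G))) {
    expect_true(all(diff(G[, j]) >= -1e-8))
    if (nrow(G) > 2) expect_true(all(diff(diff(G[, j])) <= 1e-7))
  }
})

test_that("region labels are stable under grid refinement at common points", {
  net <- toyNet()
  coarse <- computePhpp(net, c(10, 50), c(10, 50), step = 20)
  fine <- computePhpp(net, c(10, 50), c(10, 50), step = 10)
  for (i in seq_along(coarse@psii)) for (j in seq_along(coarse@psi)) {
    fi <- match(coarse@psii[i], fine@psii)
    fj <- match(coarse@psi[j], fine@psi)
    expect_identical(fine@regionId[fi, fj], coarse@regionId[i, j])
  }
})

test_that("single-photosystem regions are reductant limited; the dual region has an energy component", {
  grid <- phppGrid()
  expect_identical(unname(grid@limitation[["1"]]), "reductant_limited")
  expect_identical(unname(grid@limitation[["3"]]), "reductant_limited")
  ## in the dual-limited band extra ATP strictly helps (the toy's
  ## respiratory shuttle also makes extra NADPH valuable, hence "mixed")
  expect_true(grid@limitation[["2"]] %in% c("energy_limited", "mixed"))
})

test_that("carbon limitation is reported as neither ATP nor NADPH limited", {
  net <- toyNet()
  net <- setFluxBounds(net, "EX_co2", lower = -0.05, upper = 1000)
  lab <- diagnoseLimitation(net, psii = 60, psi = 60,
                            mode = "upper_bound")
  expect_identical(lab, "neither")
})

test_that("region-wise FVA finds linear photosynthesis active and Mehler blocked", {
  net <- toyNet()
  etc <- c("PSII", "CYTB6F", "PSI", "FNR", "QOX", "MEHLER_NADPH",
           "MEHLER_FD")
  usage <- phppFva(net, phppGrid(), reactions = etc, sampleDensity = 4)
  for (r in names(usage)) {
    expect_identical(unname(usage[[r]]["PSII"]), "active")
    expect_identical(unname(usage[[r]]["CYTB6F"]), "active")
    expect_identical(unname(usage[[r]]["PSI"]), "active")
    expect_identical(unname(usage[[r]]["MEHLER_NADPH"]), "blocked")
    expect_identical(unname(usage[[r]]["MEHLER_FD"]), "blocked")
  }
  ## the low-pumping quinol oxidase is off where energy is scarce
  expect_identical(unname(usage[["2"]]["QOX"]), "blocked")
})

test_that("scenario growth is nested: fewer routes never help", {
  net <- toyNet()
  sc <- suppressMessages(scenarioScan(net, toyScenarioSets(net),
                                      psiiFixed = 20,
                                      psiValues = c(10, 20, 40, 160)))
  g <- function(nm) sc$growth[sc$scenario == nm]
  expect_true(all(g("no_cyclic_no_sinks") <= g("cyclic_no_sinks") + 1e-9))
  expect_true(all(g("cyclic_no_sinks") <= g("full") + 1e-9))
})

test_that("without cyclic flow and reductant sinks, PSI < PSII cannot grow", {
  net <- makeToyNetwork(toyNetworkSpec(include = list(
    cyclic_fdpq = FALSE, ndh2 = FALSE, qox = FALSE, mehler = FALSE,
    hydrogenases = FALSE)))
  netNoCox <- deleteReactions(net, "COX")
  for (p1 in c(5, 10, 19)) {
    fb <- solveFba(netNoCox, photonConstraints(20, p1))
    expect_true(solverStatus(fb) != "optimal" ||
                  objectiveValue(fb) < 1e-9)
  }
})

test_that("with cyclic flow restored, growth needs PSI >= PSII photons", {
  net <- toyNet()
  sc <- suppressMessages(scenarioScan(
    net, toyScenarioSets(net)["cyclic_no_sinks"], psiiFixed = 20,
    psiValues = c(5, 10, 19, 160, 200)))
  below <- sc$psi < 20
  expect_true(all(!sc$grows[below]))
  expect_true(any(sc$grows[!below]))   # high PSI supports growth
})

test_that("the full network secretes nothing across the scan", {
  net <- toyNet()
  sc <- suppressMessages(scenarioScan(net, toyScenarioSets(net)["full"],
                                      psiiFixed = 20,
                                      psiValues = c(10, 20, 30)))
  expect_true(all(sc$secreted[sc$grows] == ""))
})
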