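## Network construction, SBML round trips, biomass assembly, deletion.

test_that("network validity invariants are enforced", {
  expect_error(makeNetwork(list(
    list(id = "R1", stoich = c(a = -1, b = 1), lower_bound = 2,
         upper_bound = 1))), "lower_bound")
  expect_error(makeNetwork(list(
    list(id = "R1", stoich = c(a = -1)),
    list(id = "R1", stoich = c(a = 1)))), "duplicated")
  net <- makeNetwork(list(list(id = "R1", stoich = c(a = -1, b = 1),
                               lower_bound = 0, upper_bound = 10)))
  expect_equal(nReactions(net), 1L)
  expect_equal(nMetabolites(net), 2L)
  expect_error(objectiveId(net) <- "nope", "not in model")
})

test_that("SBML round trip preserves stoichiometry, bounds, GPRs and objective", {
  net <- toyNet()
  tf <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, tf)
  net2 <- readSBML(tf)
  expect_equal(nReactions(net2), nReactions(net))
  S1 <- as.matrix(stoichiometryMatrix(net))
  S2 <- as.matrix(stoichiometryMatrix(net2))[rownames(S1), colnames(S1)]
  expect_equal(S2, S1)
  b1 <- fluxBounds(net)
  expect_equal(fluxBounds(net2)[rownames(b1), ], b1)  # bit-exact bounds
  expect_identical(objectiveId(net2), objectiveId(net))
  expect_setequal(geneIds(net2), geneIds(net))
  ## GPR semantics under random gene subsets
  g1 <- gprRules(net); g2 <- gprRules(net2)
  set.seed(11)
  for (k in 1:10) {
    sub <- sample(geneIds(net), sample.int(length(geneIds(net)), 1))
    for (r in names(g1)[nzchar(g1)])
      expect_identical(evalGpr(g2[[r]], sub), evalGpr(g1[[r]], sub))
  }
  ## exchange flags survive (single-metabolite detection)
  expect_equal(sum(isExchange(net2)), sum(isExchange(net)))
})

test_that("reader accepts Level 2 kinetic-law bounds and notes GPRs", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
 <model id="m">
  <listOfSpecies>
   <species id="a" compartment="c"/>
   <species id="b" compartment="c"/>
   <species id="a_ext" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="T1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (g1 and g2) or g3</p></body></notes>
    <listOfReactants><speciesReference species="a_ext"/></listOfReactants>
    <listOfProducts><speciesReference species="a"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="R1" reversible="true">
    <listOfReactants><speciesReference species="a"/></listOfReactants>
    <listOfProducts><speciesReference species="b" stoichiometry="2"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, tf)
  expect_message(net <- readSBML(tf), "defaulted")  # R1 lacks bounds
  expect_equal(nReactions(net), 2L)
  b <- fluxBounds(net)
  expect_equal(unname(b["T1", ]), c(0, 10))
  expect_equal(unname(b["R1", ]), c(-1000, 1000))   # reversible default
  expect_true(isExchange(net)[["T1"]])              # boundary species
  expect_true(evalGpr(gprRules(net)[["T1"]], "g3"))
  expect_false(evalGpr(gprRules(net)[["T1"]], "g1"))
  expect_equal(unname(stoichiometryMatrix(net)["b", "R1"]), 2)
})

test_that("malformed XML fails with a line-located parse error", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<sbml>", "<model", "</sbml>"), tf)
  expect_error(readSBML(tf))
  expect_error(readSBML("/nonexistent/file.xml"), "does not exist")
})

test_that("our SBML is readable by an independent implementation", {
  ## cobrapy (with libsbml) serves as the external reference reader and
  ## LP solver; skip cleanly if the python stack is unavailable
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  ok <- tryCatch(system2(py, c("-c", shQuote("import cobra")),
                         stdout = NULL, stderr = NULL) == 0,
                 error = function(e) FALSE)
  skip_if_not(ok, "cobrapy not importable")
  net <- toyNet()
  tf <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, tf)
  script <- sprintf('
import warnings; warnings.filterwarnings("ignore")
import cobra
m = cobra.io.read_sbml_model("%s")
m.reactions.EX_photon_psii.bounds = (10, 10)
m.reactions.EX_photon_psi.bounds = (10, 10)
print(round(m.optimize().objective_value, 10))', tf)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(py, sf, stdout = TRUE)
  cobraMu <- as.numeric(out[length(out)])
  mine <- solveFba(net, photonConstraints(10, 10))
  expect_equal(cobraMu, objectiveValue(mine), tolerance = 1e-7)
})

test_that("deleteReactions removes reactions without touching the input", {
  net <- toyNet()
  n0 <- nReactions(net)
  net2 <- deleteReactions(net, c("HDH_1", "HDH_2", "UPHYDR"))
  expect_equal(nReactions(net2), n0 - 3L)
  expect_equal(nReactions(net), n0)                  # original unchanged
  expect_identical(deleteReactions(net, character(0)), net)
  expect_error(deleteReactions(net, "NOT_A_REACTION"), "NOT_A_REACTION")
  expect_warning(net3 <- deleteReactions(net, "BIOMASS"), "no objective")
  expect_true(is.na(objectiveId(net3)))
})

test_that("reaction counts report both totals", {
  cnt <- reactionCounts(toyNet())
  expect_equal(unname(cnt["total"]),
               unname(cnt["metabolic"] + cnt["exchange"]))
  expect_gt(cnt[["exchange"]], 0)
})

test_that("toy internal reactions are elementally and charge balanced", {
  mb <- checkMassBalance(toyNet())
  expect_true(all(mb$balanced))
  expect_gt(nrow(mb), 15)  # the audit covers most internal reactions
})

test_that("biomass equation scales linearly with composition fractions", {
  comp <- toyBiomassComposition()
  tab <- toyMonomerTable()
  bio <- buildBiomassEquation(comp, tab, gar = 50)
  ## doubling fractions and renormalizing reproduces the same reaction
  f2 <- comp@fractions * 2 / sum(comp@fractions * 2) * sum(comp@fractions)
  bio2 <- buildBiomassEquation(
    new("BiomassComposition", fractions = f2, aminoAcidProfile = numeric()),
    tab, gar = 50)
  expect_equal(bio2$stoich[names(bio$stoich)], bio$stoich)
  ## homogeneity degree 1: scaling fractions by 0.97 scales precursor
  ## coefficients by 0.97 (GAR term aside)
  f3 <- comp@fractions * 0.97
  bio3 <- buildBiomassEquation(
    new("BiomassComposition", fractions = f3, aminoAcidProfile = numeric()),
    tab, gar = 0)
  bio0 <- buildBiomassEquation(comp, tab, gar = 0)
  expect_equal(bio3$stoich[names(bio0$stoich)], 0.97 * bio0$stoich)
})

test_that("carbohydrate-rich composition yields a larger carbohydrate drain", {
  tab <- toyMonomerTable()
  ll <- buildBiomassEquation(toyBiomassComposition("light_limited"), tab)
  al <- buildBiomassEquation(toyBiomassComposition("ammonium_limited"), tab)
  ## carbon precursor demand is dominated by the carbohydrate fraction
  ## difference; cyanophycin appears only in the light-limited equation
  expect_true("cph_c" %in% names(ll$stoich))
  expect_false("cph_c" %in% names(al$stoich))
  carbCoef <- function(b, comp) {
    comp@fractions[["carbohydrate"]] * tab$carbohydrate[["cx_c"]]
  }
  expect_gt(carbCoef(al, toyBiomassComposition("ammonium_limited")),
            carbCoef(ll, toyBiomassComposition("light_limited")))
})

test_that("degenerate and invalid compositions are handled", {
  tab <- toyMonomerTable()
  pure <- new("BiomassComposition", fractions = c(carbohydrate = 1),
              aminoAcidProfile = numeric())
  bio <- buildBiomassEquation(pure, tab, gar = 10)
  ## drains only glucose equivalents plus the GAR ATP machinery
  drains <- names(bio$stoich)[bio$stoich < 0]
  expect_setequal(drains, c("cx_c", "atp_c", "h2o_c"))
  expect_error(new("BiomassComposition", fractions = c(protein = 0.2),
                   aminoAcidProfile = numeric()), "0.95")
  expect_error(buildBiomassEquation(
    new("BiomassComposition", fractions = c(unknown_polymer = 1),
        aminoAcidProfile = numeric()), tab), "unknown_polymer")
})

test_that("biomass composition YAML reader works", {
  tf <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("fractions:", "  protein: 0.6", "  carbohydrate: 0.4"), tf)
  comp <- readBiomassComposition(tf)
  expect_s4_class(comp, "BiomassComposition")
  expect_equal(sum(comp@fractions), 1.0)
})

test_that("reaction listing has the supplementary-table layout", {
  df <- reactionListing(toyNet())
  expect_named(df, c("id", "name", "equation", "gpr", "subsystem"))
  eq <- df$equation[df$id == "PSII"]
  expect_match(eq, "-->")
  expect_match(eq, "pqh2_c")
})
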