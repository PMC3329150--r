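## Workflow orchestration: a single YAML-configurable entry point running
## the selected analyses on a model and writing tab-separated outputs.
## Reruns of an unchanged configuration produce byte-identical tables.

## 32-bit FNV-1a in double arithmetic (kept exact by 16-bit splitting)
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

writeTsv <- function(df, path, configHash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", configHash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a configured analysis workflow
#'
#' `config` is a named list (or a path to a YAML file) with fields:
#' \describe{
#'   \item{model}{`"toy"` or a path to an SBML file.}
#'   \item{analyses}{subset of `validate`, `fba`, `fva`, `phpp`,
#'     `scenarios`, `dark_n2`, `energetics`; default runs all.}
#'   \item{outdir}{output directory (created if needed).}
#'   \item{photons}{list with `psii`, `psi` (and optional `mode`) used by
#'     `fba`/`fva`.}
#'   \item{phpp}{list with `max` and `step` for the phase-plane grid.}
#'   \item{seed}{integer seed for the synthetic batch series used by
#'     `energetics`.}
#' }
#' Unknown keys are rejected. Every output carries a header comment with
#' the configuration hash.
#'
#' @param config named list or YAML path.
#' @return invisibly, the vector of files written.
#' @export
runWorkflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("model", "analyses", "outdir", "photons", "phpp", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  model <- config$model %||% "toy"
  analyses <- config$analyses %||%
    c("validate", "fba", "fva", "phpp", "scenarios", "dark_n2", "energetics")
  outdir <- config$outdir %||% stop("config needs 'outdir'")
  photons <- config$photons %||% list(psii = 20, psi = 20, mode = "fixed")
  phppCfg <- config$phpp %||% list(max = 60, step = 10)
  seed <- config$seed %||% 1L
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- fnv1a(paste(deparse(config), collapse = ""))
  net <- if (identical(model, "toy")) makeToyNetwork() else {
    if (!file.exists(model)) stop("model file not found: ", model)
    readSBML(model)
  }
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    writeTsv(df, path, hash)
    files <<- c(files, path)
  }
  cts <- photonConstraints(photons$psii, photons$psi,
                           photons$mode %||% "fixed")
  if ("validate" %in% analyses) {
    mb <- checkMassBalance(net)
    emit(mb, "mass_balance.tsv")
    emit(reactionListing(net), "reactions.tsv")
  }
  if ("fba" %in% analyses) {
    fb <- solveFba(net, cts)
    if (fb@status != "optimal") stop("FBA failed: ", fb@status)
    mn <- minimizeFluxNorm(net, fb@objectiveValue, cts)
    emit(data.frame(reaction = names(fluxValues(mn)),
                    flux = unname(fluxValues(mn))), "fba_fluxes.tsv")
  }
  if ("fva" %in% analyses) {
    fva <- runFva(net, cts, fixObjective = "max")
    emit(writeFvaReportDf(fva), "fva.tsv")
  }
  if ("phpp" %in% analyses) {
    grid <- computePhpp(net, c(0, phppCfg$max), c(0, phppCfg$max),
                        step = phppCfg$step)
    gdf <- data.frame(psii = rep(grid@psii, times = length(grid@psi)),
                      psi = rep(grid@psi, each = length(grid@psii)),
                      growth = as.vector(grid@growth),
                      region = as.vector(grid@regionId))
    emit(gdf, "phpp.tsv")
    emit(data.frame(region = names(grid@limitation),
                    limitation = unname(grid@limitation)),
         "phpp_limitation.tsv")
  }
  if ("scenarios" %in% analyses) {
    sc <- scenarioScan(net, toyScenarioSets(net), psiiFixed = photons$psii,
                       psiValues = seq(0, phppCfg$max, by = phppCfg$step))
    emit(sc, "scenarios.tsv")
  }
  if ("dark_n2" %in% analyses) {
    dk <- darkN2Fixation(net)
    emit(data.frame(quantity = c("n2_per_glycogen", "h2_per_glycogen",
                                 "o2_per_n2", "cyanophycin_flux"),
                    value = c(dk@n2PerGlycogen, dk@h2PerGlycogen,
                              dk@o2PerN2, dk@cyanophycinFlux)),
         "dark_n2.tsv")
  }
  if ("energetics" %in% analyses) {
    est <- makeToyNetwork(toyNetworkSpec(gar = 0, ngar = 0))
    grid <- toyBatchGrid()
    batches <- simulateBatches(net, grid, noiseCv = 0, seed = seed)
    ep <- estimateAtpRequirements(est, batches)
    emit(data.frame(parameter = c("GAR", "NGAR"),
                    value = c(ep@gar, ep@ngar)), "energetics.tsv")
  }
  invisible(files)
}

writeFvaReportDf <- function(fva, zeroTol = 1e-9) {
  r <- fvaRanges(fva)
  data.frame(reaction = rownames(r), min = r[, "min"], max = r[, "max"],
             span = r[, "max"] - r[, "min"],
             class = as.character(classifyUsage(fva, zeroTol)),
             stringsAsFactors = FALSE)
}

#' Electron-transport scenario definitions for the toy network
#'
#' Mirrors the canonical knockout scenarios: (A) no cyclic photosynthesis
#' and no alternative reductant sinks, (B) cyclic restored but sinks still
#' removed, (C) the full network.
#'
#' @param network a toy [MetabolicNetwork-class].
#' @return named list of reaction-id vectors to remove.
#' @export
toyScenarioSets <- function(network) {
  cyclic <- c("FDPQ", "NDH1", "NDH2")
  sinks <- c("COX", "QOX", "MEHLER_NADPH", "MEHLER_FD", "HDH_1", "HDH_2",
             "UPHYDR")
  list(no_cyclic_no_sinks = intersect(c(cyclic, sinks),
                                      network@reactions$id),
       cyclic_no_sinks = intersect(sinks, network@reactions$id),
       full = character(0))
}
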