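## Construction, validation and editing of MetabolicNetwork objects, and
## biomass-equation assembly from measured macromolecular composition.

BIG_BOUND <- 1000  # conventional capacity bound, mmol g-1 AFDW h-1

#' Construct a MetabolicNetwork from reaction definitions
#'
#' Each reaction is a list with elements `id`, `stoich` (named numeric,
#' reactants negative), and optionally `name`, `lower_bound`,
#' `upper_bound`, `gpr`, `subsystem`, `reversible`. Default bounds are
#' `[0, 1000]` for irreversible and `[-1000, 1000]` for reversible
#' reactions. Exchange reactions are auto-flagged by single-metabolite
#' stoichiometry.
#'
#' @param reactionList list of reaction definitions (see Details).
#' @param metaboliteInfo optional data.frame with columns `id` and any of
#'   `name`, `compartment`, `formula`, `charge`; metabolites present only
#'   in stoichiometries get compartment "c" and no formula.
#' @param objective id of the objective reaction, or `NA`.
#' @param compartments character vector; inferred from metabolites if
#'   missing.
#' @return a [MetabolicNetwork-class].
#' @export
makeNetwork <- function(reactionList, metaboliteInfo = NULL,
                        objective = NA_character_, compartments = NULL) {
  ids <- vapply(reactionList, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicated reaction ids")
  mets <- unique(unlist(lapply(reactionList, function(r) names(r$stoich))))
  minfo <- data.frame(id = mets, name = mets,
                      compartment = "c", formula = NA_character_,
                      charge = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(metaboliteInfo)) {
    mi <- as.data.frame(metaboliteInfo, stringsAsFactors = FALSE)
    idx <- match(mi$id, minfo$id)
    known <- !is.na(idx)
    for (col in intersect(c("name", "compartment", "formula", "charge"),
                          names(mi)))
      minfo[[col]][idx[known]] <- mi[[col]][known]
  }
  rxn <- data.frame(
    id = ids,
    name = vapply(reactionList, function(r) r$name %||% r$id, character(1)),
    lower_bound = vapply(reactionList, function(r) {
      if (!is.null(r$lower_bound)) r$lower_bound
      else if (isTRUE(r$reversible)) -BIG_BOUND else 0
    }, numeric(1)),
    upper_bound = vapply(reactionList, function(r)
      r$upper_bound %||% BIG_BOUND, numeric(1)),
    gpr = vapply(reactionList, function(r) r$gpr %||% "", character(1)),
    subsystem = vapply(reactionList, function(r) r$subsystem %||% "",
                       character(1)),
    is_exchange = vapply(reactionList, function(r)
      r$is_exchange %||% (length(r$stoich) == 1L), logical(1)),
    stringsAsFactors = FALSE)
  ii <- unlist(lapply(reactionList, function(r) match(names(r$stoich), mets)))
  jj <- rep(seq_along(reactionList),
            vapply(reactionList, function(r) length(r$stoich), integer(1)))
  xx <- unlist(lapply(reactionList, function(r) unname(r$stoich)))
  S <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(length(mets), length(ids)),
                    dimnames = list(mets, ids))
  if (is.null(compartments)) compartments <- unique(minfo$compartment)
  net <- new("MetabolicNetwork", reactions = rxn, metabolites = minfo,
             stoichiometry = S, objective = objective,
             compartments = compartments)
  validObject(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count reactions by category
#'
#' Reports the total reaction count alongside the split into
#' metabolic/transport and exchange reactions, since published totals may
#' quote either convention.
#'
#' @param network a [MetabolicNetwork-class].
#' @return named integer vector with `total`, `metabolic`, `exchange`.
#' @export
reactionCounts <- function(network) {
  ex <- sum(network@reactions$is_exchange)
  c(total = nrow(network@reactions),
    metabolic = nrow(network@reactions) - ex,
    exchange = ex)
}

#' Delete reactions from a network
#'
#' Returns a copy of the network without the given reactions; the input is
#' unmodified. Internally the reactions are removed from the matrix (the
#' scan code in [deletionSpanScan()] uses bound-fixing to `[0,0]` for
#' speed; this function performs true removal). Deleting the objective
#' reaction yields a network with no objective and a warning.
#'
#' @param network a [MetabolicNetwork-class].
#' @param ids character vector of reaction ids to delete.
#' @return a [MetabolicNetwork-class].
#' @export
deleteReactions <- function(network, ids) {
  if (!length(ids)) return(network)
  unknown <- setdiff(ids, network@reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- !(network@reactions$id %in% ids)
  obj <- network@objective
  if (!is.na(obj) && obj %in% ids) {
    warning("objective reaction '", obj, "' deleted; network has no objective")
    obj <- NA_character_
  }
  net <- new("MetabolicNetwork",
             reactions = network@reactions[keep, , drop = FALSE],
             metabolites = network@metabolites,
             stoichiometry = network@stoichiometry[, keep, drop = FALSE],
             objective = obj, compartments = network@compartments)
  rownames(net@reactions) <- NULL
  validObject(net)
  net
}

## parse "C6H12O6"-style formulas (element tokens = capital + lowercase
## letters, optional count); returns named numeric vector
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)",
                                       formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9.]*$", "", toks)
  ct <- sub("^[A-Za-z]*", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)
}

#' Audit elemental and charge balance
#'
#' For every internal reaction whose metabolites all carry formulas,
#' checks that each element (and, when charges are given, charge) balances
#' within tolerance. Exchange reactions, demand/sink reactions and the
#' biomass/objective reaction are exempt, as are reactions touching any
#' metabolite without a formula (e.g. photons).
#'
#' @param network a [MetabolicNetwork-class].
#' @param tol numeric tolerance per element (default `1e-6`).
#' @return data.frame of audited reactions with the worst imbalance per
#'   reaction; attribute `"skipped"` lists unaudited reaction ids.
#' @export
checkMassBalance <- function(network, tol = 1e-6) {
  S <- network@stoichiometry
  met <- network@metabolites
  forms <- lapply(met$formula, function(f)
    tryCatch(parseFormula(f), error = function(e) NULL))
  names(forms) <- met$id
  hasForm <- !vapply(forms, is.null, logical(1))
  res <- list(); skipped <- character()
  for (j in seq_len(ncol(S))) {
    rid <- colnames(S)[j]
    if (network@reactions$is_exchange[j] ||
        identical(rid, network@objective) ||
        grepl("^(DM_|SINK_|SK_)", rid)) { skipped <- c(skipped, rid); next }
    coef <- S[, j]
    act <- which(coef != 0)
    if (!length(act) || !all(hasForm[act])) { skipped <- c(skipped, rid); next }
    bal <- list()
    for (i in act) {
      f <- forms[[i]]
      for (el in names(f))
        bal[[el]] <- (bal[[el]] %||% 0) + coef[i] * f[[el]]
    }
    if (all(!is.na(met$charge[act])))
      bal[["charge"]] <- sum(coef[act] * met$charge[act])
    worst <- if (length(bal)) max(abs(unlist(bal))) else 0
    res[[rid]] <- worst
  }
  out <- data.frame(reaction = names(res),
                    max_imbalance = unlist(res, use.names = FALSE),
                    balanced = unlist(res, use.names = FALSE) <= tol,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Build a biomass drain reaction from macromolecular composition
#'
#' Converts measured mass fractions of ash-free dry weight into a biomass
#' equation: each macromolecule's fraction is multiplied by its
#' per-gram precursor demands (mmol precursor per g macromolecule), and the
#' growth-associated ATP requirement (GAR) is added as an ATP + H2O ->
#' ADP + Pi + H hydrolysis term. Coefficients are linear
#' (homogeneous of degree 1) in the fractions.
#'
#' @param composition a [BiomassComposition-class].
#' @param monomerTable named list: macromolecule -> named numeric vector of
#'   precursor coefficients (mmol per g of that macromolecule; consumed
#'   species positive in the table, they become negative in the reaction;
#'   byproducts negative in the table).
#' @param gar growth-associated ATP requirement, mmol ATP per g biomass.
#' @param atpSpecies named character vector mapping roles `atp`, `adp`,
#'   `pi`, `h2o`, `h` to metabolite ids (defaults match the toy network).
#' @param id reaction id for the biomass equation.
#' @return reaction definition list suitable for [makeNetwork()]: the
#'   biomass drain with precursor coefficients in mmol per g AFDW.
#' @export
buildBiomassEquation <- function(composition, monomerTable, gar = 0,
    atpSpecies = c(atp = "atp_c", adp = "adp_c", pi = "pi_c",
                   h2o = "h2o_c", h = "h_c"),
    id = "BIOMASS") {
  stopifnot(is(composition, "BiomassComposition"))
  validObject(composition)
  f <- composition@fractions
  active <- names(f)[f > 0]
  missing <- setdiff(active, names(monomerTable))
  if (length(missing))
    stop("monomer table lacks entries for: ", paste(missing, collapse = ", "))
  stoich <- numeric()
  at <- function(sp) if (sp %in% names(stoich)) stoich[[sp]] else 0
  for (m in active) {
    tab <- monomerTable[[m]]
    for (sp in names(tab))
      stoich[sp] <- at(sp) - f[[m]] * tab[[sp]]
  }
  if (gar > 0) {
    for (role in c("atp", "h2o"))
      stoich[atpSpecies[[role]]] <- at(atpSpecies[[role]]) - gar
    for (role in c("adp", "pi", "h"))
      stoich[atpSpecies[[role]]] <- at(atpSpecies[[role]]) + gar
  }
  stoich <- stoich[abs(stoich) > 1e-12]
  list(id = id, name = "Biomass equation", stoich = stoich,
       lower_bound = 0, upper_bound = BIG_BOUND, gpr = "",
       subsystem = "Biomass", is_exchange = FALSE)
}

#' Read a biomass composition from YAML
#'
#' Expects top-level keys `fractions` (macromolecule: mass fraction) and
#' optionally `amino_acid_profile`.
#'
#' @param path YAML file path.
#' @return a [BiomassComposition-class].
#' @export
readBiomassComposition <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$fractions)) stop("YAML lacks 'fractions'")
  new("BiomassComposition",
      fractions = unlist(y$fractions),
      aminoAcidProfile = if (is.null(y$amino_acid_profile)) numeric()
                         else unlist(y$amino_acid_profile))
}

#' Tab-separated reaction listing
#'
#' Writes (or returns) the model's reaction table in the conventional
#' supplementary layout: id, name, equation, GPR, subsystem.
#'
#' @param network a [MetabolicNetwork-class].
#' @param path optional output file; when `NULL` the data.frame is
#'   returned invisibly without writing.
#' @return data.frame (invisibly when written).
#' @export
reactionListing <- function(network, path = NULL) {
  S <- network@stoichiometry
  eqn <- vapply(seq_len(ncol(S)), function(j) {
    coef <- S[, j]
    lhs <- which(coef < 0); rhs <- which(coef > 0)
    fmt <- function(ix) paste(
      ifelse(abs(coef[ix]) == 1, rownames(S)[ix],
             paste0("(", format(abs(coef[ix]), trim = TRUE), ") ",
                    rownames(S)[ix])), collapse = " + ")
    arrow <- if (network@reactions$lower_bound[j] < 0) " <=> " else " --> "
    paste0(fmt(lhs), arrow, fmt(rhs))
  }, character(1))
  out <- data.frame(id = network@reactions$id, name = network@reactions$name,
                    equation = eqn, gpr = network@reactions$gpr,
                    subsystem = network@reactions$subsystem,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(out)
}

#' Add a reaction to a network
#'
#' New metabolites appearing in the stoichiometry are created in
#' compartment "c" without formulas.
#'
#' @param network a [MetabolicNetwork-class].
#' @param reaction a reaction definition list (see [makeNetwork()]).
#' @return a [MetabolicNetwork-class] with the reaction appended.
#' @export
addReaction <- function(network, reaction) {
  if (reaction$id %in% network@reactions$id)
    stop("reaction id already present: ", reaction$id)
  S <- network@stoichiometry
  newMets <- setdiff(names(reaction$stoich), rownames(S))
  met <- network@metabolites
  if (length(newMets)) {
    met <- rbind(met, data.frame(id = newMets, name = newMets,
                                 compartment = "c", formula = NA_character_,
                                 charge = NA_real_, stringsAsFactors = FALSE))
    S <- rbind(S, Matrix::Matrix(0, length(newMets), ncol(S), sparse = TRUE,
                                 dimnames = list(newMets, colnames(S))))
  }
  col <- Matrix::Matrix(0, nrow(S), 1, sparse = TRUE,
                        dimnames = list(rownames(S), reaction$id))
  col[names(reaction$stoich), 1] <- unname(reaction$stoich)
  S <- cbind(S, col)
  rxn <- rbind(network@reactions, data.frame(
    id = reaction$id, name = reaction$name %||% reaction$id,
    lower_bound = reaction$lower_bound %||%
      (if (isTRUE(reaction$reversible)) -BIG_BOUND else 0),
    upper_bound = reaction$upper_bound %||% BIG_BOUND,
    gpr = reaction$gpr %||% "", subsystem = reaction$subsystem %||% "",
    is_exchange = reaction$is_exchange %||% (length(reaction$stoich) == 1L),
    stringsAsFactors = FALSE))
  rownames(rxn) <- NULL
  net <- new("MetabolicNetwork", reactions = rxn, metabolites = met,
             stoichiometry = S, objective = network@objective,
             compartments = unique(c(network@compartments,
                                     met$compartment)))
  validObject(net)
  net
}
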