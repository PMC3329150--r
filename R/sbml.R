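## SBML input/output. The writer emits Level 3 + fbc version 2; the reader
## accepts Level 3 + fbc as well as Level 2 files in which flux bounds are
## stored as kinetic-law parameters and gene associations live in notes
## (the era-typical dialect of published genome-scale models).

SBML_CORE_L3 <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitizeSid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("_", x))
}

gprToFbcXml <- function(tree) {
  if (is.null(tree)) return(NULL)
  switch(tree$op,
    gene = list(`fbc:geneProductRef` = structure(
      list(), `fbc:geneProduct` = paste0("G_", sanitizeSid(tree$id)))),
    and = list(`fbc:and` = do.call(c, lapply(tree$args, gprToFbcXml))),
    or = list(`fbc:or` = do.call(c, lapply(tree$args, gprToFbcXml))))
}

## build nested xml via xml2 add_child calls from the structure above
addGprNode <- function(parent, nodeList) {
  nm <- names(nodeList)[1]
  node <- nodeList[[1]]
  child <- xml2::xml_add_child(parent, nm)
  ats <- attributes(node)
  for (a in setdiff(names(ats), c("names")))
    xml2::xml_set_attr(child, a, ats[[a]])
  if (length(node)) {
    for (k in seq_along(node)) addGprNode(child, node[k])
  }
  child
}

#' Write a network to SBML (Level 3 + fbc)
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSBML <- function(network, path) {
  rxn <- network@reactions
  met <- network@metabolites
  S <- network@stoichiometry
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_CORE_L3, `xmlns:fbc` = SBML_FBC,
    level = "3", version = "1", `fbc:required` = "false")
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               `fbc:strict` = "false")
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in network@compartments)
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(los, "species",
      id = sanitizeSid(met$id[i]), name = met$name[i] %||% met$id[i],
      compartment = met$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(met$formula[i]) && nzchar(met$formula[i]))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[i])
    if (!is.na(met$charge[i]))
      xml2::xml_set_attr(sp, "fbc:charge",
                         format(met$charge[i], scientific = FALSE))
  }
  ## flux-bound parameters (deduplicated by value)
  lop <- xml2::xml_add_child(model, "listOfParameters")
  allBounds <- unique(c(rxn$lower_bound, rxn$upper_bound))
  pid <- paste0("fb_", seq_along(allBounds))
  names(pid) <- vapply(allBounds, function(v)
    format(v, digits = 17, trim = TRUE), character(1))
  for (k in seq_along(allBounds))
    xml2::xml_add_child(lop, "parameter", id = pid[k],
      value = format(allBounds[k], digits = 17, trim = TRUE),
      constant = "true")
  boundRef <- function(v) pid[[format(v, digits = 17, trim = TRUE)]]
  lor <- xml2::xml_add_child(model, "listOfReactions")
  genes <- character()
  for (j in seq_len(nrow(rxn))) {
    rnode <- xml2::xml_add_child(lor, "reaction",
      id = sanitizeSid(rxn$id[j]), name = rxn$name[j],
      reversible = if (rxn$lower_bound[j] < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rnode, "fbc:lowerFluxBound", boundRef(rxn$lower_bound[j]))
    xml2::xml_set_attr(rnode, "fbc:upperFluxBound", boundRef(rxn$upper_bound[j]))
    coef <- S[, j]
    rea <- which(coef < 0); pro <- which(coef > 0)
    if (length(rea)) {
      lr <- xml2::xml_add_child(rnode, "listOfReactants")
      for (i in rea)
        xml2::xml_add_child(lr, "speciesReference",
          species = sanitizeSid(rownames(S)[i]),
          stoichiometry = format(-coef[i], digits = 17, trim = TRUE),
          constant = "true")
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (i in pro)
        xml2::xml_add_child(lp, "speciesReference",
          species = sanitizeSid(rownames(S)[i]),
          stoichiometry = format(coef[i], digits = 17, trim = TRUE),
          constant = "true")
    }
    if (nzchar(rxn$gpr[j])) {
      tree <- gprParse(rxn$gpr[j])
      genes <- union(genes, gprGenes(rxn$gpr[j]))
      gpa <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      addGprNode(gpa, gprToFbcXml(tree))
    }
  }
  if (!is.na(network@objective)) {
    loo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                               `fbc:activeObjective` = "obj")
    onode <- xml2::xml_add_child(loo, "fbc:objective", `fbc:id` = "obj",
                                 `fbc:type` = "maximize")
    lfo <- xml2::xml_add_child(onode, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      `fbc:reaction` = sanitizeSid(network@objective),
      `fbc:coefficient` = "1")
  }
  if (length(genes)) {
    logp <- xml2::xml_add_child(model, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(logp, "fbc:geneProduct",
        `fbc:id` = paste0("G_", sanitizeSid(g)), `fbc:label` = g,
        `fbc:name` = g)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

attrLocal <- function(node, local) {
  ats <- xml2::xml_attrs(node)
  hit <- which(names(ats) == local | endsWith(names(ats), paste0(":", local)))
  if (length(hit)) ats[[hit[1]]] else NA_character_
}

fbcPrefix <- function(doc) {
  ns <- xml2::xml_ns(doc)
  hit <- which(grepl("/fbc/", unlist(ns)))
  if (length(hit)) names(ns)[hit[1]] else NA_character_
}

parseFbcGpr <- function(node, geneLabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- attrLocal(node, "geneProduct")
    return(geneLabel(gid))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, parseFbcGpr, character(1), geneLabel = geneLabel)
  if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
  else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
  else if (length(parts) == 1) parts else paste(parts, collapse = " ")
}

#' Read an SBML model
#'
#' Accepts SBML Level 3 with the fbc extension (bounds as referenced
#' parameters, GPRs as geneProductAssociations) and Level 2 files in which
#' bounds are kinetic-law parameters named LOWER_BOUND / UPPER_BOUND and
#' gene associations are stored in reaction notes as
#' `GENE_ASSOCIATION: ...`. Missing bounds default to `[0, 1000]`
#' (irreversible) or `[-1000, 1000]` (reversible), reported via `message()`.
#' Exchange reactions are flagged by single-metabolite stoichiometry or by
#' involvement of boundary-condition species.
#'
#' @param path SBML file path.
#' @return a [MetabolicNetwork-class].
#' @export
readSBML <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  doc <- xml2::read_xml(path)  # malformed XML -> error naming the line
  nsmap <- xml2::xml_ns(doc)
  corePrefix <- names(nsmap)[grepl("sbml.org/sbml", unlist(nsmap)) &
                             !grepl("/fbc/", unlist(nsmap))][1]
  q <- function(tag) paste0(corePrefix, ":", tag)
  model <- xml2::xml_find_first(doc, paste0("//", q("model")), nsmap)
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)

  ## species
  spNodes <- xml2::xml_find_all(model, paste0(".//", q("listOfSpecies"),
                                              "/", q("species")), nsmap)
  metDf <- data.frame(
    id = vapply(spNodes, function(s) xml2::xml_attr(s, "id"), character(1)),
    name = vapply(spNodes, function(s)
      xml2::xml_attr(s, "name") %NA% xml2::xml_attr(s, "id"), character(1)),
    compartment = vapply(spNodes, function(s)
      xml2::xml_attr(s, "compartment") %NA% "c", character(1)),
    formula = vapply(spNodes, function(s)
      attrLocal(s, "chemicalFormula"), character(1)),
    charge = vapply(spNodes, function(s)
      suppressWarnings(as.numeric(attrLocal(s, "charge"))), numeric(1)),
    stringsAsFactors = FALSE)
  boundarySp <- metDf$id[vapply(spNodes, function(s)
    identical(xml2::xml_attr(s, "boundaryCondition"), "true"), logical(1))]

  ## flux-bound parameters (L3 fbc)
  parNodes <- xml2::xml_find_all(model, paste0("./", q("listOfParameters"),
                                               "/", q("parameter")), nsmap)
  parVal <- vapply(parNodes, function(p)
    as.numeric(xml2::xml_attr(p, "value")), numeric(1))
  names(parVal) <- vapply(parNodes, function(p) xml2::xml_attr(p, "id"),
                          character(1))

  ## gene product labels (L3 fbc)
  fp <- fbcPrefix(doc)
  geneLab <- character()
  if (!is.na(fp)) {
    gpNodes <- xml2::xml_find_all(model,
      paste0(".//", fp, ":listOfGeneProducts/", fp, ":geneProduct"), nsmap)
    geneLab <- vapply(gpNodes, function(g)
      attrLocal(g, "label") %NA% attrLocal(g, "id"), character(1))
    names(geneLab) <- vapply(gpNodes, function(g) attrLocal(g, "id"),
                             character(1))
  }
  geneLabel <- function(gid) {
    if (gid %in% names(geneLab)) geneLab[[gid]] else gid
  }

  rxNodes <- xml2::xml_find_all(model, paste0(".//", q("listOfReactions"),
                                              "/", q("reaction")), nsmap)
  defaulted <- character()
  reacts <- lapply(rxNodes, function(r) {
    rid <- xml2::xml_attr(r, "id")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    getRefs <- function(tag, sign) {
      refs <- xml2::xml_find_all(r, paste0("./", q(tag), "/",
                                           q("speciesReference")), nsmap)
      if (!length(refs)) return(numeric())
      v <- vapply(refs, function(x) {
        st <- xml2::xml_attr(x, "stoichiometry")
        if (is.na(st)) 1 else as.numeric(st)
      }, numeric(1)) * sign
      names(v) <- vapply(refs, function(x) xml2::xml_attr(x, "species"),
                         character(1))
      v
    }
    stoich <- c(getRefs("listOfReactants", -1), getRefs("listOfProducts", 1))
    ## merge duplicates
    stoich <- tapply(stoich, names(stoich), sum)
    touchesBoundary <- any(names(stoich) %in% boundarySp)
    stoich <- stoich[!(names(stoich) %in% boundarySp)]
    ## bounds: fbc attributes, then kinetic law, then defaults
    lbRef <- attrLocal(r, "lowerFluxBound"); ubRef <- attrLocal(r, "upperFluxBound")
    lb <- if (!is.na(lbRef) && lbRef %in% names(parVal)) parVal[[lbRef]] else NA
    ub <- if (!is.na(ubRef) && ubRef %in% names(parVal)) parVal[[ubRef]] else NA
    if (is.na(lb) || is.na(ub)) {
      klPars <- xml2::xml_find_all(r, paste0("./", q("kineticLaw"),
        "//", q("parameter")), nsmap)
      for (p in klPars) {
        pid <- toupper(xml2::xml_attr(p, "id"))
        v <- as.numeric(xml2::xml_attr(p, "value"))
        if (pid == "LOWER_BOUND" && is.na(lb)) lb <- v
        if (pid == "UPPER_BOUND" && is.na(ub)) ub <- v
      }
    }
    if (is.na(lb)) { lb <- if (rev) -BIG_BOUND else 0
                     defaulted <<- union(defaulted, rid) }
    if (is.na(ub)) { ub <- BIG_BOUND; defaulted <<- union(defaulted, rid) }
    ## GPR: fbc association, else notes
    gpr <- ""
    if (!is.na(fp)) {
      gpa <- xml2::xml_find_first(r,
        paste0("./", fp, ":geneProductAssociation"), nsmap)
      if (!inherits(gpa, "xml_missing")) {
        kids <- xml2::xml_children(gpa)
        if (length(kids))
          gpr <- parseFbcGpr(kids[[1]], geneLabel)
      }
    }
    if (!nzchar(gpr)) {
      notes <- xml2::xml_find_first(r, paste0("./", q("notes")), nsmap)
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt,
          regexpr("GENE[ _]ASSOCIATION:[^\n<]*", txt))
        if (length(m))
          gpr <- trimws(sub("GENE[ _]ASSOCIATION:", "", m[1]))
      }
    }
    list(id = rid, name = xml2::xml_attr(r, "name") %NA% rid,
         stoich = stoich, lower_bound = lb, upper_bound = ub, gpr = gpr,
         subsystem = "",
         is_exchange = length(stoich) == 1L || touchesBoundary)
  })
  if (length(defaulted))
    message("bounds defaulted for ", length(defaulted), " reaction(s): ",
            paste(utils::head(defaulted, 5), collapse = ", "),
            if (length(defaulted) > 5) " ...")

  ## objective (fbc)
  objective <- NA_character_
  if (!is.na(fp)) {
    fo <- xml2::xml_find_first(model,
      paste0(".//", fp, ":listOfObjectives//", fp, ":fluxObjective"), nsmap)
    if (!inherits(fo, "xml_missing"))
      objective <- attrLocal(fo, "reaction")
  }
  keepMet <- setdiff(metDf$id, boundarySp)
  metDf <- metDf[metDf$id %in% keepMet, , drop = FALSE]
  net <- makeNetwork(reacts, metaboliteInfo = metDf, objective = objective,
                     compartments = unique(metDf$compartment))
  net
}

`%NA%` <- function(a, b) if (is.na(a)) b else a
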