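## Flux balance analysis, quadratic flux-norm minimization, flux
## variability analysis and usage classification.
##
## Constraints are given as a list; each element is one of
##   list(reaction = "id", fixed = v)          - fix a flux to a value
##   list(reaction = "id", lb = a, ub = b)     - replace a reaction's bounds
##   list(coef = c(id1 = w1, ...), fixed = v)  - fix a linear combination
##   list(coef = c(...), lb = a, ub = b)       - bound a linear combination
## Reaction-level constraints replace the model bounds for that reaction.

applyConstraints <- function(network, constraints) {
  rxn <- network@reactions
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  names(lb) <- names(ub) <- rxn$id
  extraA <- NULL; extraSense <- character(); extraRhs <- numeric()
  for (ct in constraints) {
    if (!is.null(ct$reaction)) {
      if (!ct$reaction %in% rxn$id)
        stop("constraint references unknown reaction: ", ct$reaction)
      if (!is.null(ct$fixed)) {
        lb[ct$reaction] <- ct$fixed; ub[ct$reaction] <- ct$fixed
      } else {
        if (!is.null(ct$lb)) lb[ct$reaction] <- ct$lb
        if (!is.null(ct$ub)) ub[ct$reaction] <- ct$ub
      }
    } else if (!is.null(ct$coef)) {
      bad <- setdiff(names(ct$coef), rxn$id)
      if (length(bad))
        stop("constraint references unknown reaction: ",
             paste(bad, collapse = ", "))
      row <- numeric(nrow(rxn)); names(row) <- rxn$id
      row[names(ct$coef)] <- ct$coef
      if (!is.null(ct$fixed)) {
        extraA <- rbind(extraA, row); extraSense <- c(extraSense, "=")
        extraRhs <- c(extraRhs, ct$fixed)
      } else {
        if (!is.null(ct$lb)) {
          extraA <- rbind(extraA, row); extraSense <- c(extraSense, ">=")
          extraRhs <- c(extraRhs, ct$lb)
        }
        if (!is.null(ct$ub)) {
          extraA <- rbind(extraA, row); extraSense <- c(extraSense, "<=")
          extraRhs <- c(extraRhs, ct$ub)
        }
      }
    } else stop("constraint needs 'reaction' or 'coef'")
  }
  if (any(lb > ub + 1e-12))
    stop("constraint makes lower bound exceed upper bound for: ",
         paste(names(lb)[lb > ub + 1e-12], collapse = ", "))
  list(lb = lb, ub = ub, extraA = extraA, extraSense = extraSense,
       extraRhs = extraRhs)
}

## assemble and solve the LP for an arbitrary linear objective over fluxes
lpOverFluxes <- function(network, constraints, objCoef, sense) {
  cs <- applyConstraints(network, constraints)
  S <- as.matrix(network@stoichiometry)
  A <- rbind(S, cs$extraA)
  rowSense <- c(rep("=", nrow(S)), cs$extraSense)
  rhs <- c(rep(0, nrow(S)), cs$extraRhs)
  lpSolve2(objCoef, A, rowSense, rhs, cs$lb, cs$ub, sense = sense)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the objective reaction's flux subject to
#' steady-state mass balance, capacity/reversibility bounds, and any extra
#' constraints. Infeasibility and unboundedness are reported in the
#' returned status, never as silent zeros.
#'
#' @param network a [MetabolicNetwork-class] with an objective reaction.
#' @param constraints constraint list (see package docs / examples).
#' @param sense `"max"` or `"min"`.
#' @param objective optional reaction id overriding the network objective.
#' @return a [FluxDistribution-class].
#' @export
solveFba <- function(network, constraints = list(), sense = "max",
                     objective = NULL) {
  obj <- objective %||% network@objective
  if (is.na(obj)) stop("network has no objective reaction")
  ids <- network@reactions$id
  cc <- as.numeric(ids == obj)
  r <- lpOverFluxes(network, constraints, cc, sense)
  if (r$status != "optimal")
    return(new("FluxDistribution", values = numeric(), objectiveValue = NA_real_,
               status = r$status))
  v <- r$x; names(v) <- ids
  fd <- new("FluxDistribution", values = v, objectiveValue = r$objval,
            status = "optimal")
  attr(fd, "duals") <- r$duals
  fd
}

#' Minimize the overall flux magnitude at a fixed objective value
#'
#' Among flux distributions attaining the given objective value, returns
#' one minimizing the sum of squared fluxes (quadratic norm; primary), or
#' the sum of absolute fluxes (`norm = "L1"` fallback, solved as an LP).
#' Norm minimization suppresses futile cycles: no thermodynamically
#' infeasible loop carries avoidable flux.
#'
#' @param network a [MetabolicNetwork-class].
#' @param fixedObjectiveValue objective flux to fix; `NULL` fixes the
#'   current FBA maximum under `constraints`.
#' @param constraints constraint list.
#' @param norm `"L2"` (default) or `"L1"`.
#' @param objective optional reaction id overriding the network objective.
#' @return a [FluxDistribution-class] with attribute `"fluxNorm"`.
#' @export
minimizeFluxNorm <- function(network, fixedObjectiveValue = NULL,
                             constraints = list(), norm = c("L2", "L1"),
                             objective = NULL) {
  norm <- match.arg(norm)
  obj <- objective %||% network@objective
  if (is.null(fixedObjectiveValue)) {
    fb <- solveFba(network, constraints, objective = obj)
    if (fb@status != "optimal")
      return(new("FluxDistribution", values = numeric(),
                 objectiveValue = NA_real_, status = fb@status))
    fixedObjectiveValue <- fb@objectiveValue
  }
  cts <- constraints
  if (!is.na(obj))
    cts <- c(cts, list(list(reaction = obj, fixed = fixedObjectiveValue)))
  cs <- applyConstraints(network, cts)
  S <- as.matrix(network@stoichiometry)
  ids <- network@reactions$id
  n <- length(ids)
  if (norm == "L2") {
    eq <- rbind(S, cs$extraA[cs$extraSense == "=", , drop = FALSE])
    beq <- c(rep(0, nrow(S)), cs$extraRhs[cs$extraSense == "="])
    gei <- cs$extraSense %in% c(">=", "<=")
    Aineq <- NULL; bineq <- NULL
    if (any(gei)) {
      sgn <- ifelse(cs$extraSense[gei] == ">=", 1, -1)
      Aineq <- cs$extraA[gei, , drop = FALSE] * sgn
      bineq <- cs$extraRhs[gei] * sgn
    }
    r <- qpSolveNorm(eq, beq, cs$lb, cs$ub, Aineq, bineq)
    if (r$status != "optimal")
      return(new("FluxDistribution", values = numeric(),
                 objectiveValue = NA_real_, status = "infeasible"))
    v <- r$x; names(v) <- ids
    fd <- new("FluxDistribution", values = v,
              objectiveValue = fixedObjectiveValue, status = "optimal")
    attr(fd, "fluxNorm") <- r$norm
    attr(fd, "normType") <- "L2"
    return(fd)
  }
  ## L1: v = p - m, p,m >= 0, minimize sum(p + m)
  A <- rbind(S, cs$extraA)
  rowSense <- c(rep("=", nrow(S)), cs$extraSense)
  rhs <- c(rep(0, nrow(S)), cs$extraRhs)
  A2 <- cbind(A, -A)
  lb2 <- c(pmax(cs$lb, 0), pmax(-cs$ub, 0))
  ub2 <- c(pmax(cs$ub, 0), pmax(-cs$lb, 0))
  r <- lpSolve2(rep(1, 2 * n), A2, rowSense, rhs, lb2, ub2, sense = "min")
  if (r$status != "optimal")
    return(new("FluxDistribution", values = numeric(),
               objectiveValue = NA_real_, status = r$status))
  v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  names(v) <- ids
  fd <- new("FluxDistribution", values = v,
            objectiveValue = fixedObjectiveValue, status = "optimal")
  attr(fd, "fluxNorm") <- r$objval
  attr(fd, "normType") <- "L1"
  fd
}

#' Flux variability analysis
#'
#' Minimizes and maximizes each flux individually under the given
#' constraints (2 LP solves per reaction). Measured rates enter as fixed
#' constraints; when `fixObjective` is `"max"` the objective is first
#' optimized and then fixed to its optimum.
#'
#' @param network a [MetabolicNetwork-class].
#' @param constraints constraint list.
#' @param reactions optional id subset (default: all reactions).
#' @param fixObjective `NULL` (leave free; appropriate when constraints
#'   already fix the measured growth rate), `"max"`, or a numeric value.
#' @return an [FvaResult-class].
#' @export
runFva <- function(network, constraints = list(), reactions = NULL,
                   fixObjective = NULL) {
  cts <- constraints
  if (!is.null(fixObjective)) {
    val <- if (identical(fixObjective, "max")) {
      fb <- solveFba(network, cts)
      if (fb@status != "optimal")
        stop("objective optimization failed (", fb@status,
             ") under the given constraints")
      fb@objectiveValue
    } else fixObjective
    cts <- c(cts, list(list(reaction = network@objective, fixed = val)))
  }
  ids <- network@reactions$id
  subset <- reactions %||% ids
  bad <- setdiff(subset, ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  ranges <- matrix(NA_real_, length(subset), 2,
                   dimnames = list(subset, c("min", "max")))
  for (rid in subset) {
    cc <- as.numeric(ids == rid)
    lo <- lpOverFluxes(network, cts, cc, "min")
    if (lo$status != "optimal")
      stop("FVA infeasible while minimizing ", rid, " (status ", lo$status,
           "); check the constraint set")
    hi <- lpOverFluxes(network, cts, cc, "max")
    if (hi$status != "optimal")
      stop("FVA infeasible while maximizing ", rid, " (status ", hi$status, ")")
    ranges[rid, ] <- c(lo$objval, hi$objval)
  }
  ## clamp tiny inversions from solver tolerance
  sw <- ranges[, "min"] > ranges[, "max"]
  if (any(sw)) {
    mid <- (ranges[sw, "min"] + ranges[sw, "max"]) / 2
    ranges[sw, "min"] <- ranges[sw, "max"] <- mid
  }
  new("FvaResult", ranges = ranges,
      context = list(constraints = cts, fixObjective = fixObjective))
}

#' Classify reaction usage from FVA ranges
#'
#' Partitions reactions into `required` (flux must be non-zero: the range
#' excludes 0), `inactive` (flux must be zero: min = max = 0) and
#' `optional` (may or may not carry flux), up to a zero tolerance.
#' The partition is exhaustive and exclusive.
#'
#' @param fva an [FvaResult-class].
#' @param zeroTol numeric zero tolerance (default `1e-9` targets solver
#'   noise; biological activity thresholds are a separate, larger scale).
#' @return named factor with levels required/optional/inactive.
#' @export
classifyUsage <- function(fva, zeroTol = 1e-9) {
  r <- fva@ranges
  lab <- ifelse(r[, "min"] > zeroTol | r[, "max"] < -zeroTol, "required",
         ifelse(abs(r[, "min"]) <= zeroTol & abs(r[, "max"]) <= zeroTol,
                "inactive", "optional"))
  factor(lab, levels = c("required", "optional", "inactive"))
}

#' Flux spans
#'
#' The span of a reaction is its FVA max minus min, a measure of how well
#' the flux is resolved by the constraints. Returns per-reaction spans
#' and their mean over the subset.
#'
#' @param fva an [FvaResult-class].
#' @param subset reaction ids (default: all in `fva`).
#' @return list with `spans` (named numeric) and `meanSpan`.
#' @export
fluxSpanSummary <- function(fva, subset = NULL) {
  r <- fva@ranges
  subset <- subset %||% rownames(r)
  if (!length(subset)) stop("empty reaction subset")
  bad <- setdiff(subset, rownames(r))
  if (length(bad)) stop("subset not covered by FVA result: ",
                        paste(bad, collapse = ", "))
  spans <- r[subset, "max"] - r[subset, "min"]
  list(spans = spans, meanSpan = mean(spans))
}

#' Write a tab-separated FVA report
#'
#' Columns: reaction id, min, max, span, usage class.
#'
#' @param fva an [FvaResult-class].
#' @param path output path.
#' @param zeroTol passed to [classifyUsage()].
#' @return the report data.frame, invisibly.
#' @export
writeFvaReport <- function(fva, path, zeroTol = 1e-9) {
  r <- fva@ranges
  out <- data.frame(reaction = rownames(r), min = r[, "min"], max = r[, "max"],
                    span = r[, "max"] - r[, "min"],
                    class = as.character(classifyUsage(fva, zeroTol)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
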