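## Shared fixtures and independent oracles. Networks are built in code;
## the toy phototroph is cached per session since it is immutable.

.cache <- new.env(parent = emptyenv())

toyNet <- function() {
  if (is.null(.cache$toy)) .cache$toy <- makeToyNetwork()
  .cache$toy
}

toyNetNoGar <- function() {
  if (is.null(.cache$toy0))
    .cache$toy0 <- makeToyNetwork(toyNetworkSpec(gar = 0, ngar = 0))
  .cache$toy0
}

## linear chain A -> B -> C with a fixed substrate supply and a blocked
## side branch (closed exchange E, E -> C)
chainNet <- function(supply = 5) {
  makeNetwork(list(
    list(id = "EX_A", stoich = c(A = 1), lower_bound = supply,
         upper_bound = supply),
    list(id = "R1", stoich = c(A = -1, B = 1)),
    list(id = "R2", stoich = c(B = -1, C = 1)),
    list(id = "EX_E", stoich = c(E = 1), lower_bound = 0, upper_bound = 0),
    list(id = "R3", stoich = c(E = -1, C = 1)),
    list(id = "EX_C", stoich = c(C = -1))),
    objective = "EX_C")
}

## A -> B with a parallel futile 2-cycle B <-> D
cycleNet <- function() {
  makeNetwork(list(
    list(id = "EX_A", stoich = c(A = 1), lower_bound = 3, upper_bound = 3),
    list(id = "R1", stoich = c(A = -1, B = 1)),
    list(id = "CYC1", stoich = c(B = -1, D = 1)),
    list(id = "CYC2", stoich = c(D = -1, B = 1)),
    list(id = "EX_B", stoich = c(B = -1))),
    objective = "EX_B")
}

## small branched network for brute-force oracles: substrate splits over
## two routes with different yields
branchNet <- function() {
  makeNetwork(list(
    list(id = "EX_S", stoich = c(S = 1), lower_bound = 0, upper_bound = 4),
    list(id = "HIGH", stoich = c(S = -1, P = 2), upper_bound = 3),
    list(id = "LOW", stoich = c(S = -1, P = 1)),
    list(id = "EX_P", stoich = c(P = -1))),
    objective = "EX_P")
}

## brute-force LP oracle by vertex enumeration: max c'v s.t. S v = 0,
## lb <= v <= ub. Enumerates all choices of n - rank(S) variables pinned
## at a bound; only usable for tiny networks.
bruteForceLpMax <- function(network, objective = NULL,
                            constraints = list()) {
  cs <- cyanoflux:::applyConstraints(network, constraints)
  stopifnot(is.null(cs$extraA))
  S <- as.matrix(stoichiometryMatrix(network))
  ids <- reactionIds(network)
  obj <- objective %||% objectiveId(network)
  cc <- as.numeric(ids == obj)
  n <- ncol(S)
  rk <- qr(S)$rank
  nfree <- n - rk
  best <- -Inf; bestV <- NULL
  for (pin in utils::combn(n, nfree, simplify = FALSE)) {
    rest <- setdiff(seq_len(n), pin)
    for (mask in seq_len(2^nfree) - 1L) {
      atUb <- as.logical(bitwAnd(mask, 2^(seq_len(nfree) - 1L)) > 0)
      vp <- ifelse(atUb, cs$ub[pin], cs$lb[pin])
      rhs <- -S[, pin, drop = FALSE] %*% vp
      sol <- tryCatch(qr.solve(S[, rest, drop = FALSE], rhs,
                               tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[pin] <- vp; v[rest] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < cs$lb - 1e-7) || any(v > cs$ub + 1e-7)) next
      val <- sum(cc * v)
      if (val > best + 1e-12) { best <- val; bestV <- v }
    }
  }
  list(objval = best, v = stats::setNames(bestV, ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## closed-form dark N2/glycogen optimum for the toy stoichiometry: carbon
## and ATP balances meet where both bind; respiratory ATP yields follow
## from the proton coefficients (NADH via NDH-1 + b6f + COX; NADPH via
## reverse FNR + FdPq + b6f + COX)
darkYieldOracle <- function(spec = toyNetworkSpec(), ngar = 0,
                            glycogenCap = 0.171) {
  q <- spec$atpPerProton
  aNadh <- (spec$protonPerNdh1 + spec$protonPerCytb6f +
              spec$protonPerCox) * q
  aNadph <- (spec$protonPerCytb6f + spec$protonPerCox) * q
  K1 <- 4 + 6 * aNadh + 6 * aNadph   # ATP per glycogen fully catabolized
  K2 <- 20 + 4 * aNadph              # ATP per N2 incl. cyanophycin cost
  m <- ngar / glycogenCap            # maintenance per glycogen supplied
  cFrac <- (1.5 * K2 + m) / (K1 + 1.5 * K2)
  n2 <- 1.5 * (1 - cFrac)
  ## O2: half an O2 per NADH respired (6c) plus per excess NADPH respired
  o2 <- 0.5 * (6 * cFrac + 6 * cFrac - 4 * n2)
  list(n2PerGlycogen = n2, o2PerN2 = o2 / n2)
}

## evidence-set fixture carved from named toy reactions
toyEvidenceSets <- function(rH, rL, rE, epsilon = 0.01) {
  new("ReactionEvidenceSets", rE = rE, rH = rH, rL = rL, epsilon = epsilon)
}

## exhaustive TPD oracle: enumerate all binary assignments (3 states per
## R_H reaction, 2 per R_L), keep LP-feasible ones, return the maximal
## evidence score and the minimal flux norm among score-optimal
## assignments
tpdExhaustiveOracle <- function(network, sets) {
  h <- length(sets@rH); l <- length(sets@rL)
  eps <- sets@epsilon
  states <- expand.grid(rep(list(0:2), h), KEEP.OUT.ATTRS = FALSE)
  zstates <- expand.grid(rep(list(0:1), l), KEEP.OUT.ATTRS = FALSE)
  bestScore <- -Inf; bestNorm <- Inf
  for (i in seq_len(max(nrow(states), 1))) {
    for (j in seq_len(max(nrow(zstates), 1))) {
      cts <- lapply(names(sets@rE), function(r)
        list(reaction = r, fixed = sets@rE[[r]]))
      score <- 0
      for (k in seq_len(h)) {
        s <- states[i, k]
        r <- sets@rH[k]
        if (s == 1) { cts <- c(cts, list(list(reaction = r, lb = eps)))
                      score <- score + 1 }
        else if (s == 2) { cts <- c(cts, list(list(reaction = r, ub = -eps)))
                           score <- score + 1 }
        else cts <- c(cts, list(list(reaction = r, fixed = 0)))
      }
      for (k in seq_len(l)) {
        if (zstates[j, k] == 1) {
          cts <- c(cts, list(list(reaction = sets@rL[k], fixed = 0)))
          score <- score + 1
        }
      }
      feas <- tryCatch({
        mn <- cyanoflux:::minimizeFluxNormFree(network, cts, "L2")
        if (is.null(mn)) NULL else attr(mn, "fluxNorm")
      }, error = function(e) NULL)
      if (is.null(feas)) next
      if (score > bestScore + 1e-9) { bestScore <- score; bestNorm <- feas }
      else if (abs(score - bestScore) < 1e-9 && feas < bestNorm)
        bestNorm <- feas
    }
  }
  list(score = bestScore, norm = bestNorm)
}
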