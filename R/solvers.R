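## Dense bounded-variable two-phase simplex and a quadratic-program wrapper.
## Problems are small (tens of variables), so the basis system is solved
## directly each iteration; robustness is favored over speed.

## Solve: max/min c'x  s.t.  A x (sense) b,  lb <= x <= ub
## sense per row: "=", "<=", ">=".
## Returns list(status, x, objval, duals, reduced). Duals are for the rows
## (marginal change of the max-form objective per unit rhs); for sense=min
## they refer to the original minimization objective.
lpSolve2 <- function(obj, A, rowSense, rhs, lb, ub, sense = "max",
                     tol = 1e-9, maxit = NULL) {
  n <- length(obj)
  m <- length(rhs)
  stopifnot(ncol(A) == n, nrow(A) == m, length(rowSense) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  minimize <- identical(sense, "min")
  cc <- if (minimize) -obj else obj

  ## slack per row: "<=": [0,Inf), ">=": (-Inf,0], "=": [0,0]
  slb <- ifelse(rowSense == "<=", 0, ifelse(rowSense == ">=", -Inf, 0))
  sub <- ifelse(rowSense == "<=", Inf, ifelse(rowSense == ">=", 0, 0))
  Aa <- cbind(as.matrix(A), diag(m))
  L <- c(lb, slb); U <- c(ub, sub)
  cA <- c(cc, rep(0, m))
  N <- n + m
  if (is.null(maxit)) maxit <- 200L * (N + m) + 2000L

  ## initial: basis = slacks; structural nonbasic at a finite bound
  basis <- (n + 1L):N
  ## nonbasic status: value each nonbasic variable sits at
  xval <- numeric(N)
  xval[seq_len(n)] <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  inbasis <- rep(FALSE, N); inbasis[basis] <- TRUE

  recomputeXB <- function() {
    bres <- rhs - Aa[, !inbasis, drop = FALSE] %*% xval[!inbasis]
    AB <- Aa[, basis, drop = FALSE]
    drop(solve(AB, bres))
  }
  xB <- tryCatch(recomputeXB(), error = function(e) NULL)
  if (is.null(xB)) return(list(status = "infeasible"))

  feastol <- 1e-7
  iter <- 0L
  bland <- FALSE
  phase <- 1L

  repeat {
    iter <- iter + 1L
    if (iter > maxit) return(list(status = "maxit"))
    if (iter %% 500L == 0L) bland <- TRUE
    AB <- Aa[, basis, drop = FALSE]
    lB <- L[basis]; uB <- U[basis]

    if (phase == 1L) {
      below <- xB < lB - feastol
      above <- xB > uB + feastol
      if (!any(below) && !any(above)) {
        phase <- 2L
        next
      }
      e <- numeric(m); e[above] <- 1; e[below] <- -1
      y <- tryCatch(drop(solve(t(AB), e)), error = function(err) NULL)
      if (is.null(y)) return(list(status = "infeasible"))
      nb <- which(!inbasis)
      g <- drop(crossprod(Aa[, nb, drop = FALSE], y))  # y'A_j
      atLow <- xval[nb] <= L[nb] + 1e-12 & is.finite(L[nb])
      atUp <- xval[nb] >= U[nb] - 1e-12 & is.finite(U[nb])
      fixed <- is.finite(L[nb]) & is.finite(U[nb]) & (U[nb] - L[nb] < 1e-15)
      ## improving: increase from low if y'A_j > tol; decrease from up if < -tol
      candUpIdx <- which(!fixed & atLow & g > tol)
      candDnIdx <- which(!fixed & atUp & !atLow & g < -tol)
      if (!length(candUpIdx) && !length(candDnIdx)) {
        inf <- sum(pmax(0, lB - xB)) + sum(pmax(0, xB - uB))
        if (inf <= 1e-6) { phase <- 2L; next }
        return(list(status = "infeasible"))
      }
      if (bland) {
        allc <- c(nb[candUpIdx], nb[candDnIdx])
        jsel <- min(allc)
        dirUp <- jsel %in% nb[candUpIdx]
      } else {
        bestUp <- if (length(candUpIdx)) candUpIdx[which.max(g[candUpIdx])] else NA
        bestDn <- if (length(candDnIdx)) candDnIdx[which.min(g[candDnIdx])] else NA
        if (!is.na(bestUp) && (is.na(bestDn) || g[bestUp] >= -g[bestDn])) {
          jsel <- nb[bestUp]; dirUp <- TRUE
        } else { jsel <- nb[bestDn]; dirUp <- FALSE }
      }
    } else {
      ## phase 2: optimality pricing on cA
      y <- tryCatch(drop(solve(t(AB), cA[basis])), error = function(err) NULL)
      if (is.null(y)) return(list(status = "infeasible"))
      nb <- which(!inbasis)
      d <- cA[nb] - drop(crossprod(Aa[, nb, drop = FALSE], y))
      atLow <- xval[nb] <= L[nb] + 1e-12 & is.finite(L[nb])
      atUp <- xval[nb] >= U[nb] - 1e-12 & is.finite(U[nb])
      fixed <- is.finite(L[nb]) & is.finite(U[nb]) & (U[nb] - L[nb] < 1e-15)
      candUpIdx <- which(!fixed & atLow & d > tol)
      candDnIdx <- which(!fixed & atUp & !atLow & d < -tol)
      if (!length(candUpIdx) && !length(candDnIdx)) {
        ## optimal
        x <- xval
        x[basis] <- xB
        objval <- sum(cc * x[seq_len(n)])
        reduced <- numeric(N)
        reduced[nb] <- d
        sgn <- if (minimize) -1 else 1
        return(list(status = "optimal", x = x[seq_len(n)],
                    objval = sgn * objval, duals = sgn * y,
                    reduced = sgn * reduced[seq_len(n)]))
      }
      if (bland) {
        allc <- c(nb[candUpIdx], nb[candDnIdx])
        jsel <- min(allc)
        dirUp <- jsel %in% nb[candUpIdx]
      } else {
        bestUp <- if (length(candUpIdx)) candUpIdx[which.max(d[candUpIdx])] else NA
        bestDn <- if (length(candDnIdx)) candDnIdx[which.min(d[candDnIdx])] else NA
        if (!is.na(bestUp) && (is.na(bestDn) || d[bestUp] >= -d[bestDn])) {
          jsel <- nb[bestUp]; dirUp <- TRUE
        } else { jsel <- nb[bestDn]; dirUp <- FALSE }
      }
    }

    ## ratio test: entering jsel moves up (dirUp) or down; xB changes by
    ## -t*w (up) or +t*w (down), w = AB^-1 A_j
    w <- drop(solve(AB, Aa[, jsel]))
    sgn <- if (dirUp) 1 else -1
    dxB <- -sgn * w
    tmax <- U[jsel] - L[jsel]   # bound flip distance (may be Inf)
    tbest <- tmax; leave <- 0L; leaveBound <- NA
    for (i in seq_len(m)) {
      di <- dxB[i]
      if (abs(di) < 1e-11) next
      xi <- xB[i]
      if (phase == 1L && xi > uB[i] + feastol) {
        ## infeasible above: moving down blocks at uB (becomes feasible),
        ## moving up is unbounded w.r.t. this row (worsens, but pricing
        ## guarantees net improvement); block only when decreasing
        ti <- if (di < 0) (xi - uB[i]) / (-di) else Inf
        bnd <- uB[i]
      } else if (phase == 1L && xi < lB[i] - feastol) {
        ti <- if (di > 0) (lB[i] - xi) / di else Inf
        bnd <- lB[i]
      } else {
        if (di > 0) { ti <- if (is.finite(uB[i])) (uB[i] - xi) / di else Inf; bnd <- uB[i] }
        else { ti <- if (is.finite(lB[i])) (xi - lB[i]) / (-di) else Inf; bnd <- lB[i] }
      }
      if (ti < tbest - 1e-12 || (ti < tbest + 1e-12 && leave == 0L)) {
        if (ti < tbest) { tbest <- ti; leave <- i; leaveBound <- bnd }
      }
    }
    if (!is.finite(tbest)) {
      if (phase == 1L) return(list(status = "infeasible"))
      return(list(status = "unbounded"))
    }
    tbest <- max(tbest, 0)
    ## apply step
    if (leave == 0L) {
      ## bound flip of entering variable
      xval[jsel] <- xval[jsel] + sgn * tbest
      xB <- xB + dxB * tbest
    } else {
      xB <- xB + dxB * tbest
      lv <- basis[leave]
      inbasis[lv] <- FALSE
      xval[lv] <- leaveBound
      basis[leave] <- jsel
      inbasis[jsel] <- TRUE
      newxB <- xB
      newxB[leave] <- xval[jsel] + sgn * tbest
      xval[jsel] <- 0
      xB <- newxB
      ## periodic refresh against drift
      if (iter %% 60L == 0L) {
        xB2 <- tryCatch(recomputeXB(), error = function(e) NULL)
        if (!is.null(xB2)) xB <- xB2
      }
    }
  }
}

## Equality-constrained convex QP:
##   min x'x (times weight) s.t. Aeq x = beq, Aineq x >= bineq, lb<=x<=ub
## via quadprog, with rank reduction of the equality rows.
qpSolveNorm <- function(Aeq, beq, lb, ub, Aineq = NULL, bineq = NULL) {
  n <- length(lb)
  Aeq <- as.matrix(Aeq)
  ## substitute out variables fixed by their bounds (quadprog is fragile
  ## with equalities encoded as paired inequalities)
  fixed <- is.finite(lb) & is.finite(ub) & (ub - lb < 1e-12)
  if (any(fixed)) {
    xf <- lb[fixed]
    free <- !fixed
    if (!any(free)) {
      x <- lb
      if (nrow(Aeq) && max(abs(Aeq %*% x - beq)) > 1e-5)
        return(list(status = "infeasible"))
      return(list(status = "optimal", x = x, norm = sum(x^2)))
    }
    beq2 <- if (nrow(Aeq)) beq - drop(Aeq[, fixed, drop = FALSE] %*% xf)
            else beq
    bineq2 <- if (!is.null(Aineq) && nrow(Aineq))
      bineq - drop(Aineq[, fixed, drop = FALSE] %*% xf) else bineq
    sub <- qpSolveNorm(Aeq[, free, drop = FALSE], beq2, lb[free], ub[free],
                       if (!is.null(Aineq)) Aineq[, free, drop = FALSE],
                       bineq2)
    if (sub$status != "optimal") return(sub)
    x <- numeric(n); x[fixed] <- xf; x[free] <- sub$x
    return(list(status = "optimal", x = x, norm = sum(x^2)))
  }
  ## null-space parametrization: x = x0 + Z w with A_eq x0 = b_eq and
  ## Z an orthonormal basis of the null space; the reduced QP has an
  ## identity Hessian and only inequality constraints, which quadprog
  ## handles robustly
  if (nrow(Aeq)) {
    qrA <- qr(t(Aeq))
    rk <- qrA$rank
    keep <- qrA$pivot[seq_len(rk)]
    A2 <- Aeq[keep, , drop = FALSE]; b2 <- beq[keep]
    x0 <- drop(crossprod(A2, solve(tcrossprod(A2), b2)))
    if (max(abs(Aeq %*% x0 - beq)) > 1e-6)
      return(list(status = "infeasible"))  # inconsistent equality system
    Qfull <- qr.Q(qrA, complete = TRUE)
    Z <- Qfull[, -seq_len(rk), drop = FALSE]
  } else {
    x0 <- numeric(n)
    Z <- diag(n)
  }
  k <- ncol(Z)
  if (k == 0L) {
    if (any(x0 < lb - 1e-7) || any(x0 > ub + 1e-7))
      return(list(status = "infeasible"))
    return(list(status = "optimal", x = x0, norm = sum(x0^2)))
  }
  Alist <- list(); blist <- list()
  fin <- is.finite(lb)
  if (any(fin)) {
    Alist <- c(Alist, list(t(Z[fin, , drop = FALSE])))
    blist <- c(blist, list(lb[fin] - x0[fin]))
  }
  fup <- is.finite(ub)
  if (any(fup)) {
    Alist <- c(Alist, list(-t(Z[fup, , drop = FALSE])))
    blist <- c(blist, list(x0[fup] - ub[fup]))
  }
  if (!is.null(Aineq) && nrow(Aineq)) {
    AZ <- as.matrix(Aineq) %*% Z
    Alist <- c(Alist, list(t(AZ)))
    blist <- c(blist, list(bineq - drop(as.matrix(Aineq) %*% x0)))
  }
  Amat <- if (length(Alist)) do.call(cbind, Alist) else matrix(0, k, 0)
  bvec <- unlist(blist)
  sol <- NULL
  ## degenerate vertices can make quadprog report a feasible problem
  ## inconsistent; retry with a tiny feasibility relaxation
  for (slack in c(0, 1e-9, 1e-7)) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = diag(2, k),
                         dvec = -2 * drop(crossprod(Z, x0)),
                         Amat = Amat, bvec = bvec - slack, meq = 0),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) return(list(status = "infeasible"))
  x <- x0 + drop(Z %*% sol$solution)
  ## clip solver noise at the bounds
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, norm = sum(x^2))
}
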