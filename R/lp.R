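# Internal linear-programming core.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with a two-phase primal simplex for bounded variables (nonbasic variables
# rest at a finite bound; bound flips are handled without basis changes).
# Pricing is Dantzig's rule with an automatic switch to Bland's smallest-
# index rule while degenerate pivots stall, the tableau is refactorised from
# the basis periodically and before optimality is accepted, and the final
# solution is reconstructed exactly from the final basis and validated. If
# validation fails, the solve is repeated once in a slow safe mode (Bland
# pricing throughout, frequent refactorisation). Infinite bounds are clamped
# to +/- .lp_big; a solution pressing against a clamped infinite bound with
# nonzero objective weight is reported "unbounded".

.lp_big <- 1e7

#' Solve a bounded linear programme
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or sparse; constraints are
#'   equalities `A x = b`.
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n; `-Inf`/`Inf` allowed.
#' @param sense `"max"` or `"min"`.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and `x` (length n, `NA` unless optimal).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  res <- tryCatch(lp_simplex(obj, A, b, lb, ub, sense, tol, safe = FALSE),
                  error = function(e) e)
  if (inherits(res, "error"))
    res <- lp_simplex(obj, A, b, lb, ub, sense, tol, safe = TRUE)
  res
}

lp_simplex <- function(obj, A, b, lb, ub, sense, tol, safe = FALSE) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  inf_lb <- !is.finite(lb); inf_ub <- !is.finite(ub)
  lbc <- ifelse(inf_lb, -.lp_big, lb)
  ubc <- ifelse(inf_ub, .lp_big, ub)
  cvec <- if (sense == "max") obj else -obj
  refac_every <- if (safe) 100L else 2000L

  N <- n + m                                 # structural + artificial
  # start: structurals at the bound closer to zero
  x <- ifelse(abs(lbc) <= abs(ubc), lbc, ubc)
  stat <- ifelse(abs(lbc) <= abs(ubc), 1L, 2L)   # 1 at lb, 2 at ub
  r0 <- b - as.numeric(A %*% x)
  sg <- ifelse(r0 >= 0, 1, -1)
  # scale A's rows so every artificial starts at |r0| >= 0; the artificial
  # block stays an exact identity (it is the starting basis)
  Tab <- cbind(A * sg, diag(m))
  bS <- b * sg
  basis <- n + seq_len(m)
  xB <- abs(r0)
  LB <- c(lbc, rep(0, m)); UB <- c(ubc, rep(.lp_big, m))
  statall <- c(stat, rep(0L, m))

  Aall <- Tab                                 # row-scaled [A | I], fixed copy

  refactor <- function(basis, statall, LB, UB) {
    B <- Aall[, basis, drop = FALSE]
    Tab <- solve(B, Aall)
    xfull <- numeric(N)
    xfull[statall == 1L] <- LB[statall == 1L]
    xfull[statall == 2L] <- UB[statall == 2L]
    nb <- setdiff(seq_len(N), basis)
    xB <- drop(solve(B, bS - Aall[, nb, drop = FALSE] %*% xfull[nb]))
    list(Tab = Tab, xB = xB)
  }

  run_phase <- function(cost, Tab, basis, xB, statall, LB, UB, maxit = 200000L,
                        target = NULL) {
    stall <- 0L
    bland_left <- if (safe) maxit else 0L
    stalled_before <- FALSE
    for (it in seq_len(maxit)) {
      if (!is.null(target)) {
        # phase 1: the optimum (all artificials at zero) is known; stop there
        # instead of grinding through degenerate price-out pivots
        av <- numeric(N)
        av[statall == 1L] <- LB[statall == 1L]
        av[statall == 2L] <- UB[statall == 2L]
        av[basis] <- xB
        if (max(abs(av[(n + 1):N])) <= 1e-8)
          return(list(Tab = Tab, basis = basis, xB = xB, statall = statall,
                      status = "optimal"))
      }
      if (it %% refac_every == 0L) {          # shed accumulated pivot error
        rf <- tryCatch(refactor(basis, statall, LB, UB), error = function(e) NULL)
        if (!is.null(rf)) { Tab <- rf$Tab; xB <- rf$xB }
      }
      d <- cost - drop(cost[basis] %*% Tab)
      d[basis] <- 0
      elig <- which(statall != 0L & (UB - LB) > tol &
                    ((statall == 1L & d > tol) | (statall == 2L & d < -tol)))
      if (!length(elig)) {
        # confirm optimality against a freshly factorised tableau: reduced
        # costs drift over many pivots and can price out prematurely
        rf <- tryCatch(refactor(basis, statall, LB, UB), error = function(e) NULL)
        if (!is.null(rf)) {
          Tab <- rf$Tab; xB <- rf$xB
          d <- cost - drop(cost[basis] %*% Tab)
          d[basis] <- 0
          elig <- which(statall != 0L & (UB - LB) > tol &
                        ((statall == 1L & d > tol) | (statall == 2L & d < -tol)))
        }
        if (!length(elig))
          return(list(Tab = Tab, basis = basis, xB = xB,
                      statall = statall, status = "optimal"))
      }
      # Dantzig pricing normally; Bland's smallest-index rule while stalled
      j <- if (bland_left > 0L) {
        bland_left <- bland_left - 1L
        elig[1L]
      } else {
        elig[which.max(abs(d[elig]))]
      }
      dir <- if (statall[j] == 1L) 1 else -1
      g <- dir * Tab[, j]
      # basic variable i moves as xB[i] - g[i]*t; limits where it hits a bound
      lim <- rep(Inf, m)
      to_lb <- g > tol                        # decreasing basics -> lower bound
      to_ub <- g < -tol                       # increasing basics -> upper bound
      lim[to_lb] <- (xB[to_lb] - LB[basis[to_lb]]) / g[to_lb]
      lim[to_ub] <- (xB[to_ub] - UB[basis[to_ub]]) / g[to_ub]
      lim <- pmax(lim, 0)
      tflip <- UB[j] - LB[j]
      tstar <- min(tflip, lim)
      if (tstar >= .lp_big * 10) return(list(status = "unbounded"))
      if (tstar <= tol) stall <- stall + 1L else stall <- 0L
      if (stall > 50L && bland_left == 0L) {
        bland_left <- if (stalled_before) maxit else 2000L
        stalled_before <- TRUE
        stall <- 0L
      }
      cand <- which(lim <= tstar + tol)
      if (!length(cand)) {                    # bound flip, no basis change
        xB <- xB - g * tstar
        statall[j] <- if (statall[j] == 1L) 2L else 1L
        next
      }
      # among (near-)tied leaving rows pick the largest |pivot| for numerical
      # stability; under Bland's rule the smallest basis index (terminates)
      r <- if (bland_left > 0L) cand[which.min(basis[cand])] else
        cand[which.max(abs(g[cand]))]
      tstar <- min(tstar, lim[r])
      leave <- basis[r]
      xB <- xB - g * tstar
      entval <- (if (dir == 1) LB[j] else UB[j]) + dir * tstar
      piv <- Tab[r, j]
      Tab[r, ] <- Tab[r, ] / piv
      colj <- Tab[, j]; colj[r] <- 0
      Tab <- Tab - outer(colj, Tab[r, ])
      statall[leave] <- if (to_lb[r]) 1L else 2L
      statall[j] <- 0L
      basis[r] <- j
      xB[r] <- entval
    }
    stop("simplex: iteration limit reached")
  }

  # phase 1: drive artificials to zero
  if (any(xB > tol)) {
    c1 <- c(rep(0, n), rep(-1, m))
    p1 <- run_phase(c1, Tab, basis, xB, statall, LB, UB, target = 0)
    if (identical(p1$status, "unbounded"))
      stop("simplex: phase-1 unbounded (internal error)")
    Tab <- p1$Tab; basis <- p1$basis; xB <- p1$xB; statall <- p1$statall
    av <- numeric(N)
    av[statall == 1L] <- LB[statall == 1L]
    av[statall == 2L] <- UB[statall == 2L]
    av[basis] <- xB
    art_sum <- sum(abs(av[(n + 1):N]))
    if (art_sum > 1e-7) {
      if (!safe) stop("simplex: re-check infeasibility in safe mode")
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
  }
  UB[(n + 1):N] <- 0                          # lock artificials at zero
  xB[basis > n] <- 0
  statall[statall != 0L & seq_len(N) > n] <- 1L

  c2 <- c(cvec, rep(0, m))
  p2 <- run_phase(c2, Tab, basis, xB, statall, LB, UB)
  if (identical(p2$status, "unbounded")) {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  basis <- p2$basis; xB <- p2$xB; statall <- p2$statall

  # reconstruct the solution exactly from the final basis
  rf <- tryCatch(refactor(basis, statall, LB, UB), error = function(e) NULL)
  if (!is.null(rf)) xB <- rf$xB
  xfull <- numeric(N)
  xfull[statall == 1L] <- LB[statall == 1L]
  xfull[statall == 2L] <- UB[statall == 2L]
  xfull[basis] <- xB
  x <- xfull[seq_len(n)]
  if (max(abs(as.numeric(A %*% x) - b)) > 1e-6 ||
      any(x < lbc - 1e-6) || any(x > ubc + 1e-6) ||
      any(abs(xfull[(n + 1):N]) > 1e-6)) {
    if (isTRUE(getOption("wbmflux.lp_debug")))
      message(sprintf("final violation: res=%.3g lb=%.3g ub=%.3g art=%.3g refac_ok=%d",
                      max(abs(as.numeric(A %*% x) - b)), max(lbc - x),
                      max(x - ubc), max(abs(xfull[(n + 1):N])), !is.null(rf)))
    stop("simplex: final solution violates constraints (numerical failure)")
  }
  x <- pmin(pmax(x, lbc - 1e-9), ubc + 1e-9)
  val <- sum(obj * x)
  hit_clamp <- (inf_ub & x > 0.99 * .lp_big) | (inf_lb & x < -0.99 * .lp_big)
  if (any(hit_clamp & obj != 0)) {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  list(status = "optimal", objective = val, x = x)
}
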