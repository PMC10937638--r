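# Independent brute-force oracles used to check the LP machinery.
#
# oracle_vertices enumerates every basic feasible solution of
#   { x : A x = b, lb <= x <= ub }
# by trying all bases (column subsets of size rank(A)) with all 2^(n-r)
# assignments of the nonbasic variables to their bounds. For bounded regions
# the LP optimum is attained at one of these points, so max over vertices is
# an exhaustive, simplex-free oracle. Only usable for small n.

oracle_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  stopifnot(n <= 14, n - r <= 14)
  verts <- list()
  bases <- if (r == 0) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  for (B in bases) {
    Nset <- setdiff(seq_len(n), B)
    if (length(B) && qr(A[, B, drop = FALSE])$rank < length(B)) next
    grid <- if (length(Nset))
      expand.grid(rep(list(c(FALSE, TRUE)), length(Nset))) else data.frame()[1, , drop = FALSE]
    for (g in seq_len(max(nrow(grid), 1))) {
      xN <- if (length(Nset))
        ifelse(unlist(grid[g, ]), ub[Nset], lb[Nset]) else numeric(0)
      if (any(!is.finite(xN))) next
      rhs <- b - if (length(Nset)) as.numeric(A[, Nset, drop = FALSE] %*% xN) else b * 0
      xB <- if (length(B)) tryCatch(qr.solve(A[, B, drop = FALSE], rhs, tol = 1e-10),
                                    error = function(e) NULL) else numeric(0)
      if (is.null(xB)) next
      x <- numeric(n); x[B] <- xB; x[Nset] <- xN
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(as.numeric(A %*% x) - b)) > tol) next
      verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- unique(round(do.call(rbind, verts), 9))
  V
}

# Equality-form constraint data for a model, built independently of
# fba_constraints(): couplings become explicit inequality slacks.
oracle_constraints <- function(model) {
  S <- as.matrix(model$S)
  n <- ncol(S)
  lb <- model$rxns$lower_bound
  ub <- model$rxns$upper_bound
  cp <- model$couplings
  if (nrow(cp)) {
    A <- S
    for (q in seq_len(nrow(cp))) {
      r1 <- numeric(ncol(A)); r2 <- numeric(ncol(A))
      i <- match(cp$reaction[q], model$rxns$id)
      j <- match(cp$anchor[q], model$rxns$id)
      r1[i] <- 1; r1[j] <- -cp$factor[q]     # v_r - c v_b + s = 0, s >= 0
      r2[i] <- 1; r2[j] <- cp$factor[q]      # v_r + c v_b - t = 0, t >= 0
      A <- rbind(cbind(A, 0, 0), c(r1, 1, 0), c(r2, 0, -1))
      span <- 2 * cp$factor[q] * max(abs(c(lb[j], ub[j]))) + max(abs(c(lb[i], ub[i])))
      lb <- c(lb, 0, 0); ub <- c(ub, span, span)
    }
  } else {
    A <- S
  }
  list(A = A, b = rep(0, nrow(A)), lb = lb, ub = ub, n = n)
}

# Brute-force FBA optimum for a small model by vertex enumeration.
oracle_fba <- function(model, objective_id, sense = "max") {
  cons <- oracle_constraints(model)
  V <- oracle_vertices(cons$A, cons$b, cons$lb, cons$ub)
  if (!nrow(V)) return(NA_real_)
  vals <- V[, match(objective_id, model$rxns$id)]
  if (sense == "max") max(vals) else min(vals)
}

# Brute-force FVA interval.
oracle_fva <- function(model, reaction_id) {
  cons <- oracle_constraints(model)
  V <- oracle_vertices(cons$A, cons$b, cons$lb, cons$ub)
  vals <- V[, match(reaction_id, model$rxns$id)]
  c(min(vals), max(vals))
}
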