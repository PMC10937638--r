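# Flux balance analysis, flux variability analysis, diet application and
# reaction deletions. The feasible region throughout is
#   { v : S v = 0,  lb <= v <= ub,  |v_r| <= factor * v_anchor  for couplings }
# i.e. steady-state mass balance plus bounds plus coupling constraints. No
# fraction-of-optimum constraint is ever added: FVA maxima are "maximum net
# secretion capacities" over this region.

# Build the equality-form LP data for a model: couplings are rewritten with
# nonnegative slacks, v_r - c*v_b + s1 = 0 (s1 >= 0), v_r + c*v_b - s2 = 0
# (s2 >= 0), so the whole system is A x = 0 with bounds on x.
fba_constraints <- function(model) {
  n <- nrow(model$rxns)
  S <- as.matrix(model$S)
  cp <- model$couplings
  k <- nrow(cp)
  if (k > 0) {
    # rows are scaled by 1/factor ((1/c)v_r -+ v_b +- s = 0) so that all
    # coefficients stay near unit magnitude; the slacks then live on the
    # scale of the anchor flux and get tight finite bounds, which keeps the
    # simplex bases well conditioned
    Crows <- matrix(0, 2 * k, n + 2 * k)
    ri <- match(cp$reaction, model$rxns$id)
    bi <- match(cp$anchor, model$rxns$id)
    span <- numeric(2 * k)
    for (q in seq_len(k)) {
      Crows[2 * q - 1, ri[q]] <- 1 / cp$factor[q]
      Crows[2 * q - 1, bi[q]] <- -1
      Crows[2 * q - 1, n + 2 * q - 1] <- 1
      Crows[2 * q, ri[q]] <- 1 / cp$factor[q]
      Crows[2 * q, bi[q]] <- 1
      Crows[2 * q, n + 2 * q] <- -1
      rng <- max(abs(model$rxns$lower_bound[ri[q]]),
                 abs(model$rxns$upper_bound[ri[q]])) / cp$factor[q] +
        max(abs(model$rxns$lower_bound[bi[q]]),
            abs(model$rxns$upper_bound[bi[q]]))
      span[c(2 * q - 1, 2 * q)] <- rng
    }
    A <- rbind(cbind(S, matrix(0, nrow(S), 2 * k)), Crows)
    lb <- c(model$rxns$lower_bound, rep(0, 2 * k))
    ub <- c(model$rxns$upper_bound, span)
  } else {
    A <- S
    lb <- model$rxns$lower_bound
    ub <- model$rxns$upper_bound
  }
  list(A = A, b = rep(0, nrow(A)), lb = lb, ub = ub, n = n)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through one reaction over the model's
#' feasible region: steady-state mass balance `S v = 0`, the reaction bounds,
#' and any coupling constraints.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction id to optimise; defaults to the model's
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_outcome`: list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, and `fluxes` (named vector over all
#'   reactions; `NA` unless optimal).
#' @export
solve_fba <- function(model, objective_id = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective_id)) objective_id <- model$objective
  j <- match(objective_id, model$rxns$id)
  if (is.na(j)) stop("objective reaction not in model: ", objective_id)
  cons <- fba_constraints(model)
  obj <- numeric(ncol(cons$A)); obj[j] <- 1
  res <- lp_solve(obj, cons$A, cons$b, cons$lb, cons$ub, sense = sense)
  fl <- if (res$status == "optimal") {
    stats::setNames(res$x[seq_len(cons$n)], model$rxns$id)
  } else {
    stats::setNames(rep(NA_real_, cons$n), model$rxns$id)
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 objective_id = objective_id,
                 fluxes = fl),
            class = "flux_outcome")
}

#' @export
print.flux_outcome <- function(x, ...) {
  cat("<flux_outcome> status:", x$status,
      " objective(", x$objective_id, ") =", format(x$objective_value), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Computes, for each requested reaction, the attainable flux minimum and
#' maximum over the same feasible region as [solve_fba()] (no
#' fraction-of-optimum constraint is imposed).
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reaction ids to scan; default all reactions.
#' @return data.frame with columns `reaction`, `min_flux`, `max_flux`,
#'   `status`.
#' @export
run_fva <- function(model, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$rxns$id
  jj <- match(reaction_ids, model$rxns$id)
  if (anyNA(jj))
    stop("unknown reaction id(s): ", paste(reaction_ids[is.na(jj)], collapse = ", "))
  cons <- fba_constraints(model)
  # feasibility check before the per-reaction loop
  feas <- lp_solve(numeric(ncol(cons$A)), cons$A, cons$b, cons$lb, cons$ub, "max")
  if (feas$status == "infeasible") stop("model is infeasible; FVA undefined")
  out <- data.frame(reaction = reaction_ids,
                    min_flux = NA_real_, max_flux = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (q in seq_along(jj)) {
    obj <- numeric(ncol(cons$A)); obj[jj[q]] <- 1
    lo <- lp_solve(obj, cons$A, cons$b, cons$lb, cons$ub, "min")
    hi <- lp_solve(obj, cons$A, cons$b, cons$lb, cons$ub, "max")
    out$min_flux[q] <- if (lo$status == "optimal") lo$objective else NA_real_
    out$max_flux[q] <- if (hi$status == "optimal") hi$objective else NA_real_
    out$status[q] <- if (lo$status == "optimal" && hi$status == "optimal")
      "optimal" else "unbounded"
  }
  class(out) <- c("fva_outcome", class(out))
  out
}

#' Apply a diet to a model
#'
#' Sets the lower bound of each dietary exchange reaction to minus the diet's
#' maximal uptake (uptake-negative convention). Secretion (upper) bounds are
#' untouched. With `unlisted_policy = "closed"` all dietary exchanges not in
#' the diet get lower bound 0.
#'
#' @param model a `metabolic_model`.
#' @param diet a `diet_spec` (see [diet_spec()]) or named numeric vector of
#'   maximal uptakes in mmol/person/day, named by metabolite base id.
#' @param unlisted_policy `"closed"` (default) or `"keep"`.
#' @return modified copy of the model, with attribute `"diet_skipped"` naming
#'   diet entries that matched no dietary exchange (also warned about).
#' @export
apply_diet <- function(model, diet, unlisted_policy = c("closed", "keep")) {
  unlisted_policy <- match.arg(unlisted_policy)
  entries <- diet_entries(diet)
  dex <- diet_exchanges(model)
  dex_base <- met_base(vapply(dex, function(r) exchange_metabolite(model, r),
                              character(1)))
  if (unlisted_policy == "closed" && length(dex))
    model <- set_bounds(model, dex, lb = 0)
  hit <- match(names(entries), dex_base)
  skipped <- names(entries)[is.na(hit)]
  if (length(skipped))
    warning(length(skipped), " diet entr", if (length(skipped) == 1) "y" else "ies",
            " without a matching dietary exchange skipped: ",
            paste(skipped, collapse = ", "))
  keep <- !is.na(hit)
  if (any(keep))
    model <- set_bounds(model, dex[hit[keep]], lb = -unname(entries[keep]))
  attr(model, "diet_skipped") <- skipped
  model
}

#' Block reactions by zeroing their bounds
#'
#' The knockout convention of the deletion screens: listed reactions stay in
#' the model (indexing is preserved) but both bounds are set to 0.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to delete; unknown ids are an error.
#' @return modified copy of the model; the input is unchanged.
#' @export
delete_reactions <- function(model, ids) {
  if (!length(ids)) return(model)
  set_bounds(model, ids, lb = 0, ub = 0)
}
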