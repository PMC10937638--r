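# Small fixture networks (<= 8 reactions) used across the LP/FBA tests and
# the oracle-equivalence acceptance check. Built in code; no files.

fix_model <- function(id, rxns, st, mets = NULL, couplings = NULL,
                      objective = NULL) {
  if (is.null(mets)) {
    ids <- unique(unlist(lapply(st, names)))
    mets <- data.frame(id = ids, name = ids, compartment = met_compartment(ids),
                       stringsAsFactors = FALSE)
  }
  metabolic_model(id, mets, rxns, st, couplings = couplings, objective = objective)
}

# linear chain with uptake bound u
fixture_chain <- function(u = 5) {
  rx <- data.frame(id = c("EX_A[e]", "At", "AB", "Bt", "EX_B[e]"),
                   lower_bound = c(-u, 0, 0, 0, 0),
                   upper_bound = c(1000, 1000, 1000, 1000, 1000))
  st <- list("EX_A[e]" = c("A[e]" = -1),
             "At" = c("A[e]" = -1, "A[c]" = 1),
             "AB" = c("A[c]" = -1, "B[c]" = 1),
             "Bt" = c("B[c]" = -1, "B[e]" = 1),
             "EX_B[e]" = c("B[e]" = -1))
  fix_model("chain", rx, st, objective = "EX_B[e]")
}

# branched network with a 2:1 cofactor split: A -> B needs 2 cofactor C,
# C regenerated from A; exercises non-trivial vertex structure
fixture_branched <- function(u = 6) {
  rx <- data.frame(
    id = c("EX_A[e]", "At", "R1", "R2", "Bt", "EX_B[e]"),
    lower_bound = c(-u, 0, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000))
  st <- list(
    "EX_A[e]" = c("A[e]" = -1),
    "At" = c("A[e]" = -1, "A[c]" = 1),
    "R1" = c("A[c]" = -1, "C[c]" = 2),            # A -> 2 cofactor
    "R2" = c("A[c]" = -1, "C[c]" = -2, "B[c]" = 1), # A + 2C -> B
    "Bt" = c("B[c]" = -1, "B[e]" = 1),
    "EX_B[e]" = c("B[e]" = -1))
  fix_model("branched", rx, st, objective = "EX_B[e]")
}

# two substrates, two routes with different yields, shared sink
fixture_tworoute <- function() {
  rx <- data.frame(
    id = c("EX_A[e]", "EX_B[e]", "RA", "RB", "Pt", "EX_P[e]"),
    lower_bound = c(-4, -3, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 5, 1000))
  st <- list(
    "EX_A[e]" = c("A[e]" = -1), "EX_B[e]" = c("B[e]" = -1),
    "RA" = c("A[e]" = -1, "P[c]" = 2),
    "RB" = c("B[e]" = -1, "P[c]" = 1),
    "Pt" = c("P[c]" = -1, "P[e]" = 1),
    "EX_P[e]" = c("P[e]" = -1))
  fix_model("tworoute", rx, st, objective = "EX_P[e]")
}

# fixed-bound and blocked reactions
fixture_fixed_blocked <- function() {
  rx <- data.frame(
    id = c("EX_A[e]", "FIX", "BLK", "EX_B[e]"),
    lower_bound = c(-10, 2, 0, 0),
    upper_bound = c(1000, 2, 1000, 1000))
  st <- list(
    "EX_A[e]" = c("A[e]" = -1),
    "FIX" = c("A[e]" = -1, "B[e]" = 1),
    "BLK" = c("A[e]" = -1, "D[c]" = 1),   # D has no outlet: blocked
    "EX_B[e]" = c("B[e]" = -1))
  fix_model("fixedblocked", rx, st, objective = "EX_B[e]")
}

# coupled toy: production coupled to biomass
fixture_coupled <- function(factor = 400) {
  rx <- data.frame(
    id = c("EX_A[e]", "At", "AB", "biomass", "Bt", "EX_B[e]"),
    lower_bound = c(-5, 0, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000))
  st <- list(
    "EX_A[e]" = c("A[e]" = -1),
    "At" = c("A[e]" = -1, "A[c]" = 1),
    "AB" = c("A[c]" = -1, "B[c]" = 1),
    "biomass" = c("A[c]" = -1),
    "Bt" = c("B[c]" = -1, "B[e]" = 1),
    "EX_B[e]" = c("B[e]" = -1))
  fix_model("coupled", rx, st,
            couplings = data.frame(reaction = c("AB", "Bt"),
                                   anchor = "biomass", factor = factor),
            objective = "EX_B[e]")
}

# reversible loop plus exchange; checks that internal cycles do not leak mass
fixture_loop <- function() {
  rx <- data.frame(
    id = c("EX_A[e]", "R1", "R2", "R3", "EX_B[e]"),
    lower_bound = c(-3, -10, -10, -10, 0),
    upper_bound = c(1000, 10, 10, 10, 1000))
  st <- list(
    "EX_A[e]" = c("A[e]" = -1),
    "R1" = c("A[e]" = -1, "X[c]" = 1),
    "R2" = c("X[c]" = -1, "Y[c]" = 1),
    "R3" = c("Y[c]" = -1, "B[e]" = 1),
    "EX_B[e]" = c("B[e]" = -1))
  fix_model("loop", rx, st, objective = "EX_B[e]")
}

# seeded random sparse mass-balanced networks: random stoichiometry over a
# small metabolite set with one uptake and one secretion exchange
fixture_random <- function(seed) {
  set.seed(seed)
  nm <- 4; nr <- 6
  mets <- c("A[e]", paste0("m", seq_len(nm - 2), "[c]"), "Z[e]")
  repeat {
    st <- list("EX_A[e]" = c("A[e]" = -1), "EX_Z[e]" = c("Z[e]" = -1))
    for (k in seq_len(nr - 2)) {
      from <- sample(mets[-length(mets)], 1)
      to <- sample(setdiff(mets[-1], from), 1)
      cf <- sample(c(1, 1, 2), 2, replace = TRUE)
      st[[paste0("r", k)]] <- stats::setNames(c(-cf[1], cf[2]), c(from, to))
    }
    rx <- data.frame(id = names(st),
                     lower_bound = c(-sample(2:8, 1), 0,
                                     ifelse(stats::runif(nr - 2) < 0.3, -10, 0)),
                     upper_bound = c(1000, 1000, rep(10, nr - 2)))
    m <- try(fix_model(paste0("rand", seed), rx, st, objective = "EX_Z[e]"),
             silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
  }
}

# the full fixture battery for oracle-equivalence checks
fixture_battery <- function() {
  c(list(fixture_chain(), fixture_branched(), fixture_tworoute(),
         fixture_fixed_blocked(), fixture_coupled(), fixture_coupled(2),
         fixture_loop()),
    lapply(c(101, 202, 303, 404, 505), fixture_random))
}
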