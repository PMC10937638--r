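# FBA, FVA, diet application and reaction deletion semantics.

test_that("a linear chain is limited by its uptake bound", {
  m <- fixture_chain(u = 5)
  f <- solve_fba(m, "EX_B[e]", "max")
  expect_identical(f$status, "optimal")
  expect_equal(f$objective_value, 5)
  # nothing in, nothing out
  m0 <- set_bounds(m, "EX_A[e]", lb = 0)
  expect_equal(solve_fba(m0, "EX_B[e]")$objective_value, 0)
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  for (m in fixture_battery()) {
    f <- solve_fba(m, m$objective, "max")
    expect_identical(f$status, "optimal")
    expect_lt(max(abs(as.numeric(m$S %*% f$fluxes))), 1e-6)
    expect_true(all(f$fluxes >= m$rxns$lower_bound - 1e-6))
    expect_true(all(f$fluxes <= m$rxns$upper_bound + 1e-6))
  }
})

test_that("the branched cofactor-split optimum matches the brute-force oracle", {
  m <- fixture_branched(u = 6)
  expect_equal(solve_fba(m, "EX_B[e]")$objective_value,
               oracle_fba(m, "EX_B[e]"), tolerance = 1e-8)
})

test_that("FVA brackets match vertex enumeration and FBA agrees with FVA max", {
  for (m in list(fixture_branched(), fixture_coupled(), fixture_tworoute())) {
    v <- run_fva(m, m$rxns$id)
    for (rid in m$rxns$id) {
      ov <- oracle_fva(m, rid)
      row <- v[v$reaction == rid, ]
      expect_equal(c(row$min_flux, row$max_flux), ov, tolerance = 1e-6)
    }
    f <- solve_fba(m, m$objective, "max")
    expect_equal(f$objective_value,
                 v$max_flux[v$reaction == m$objective], tolerance = 1e-6)
  }
})

test_that("fixed-bound and blocked reactions give degenerate FVA intervals", {
  m <- fixture_fixed_blocked()
  v <- run_fva(m, c("FIX", "BLK"))
  expect_equal(unlist(v[v$reaction == "FIX", c("min_flux", "max_flux")]),
               c(min_flux = 2, max_flux = 2), tolerance = 1e-8)
  expect_equal(unlist(v[v$reaction == "BLK", c("min_flux", "max_flux")]),
               c(min_flux = 0, max_flux = 0), tolerance = 1e-8)
})

test_that("relaxing a bound never decreases a maximisation optimum", {
  set.seed(5)
  for (m in list(fixture_branched(), fixture_tworoute(), fixture_random(606))) {
    base <- solve_fba(m, m$objective)$objective_value
    for (rid in sample(m$rxns$id, 3)) {
      j <- match(rid, m$rxns$id)
      m2 <- set_bounds(m, rid, lb = m$rxns$lower_bound[j] - 2,
                       ub = m$rxns$upper_bound[j] + 2)
      expect_gte(solve_fba(m2, m$objective)$objective_value, base - 1e-8)
    }
  }
})

test_that("zero anchor flux collapses coupled reactions to [0,0]", {
  m <- fixture_coupled(factor = 400)
  m0 <- set_bounds(m, "biomass", lb = 0, ub = 0)
  v <- run_fva(m0, c("AB", "Bt"))
  expect_equal(v$min_flux, c(0, 0), tolerance = 1e-8)
  expect_equal(v$max_flux, c(0, 0), tolerance = 1e-8)
  # with the anchor free the coupled optimum is 400/401 of the uncoupled one
  expect_equal(solve_fba(m, "EX_B[e]")$objective_value, 5 * 400 / 401,
               tolerance = 1e-8)
})

test_that("apply_diet uses the uptake-negative convention and closes unlisted uptakes", {
  m <- make_toy_host("male")
  d <- diet_spec(c(glc_D = 10))
  m2 <- apply_diet(m, d, "closed")
  j <- match("EX_glc_D[d]", m2$rxns$id)
  expect_equal(m2$rxns$lower_bound[j], -10)
  expect_equal(m2$rxns$upper_bound[j], 1000)   # secretion bound untouched
  others <- setdiff(diet_exchanges(m2), "EX_glc_D[d]")
  expect_true(all(m2$rxns$lower_bound[match(others, m2$rxns$id)] == 0))
  # keep policy leaves unlisted uptakes alone
  m3 <- apply_diet(m, d, "keep")
  j2 <- match("EX_ser_L[d]", m3$rxns$id)
  expect_equal(m3$rxns$lower_bound[j2], -1000)
})

test_that("the reference diet opens both bile-acid exchanges", {
  m <- apply_diet(make_toy_host("male"), toy_diet(), "closed")
  expect_equal(m$rxns$lower_bound[match("EX_cholate[d]", m$rxns$id)], -1)
  expect_equal(m$rxns$lower_bound[match("EX_C02528[d]", m$rxns$id)], -1)
})

test_that("diet entries without a matching exchange are skipped with a warning", {
  m <- fixture_chain()
  expect_warning(m2 <- apply_diet(m, diet_spec(c(A = 3, ghost = 1)), "closed"),
                 "ghost")
  expect_identical(attr(m2, "diet_skipped"), "ghost")
  expect_equal(m2$rxns$lower_bound[match("EX_A[e]", m2$rxns$id)], -3)
})

test_that("an empty closed diet shuts down all exchange-driven production", {
  h <- make_toy_host("male")
  expect_equal(max_urine_secretion(h, "for", diet_spec(c(glc_D = 0))), 0,
               tolerance = 1e-8)
})

test_that("delete_reactions zeroes bounds, keeps indexing, leaves input unchanged", {
  m <- fixture_chain()
  m2 <- delete_reactions(m, "AB")
  expect_identical(m2$rxns$id, m$rxns$id)
  expect_equal(m2$rxns$lower_bound[match("AB", m2$rxns$id)], 0)
  expect_equal(m2$rxns$upper_bound[match("AB", m2$rxns$id)], 0)
  expect_equal(solve_fba(m2, "EX_B[e]")$objective_value, 0)
  expect_equal(m$rxns$upper_bound[match("AB", m$rxns$id)], 1000)  # untouched
  expect_identical(delete_reactions(m, character(0)), m)
  expect_equal(solve_fba(delete_reactions(m, character(0)), "EX_B[e]")$objective_value,
               solve_fba(m, "EX_B[e]")$objective_value)
  expect_error(delete_reactions(m, "nope"), "unknown reaction")
  # deletion never increases the optimum
  for (rid in m$rxns$id)
    expect_lte(solve_fba(delete_reactions(m, rid), "EX_B[e]")$objective_value,
               solve_fba(m, "EX_B[e]")$objective_value + 1e-8)
})
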