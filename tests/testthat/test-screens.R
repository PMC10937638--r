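# Co-metabolism decomposition, supplementation screen, knockout screens and
# minimal-deletion-set search, gene-association join.

test_that("decomposition identity holds and serine feeding flags co-metabolism", {
  h <- make_toy_host("male")
  # build the serine community from the wholebody test helpers
  comm <- serine_community()
  d <- toy_diet()
  rec <- decompose_contributions(h, comm, d, "for")
  expect_equal(rec$delta,
               rec$urine_max_personalised - rec$urine_max_germfree,
               tolerance = 1e-9)
  expect_gte(rec$delta, -1e-6)
  # the community secretes serine, not formate: the whole gain is
  # co-metabolism (microbial formate transfer is zero)
  expect_equal(rec$microbial_secretion, 0, tolerance = 1e-6)
  expect_gt(rec$co_metabolism_excess, 1)
  expect_gt(rec$delta, 0)
})

test_that("high-secretion extraction averages bridge fluxes above threshold", {
  mk <- function(v) structure(list(status = "optimal", objective_value = 1,
                                   objective_id = "x", fluxes = v),
                              class = "flux_outcome")
  f1 <- mk(c("Micro_EX_ser_L[luLI]" = 50, "Micro_EX_ac[luLI]" = 35,
             "Micro_EX_for[luLI]" = 80, "Micro_EX_gly[luLI]" = 10, "UT_for" = 3))
  f2 <- mk(c("Micro_EX_ser_L[luLI]" = 30, "Micro_EX_ac[luLI]" = 45,
             "Micro_EX_for[luLI]" = 70, "Micro_EX_gly[luLI]" = 10))
  hs <- high_secretion_metabolites(list(f1, f2), threshold = 30,
                                   exclude = "for")
  expect_setequal(hs$metabolite, c("ac", "ser_L"))   # means 40, 40; gly 10
  expect_equal(hs$mean_secretion[hs$metabolite == "ser_L"], 40)
  # all-zero solutions yield nothing
  z <- mk(c("Micro_EX_ser_L[luLI]" = 0))
  expect_equal(nrow(high_secretion_metabolites(list(z, z))), 0)
  expect_error(high_secretion_metabolites(list()), "no flux solutions")
})

test_that("supplementation screen matches the route oracle and is never negative", {
  h <- make_toy_host("male")
  d <- toy_diet()
  routes <- c("glc_D", "ser_L", "gly", "cys_L", "trp_L", "tyr_L", "orn",
              "meoh", "nh4")
  no_routes <- c("ac", "lac_D", "etoh", "succ", "but")
  scr <- diet_supplementation_screen(h, d, c(routes, no_routes), "for", 300)
  expect_true(all(scr$percent_change >= -1e-9))       # pure relaxation
  expect_true(all(scr$percent_change[scr$perturbation %in% routes] > 0))
  expect_equal(scr$percent_change[scr$perturbation %in% no_routes],
               rep(0, length(no_routes)), tolerance = 1e-9)
  # perturbed values equal the closed-form route arithmetic
  dv <- unclass(d)
  for (i in seq_len(nrow(scr))) {
    d2 <- dv; d2[scr$perturbation[i]] <- 300
    expect_equal(scr$perturbed[i], formate_oracle(d2, character(0), "male"),
                 tolerance = 1e-6)
  }
  # a candidate already unconstrained changes nothing
  d3 <- diet_with(d, glc_D = 300)
  scr3 <- diet_supplementation_screen(h, d3, "glc_D", "for", 300)
  expect_equal(scr3$percent_change, 0, tolerance = 1e-9)
  # candidates without a dietary exchange are flagged not applicable
  scr4 <- diet_supplementation_screen(h, d, "caffeine", "for", 300)
  expect_identical(scr4$note, "not_applicable")
})

test_that("ammonium raises formate without contributing carbon", {
  h <- make_toy_host("male")
  base <- max_urine_secretion(h, "for", toy_diet())
  up <- max_urine_secretion(h, "for", diet_with(toy_diet(), nh4 = 300))
  expect_gt(up, base)
  # the gain flows through the salvage endpoint: deleting it removes it
  h2 <- delete_reactions(h, "DKMPPD")
  expect_equal(max_urine_secretion(h2, "for", diet_with(toy_diet(), nh4 = 300)),
               max_urine_secretion(h2, "for", toy_diet()), tolerance = 1e-6)
})

test_that("single-knockout reductions equal independent route-oracle re-solves", {
  h <- make_toy_host("male")
  d <- toy_diet(); dv <- unclass(d)
  cand <- toy_candidate_reactions()
  scr <- single_knockout_screen(h, d, cand, "for", 10)
  base <- formate_oracle(dv, character(0), "male")
  for (i in seq_len(nrow(scr))) {
    expected <- 100 * (formate_oracle(dv, scr$perturbation[i], "male") - base) / base
    expect_equal(scr$percent_change[i], expected, tolerance = 1e-6)
  }
  expect_setequal(scr$perturbation[scr$flagged],
                  c("PSP_L", "SHMT", "GCS", "SFGTH", "TRPO2", "DKMPPD"))
  # a reaction on no formate path does nothing; redundant copies do nothing
  expect_equal(scr$percent_change[scr$perturbation == "MTHFD"], 0,
               tolerance = 1e-9)
  expect_error(single_knockout_screen(h, d, "ghost", "for"), "not in host")
  expect_error(single_knockout_screen(h, diet_spec(c(glc_D = 0)), cand, "for"),
               "baseline")
})

test_that("deleting a superset reduces at least as much as any subset", {
  h <- make_toy_host("male")
  d <- toy_diet()
  sets <- list("PSP_L", c("PSP_L", "SFGTH"), c("PSP_L", "SFGTH", "TRPO2"),
               c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"))
  vals <- vapply(sets, function(s)
    max_urine_secretion(delete_reactions(h, s), "for", d), 0)
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("minimal deletion set search is exhaustive, lexicographic and matches the oracle", {
  h <- make_toy_host("male")
  d <- toy_diet()
  scr <- single_knockout_screen(h, d, toy_candidate_reactions(), "for", 10)
  flagged <- scr$perturbation[scr$flagged]
  ms <- find_minimal_deletion_set(h, d, flagged, "for", 85)
  expect_true(ms$found)
  expect_identical(ms$method, "exhaustive")
  expect_identical(ms$set, c("DKMPPD", "PSP_L", "SFGTH", "TRPO2"))
  oc <- formate_minset_oracle(unclass(d), flagged, 85)
  expect_identical(ms$set, oc$set)
  expect_equal(ms$reduction_pct, oc$reduction_pct, tolerance = 1e-6)
  # target 0 is satisfied by the empty set
  ms0 <- find_minimal_deletion_set(h, d, flagged, "for", 0)
  expect_identical(ms0$set, character(0))
  # a single 100%-reduction reaction is returned as a singleton
  h1 <- make_toy_host("male")
  ms1 <- find_minimal_deletion_set(h1, d, c("UT_for", "PSP_L"), "for", 99)
  expect_identical(ms1$set, "UT_for")
  # unreachable target reports not-found, without an exception
  msx <- find_minimal_deletion_set(h, d, "TYRCAT", "for", 85, max_size = 1)
  expect_false(msx$found)
})

test_that("gene-association join counts match a hand join", {
  gm <- data.frame(reaction = c("PSP_L", "PSP_L", "SFGTH", "TRPO2"),
                   gene = c("PSPH", "PSPHL", "ESD", "TDO2"))
  assoc <- data.frame(gene = c("PSPH", "ESD", "APP"),
                      direction = c("positive", "positive", "negative"))
  ann <- annotate_reactions_with_genes(c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"),
                                       gm, assoc, flagged = c("PSP_L", "DKMPPD"))
  expect_equal(unname(ann$counts["n_reactions"]), 4)
  expect_equal(unname(ann$counts["n_associated"]), 2)   # PSP_L, SFGTH
  expect_equal(unname(ann$counts["n_associated_flagged"]), 1)  # PSP_L only
  expect_identical(ann$table$genes[ann$table$reaction == "DKMPPD"], "no gene")
  # empty association table: zero associated
  ann0 <- annotate_reactions_with_genes("PSP_L", gm,
                                        data.frame(gene = character(0)))
  expect_equal(unname(ann0$counts["n_associated"]), 0)
})
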