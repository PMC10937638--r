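# Community assembly: tagging, lumen plumbing, abundance-weighted community
# biomass, coupling constraints, and secretion profiling.


test_that("community biomass coefficients equal the relative abundances", {
  td <- make_toy_strains(synth_config(seed = 2, n_species = 2))
  pans <- build_toy_pans(td)
  comm <- build_community(pans, c(synthsp01 = 0.6, synthsp02 = 0.4))
  st <- stoich_list(comm)[["communityBiomass"]]
  expect_equal(unname(st["synthsp01_biomass[e]"]), -0.6)
  expect_equal(unname(st["synthsp02_biomass[e]"]), -0.4)
  expect_equal(unname(st["microbeBiomass[luM]"]), 1)
  # default coupling factor 400 on every member coupling
  expect_true(all(comm$couplings$factor == 400))
  expect_true(all(comm$members$biomass_rxn %in% comm$couplings$anchor))
  # default community biomass bounds
  j <- match("communityBiomass", comm$rxns$id)
  expect_equal(c(comm$rxns$lower_bound[j], comm$rxns$upper_bound[j]), c(0.4, 1))
})

test_that("abundances must be positive, known, unique and sum to one", {
  td <- make_toy_strains(synth_config(seed = 2, n_species = 2))
  pans <- build_toy_pans(td)
  expect_error(build_community(pans, c(synthsp01 = 0.5, synthsp02 = 0.4)),
               "sum to 1")
  expect_error(build_community(pans, c(synthsp01 = 1, ghost = 0.0001)),
               "no pan model")
  expect_error(build_community(pans, c(synthsp01 = -0.2, synthsp02 = 1.2)),
               "positive")
  ab <- c(0.5, 0.5); names(ab) <- c("synthsp01", "synthsp01")
  expect_error(build_community(pans, ab), "duplicate")
})

test_that("a one-species community matches the standalone pan secretion", {
  pan <- build_pan_model(list(formate_strain()), "fsp")
  # biomass feeds on its own amino-acid substrate, so with a free community
  # biomass range the community capacity equals the pan model's
  comm <- build_community(list(fsp = pan), c(fsp = 1), biomass_bounds = c(0, 1))
  d <- comm_diet()
  pan_max <- run_fva(suppressWarnings(apply_diet(pan, d, "closed")),
                     "EX_for[e]")$max_flux
  prof <- secretion_profile(comm, d)
  expect_equal(prof$max_flux[prof$metabolite == "for"], pan_max,
               tolerance = 1e-6)
  expect_equal(pan_max, 20)                  # 10 glucose at yield 2
})

test_that("secretion capacities separate production from diet pass-through", {
  pan <- build_pan_model(list(formate_strain()), "fsp")
  comm <- build_community(list(fsp = pan), c(fsp = 1), biomass_bounds = c(0, 1))
  prof <- secretion_profile(comm, comm_diet())
  # unconsumed diet components can pass straight through to the faeces
  expect_equal(prof$max_flux[prof$metabolite == "glc_D"], 10, tolerance = 1e-6)
  expect_equal(prof$max_flux[prof$metabolite == "aa"], 5, tolerance = 1e-6)
  # without its growth substrate the member cannot grow, the couplings block
  # all its reactions, and a non-dietary metabolite cannot be secreted
  prof2 <- secretion_profile(comm, diet_spec(c(glc_D = 10)))
  expect_equal(prof2$max_flux[prof2$metabolite == "for"], 0, tolerance = 1e-6)
  expect_equal(prof2$max_flux[prof2$metabolite == "aa"], 0, tolerance = 1e-6)
})

test_that("forcing a member biomass to zero silences all its reactions", {
  td <- make_toy_strains(synth_config(seed = 4, n_species = 2))
  pans <- build_toy_pans(td)
  comm <- build_community(pans, c(synthsp01 = 0.5, synthsp02 = 0.5),
                          biomass_bounds = c(0, 1))
  comm2 <- suppressWarnings(apply_diet(comm, toy_diet(), "closed"))
  member <- comm$members[1, ]
  comm2 <- set_bounds(comm2, member$biomass_rxn, lb = 0, ub = 0)
  member_rxns <- grep(paste0("^", member$tag, "_"), comm2$rxns$id, value = TRUE)
  v <- run_fva(comm2, member_rxns)
  expect_true(all(abs(v$min_flux) < 1e-6))
  expect_true(all(abs(v$max_flux) < 1e-6))
})

test_that("enlarging a diet entry never reduces a secretion capacity", {
  pan <- build_pan_model(list(formate_strain()), "fsp")
  comm <- build_community(list(fsp = pan), c(fsp = 1), biomass_bounds = c(0, 1))
  d1 <- comm_diet()
  d2 <- diet_with(d1, glc_D = 20)
  p1 <- secretion_profile(comm, d1)
  p2 <- secretion_profile(comm, d2)
  expect_true(all(p2$max_flux >= p1$max_flux - 1e-6))
})

test_that("tagged ids and community plumbing never collide", {
  td <- make_toy_strains(synth_config(seed = 8, n_species = 4))
  pans <- build_toy_pans(td)
  ab <- rep(0.25, 4); names(ab) <- names(pans)
  comm <- build_community(pans, ab)
  expect_false(anyDuplicated(comm$rxns$id) > 0)
  expect_false(anyDuplicated(comm$mets$id) > 0)
  expect_true(all(c("d", "fe", "luM") %in% comm$compartments))
  # every member reaction except its biomass anchor carries a coupling
  for (i in seq_len(nrow(comm$members))) {
    tg <- comm$members$tag[i]
    own <- setdiff(grep(paste0("^", tg, "_"), comm$rxns$id, value = TRUE),
                   comm$members$biomass_rxn[i])
    expect_true(all(own %in%
      comm$couplings$reaction[comm$couplings$anchor ==
                                comm$members$biomass_rxn[i]]))
  }
})
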