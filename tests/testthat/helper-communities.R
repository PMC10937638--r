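# Hand-built single-species communities used across the community,
# whole-body and screen tests.

# a minimal hand-built formate-secreting strain whose biomass runs on its own
# dedicated substrate, so growth does not compete with secretion
formate_strain <- function(id = "fstr", species = "fsp", yield = 2) {
  ids <- c("glc_D[e]", "glc_D[c]", "aa[e]", "aa[c]", "for[c]", "for[e]",
           "biomass[e]")
  mets <- data.frame(id = ids, name = met_base(ids),
                     compartment = met_compartment(ids))
  st <- list(
    "EX_glc_D[e]" = c("glc_D[e]" = -1),
    "EX_aa[e]" = c("aa[e]" = -1),
    "GLCt" = c("glc_D[e]" = -1, "glc_D[c]" = 1),
    "AAt" = c("aa[e]" = -1, "aa[c]" = 1),
    "FERM_for" = c("glc_D[c]" = -1, "for[c]" = yield),
    "fort" = c("for[c]" = -1, "for[e]" = 1),
    "EX_for[e]" = c("for[e]" = -1),
    "EX_biomass[e]" = c("biomass[e]" = -1))
  st[[paste0("biomass_", species)]] <- c("aa[c]" = -0.5, "biomass[e]" = 1)
  rx <- data.frame(id = names(st),
                   lower_bound = ifelse(startsWith(names(st), "EX_") &
                                          names(st) != "EX_biomass[e]", -1000, 0),
                   upper_bound = 1000)
  metabolic_model(id, mets, rx, st, objective = paste0("biomass_", species))
}

comm_diet <- function() diet_spec(c(glc_D = 10, aa = 5))

serine_community <- function(seed = 2) {
  # a community that secretes serine (and no formate): the co-metabolism donor
  ids <- c("glc_D[e]", "glc_D[c]", "ser_L[c]", "ser_L[e]", "biomass[e]")
  mets <- data.frame(id = ids, name = met_base(ids),
                     compartment = met_compartment(ids))
  st <- list(
    "EX_glc_D[e]" = c("glc_D[e]" = -1),
    "GLCt" = c("glc_D[e]" = -1, "glc_D[c]" = 1),
    "FERM_ser_L" = c("glc_D[c]" = -1, "ser_L[c]" = 3),
    "ser_Lt" = c("ser_L[c]" = -1, "ser_L[e]" = 1),
    "EX_ser_L[e]" = c("ser_L[e]" = -1),
    "EX_biomass[e]" = c("biomass[e]" = -1),
    "biomass_sersp" = c("glc_D[c]" = -0.5, "biomass[e]" = 1))
  rx <- data.frame(id = names(st),
                   lower_bound = ifelse(startsWith(names(st), "EX_") &
                                          names(st) != "EX_biomass[e]", -1000, 0),
                   upper_bound = 1000)
  s <- metabolic_model("serstrain", mets, rx, st, objective = "biomass_sersp")
  pan <- build_pan_model(list(s), "sersp")
  build_community(list(sersp = pan), c(sersp = 1), biomass_bounds = c(0.4, 1))
}
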