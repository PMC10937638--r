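# Closed-form oracle for the toy host's maximal urine formate secretion.
#
# The toy host's formate routes are independent (they share only the
# recycled THF / glutathione pools, which impose no net constraint), so the
# LP optimum is the sum of the diet-limited route capacities, capped by the
# urine transport bound. Deletions act by removing a route's unique step or
# both members of a redundant pair; a blocked downstream step also blocks
# upstream steps whose products would dead-end. This arithmetic is derived
# from the network by hand and is independent of the LP solver.

formate_oracle <- function(diet, deleted = character(0), sex = "male",
                           rxn_cap = 1000) {
  d <- function(m) if (m %in% names(diet)) unname(diet[m]) else 0
  del <- function(...) all(c(...) %in% deleted)
  one <- function(x) !x %in% deleted

  fol_ok <- !del("MTHFD", "MTHFD2") && !del("MTHFC", "MTHFCm") &&
    !del("FTHFL", "FTHFLm")
  sf_ok <- !del("FALDH", "FALDHm") && one("SFGTH")

  ser_from_glc <- if (one("GLYCO") && !del("PGCD", "PGCDm") &&
                      !del("PSERT", "PSERTm") && one("PSP_L"))
    2 * d("glc_D") else 0
  ser_pool <- ser_from_glc + d("ser_L") + (if (one("CYSCAT")) d("cys_L") else 0)

  # choline chain: blocked entirely if formaldehyde cannot drain or any step
  # of the peroxisomal sarcosine branch is missing (dead-end intermediates)
  chol_flux <- if (one("CHOLD") && one("BHMT") && one("DMGDH") &&
                   one("SARCStp") && one("SARCOXp") && one("GLYtp") &&
                   one("FALDtp") && sf_ok) d("chol") else 0

  meoh_cap <- if (sex == "female") 0.2 else rxn_cap
  fald_pool <- (if (one("ALCD1")) min(d("meoh"), meoh_cap) else 0) +
    (if (one("ORNCAT") && one("MMAOX")) d("orn") else 0) +
    2 * chol_flux
  for_fald <- if (sf_ok) fald_pool else 0

  shmt_run <- fol_ok && one("SHMT")
  ser_flux <- if (shmt_run) min(ser_pool, rxn_cap) else 0
  gly_pool <- ser_flux + d("gly") + chol_flux
  for_gcs <- if (fol_ok && one("GCS")) min(gly_pool, rxn_cap) else 0
  for_folate <- ser_flux + for_gcs

  for_trp <- if (one("TRPO2") && !del("FKYNH", "FKYNHm")) d("trp_L") else 0
  for_tyr <- if (one("TYRCAT")) d("tyr_L") else 0
  for_salv <- if (!del("MSALV", "MSALVm") && one("DKMPPD") &&
                  !del("AMT2", "AMT2m")) d("nh4") else 0

  min(for_folate + for_fald + for_trp + for_tyr + for_salv, rxn_cap)
}

# exhaustive minimal-deletion-set search on the closed-form oracle
formate_minset_oracle <- function(diet, candidates, target_pct = 85,
                                  max_size = 6, sex = "male") {
  base <- formate_oracle(diet, character(0), sex)
  cand <- sort(unique(candidates))
  for (k in seq_len(min(max_size, length(cand)))) {
    for (s in utils::combn(cand, k, simplify = FALSE)) {
      red <- 100 * (base - formate_oracle(diet, s, sex)) / base
      if (red >= target_pct) return(list(found = TRUE, set = s,
                                         reduction_pct = red))
    }
  }
  list(found = FALSE, set = character(0), reduction_pct = NA_real_)
}
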