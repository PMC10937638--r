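# Seeded synthetic generators for every input the pipeline consumes: toy
# fermenting strain models, a toy sex-specific whole-body host embodying the
# main host formate-producing routes, two-group gOTU count tables with
# planted abundance shifts, and log-normal urine metabolome tables with
# covariate effects. Identical config + seed give identical outputs.

#' Synthetic-data configuration
#'
#' Bundles the seed and the study conditions emulated by all generators:
#' cohort sizes, sequencing depth, planted effects, and covariate
#' distributions (age ~ N(70, 6), BMI ~ N(26, 4), sex ~ Bernoulli(0.5)).
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_species number of microbial species in the toy ecosystem.
#' @param n_strains_per_species strains per species (pan-model input).
#' @param n_samples_per_group stool-cohort group size (healthy / AD).
#' @param depth sequencing depth per sample (reads).
#' @param n_planted_up,n_planted_down number of species with planted
#'   increased / decreased abundance in the AD group.
#' @param fold_change planted abundance fold-change.
#' @param metabolome_groups named group sizes for the urine cohort.
#' @param n_metabolites urine metabolites quantified.
#' @param n_detected metabolites with predominantly non-zero measurements
#'   (the rest get high zero-inflation and fall to the 50% detection filter).
#' @param ad_formate_effect,ad_fumarate_effect planted log-scale AD effects.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_species = 6L,
                         n_strains_per_species = 2L,
                         n_samples_per_group = 24L,
                         depth = 50000L,
                         n_planted_up = 5L,
                         n_planted_down = 5L,
                         fold_change = 3,
                         metabolome_groups = c(HC = 49L, SCD = 45L,
                                               MCI = 49L, AD = 34L),
                         n_metabolites = 49L,
                         n_detected = 16L,
                         ad_formate_effect = -0.4,
                         ad_fumarate_effect = -0.5) {
  stopifnot(n_species >= 2, fold_change > 0)
  structure(as.list(environment()), class = "synth_config")
}

# run code under a derived seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# microbial products a toy fermenter may secrete; serine carries a higher
# toy yield than the host's own glucose route, so serine-secreting microbes
# create genuine host-microbiome co-metabolism
.synth_products <- c(for_ = "for", ac = "ac", ser_L = "ser_L", gly = "gly",
                     trp_L = "trp_L", tyr_L = "tyr_L", cys_L = "cys_L",
                     orn = "orn", nh4 = "nh4")
.synth_yields <- c(for_ = 2, ac = 2, ser_L = 3, gly = 2, trp_L = 1,
                   tyr_L = 1, cys_L = 1, orn = 1, nh4 = 2)

make_strain_model <- function(strain_id, species, products, aux_trp = FALSE) {
  yields <- .synth_yields[match(products, .synth_products)]
  mets <- c("glc_D[e]", "glc_D[c]", "biomass[e]",
            paste0(products, "[c]"), paste0(products, "[e]"))
  if (aux_trp) mets <- union(mets, c("trp_L[e]", "trp_L[c]"))
  mdf <- data.frame(id = mets, name = met_base(mets),
                    compartment = met_compartment(mets),
                    stringsAsFactors = FALSE)
  st <- list("EX_glc_D[e]" = c("glc_D[e]" = -1),
             "GLCt" = c("glc_D[e]" = -1, "glc_D[c]" = 1),
             "EX_biomass[e]" = c("biomass[e]" = -1))
  bio <- c("glc_D[c]" = -0.5, "biomass[e]" = 1)
  if (aux_trp) {
    bio <- c(bio, "trp_L[c]" = -0.05)
    st[["TRPt"]] <- c("trp_L[e]" = -1, "trp_L[c]" = 1)
    st[["EX_trp_L[e]"]] <- c("trp_L[e]" = -1)
  }
  st[[paste0("biomass_", species)]] <- bio
  for (k in seq_along(products)) {
    p <- products[k]
    st[[paste0("FERM_", p)]] <- stats::setNames(c(-1, yields[k]),
                                                paste0(c("glc_D", p), "[c]"))
    st[[paste0(p, "t")]] <- stats::setNames(c(-1, 1), paste0(p, c("[c]", "[e]")))
    if (!paste0("EX_", p, "[e]") %in% names(st))
      st[[paste0("EX_", p, "[e]")]] <- stats::setNames(-1, paste0(p, "[e]"))
  }
  rx <- data.frame(id = names(st), stringsAsFactors = FALSE)
  rx$lower_bound <- ifelse(startsWith(rx$id, "EX_") & rx$id != "EX_biomass[e]",
                           -1000, 0)
  rx$upper_bound <- 1000
  metabolic_model(strain_id, mdf, rx, st,
                  objective = paste0("biomass_", species))
}

#' Generate toy fermenting strain models
#'
#' Each species gets a seeded secretion repertoire drawn from formate,
#' acetate, amino acids (L-serine, glycine, L-tryptophan, L-tyrosine,
#' L-cysteine, ornithine) and ammonium; its strains carry overlapping subsets
#' of that repertoire, so the pan model (the union) is strictly richer than
#' single strains. Species 1 is always a formate producer and species 2 a
#' serine producer (the co-metabolism donor). Every strain grows on the
#' synthetic diet.
#'
#' @param cfg a [synth_config()].
#' @return list with `strains` (list of `metabolic_model`), `species_map`
#'   (data.frame strain_id/species), and `truth` (per-species product sets).
#' @export
make_toy_strains <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"), cfg$n_species >= 2)
  with_seed(cfg$seed * 13 + 1, {
    species <- sprintf("synthsp%02d", seq_len(cfg$n_species))
    # species 1 and 2 are the sole formate and serine producers; the other
    # species draw from the remaining products, so the planted depletion of
    # the producer species gives an identifiable community-level signal
    other_products <- setdiff(.synth_products, c("for", "ser_L"))
    repertoire <- lapply(seq_len(cfg$n_species), function(i) {
      base <- sample(other_products, sample(2:4, 1))
      if (i == 1) base <- union("for", base)
      if (i == 2) base <- union("ser_L", base)
      if (i %% 3 == 0) base <- setdiff(base, "trp_L")  # trp auxotroph species
      if (!length(base)) base <- "ac"
      unname(base)
    })
    strains <- list(); map <- list()
    for (i in seq_along(species)) {
      rep_i <- repertoire[[i]]
      for (k in seq_len(cfg$n_strains_per_species)) {
        keep <- if (k == 1) rep_i else
          sample(rep_i, max(1, length(rep_i) - sample(0:1, 1)))
        if (k == cfg$n_strains_per_species)   # union over strains = repertoire
          keep <- union(keep, setdiff(rep_i, unlist(keep)))
        sid <- sprintf("%s_str%d", species[i], k)
        strains[[sid]] <- make_strain_model(sid, species[i], unique(keep),
                                            aux_trp = (i %% 3 == 0))
        map[[sid]] <- data.frame(strain_id = sid, species = species[i],
                                 stringsAsFactors = FALSE)
      }
    }
    list(strains = strains, species_map = do.call(rbind, map),
         truth = stats::setNames(repertoire, species))
  })
}

#' The synthetic reference diet
#'
#' A toy stand-in for an average European diet in mmol/person/day,
#' supplemented with the two primary bile acids (cholic acid `cholate`,
#' chenodeoxycholic acid `C02528`). Magnitudes are chosen so that each host
#' formate route is limited by its own dietary precursor.
#'
#' @return a `diet_spec`.
#' @export
toy_diet <- function() {
  diet_spec(c(
    glc_D = 20, ser_L = 1, gly = 1, cys_L = 1, trp_L = 20, tyr_L = 8,
    orn = 10, meoh = 5, chol = 5, nh4 = 20, o2 = 1000,
    ac = 10, lac_D = 5, etoh = 5, succ = 5, but = 5, his_L = 2,
    cholate = 1, C02528 = 1))
}

# reaction table of the toy host, compartment c unless tagged; redundant
# isozyme/organ copies (suffix m) mirror the multi-copy redundancy of organ-
# resolved whole-body models, leaving PSP_L, SFGTH, TRPO2 and DKMPPD as the
# single-copy endpoints of the four major formate routes
toy_host_pathways <- function() {
  list(
    # serine synthesis from 3-phosphoglycerate
    GLYCO  = c("glc_D[c]" = -1, "3pg[c]" = 2),
    PGCD   = c("3pg[c]" = -1, "3php[c]" = 1),
    PGCDm  = c("3pg[c]" = -1, "3php[c]" = 1),
    PSERT  = c("3php[c]" = -1, "pser_L[c]" = 1),
    PSERTm = c("3php[c]" = -1, "pser_L[c]" = 1),
    PSP_L  = c("pser_L[c]" = -1, "ser_L[c]" = 1),
    # folate one-carbon chain: serine/glycine -> 5,10-CH2-THF -> formate
    SHMT   = c("ser_L[c]" = -1, "thf[c]" = -1, "gly[c]" = 1, "mlthf[c]" = 1),
    GCS    = c("gly[c]" = -1, "thf[c]" = -1, "mlthf[c]" = 1),
    MTHFD  = c("mlthf[c]" = -1, "methf[c]" = 1),
    MTHFD2 = c("mlthf[c]" = -1, "methf[c]" = 1),
    MTHFC  = c("methf[c]" = -1, "10fthf[c]" = 1),
    MTHFCm = c("methf[c]" = -1, "10fthf[c]" = 1),
    FTHFL  = c("10fthf[c]" = -1, "thf[c]" = 1, "for[c]" = 1),
    FTHFLm = c("10fthf[c]" = -1, "thf[c]" = 1, "for[c]" = 1),
    # cysteine feeds the serine pool (lumped catabolism)
    CYSCAT = c("cys_L[c]" = -1, "ser_L[c]" = 1),
    # choline -> betaine -> dimethylglycine -> sarcosine (peroxisomal
    # oxidation) with formaldehyde release at the demethylation steps
    CHOLD  = c("chol[c]" = -1, "glyb[c]" = 1),
    BHMT   = c("glyb[c]" = -1, "dmgly[c]" = 1),
    DMGDH  = c("dmgly[c]" = -1, "sarcs[c]" = 1, "fald[c]" = 1),
    SARCStp = c("sarcs[c]" = -1, "sarcs[x]" = 1),
    SARCOXp = c("sarcs[x]" = -1, "gly[x]" = 1, "fald[x]" = 1),
    GLYtp  = c("gly[x]" = -1, "gly[c]" = 1),
    FALDtp = c("fald[x]" = -1, "fald[c]" = 1),
    # methanol and methylamine sources of formaldehyde
    ALCD1  = c("meoh[c]" = -1, "fald[c]" = 1),
    ORNCAT = c("orn[c]" = -1, "mma[c]" = 1),
    MMAOX  = c("mma[c]" = -1, "fald[c]" = 1),
    # formaldehyde -> S-formylglutathione -> formate (glutathione recycled)
    FALDH  = c("fald[c]" = -1, "gthrd[c]" = -1, "Sfglutth[c]" = 1),
    FALDHm = c("fald[c]" = -1, "gthrd[c]" = -1, "Sfglutth[c]" = 1),
    SFGTH  = c("Sfglutth[c]" = -1, "for[c]" = 1, "gthrd[c]" = 1),
    # tryptophan dioxygenase route via N-formylkynurenine
    TRPO2  = c("trp_L[c]" = -1, "o2[c]" = -1, "Lfmkynr[c]" = 1),
    FKYNH  = c("Lfmkynr[c]" = -1, "lkynr[c]" = 1, "for[c]" = 1),
    FKYNHm = c("Lfmkynr[c]" = -1, "lkynr[c]" = 1, "for[c]" = 1),
    # methionine-salvage formate source; ammonium-dependent re-amination
    # makes this the nitrogen-limited route
    MSALV  = c("met_L[c]" = -1, "dkmpp[c]" = 1),
    MSALVm = c("met_L[c]" = -1, "dkmpp[c]" = 1),
    DKMPPD = c("dkmpp[c]" = -1, "for[c]" = 1, "2kmb[c]" = 1),
    AMT2   = c("2kmb[c]" = -1, "nh4[c]" = -1, "met_L[c]" = 1),
    AMT2m  = c("2kmb[c]" = -1, "nh4[c]" = -1, "met_L[c]" = 1),
    # lumped tyrosine catabolism releasing fumarate
    TYRCAT = c("tyr_L[c]" = -1, "for[c]" = 1, "fum[c]" = 1)
  )
}

#' Generate the toy whole-body host model
#'
#' A compact host with diet (`d`), large-intestinal lumen (`luLI`), systemic
#' (`c`), peroxisomal (`x`) and urine (`u`) compartments carrying the main
#' formate-producing routes: serine synthesis from 3-phosphoglycerate ending
#' in PSP_L, the folate one-carbon chain, choline/methanol/methylamine
#' formaldehyde sources funnelled through SFGTH, tryptophan catabolism via
#' TRPO2, and the nitrogen-limited methionine-salvage route ending in
#' DKMPPD. Upstream steps exist as redundant copies; the four endpoints are
#' single. The female variant differs from the male in one flux bound
#' (methanol oxidation capacity).
#'
#' @param sex `"male"` or `"female"`.
#' @return a `host_model`.
#' @export
make_toy_host <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  diet_mets <- names(diet_entries(toy_diet()))
  urine_mets <- c("for", "fum", "lkynr", "nh4", "gly")
  st <- toy_host_pathways()
  rx <- data.frame(id = names(st), lower_bound = 0, upper_bound = 1000,
                   subsystem = "formate metabolism", genes = NA_character_,
                   stringsAsFactors = FALSE)
  if (sex == "female") rx$upper_bound[rx$id == "ALCD1"] <- 0.2
  # diet -> lumen -> systemic transport chains
  for (b in diet_mets) {
    st[[paste0("EX_", b, "[d]")]] <- stats::setNames(-1, paste0(b, "[d]"))
    st[[paste0("Dt_", b)]] <- stats::setNames(c(-1, 1), paste0(b, c("[d]", "[luLI]")))
    st[[paste0("LIt_", b)]] <- stats::setNames(c(-1, 1), paste0(b, c("[luLI]", "[c]")))
  }
  # microbially supplied metabolites absorbed from the lumen (no diet entry)
  for (b in c("for")) {
    st[[paste0("LIt_", b)]] <- stats::setNames(c(-1, 1), paste0(b, c("[luLI]", "[c]")))
  }
  for (b in urine_mets) {
    st[[paste0("UT_", b)]] <- stats::setNames(c(-1, 1), paste0(b, c("[c]", "[u]")))
    st[[paste0("EX_", b, "[u]")]] <- stats::setNames(-1, paste0(b, "[u]"))
  }
  extra <- setdiff(names(st), rx$id)
  rx <- rbind(rx, data.frame(
    id = extra,
    lower_bound = ifelse(grepl("^EX_.*\\[d\\]$", extra), -1000, 0),
    upper_bound = ifelse(grepl("^(Dt_|LIt_)", extra), TRANSFER_BOUND, 1000),
    subsystem = ifelse(grepl("\\[u\\]$|^UT_", extra), "urine", "absorption"),
    genes = NA_character_, stringsAsFactors = FALSE))
  ids <- unique(unlist(lapply(st, names)))
  mets <- data.frame(id = ids, name = met_base(ids),
                     compartment = met_compartment(ids),
                     stringsAsFactors = FALSE)
  m <- metabolic_model(paste0("toyhost_", sex), mets, rx, st,
                       objective = "EX_for[u]")
  host_model(m, sex)
}

#' The knockout candidate list of the toy host
#'
#' The formate-pathway reactions plus the three peroxisomal transport
#' reactions, mirroring a curated candidate table; central glycolysis and
#' plain absorption/urine transports are not candidates.
#'
#' @return character vector of reaction ids.
#' @export
toy_candidate_reactions <- function() {
  setdiff(names(toy_host_pathways()), "GLYCO")
}

#' Generate a gOTU count table with planted group shifts
#'
#' Log-normal baseline composition over `n_species` species, each split into
#' 1-3 gOTUs (plus a few genus-only gOTUs that the taxonomy collapse must
#' drop); planted fold-changes applied to the AD group before compositional
#' closure; multinomial read sampling at the configured depth. Covariates
#' (age, sex, BMI, APOE genotype) are drawn per sample, with APOE4 enriched
#' among cases.
#'
#' @param cfg a [synth_config()]; `n_species` here is the number of taxa in
#'   the abundance table (use a larger value than for the toy ecosystem).
#' @param n_taxa number of species in the table (default `max(n_species, 40)`).
#' @return list with `counts` (a `count_table`, gOTU level), `meta`
#'   (per-sample covariates incl. `group`), and `truth` (planted directions).
#' @export
make_abundance_counts <- function(cfg, n_taxa = max(cfg$n_species, 40L)) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$fold_change <= 0) stop("fold_change must be positive")
  with_seed(cfg$seed * 13 + 2, {
    n <- 2L * cfg$n_samples_per_group
    species <- sprintf("synthsp%02d", seq_len(n_taxa))
    group <- rep(c("HC", "AD"), each = cfg$n_samples_per_group)
    samples <- sprintf("S%02d", seq_len(n))
    base <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1.2)
    # the first species (the formate/serine producers of the toy ecosystem)
    # are planted as decreased in AD, so AD communities secrete less formate
    down <- species[seq_len(cfg$n_planted_down)]
    up <- species[cfg$n_planted_down + seq_len(cfg$n_planted_up)]
    expected <- matrix(base, n_taxa, n, dimnames = list(species, samples))
    expected[up, group == "AD"] <- expected[up, group == "AD"] * cfg$fold_change
    expected[down, group == "AD"] <- expected[down, group == "AD"] / cfg$fold_change
    # biological sample-to-sample variation, then compositional closure
    noise <- matrix(stats::rlnorm(n_taxa * n, 0, 0.5), n_taxa, n)
    probs <- sweep(expected * noise, 2, colSums(expected * noise), "/")
    # split species into gOTUs; add genus-only gOTUs that carry reads too
    n_gotu <- sample(1:3, n_taxa, replace = TRUE)
    gotu_sp <- rep(species, n_gotu)
    gotu_id <- sprintf("G%06d", seq_along(gotu_sp))
    w <- stats::runif(length(gotu_sp), 0.2, 1)
    counts <- matrix(0L, length(gotu_sp) + 3L, n,
                     dimnames = list(c(gotu_id, paste0("G_genusonly", 1:3)),
                                     samples))
    for (j in seq_len(n)) {
      p_g <- probs[gotu_sp, j] * w
      p_g <- c(p_g * 0.97, rep(0.01, 3))          # 3% genus-level reads
      counts[, j] <- stats::rmultinom(1, cfg$depth, p_g / sum(p_g))
    }
    tax <- stats::setNames(c(gotu_sp, rep(NA_character_, 3)), rownames(counts))
    apoe_p <- list(HC = c(E33 = 0.70, E34 = 0.25, E44 = 0.05),
                   AD = c(E33 = 0.40, E34 = 0.40, E44 = 0.20))
    meta <- data.frame(
      sample_id = samples, group = factor(group, levels = c("HC", "AD")),
      age = round(stats::rnorm(n, 70, 6), 1),
      sex = sample(c("male", "female"), n, replace = TRUE),
      bmi = round(stats::rnorm(n, 26, 4), 1),
      apoe = vapply(group, function(g)
        sample(names(apoe_p[[g]]), 1, prob = apoe_p[[g]]), ""),
      stringsAsFactors = FALSE)
    list(counts = count_table(counts, tax), meta = meta,
         truth = data.frame(species = c(up, down),
                            direction = rep(c("up", "down"),
                                            c(length(up), length(down))),
                            fold_change = rep(cfg$fold_change,
                                              length(up) + length(down)),
                            stringsAsFactors = FALSE))
  })
}

.urine_metabolites <- c(
  "formate", "fumarate", "citrate", "succinate", "hippurate", "glycine",
  "alanine", "taurine", "betaine", "tmao", "dimethylamine", "creatine",
  "lactate", "acetate", "glucose", "urea")

#' Generate a creatinine-normalised urine metabolome table
#'
#' Log-normal concentrations for `n_metabolites` metabolites over the four
#' study groups; `n_detected` metabolites are measured in essentially all
#' samples while the remainder carry high zero-inflation (so the 50%
#' detection filter removes them). Negative AD (and milder SCD/MCI) effects
#' are planted on formate and fumarate; age and BMI act on the log scale.
#'
#' @param cfg a [synth_config()].
#' @return list with `conc` (samples x metabolites matrix), `meta`
#'   (sample covariates: age, sex, bmi, group), and `truth` (planted
#'   log-scale effects).
#' @export
make_metabolome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed * 13 + 3, {
    gs <- cfg$metabolome_groups
    n <- sum(gs)
    group <- factor(rep(names(gs), gs), levels = names(gs))
    samples <- sprintf("U%03d", seq_len(n))
    nmet <- cfg$n_metabolites
    mets <- c(.urine_metabolites[seq_len(min(cfg$n_detected, 16L))],
              sprintf("m%02d", seq_len(max(0, nmet - min(cfg$n_detected, 16L)))))
    meta <- data.frame(
      sample_id = samples, group = group,
      age = round(stats::rnorm(n, 70, 6), 1),
      sex = sample(c("male", "female"), n, replace = TRUE),
      bmi = round(stats::rnorm(n, 26, 4), 1),
      stringsAsFactors = FALSE)
    eff <- matrix(0, nmet, 4, dimnames = list(mets, names(gs)))
    eff["formate", ] <- c(0, 0.4, 0.6, 1) * cfg$ad_formate_effect
    eff["fumarate", ] <- c(0, 0.4, 0.6, 1) * cfg$ad_fumarate_effect
    age_beta <- stats::rnorm(nmet, 0, 0.004)
    bmi_beta <- stats::rnorm(nmet, 0, 0.008)
    mu0 <- stats::rnorm(nmet, 1, 0.8)
    logc <- sapply(seq_len(nmet), function(k)
      mu0[k] + eff[k, as.integer(group)] + age_beta[k] * (meta$age - 70) +
        bmi_beta[k] * (meta$bmi - 26) + stats::rnorm(n, 0, 0.6))
    conc <- exp(logc)
    dimnames(conc) <- list(samples, mets)
    # zero-inflation: detected metabolites rarely missing, the rest mostly
    zrate <- c(rep(0.02, cfg$n_detected),
               stats::runif(nmet - cfg$n_detected, 0.55, 0.9))
    zero <- matrix(stats::runif(n * nmet) < rep(zrate, each = n), n, nmet)
    conc[zero] <- 0
    list(conc = conc, meta = meta,
         truth = data.frame(metabolite = mets, effect_AD = eff[, "AD"],
                            zero_rate = zrate, stringsAsFactors = FALSE))
  })
}
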