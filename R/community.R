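# Per-sample microbiome community models. Every member pan model is copied
# into the community with tagged reaction/metabolite ids; its extracellular
# exchanges are rewired into reversible transfer reactions against a shared
# lumen [luM], which is in turn connected to dietary [d] and faecal [fe]
# exchanges. Every member reaction is coupled to that member's biomass
# reaction (|v| <= factor * v_biomass, factor 400 by default) so a microbe
# can only be metabolically active if it grows. The community biomass
# reaction consumes the member biomass metabolites with coefficients equal to
# the relative abundances.

TRANSFER_BOUND <- 1e4

tag_id <- function(tag, ids) paste0(tag, "_", ids)

#' Assemble a community model from pan models and relative abundances
#'
#' @param pans list of `pan_model`s, named by species or carrying
#'   `species_name` fields.
#' @param abundances named numeric vector of relative abundances (names =
#'   species); must sum to 1 within `1e-6` (then renormalised exactly).
#' @param coupling_factor coupling constant tying member reactions to member
#'   biomass; default 400.
#' @param biomass_bounds bounds (per day) on the community biomass reaction,
#'   default `c(0.4, 1)`.
#' @return a `community_model`: a `metabolic_model` with fields `members`
#'   (data.frame species/abundance/tag/biomass reaction) and
#'   `community_biomass_id`.
#' @export
build_community <- function(pans, abundances, coupling_factor = 400,
                            biomass_bounds = c(0.4, 1)) {
  if (is.null(names(pans)))
    names(pans) <- vapply(pans, function(p) p$species_name %||% p$id, "")
  if (anyDuplicated(names(abundances))) stop("duplicate species in abundances")
  if (any(abundances <= 0)) stop("abundances must be positive")
  missing_pan <- setdiff(names(abundances), names(pans))
  if (length(missing_pan))
    stop("species with abundance but no pan model: ",
         paste(missing_pan, collapse = ", "))
  s <- sum(abundances)
  if (abs(s - 1) > 1e-6)
    stop("abundances must sum to 1 (got ", format(s), ")")
  abundances <- abundances / s
  if (coupling_factor <= 0) stop("coupling_factor must be positive")

  mets <- list(); rx <- list(); st <- list(); cpl <- list()
  members <- data.frame(species = names(abundances),
                        abundance = unname(abundances),
                        tag = gsub("[^0-9A-Za-z]", "_", names(abundances)),
                        biomass_rxn = NA_character_, stringsAsFactors = FALSE)
  lum_mets <- character(0)    # base ids pooled in the shared lumen
  bio_terms <- numeric(0)     # community biomass stoichiometry

  for (i in seq_len(nrow(members))) {
    sp <- members$species[i]; tg <- members$tag[i]
    pan <- pans[[sp]]
    sl <- stoich_list(pan)
    bio_id <- pan$biomass_id %||% pan$rxns$id[startsWith(pan$rxns$id, "biomass")][1]
    members$biomass_rxn[i] <- tag_id(tg, bio_id)
    ex <- exchange_reactions(pan)
    ex_met <- vapply(ex, function(r) exchange_metabolite(pan, r), character(1))
    bio_met <- names(sl[[bio_id]])[sl[[bio_id]] > 0]
    # tagged copies of all metabolites and non-exchange reactions
    pm <- pan$mets
    pm$id <- tag_id(tg, pm$id)
    mets[[tg]] <- pm
    keep <- !pan$rxns$id %in% ex
    pr <- pan$rxns[keep, , drop = FALSE]
    for (j in seq_len(nrow(pr))) {
      new_id <- tag_id(tg, pr$id[j])
      v <- sl[[pr$id[j]]]
      names(v) <- tag_id(tg, names(v))
      st[[new_id]] <- v
      if (pr$id[j] != bio_id)
        cpl[[new_id]] <- data.frame(reaction = new_id,
                                    anchor = members$biomass_rxn[i],
                                    factor = coupling_factor)
    }
    pr$id <- tag_id(tg, pr$id)
    rx[[tg]] <- pr
    # transfers species[e] <-> shared lumen, except the biomass metabolite
    tr_met <- setdiff(ex_met, bio_met)
    for (mm in tr_met) {
      base <- met_base(mm)
      tid <- paste0(tg, "_IEX_", base, "[luM]")
      st[[tid]] <- stats::setNames(c(-1, 1),
                                   c(tag_id(tg, mm), paste0(base, "[luM]")))
      rx[[tid]] <- data.frame(id = tid, lower_bound = -TRANSFER_BOUND,
                              upper_bound = TRANSFER_BOUND,
                              subsystem = "transfer", genes = NA_character_)
      cpl[[tid]] <- data.frame(reaction = tid, anchor = members$biomass_rxn[i],
                               factor = coupling_factor)
      lum_mets <- union(lum_mets, base)
    }
    # member biomass metabolite feeds the community biomass reaction
    if (length(bio_met) != 1)
      stop("species ", sp, " biomass must produce exactly one biomass metabolite")
    bio_terms[tag_id(tg, bio_met)] <- -members$abundance[i]
  }

  # shared lumen + diet/faecal plumbing for every pooled metabolite
  plumb_mets <- do.call(rbind, lapply(lum_mets, function(b) data.frame(
    id = paste0(b, c("[luM]", "[d]", "[fe]")), name = b,
    compartment = c("luM", "d", "fe"), formula = NA_character_,
    charge = NA_integer_, stringsAsFactors = FALSE)))
  for (b in lum_mets) {
    st[[paste0("EX_", b, "[d]")]] <- stats::setNames(-1, paste0(b, "[d]"))
    st[[paste0("DUt_", b)]] <- stats::setNames(c(-1, 1),
                                               paste0(b, c("[d]", "[luM]")))
    st[[paste0("UFEt_", b)]] <- stats::setNames(c(-1, 1),
                                                paste0(b, c("[luM]", "[fe]")))
    st[[paste0("EX_", b, "[fe]")]] <- stats::setNames(-1, paste0(b, "[fe]"))
  }
  plumb_rx <- do.call(rbind, lapply(lum_mets, function(b) data.frame(
    id = paste0(c("EX_", "DUt_", "UFEt_", "EX_"), b,
                c("[d]", "", "", "[fe]")),
    lower_bound = c(-1000, 0, 0, 0),
    upper_bound = c(1000, TRANSFER_BOUND, TRANSFER_BOUND, 1000),
    subsystem = "community plumbing", genes = NA_character_,
    stringsAsFactors = FALSE)))

  # community biomass: sum_i a_i * biomass_i -> microbeBiomass[luM] -> faeces
  st[["communityBiomass"]] <- c(bio_terms,
                                stats::setNames(1, "microbeBiomass[luM]"))
  st[["UFEt_microbeBiomass"]] <- stats::setNames(
    c(-1, 1), c("microbeBiomass[luM]", "microbeBiomass[fe]"))
  st[["EX_microbeBiomass[fe]"]] <- stats::setNames(-1, "microbeBiomass[fe]")
  bio_rx <- data.frame(
    id = c("communityBiomass", "UFEt_microbeBiomass", "EX_microbeBiomass[fe]"),
    lower_bound = c(biomass_bounds[1], 0, 0),
    upper_bound = c(biomass_bounds[2], TRANSFER_BOUND, 1000),
    subsystem = "community biomass", genes = NA_character_,
    stringsAsFactors = FALSE)
  bio_mets <- data.frame(id = c("microbeBiomass[luM]", "microbeBiomass[fe]"),
                         name = "microbeBiomass", compartment = c("luM", "fe"),
                         formula = NA_character_, charge = NA_integer_,
                         stringsAsFactors = FALSE)

  all_mets <- rbind(do.call(rbind, mets), plumb_mets, bio_mets)
  all_rx <- rbind(do.call(rbind, rx), plumb_rx, bio_rx)
  if (anyDuplicated(all_rx$id))
    stop("reaction id collision after tagging: ",
         paste(unique(all_rx$id[duplicated(all_rx$id)]), collapse = ", "))
  cm <- metabolic_model("community", all_mets, all_rx, st,
                        couplings = do.call(rbind, cpl),
                        objective = "communityBiomass")
  cm$members <- members
  cm$community_biomass_id <- "communityBiomass"
  class(cm) <- c("community_model", class(cm))
  cm
}

#' Maximal net secretion capacities of a community under a diet
#'
#' Applies the diet (unlisted dietary uptakes closed) and runs FVA over the
#' faecal exchange reactions. A zero maximum means the community cannot
#' secrete that metabolite under the given constraints.
#'
#' @param community a `community_model`.
#' @param diet a `diet_spec`.
#' @param fix_biomass if `TRUE`, fix the community biomass at its upper
#'   bound; default `FALSE` (full `[lb, ub]` range).
#' @return data.frame (`fva_outcome`) over faecal exchanges with an extra
#'   column `metabolite` (base id); `max_flux` is the maximal net secretion.
#' @export
secretion_profile <- function(community, diet, fix_biomass = FALSE) {
  stopifnot(inherits(community, "community_model"))
  m <- suppressWarnings(apply_diet(community, diet, "closed"))
  if (fix_biomass) {
    j <- match(community$community_biomass_id, m$rxns$id)
    m <- set_bounds(m, community$community_biomass_id,
                    lb = m$rxns$upper_bound[j])
  }
  fe <- exchange_reactions(m, "fe")
  feas <- solve_fba(m, community$community_biomass_id, "max")
  if (feas$status != "optimal")
    stop("community model ", feas$status, " under the given diet")
  out <- run_fva(m, fe)
  out$metabolite <- met_base(vapply(fe, function(r) exchange_metabolite(m, r),
                                    character(1)))
  out
}
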