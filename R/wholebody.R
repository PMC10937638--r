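# Attachment of a microbiome community to the large-intestinal lumen [luLI]
# of a whole-body host model, and the urine/microbial secretion objectives.
# The germ-free host is simply the bare host model; the attached model
# replaces the community's diet/faecal plumbing with luM <-> luLI bridge
# reactions (one per metabolite shared by both lumens, written luM -> luLI
# positive = microbe-to-host), so that all nutrition enters through the
# host's dietary exchanges.

#' Declare a model as a sex-specific whole-body host
#'
#' @param model a `metabolic_model` with compartments including `d` (diet),
#'   `luLI` (large-intestinal lumen) and `u` (urine), and at least one urine
#'   exchange reaction `EX_<base>[u]`.
#' @param sex `"male"` or `"female"`.
#' @return a `host_model`.
#' @export
host_model <- function(model, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(model, "metabolic_model"))
  need <- setdiff(c("d", "luLI", "u"), model$compartments)
  if (length(need))
    stop("host model lacks compartment(s): ", paste(need, collapse = ", "))
  if (!length(exchange_reactions(model, "u")))
    stop("host model has no urine exchange reaction (EX_<base>[u])")
  model$sex <- sex
  class(model) <- unique(c("host_model", class(model)))
  model
}

#' Attach a community model to a host's large-intestinal lumen
#'
#' Drops the community's own dietary and faecal plumbing (the microbe-biomass
#' faecal drain is kept) and adds one reversible bridge reaction
#' `Micro_EX_<base>[luLI]` per metabolite present in both the shared microbial
#' lumen `[luM]` and the host's `[luLI]`. Community coupling constraints are
#' preserved; the community biomass lower bound is relaxed to 0 by default so
#' the microbiome can idle (the germ-free host is then always a feasible
#' sub-behaviour of the attached model).
#'
#' @param host a `host_model`.
#' @param community a `community_model`.
#' @param relax_biomass_lb relax community biomass lower bound to 0
#'   (default `TRUE`); set `FALSE` to keep the community's own bounds.
#' @return a `host_microbiome_model`.
#' @export
attach_community <- function(host, community, relax_biomass_lb = TRUE) {
  stopifnot(inherits(host, "host_model"), inherits(community, "community_model"))
  if (!"luLI" %in% host$compartments)
    stop("host model lacks the large-intestinal lumen compartment 'luLI'")
  csl <- stoich_list(community)
  # community reactions to drop: dietary + faecal plumbing (keep microbe
  # biomass drain so community growth has an outlet)
  drop_rx <- grep("^(EX_.*\\[d\\]|DUt_|UFEt_|EX_.*\\[fe\\])", community$rxns$id,
                  value = TRUE)
  drop_rx <- setdiff(drop_rx, c("UFEt_microbeBiomass", "EX_microbeBiomass[fe]"))
  keep <- !community$rxns$id %in% drop_rx
  crx <- community$rxns[keep, , drop = FALSE]
  cst <- csl[crx$id]
  used_mets <- unique(unlist(lapply(cst, names)))
  cmets <- community$mets[community$mets$id %in% used_mets, , drop = FALSE]

  clash <- intersect(crx$id, host$rxns$id)
  if (length(clash))
    stop("reaction id collision between host and community: ",
         paste(clash, collapse = ", "))
  mclash <- intersect(cmets$id, host$mets$id)
  if (length(mclash))
    stop("metabolite id collision between host and community: ",
         paste(mclash, collapse = ", "))

  lum <- cmets$id[cmets$compartment == "luM"]
  lum <- setdiff(lum, "microbeBiomass[luM]")
  host_li <- host$mets$id[host$mets$compartment == "luLI"]
  shared <- intersect(met_base(lum), met_base(host_li))
  br_ids <- paste0("Micro_EX_", shared, "[luLI]")
  br_st <- lapply(shared, function(b) stats::setNames(
    c(-1, 1), paste0(b, c("[luM]", "[luLI]"))))
  names(br_st) <- br_ids
  br_rx <- data.frame(id = br_ids, lower_bound = -TRANSFER_BOUND,
                      upper_bound = TRANSFER_BOUND, subsystem = "lumen bridge",
                      genes = NA_character_, stringsAsFactors = FALSE)

  hsl <- stoich_list(host)
  st <- c(hsl, cst, br_st)
  rx <- rbind(host$rxns, crx, br_rx)
  mets <- rbind(host$mets, cmets)
  if (relax_biomass_lb) {
    j <- match(community$community_biomass_id, rx$id)
    rx$lower_bound[j] <- 0
  }
  m <- metabolic_model(paste0(host$id, "+microbiome"), mets, rx, st,
                       couplings = community$couplings,
                       objective = host$objective,
                       compartments = union(host$compartments,
                                            community$compartments))
  m$sex <- host$sex
  m$members <- community$members
  m$community_biomass_id <- community$community_biomass_id
  m$bridge_reactions <- stats::setNames(br_ids, shared)
  class(m) <- unique(c("host_microbiome_model", class(m)))
  m
}

#' Maximal urine secretion of a metabolite
#'
#' Applies the diet to the (host or host+microbiome) model and maximises the
#' urine exchange `EX_<base>[u]`. Passing a bare `host_model` yields the
#' germ-free value.
#'
#' @param m a `host_model` or `host_microbiome_model`.
#' @param metabolite_base metabolite base id, e.g. `"for"` for formate.
#' @param diet a `diet_spec`.
#' @param value_only return just the optimum (default); otherwise the full
#'   `flux_outcome`.
#' @return maximal urine secretion flux (mmol/person/day).
#' @export
max_urine_secretion <- function(m, metabolite_base, diet, value_only = TRUE) {
  rid <- paste0("EX_", metabolite_base, "[u]")
  if (!rid %in% m$rxns$id)
    stop("no urine exchange reaction for metabolite: ", metabolite_base)
  md <- suppressWarnings(apply_diet(m, diet, "closed"))
  f <- solve_fba(md, rid, "max")
  if (f$status != "optimal")
    stop("urine secretion solve ", f$status, " for ", metabolite_base)
  if (value_only) f$objective_value else f
}

#' Maximal microbial secretion of a metabolite into the host
#'
#' Optimises the flux through the `[luM] -> [luLI]` bridge reaction of the
#' metabolite, i.e. the maximal net transfer from the microbiome to the host
#' lumen, reported as a nonnegative magnitude.
#'
#' @param m a `host_microbiome_model`.
#' @param metabolite_base metabolite base id.
#' @param diet a `diet_spec`.
#' @return maximal microbe-to-host transfer flux (>= 0, mmol/person/day).
#' @export
microbial_secretion_flux <- function(m, metabolite_base, diet) {
  if (!inherits(m, "host_microbiome_model"))
    stop("microbial secretion is defined only for host+microbiome models ",
         "(germ-free hosts have no bridge reactions)")
  rid <- m$bridge_reactions[metabolite_base]
  if (is.na(rid))
    stop("no lumen bridge reaction for metabolite: ", metabolite_base)
  md <- suppressWarnings(apply_diet(m, diet, "closed"))
  f <- solve_fba(md, rid, "max")
  if (f$status != "optimal")
    stop("microbial secretion solve ", f$status, " for ", metabolite_base)
  max(f$objective_value, 0)
}
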