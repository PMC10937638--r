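# Pan-species reconstructions: the union of the strain reconstructions of one
# species. Duplicate reactions keep the widest bounds, so the pan model's
# feasible set contains every strain's (union monotonicity); the pan biomass
# is the arithmetic mean of the strain biomass stoichiometries over the union
# of precursors (a strain lacking a precursor contributes coefficient 0).

#' Build a pan-species model from strain models
#'
#' @param strain_models list of `metabolic_model`s, one per strain; each must
#'   contain exactly one biomass reaction (id prefix `"biomass"`).
#' @param species_name species label for the pan model.
#' @param biomass_mode `"mean"` (default: average strain biomass
#'   stoichiometry) or `"first"` (take the first strain's biomass as is).
#' @return a `pan_model`: a `metabolic_model` with extra fields
#'   `species_name`, `source_strain_ids`, `biomass_id`.
#' @export
build_pan_model <- function(strain_models, species_name,
                            biomass_mode = c("mean", "first")) {
  biomass_mode <- match.arg(biomass_mode)
  if (!length(strain_models)) stop("need at least one strain model")
  stopifnot(all(vapply(strain_models, inherits, logical(1), "metabolic_model")))
  bio_ids <- lapply(strain_models, function(m)
    m$rxns$id[startsWith(m$rxns$id, "biomass")])
  nbio <- lengths(bio_ids)
  if (any(nbio == 0))
    stop("strain(s) without a biomass reaction: ",
         paste(vapply(strain_models[nbio == 0], `[[`, "", "id"), collapse = ", "))
  if (any(nbio > 1))
    stop("strain(s) with more than one biomass reaction: ",
         paste(vapply(strain_models[nbio > 1], `[[`, "", "id"), collapse = ", "))
  bio_ids <- unlist(bio_ids)
  if (length(unique(bio_ids)) > 1)
    stop("strain biomass reactions must share one id to be merged; got: ",
         paste(unique(bio_ids), collapse = ", "))
  biomass_id <- bio_ids[[1]]

  mets <- unique(do.call(rbind, lapply(strain_models, `[[`, "mets")))
  if (anyDuplicated(mets$id))
    stop("conflicting metabolite definitions across strains for: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  st <- list(); lbs <- list(); ubs <- list(); meta <- list()
  bio_st <- list()
  for (m in strain_models) {
    sl <- stoich_list(m)
    for (i in seq_len(nrow(m$rxns))) {
      rid <- m$rxns$id[i]
      if (rid == biomass_id) {
        bio_st[[length(bio_st) + 1L]] <- sl[[rid]]
      }
      if (is.null(st[[rid]])) {
        st[[rid]] <- sl[[rid]]
        lbs[[rid]] <- m$rxns$lower_bound[i]
        ubs[[rid]] <- m$rxns$upper_bound[i]
        meta[[rid]] <- m$rxns[i, c("subsystem", "genes")]
      } else {
        if (rid != biomass_id && !identical(sort(names(st[[rid]])), sort(names(sl[[rid]])))) {
          stop("reaction ", rid, " has conflicting stoichiometry across strains")
        }
        lbs[[rid]] <- min(lbs[[rid]], m$rxns$lower_bound[i])   # widest bounds
        ubs[[rid]] <- max(ubs[[rid]], m$rxns$upper_bound[i])
      }
    }
  }
  if (biomass_mode == "mean" && length(bio_st) > 1) {
    prec <- unique(unlist(lapply(bio_st, names)))
    acc <- stats::setNames(numeric(length(prec)), prec)
    for (bs in bio_st) acc[names(bs)] <- acc[names(bs)] + bs
    st[[biomass_id]] <- acc / length(bio_st)
  } else {
    st[[biomass_id]] <- bio_st[[1]]
  }
  rids <- names(st)
  rx <- data.frame(id = rids,
                   lower_bound = unlist(lbs)[rids],
                   upper_bound = unlist(ubs)[rids],
                   subsystem = vapply(meta[rids], function(x) x$subsystem, ""),
                   genes = vapply(meta[rids], function(x) x$genes, ""),
                   stringsAsFactors = FALSE)
  pan <- metabolic_model(paste0("pan_", species_name), mets, rx, st,
                         objective = biomass_id)
  pan$species_name <- species_name
  pan$source_strain_ids <- vapply(strain_models, `[[`, "", "id")
  pan$biomass_id <- biomass_id
  class(pan) <- c("pan_model", class(pan))
  pan
}

#' Check that a pan model grows under a diet
#'
#' Applies the diet (unlisted dietary uptakes closed) and maximises the
#' biomass reaction; errors if the model is infeasible or grows below
#' `min_growth`.
#'
#' @param pan a `pan_model` (or any model with a `biomass_id` field /
#'   `biomass`-prefixed reaction).
#' @param diet a `diet_spec`.
#' @param min_growth minimal acceptable growth (flux through biomass),
#'   default `1e-6`.
#' @return the achieved maximal growth rate, invisibly test-friendly.
#' @export
check_growth <- function(pan, diet, min_growth = 1e-6) {
  biomass_id <- pan$biomass_id %||%
    pan$rxns$id[startsWith(pan$rxns$id, "biomass")][1]
  if (is.na(biomass_id)) stop("model has no biomass reaction")
  # a diet broader than one species' exchanges is normal, not a warning
  m <- suppressWarnings(apply_diet(pan, diet, "closed"))
  f <- solve_fba(m, biomass_id, "max")
  sp <- pan$species_name %||% pan$id
  if (f$status != "optimal")
    stop("viability check failed for ", sp, ": model ", f$status, " under diet")
  if (f$objective_value < min_growth)
    stop("viability check failed for ", sp, ": maximal growth ",
         format(f$objective_value), " < ", format(min_growth), " under diet")
  f$objective_value
}
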