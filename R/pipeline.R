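# End-to-end orchestration of the synthetic study: generators -> pan models
# -> per-sample communities -> whole-body attachment -> co-metabolism
# decomposition -> statistics. Mirrors the full analysis on desk-scale toy
# inputs so every stage is exercised offline.

#' Build pan models for a toy ecosystem
#'
#' @param strain_data output of [make_toy_strains()].
#' @param diet optional `diet_spec`; when given, every pan model is
#'   viability-checked under it.
#' @return named list of `pan_model`s.
#' @export
build_toy_pans <- function(strain_data, diet = NULL) {
  sm <- split(strain_data$species_map$strain_id, strain_data$species_map$species)
  pans <- lapply(names(sm), function(sp)
    build_pan_model(strain_data$strains[sm[[sp]]], sp))
  names(pans) <- names(sm)
  if (!is.null(diet)) invisible(lapply(pans, check_growth, diet = diet))
  pans
}

#' Run the full synthetic host-microbiome study
#'
#' Generates the toy ecosystem and cohorts, builds per-sample community
#' models from mapped relative abundances, attaches them to the sex-matched
#' toy host, decomposes urinary secretion of the target metabolite into
#' microbial and co-metabolic parts for a subset of samples, and runs the
#' metabolome, abundance, log-ratio and flux statistics.
#'
#' @param cfg a [synth_config()].
#' @param diet a `diet_spec` (default [toy_diet()]).
#' @param metabolite target metabolite base id (default `"for"`, formate).
#' @param n_flux_samples samples per group put through the (expensive)
#'   whole-body flux decomposition; the remaining samples contribute to the
#'   abundance/metabolome statistics only.
#' @return list with elements `pans`, `abundance` (mapped abundance table),
#'   `meta`, `decomposition` (one row per flux sample), `flux_stats`,
#'   `metabolome_stats`, `abundance_stats`, `logratio`, `truth`.
#' @export
run_synthetic_study <- function(cfg = synth_config(), diet = toy_diet(),
                                metabolite = "for", n_flux_samples = 2) {
  strain_data <- make_toy_strains(cfg)
  pans <- build_toy_pans(strain_data, diet)
  ab_data <- make_abundance_counts(cfg)
  species_counts <- collapse_to_species(ab_data$counts)
  ab <- map_filter_normalise(species_counts, names(pans))
  hosts <- list(male = make_toy_host("male"), female = make_toy_host("female"))

  meta <- ab_data$meta
  pick <- unlist(lapply(split(seq_len(nrow(meta)), meta$group),
                        utils::head, n_flux_samples))
  dec <- lapply(pick, function(i) {
    comm <- build_community(pans, ab$abundances[, meta$sample_id[i]])
    comm$id <- meta$sample_id[i]
    decompose_contributions(hosts[[meta$sex[i]]], comm, diet, metabolite)
  })
  dec <- do.call(rbind, dec)
  dec$group <- meta$group[pick]
  dec$apoe <- meta$apoe[pick]

  flux_stats <- if (length(unique(dec$group)) == 2 && nrow(dec) >= 4) {
    tryCatch(suppressWarnings(flux_group_regression(
      dec[, c("urine_max_personalised", "microbial_secretion"), drop = FALSE],
      data.frame(group = dec$group, apoe = dec$apoe, sex = dec$sex))),
      error = function(e) NULL)
  } else NULL

  met <- make_metabolome(cfg)
  conc <- filter_detected(met$conc)
  met_stats <- metabolite_group_regression(conc, met$meta)

  ab_stats <- suppressWarnings(fractional_abundance_regression(
    ab, meta[, c("group", "apoe")]))
  lr <- logratio_test(species_counts,
                      up_set = ab_data$truth$species[ab_data$truth$direction == "up"],
                      down_set = ab_data$truth$species[ab_data$truth$direction == "down"],
                      group = meta$group)

  list(pans = pans, abundance = ab, meta = meta, decomposition = dec,
       flux_stats = flux_stats, metabolome_stats = met_stats,
       abundance_stats = ab_stats, logratio = lr,
       truth = list(abundance = ab_data$truth, metabolome = met$truth,
                    products = strain_data$truth))
}
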