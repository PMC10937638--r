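# The three in-silico experiments: host-microbiome co-metabolism
# decomposition, the diet-supplementation screen, and the reaction-deletion
# screens including exhaustive minimal-deletion-set search.

#' Decompose urinary secretion into microbial and co-metabolic parts
#'
#' Three LP solves: maximal urine secretion of the personalised
#' (host+microbiome) model, of the germ-free host, and the maximal microbial
#' secretion across the lumen bridge. `delta` is the personalised minus
#' germ-free difference; `co_metabolism_excess = delta - microbial_secretion`
#' is the part of the gain that cannot be explained by direct microbial
#' secretion of the metabolite itself and therefore flags host-microbe
#' co-metabolism via other microbial metabolites.
#'
#' @param host a `host_model` (germ-free baseline).
#' @param community a `community_model`.
#' @param diet a `diet_spec`.
#' @param metabolite metabolite base id (e.g. `"for"`).
#' @return one-row data.frame (`decomposition_record`).
#' @export
decompose_contributions <- function(host, community, diet, metabolite) {
  joint <- attach_community(host, community)
  pers <- tryCatch(max_urine_secretion(joint, metabolite, diet),
                   error = function(e) stop("personalised solve failed: ",
                                            conditionMessage(e)))
  germ <- tryCatch(max_urine_secretion(host, metabolite, diet),
                   error = function(e) stop("germ-free solve failed: ",
                                            conditionMessage(e)))
  micro <- if (!metabolite %in% names(joint$bridge_reactions)) {
    0   # the community does not carry the metabolite: nothing can transfer
  } else {
    tryCatch(microbial_secretion_flux(joint, metabolite, diet),
             error = function(e) stop("microbial secretion solve failed: ",
                                      conditionMessage(e)))
  }
  data.frame(sample = community$id,
             sex = host$sex,
             metabolite = metabolite,
             urine_max_personalised = pers,
             urine_max_germfree = germ,
             delta = pers - germ,
             microbial_secretion = micro,
             co_metabolism_excess = (pers - germ) - micro,
             stringsAsFactors = FALSE)
}

#' Highly secreted microbial metabolites across flux solutions
#'
#' Extracts the lumen-bridge (`Micro_EX_<base>[luLI]`) fluxes from a list of
#' flux solutions (typically the solutions of maximising urine secretion of
#' a target metabolite on personalised models) and returns the metabolites
#' whose mean microbe-to-host secretion exceeds the threshold, excluding the
#' target itself.
#'
#' @param flux_solutions list of `flux_outcome`s.
#' @param threshold mean-flux threshold in mmol/person/day (default 30).
#' @param exclude metabolite base id(s) to exclude (the target).
#' @return data.frame of metabolites and mean secretion, above-threshold only.
#' @export
high_secretion_metabolites <- function(flux_solutions, threshold = 30,
                                       exclude = character(0)) {
  if (!length(flux_solutions)) stop("no flux solutions given")
  if (inherits(flux_solutions, "flux_outcome"))
    flux_solutions <- list(flux_solutions)
  rows <- lapply(flux_solutions, function(f) {
    br <- grep("^Micro_EX_.*\\[luLI\\]$", names(f$fluxes), value = TRUE)
    stats::setNames(pmax(f$fluxes[br], 0),
                    sub("^Micro_EX_(.*)\\[luLI\\]$", "\\1", br))
  })
  mets <- sort(unique(unlist(lapply(rows, names))))
  mean_flux <- vapply(mets, function(b)
    mean(vapply(rows, function(r) if (b %in% names(r)) r[[b]] else 0, 0)), 0)
  out <- data.frame(metabolite = mets, mean_secretion = unname(mean_flux),
                    stringsAsFactors = FALSE)
  out <- out[!out$metabolite %in% exclude & out$mean_secretion > threshold, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diet-supplementation screen on the germ-free host
#'
#' For each candidate metabolite, opens its dietary uptake to `bound`
#' (300 mmol/d by default) on top of the reference diet and recomputes the
#' maximal urine secretion of the target; `percent_change > 0` marks usable
#' precursors. Candidates without a dietary exchange are flagged
#' `not_applicable`.
#'
#' @param host a `host_model`.
#' @param diet reference `diet_spec`.
#' @param candidates metabolite base ids to supplement.
#' @param metabolite target metabolite base id (default `"for"`).
#' @param bound supplemented maximal intake (mmol/person/day).
#' @return data.frame of screen records (one per candidate).
#' @export
diet_supplementation_screen <- function(host, diet, candidates,
                                        metabolite = "for", bound = 300) {
  dex_base <- met_base(vapply(diet_exchanges(host), function(r)
    exchange_metabolite(host, r), character(1)))
  baseline <- max_urine_secretion(host, metabolite, diet)
  out <- lapply(candidates, function(b) {
    if (!b %in% dex_base)
      return(data.frame(perturbation = b, baseline = baseline,
                        perturbed = NA_real_, percent_change = NA_real_,
                        note = "not_applicable", stringsAsFactors = FALSE))
    v <- max_urine_secretion(host, metabolite, diet_with(diet,
                                                         stats::setNames(bound, b)))
    data.frame(perturbation = b, baseline = baseline, perturbed = v,
               percent_change = if (baseline > 0)
                 100 * (v - baseline) / baseline else NA_real_,
               note = if (baseline > 0) "" else "undefined_baseline",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Single-reaction knockout screen
#'
#' Deletes each candidate reaction in turn (both bounds to zero) and records
#' the percent change of the maximal urine secretion of the target
#' metabolite relative to the intact baseline. The flagged subset collects
#' reactions whose deletion reduces the target by more than `threshold_pct`.
#'
#' @param host a `host_model` (typically germ-free).
#' @param diet a `diet_spec`.
#' @param candidates reaction ids to screen.
#' @param metabolite target metabolite base id.
#' @param threshold_pct flag threshold (percent reduction, default 10).
#' @return data.frame with one record per candidate and a logical `flagged`
#'   column.
#' @export
single_knockout_screen <- function(host, diet, candidates, metabolite = "for",
                                   threshold_pct = 10) {
  unknown <- setdiff(candidates, host$rxns$id)
  if (length(unknown))
    stop("candidate reaction(s) not in host: ", paste(unknown, collapse = ", "))
  baseline <- max_urine_secretion(host, metabolite, diet)
  if (baseline <= 0)
    stop("baseline urine secretion is zero; knockout screen undefined")
  rows <- lapply(candidates, function(r) {
    v <- max_urine_secretion(delete_reactions(host, r), metabolite, diet)
    data.frame(perturbation = r, baseline = baseline, perturbed = v,
               percent_change = 100 * (v - baseline) / baseline,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- -out$percent_change > threshold_pct
  out
}

#' Minimal deletion set achieving a target reduction
#'
#' Exhaustive smallest-first search over subsets of the candidate reactions
#' (sizes 1 to `max_size`) for the smallest set whose joint deletion reduces
#' the maximal urine secretion of the target by at least
#' `reduction_target_pct`; ties at the smallest size are broken
#' lexicographically on the sorted reaction ids. With more than `exhaustive_limit`
#' candidates a clearly-labelled greedy heuristic is used instead.
#'
#' @param host a `host_model`.
#' @param diet a `diet_spec`.
#' @param candidates candidate reaction ids (typically pre-filtered to those
#'   with a noticeable single-deletion effect).
#' @param metabolite target metabolite base id.
#' @param reduction_target_pct required percent reduction (default 85).
#' @param max_size largest subset size searched (default 6).
#' @param exhaustive_limit candidate-count limit for exhaustive search.
#' @return list with `found` (logical), `set` (reaction ids, empty when the
#'   target is 0), `reduction_pct`, `method` (`"exhaustive"`/`"greedy"`).
#' @export
find_minimal_deletion_set <- function(host, diet, candidates, metabolite = "for",
                                      reduction_target_pct = 85, max_size = 6,
                                      exhaustive_limit = 20) {
  if (!length(candidates)) stop("no candidate reactions given")
  baseline <- max_urine_secretion(host, metabolite, diet)
  if (baseline <= 0) stop("baseline urine secretion is zero")
  if (reduction_target_pct <= 0)
    return(list(found = TRUE, set = character(0), reduction_pct = 0,
                method = "exhaustive"))
  reduction <- function(set) {
    v <- max_urine_secretion(delete_reactions(host, set), metabolite, diet)
    100 * (baseline - v) / baseline
  }
  cand <- sort(unique(candidates))
  if (length(cand) <= exhaustive_limit) {
    for (k in seq_len(min(max_size, length(cand)))) {
      subsets <- utils::combn(cand, k, simplify = FALSE)
      # combn over sorted ids emits subsets in lexicographic order already
      for (s in subsets) {
        r <- reduction(s)
        if (r >= reduction_target_pct)
          return(list(found = TRUE, set = s, reduction_pct = r,
                      method = "exhaustive"))
      }
    }
    return(list(found = FALSE, set = character(0), reduction_pct = NA_real_,
                method = "exhaustive"))
  }
  # greedy fallback for large candidate lists (heuristic, not minimal-proof)
  chosen <- character(0)
  for (k in seq_len(max_size)) {
    rest <- setdiff(cand, chosen)
    red <- vapply(rest, function(r) reduction(c(chosen, r)), 0)
    chosen <- sort(c(chosen, rest[which.max(red)]))
    if (max(red) >= reduction_target_pct)
      return(list(found = TRUE, set = chosen, reduction_pct = max(red),
                  method = "greedy"))
  }
  list(found = FALSE, set = chosen, reduction_pct = NA_real_, method = "greedy")
}

#' Annotate reactions with gene-disease associations
#'
#' Joins a reaction -> gene map with a gene -> disease-association table
#' (e.g. an AD Atlas query export) and reports per-reaction associated genes
#' and summary counts.
#'
#' @param reactions character vector of reaction ids.
#' @param gene_map data.frame with columns `reaction`, `gene`.
#' @param association_table data.frame with columns `gene`, `direction`
#'   (e.g. `"positive"`/`"negative"`), optionally more.
#' @param flagged optional reaction ids with a large flux effect (e.g. the
#'   >10% knockout subset) for the joint count.
#' @return list with `table` (per-reaction annotation) and `counts`
#'   (`n_reactions`, `n_associated`, `n_associated_flagged`).
#' @export
annotate_reactions_with_genes <- function(reactions, gene_map,
                                          association_table,
                                          flagged = character(0)) {
  stopifnot(all(c("reaction", "gene") %in% names(gene_map)),
            "gene" %in% names(association_table))
  if (!"direction" %in% names(association_table))
    association_table[["direction"]] <- rep(NA_character_,
                                            nrow(association_table))
  tab <- lapply(reactions, function(r) {
    genes <- gene_map$gene[gene_map$reaction == r]
    assoc <- association_table[association_table$gene %in% genes, , drop = FALSE]
    data.frame(reaction = r,
               genes = if (length(genes)) paste(genes, collapse = ";") else "no gene",
               associated = nrow(assoc) > 0,
               associated_genes = paste(assoc$gene, collapse = ";"),
               direction = paste(unique(assoc$direction), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  list(table = tab,
       counts = c(n_reactions = length(reactions),
                  n_associated = sum(tab$associated),
                  n_associated_flagged = sum(tab$associated &
                                               tab$reaction %in% flagged)))
}
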