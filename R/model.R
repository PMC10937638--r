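# S3 data model for constraint-based metabolic models.
#
# Identifier dialect: metabolite ids are "base[compartment]" (e.g. "for[u]",
# "glc_D[luLI]"); exchange reactions are single-metabolite boundary reactions
# with id prefix "EX_", negative flux = uptake, positive = secretion. All
# fluxes are carried in mmol/person/day.

#' Construct a metabolic model
#'
#' A `metabolic_model` bundles compartmented metabolites, bounded reactions
#' (columns of the stoichiometric matrix S), optional coupling constraints
#' tying reactions to a biomass reaction, and an optional objective reaction.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `charge`. Metabolite ids must be unique and follow
#'   the `base[compartment]` dialect.
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`
#'   and optionally `subsystem`, `genes` (list column or `;`-separated string).
#' @param stoichiometry named list: reaction id -> named numeric vector of
#'   metabolite coefficients (negative = consumed).
#' @param couplings optional data.frame with columns `reaction`, `anchor`,
#'   `factor` encoding `|v_reaction| <= factor * v_anchor` as the two linear
#'   constraints `v_r - factor*v_b <= 0` and `v_r + factor*v_b >= 0`.
#' @param objective optional reaction id used as default FBA objective.
#' @param compartments optional character vector of compartment tags; derived
#'   from metabolite ids when omitted.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            couplings = NULL, objective = NULL,
                            compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!all(c("id", "compartment") %in% names(metabolites)))
    stop("metabolites need columns 'id' and 'compartment'")
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!all(c("id", "lower_bound", "upper_bound") %in% names(reactions)))
    stop("reactions need columns 'id', 'lower_bound', 'upper_bound'")
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!"genes" %in% names(reactions)) reactions$genes <- NA_character_
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (is.null(compartments))
    compartments <- sort(unique(metabolites$compartment))
  m <- structure(list(
    id = as.character(id),
    mets = metabolites[, c("id", "name", "compartment", "formula", "charge")],
    rxns = reactions[, c("id", "lower_bound", "upper_bound", "subsystem", "genes")],
    S = build_S(metabolites$id, reactions$id, stoichiometry),
    couplings = normalize_couplings(couplings),
    objective = if (is.null(objective)) NA_character_ else as.character(objective),
    compartments = compartments
  ), class = "metabolic_model")
  validate_model(m)
}

build_S <- function(met_ids, rxn_ids, stoichiometry) {
  stopifnot(is.list(stoichiometry))
  missing_rxn <- setdiff(rxn_ids, names(stoichiometry))
  if (length(missing_rxn))
    stop("no stoichiometry for reaction(s): ", paste(missing_rxn, collapse = ", "))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- stoichiometry[[rxn_ids[j]]]
    if (!length(st)) stop("empty stoichiometry for reaction ", rxn_ids[j])
    idx <- match(names(st), met_ids)
    if (anyNA(idx))
      stop("reaction ", rxn_ids[j], " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

normalize_couplings <- function(couplings) {
  if (is.null(couplings) || (is.data.frame(couplings) && nrow(couplings) == 0))
    return(data.frame(reaction = character(0), anchor = character(0),
                      factor = numeric(0), stringsAsFactors = FALSE))
  couplings <- as.data.frame(couplings, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "anchor", "factor") %in% names(couplings)))
  if (any(couplings$factor <= 0)) stop("coupling factors must be positive")
  couplings[, c("reaction", "anchor", "factor")]
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, compartment tags, and that coupling
#' constraints reference existing reactions. Called by all constructors.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable in pipelines; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (any(model$rxns$lower_bound > model$rxns$upper_bound + 1e-12))
    stop("reaction(s) with lower_bound > upper_bound: ",
         paste(model$rxns$id[model$rxns$lower_bound > model$rxns$upper_bound + 1e-12],
               collapse = ", "))
  comp <- met_compartment(model$mets$id)
  if (any(is.na(comp) | comp == ""))
    stop("metabolite id(s) without a [compartment] tag: ",
         paste(model$mets$id[is.na(comp) | comp == ""], collapse = ", "))
  bad <- !comp %in% model$compartments
  if (any(bad))
    stop("metabolite compartment(s) not declared: ",
         paste(unique(comp[bad]), collapse = ", "))
  cp <- model$couplings
  if (nrow(cp)) {
    unk <- setdiff(unique(c(cp$reaction, cp$anchor)), model$rxns$id)
    if (length(unk))
      stop("coupling references unknown reaction(s): ", paste(unk, collapse = ", "))
  }
  if (!is.na(model$objective) && !model$objective %in% model$rxns$id)
    stop("objective reaction not in model: ", model$objective)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$mets),
      "  reactions: ", nrow(x$rxns),
      "  couplings: ", nrow(x$couplings), "\n",
      "  compartments: ", paste(x$compartments, collapse = ", "), "\n",
      "  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Split metabolite ids into base and compartment
#'
#' @param ids metabolite ids in `base[compartment]` form.
#' @return character vector (`met_base`: the base id; `met_compartment`: the
#'   compartment tag, `NA` if the id carries none).
#' @export
met_base <- function(ids) sub("\\[[^]]*\\]$", "", ids)

#' @rdname met_base
#' @export
met_compartment <- function(ids) {
  out <- rep(NA_character_, length(ids))
  has <- grepl("\\[[^]]+\\]$", ids)
  out[has] <- sub("^.*\\[([^]]+)\\]$", "\\1", ids[has])
  out
}

#' List exchange reactions of a model
#'
#' Exchange reactions are recognised by the `EX_` id prefix together with
#' single-metabolite stoichiometry.
#'
#' @param model a `metabolic_model`.
#' @param compartment optional compartment tag; restrict to exchanges whose
#'   metabolite lives there.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model, compartment = NULL) {
  nmet <- Matrix::colSums(model$S != 0)
  ex <- model$rxns$id[startsWith(model$rxns$id, "EX_") & nmet == 1]
  if (!is.null(compartment)) {
    mets <- vapply(ex, function(r) exchange_metabolite(model, r), character(1))
    ex <- ex[met_compartment(mets) %in% compartment]
  }
  unname(ex)
}

# the single metabolite of an exchange reaction
exchange_metabolite <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  rownames(model$S)[Matrix::which(model$S[, j] != 0)]
}

# the compartment holding dietary exchanges: "d" when present (community/host
# models), otherwise "e" (standalone microbe models)
diet_compartment <- function(model) {
  if ("d" %in% model$compartments) "d" else "e"
}

#' List dietary exchange reactions
#'
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids in the model's dietary
#'   compartment (`d` when present, else `e` for standalone microbes).
#' @export
diet_exchanges <- function(model) {
  exchange_reactions(model, diet_compartment(model))
}

#' Change reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids.
#' @param lb,ub optional new bounds (recycled along `ids`); `NULL` leaves the
#'   respective bound untouched.
#' @return modified copy of the model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  j <- match(ids, model$rxns$id)
  if (anyNA(j)) stop("unknown reaction id(s): ", paste(ids[is.na(j)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lower_bound[j] <- rep_len(lb, length(j))
  if (!is.null(ub)) model$rxns$upper_bound[j] <- rep_len(ub, length(j))
  validate_model(model)
}

# stoichiometry of one reaction as a named numeric vector
reaction_stoich <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  if (is.na(j)) stop("unknown reaction id: ", rxn_id)
  col <- model$S[, j]
  nz <- Matrix::which(col != 0)
  stats::setNames(as.numeric(col[nz]), rownames(model$S)[nz])
}

# full stoichiometry list (reaction id -> named vector)
stoich_list <- function(model) {
  Ss <- methods::as(model$S, "TsparseMatrix")
  out <- split(data.frame(i = Ss@i + 1L, x = Ss@x),
               factor(Ss@j + 1L, levels = seq_len(ncol(model$S))))
  res <- lapply(out, function(d) stats::setNames(d$x, rownames(model$S)[d$i]))
  names(res) <- colnames(model$S)
  res
}
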