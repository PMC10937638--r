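# On-disk formats. The documented JSON dialect is canonical; SBML Level 3 +
# fbc is supported read/write for interoperability (coupling constraints,
# which SBML does not standardise, travel in a wbmflux annotation element).
# Diets are TSV with columns metabolite_id, flux_mmol_per_person_per_day.

#' Construct a diet specification
#'
#' A diet maps metabolite base ids to maximal uptake rates in
#' mmol/person/day; [apply_diet()] turns entry `m: u` into a lower bound of
#' `-u` on the dietary exchange of `m`.
#'
#' @param entries named nonnegative numeric vector (names = metabolite base
#'   ids, e.g. `glc_D`).
#' @return object of class `diet_spec`.
#' @export
diet_spec <- function(entries) {
  entries <- unlist(entries)
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("diet entries must be named by metabolite base id")
  if (any(entries < 0)) stop("diet uptake values must be nonnegative")
  structure(as.numeric(entries), names = names(entries), class = "diet_spec")
}

diet_entries <- function(diet) {
  if (inherits(diet, "diet_spec")) return(unclass(diet))
  if (is.numeric(diet) && !is.null(names(diet))) return(unclass(diet_spec(diet)))
  stop("diet must be a diet_spec or a named numeric vector")
}

#' Amend a diet
#'
#' @param diet a `diet_spec`.
#' @param ... named uptake values (mmol/person/day) to add or overwrite.
#' @return modified `diet_spec`.
#' @export
diet_with <- function(diet, ...) {
  e <- diet_entries(diet)
  add <- c(...)
  e[names(add)] <- add
  diet_spec(e)
}

#' Read / write diet TSV
#'
#' @param path file path; TSV with columns `metabolite_id`,
#'   `flux_mmol_per_person_per_day`.
#' @return `read_diet`: a `diet_spec`.
#' @export
read_diet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "flux_mmol_per_person_per_day") %in% names(d)))
  diet_spec(stats::setNames(d$flux_mmol_per_person_per_day, d$metabolite_id))
}

#' @rdname read_diet
#' @param diet a `diet_spec`.
#' @export
write_diet <- function(diet, path) {
  e <- diet_entries(diet)
  utils::write.table(
    data.frame(metabolite_id = names(e), flux_mmol_per_person_per_day = unname(e)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolic model from disk
#'
#' @param path file path.
#' @param format `"json"` (the package's canonical dialect) or `"sbml"`
#'   (Level 3 + fbc); guessed from the file extension when omitted.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("guess", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("guess", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e)))
  for (fld in c("id", "metabolites", "reactions"))
    if (is.null(doc[[fld]])) stop("model JSON lacks required field '", fld, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry without id")
    data.frame(id = m$id,
               name = m$name %||% m$id,
               compartment = m$compartment %||% met_compartment(m$id),
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rx <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without id")
    data.frame(id = r$id,
               lower_bound = r$lower_bound %||% -1000,
               upper_bound = r$upper_bound %||% 1000,
               subsystem = r$subsystem %||% NA_character_,
               genes = if (length(r$genes)) paste(unlist(r$genes), collapse = ";")
                       else NA_character_,
               stringsAsFactors = FALSE)
  }))
  st <- lapply(doc$reactions, function(r) unlist(r$stoichiometry))
  names(st) <- rx$id
  cp <- if (length(doc$couplings)) {
    do.call(rbind, lapply(doc$couplings, function(k)
      data.frame(reaction = k$reaction, anchor = k$anchor, factor = k$factor,
                 stringsAsFactors = FALSE)))
  } else NULL
  metabolic_model(doc$id, mets, rx, st, couplings = cp,
                  objective = doc$objective %||% NULL,
                  compartments = if (length(doc$compartments))
                    unlist(doc$compartments) else NULL)
}

write_model_json <- function(model, path) {
  sl <- stoich_list(model)
  doc <- list(
    id = model$id,
    compartments = model$compartments,
    objective = if (is.na(model$objective)) NULL else model$objective,
    metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
      m <- model$mets[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$rxns)), function(i) {
      r <- model$rxns[i, ]
      out <- list(id = r$id, stoichiometry = as.list(sl[[r$id]]),
                  lower_bound = r$lower_bound, upper_bound = r$upper_bound)
      if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
      if (!is.na(r$genes)) out$genes <- strsplit(r$genes, ";")[[1]]
      out
    }),
    couplings = if (nrow(model$couplings)) lapply(seq_len(nrow(model$couplings)),
      function(i) as.list(model$couplings[i, ])) else NULL
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SBML Level 3 + fbc -----------------------------------------------------

# SBML SIds cannot contain brackets; encode them numerically as libSBML does.
sbml_encode <- function(ids) gsub("\\[", "__91__", gsub("\\]", "__93__", ids))
sbml_decode <- function(ids) gsub("__91__", "[", gsub("__93__", "]", ids))

write_model_sbml <- function(model, path) {
  sl <- stoich_list(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x); x <- gsub("<", "&lt;", x); gsub(">", "&gt;", x)
  }
  bnd_ids <- character(0); bnd_val <- numeric(0)
  bnd <- function(v) {
    id <- sprintf("b_%s", gsub("[^0-9A-Za-z]", "_", format(v, scientific = FALSE)))
    if (!id %in% bnd_ids) {
      bnd_ids <<- c(bnd_ids, id); bnd_val[id] <<- v
    }
    id
  }
  rx_lines <- vapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    st <- sl[[r$id]]
    sub <- st[st < 0]; prd <- st[st > 0]
    spref <- function(v, tag) {
      if (!length(v)) return("")
      paste0("      <listOf", tag, ">\n",
             paste(sprintf(
               '        <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
               sbml_encode(names(v)), format(abs(unname(v)), digits = 15)),
               collapse = "\n"),
             "\n      </listOf", tag, ">\n")
    }
    paste0(sprintf(
      '    <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">\n',
      sbml_encode(r$id), tolower(r$lower_bound < 0), bnd(r$lower_bound),
      bnd(r$upper_bound)),
      spref(sub, "Reactants"), spref(prd, "Products"),
      "    </reaction>")
  }, character(1))
  met_lines <- sprintf(
    '    <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    sbml_encode(model$mets$id), esc(model$mets$name), model$mets$compartment)
  cmp_lines <- sprintf('    <compartment id="%s" constant="true"/>',
                       model$compartments)
  par_lines <- sprintf(
    '    <parameter id="%s" value="%s" constant="true"/>',
    bnd_ids, format(unname(bnd_val[bnd_ids]), digits = 15))
  cp_block <- if (nrow(model$couplings)) {
    paste0("    <annotation>\n      <wbmflux:couplings xmlns:wbmflux=\"https://wbmflux.invalid/couplings\">\n",
           paste(sprintf(
             '        <wbmflux:coupling reaction="%s" anchor="%s" factor="%s"/>',
             sbml_encode(model$couplings$reaction),
             sbml_encode(model$couplings$anchor),
             format(model$couplings$factor, digits = 15)), collapse = "\n"),
           "\n      </wbmflux:couplings>\n    </annotation>\n")
  } else ""
  obj_block <- if (!is.na(model$objective)) paste0(
    '    <fbc:listOfObjectives fbc:activeObjective="obj">\n',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">\n',
    '        <fbc:listOfFluxObjectives>\n',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>\n',
            sbml_encode(model$objective)),
    '        </fbc:listOfFluxObjectives>\n      </fbc:objective>\n',
    '    </fbc:listOfObjectives>\n') else ""
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    sprintf('  <model id="%s" fbc:strict="true">\n',
            gsub("[^0-9A-Za-z_]", "_", model$id)),
    cp_block,
    "  <listOfCompartments>\n", paste(cmp_lines, collapse = "\n"),
    "\n  </listOfCompartments>\n",
    "  <listOfSpecies>\n", paste(met_lines, collapse = "\n"),
    "\n  </listOfSpecies>\n",
    "  <listOfParameters>\n", paste(par_lines, collapse = "\n"),
    "\n  </listOfParameters>\n",
    "  <listOfReactions>\n", paste(rx_lines, collapse = "\n"),
    "\n  </listOfReactions>\n",
    obj_block,
    "  </model>\n</sbml>\n")
  writeLines(xml, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          w = "https://wbmflux.invalid/couplings")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mdl))) stop("SBML file has no <model> element")
  att <- function(nodes, a) xml2::xml_attr(nodes, a)
  cmp <- att(xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns), "id")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = sbml_decode(sub("^M_", "", att(sp, "id"))),
    name = ifelse(is.na(att(sp, "name")), sbml_decode(sub("^M_", "", att(sp, "id"))),
                  att(sp, "name")),
    compartment = att(sp, "compartment"), stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(att(pars, "value")), att(pars, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  ids <- sbml_decode(sub("^R_", "", att(rxn_nodes, "id")))
  lbp <- att(rxn_nodes, "lowerFluxBound"); ubp <- att(rxn_nodes, "upperFluxBound")
  rx <- data.frame(id = ids,
                   lower_bound = ifelse(is.na(lbp), -1000, unname(pval[lbp])),
                   upper_bound = ifelse(is.na(ubp), 1000, unname(pval[ubp])),
                   stringsAsFactors = FALSE)
  st <- lapply(seq_along(rxn_nodes), function(i) {
    node <- rxn_nodes[[i]]
    rs <- xml2::xml_find_all(node, ".//s:listOfReactants/s:speciesReference", ns)
    ps <- xml2::xml_find_all(node, ".//s:listOfProducts/s:speciesReference", ns)
    v <- c(stats::setNames(-as.numeric(att(rs, "stoichiometry")),
                           sbml_decode(sub("^M_", "", att(rs, "species")))),
           stats::setNames(as.numeric(att(ps, "stoichiometry")),
                           sbml_decode(sub("^M_", "", att(ps, "species")))))
    if (!length(v)) stop("SBML reaction ", ids[i], " has empty stoichiometry")
    v
  })
  names(st) <- ids
  cpn <- xml2::xml_find_all(doc, ".//w:coupling", ns)
  cp <- if (length(cpn)) data.frame(
    reaction = sbml_decode(att(cpn, "reaction")),
    anchor = sbml_decode(att(cpn, "anchor")),
    factor = as.numeric(att(cpn, "factor")), stringsAsFactors = FALSE) else NULL
  objn <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  obj <- if (!is.na(xml2::xml_name(objn)))
    sbml_decode(sub("^R_", "", xml2::xml_attr(objn, "reaction"))) else NULL
  metabolic_model(xml2::xml_attr(mdl, "id"), mets, rx, st, couplings = cp,
                  objective = obj, compartments = cmp)
}
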