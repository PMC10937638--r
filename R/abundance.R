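# gOTU count tables -> model-ready relative abundances: taxonomy collapse,
# reconstruction-database mapping, low-abundance cut-off, renormalisation and
# mapped-read bookkeeping.

#' Construct a count table
#'
#' @param counts numeric matrix, taxa (rows) x samples (columns), nonnegative
#'   read counts; rownames = taxon ids, colnames = sample ids.
#' @param taxonomy optional named character vector mapping taxon id ->
#'   species name (`NA` = no species-level taxonomy).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts need rownames (taxa) and colnames (samples)")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples; taxonomy: ", if (is.null(x$taxonomy)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Read a count table
#'
#' TSV tables are taxa x samples with taxon ids in the first column; an
#' optional taxonomy TSV maps `taxon_id` to `species`. BIOM(JSON) files are
#' accepted read-only via the biomformat package.
#'
#' @param path counts file (TSV or .biom JSON).
#' @param taxonomy_path optional taxonomy TSV with columns `taxon_id`,
#'   `species`.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom files requires the biomformat package")
    bm <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(bm))
  } else {
    d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    counts <- as.matrix(d)
  }
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    td <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    stopifnot(all(c("taxon_id", "species") %in% names(td)))
    tax <- stats::setNames(td$species, td$taxon_id)
  }
  count_table(counts, tax)
}

#' Collapse gOTU counts to species level
#'
#' Sums rows sharing a species assignment; gOTUs without species-level
#' taxonomy are dropped and reported in the `"dropped"` attribute.
#'
#' @param counts a `count_table` with taxonomy present.
#' @return species-level `count_table` (taxonomy becomes the identity map);
#'   attribute `"dropped"` lists dropped taxon ids, attribute
#'   `"dropped_reads"` the per-sample read totals they carried.
#' @export
collapse_to_species <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  if (is.null(counts$taxonomy)) stop("taxonomy mapping required")
  if (nrow(counts$counts) == 0) stop("empty count table")
  sp <- counts$taxonomy[rownames(counts$counts)]
  no_species <- is.na(sp) | !nzchar(sp)
  dropped <- rownames(counts$counts)[no_species]
  dropped_reads <- colSums(counts$counts[no_species, , drop = FALSE])
  kept <- counts$counts[!no_species, , drop = FALSE]
  if (nrow(kept) == 0) stop("no gOTU has species-level taxonomy")
  agg <- rowsum(kept, group = sp[!no_species])
  out <- count_table(agg, stats::setNames(rownames(agg), rownames(agg)))
  attr(out, "dropped") <- dropped
  attr(out, "dropped_reads") <- dropped_reads
  out
}

#' Map species to a model resource, filter, and normalise
#'
#' Removes species without a metabolic reconstruction, converts counts to
#' per-sample relative abundances, removes species below the low-abundance
#' cut-off per sample, and renormalises each sample to sum to one. The
#' per-sample `mapped_fraction` is the fraction of the sample's total reads
#' retained in the final table.
#'
#' @param counts a species-level `count_table` (see [collapse_to_species()]).
#' @param model_species character vector of species covered by the
#'   reconstruction resource.
#' @param cutoff relative-abundance cut-off in `[0, 1)`; species strictly
#'   below it (after mapping, before renormalisation) are removed per sample.
#' @return an `abundance_table`: list with `abundances` (species x samples,
#'   columns summing to 1) and `mapped_fraction` (per sample).
#' @export
map_filter_normalise <- function(counts, model_species, cutoff = 1e-5) {
  stopifnot(inherits(counts, "count_table"))
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  cm <- counts$counts
  total <- colSums(cm)
  mapped <- cm[rownames(cm) %in% model_species, , drop = FALSE]
  if (nrow(mapped) == 0 || any(colSums(mapped) == 0)) {
    bad <- colnames(cm)[colSums(mapped) == 0 | rep(nrow(mapped) == 0, ncol(cm))]
    stop("sample(s) with zero mappable reads: ", paste(bad, collapse = ", "))
  }
  rel <- sweep(mapped, 2, colSums(mapped), "/")
  rel[rel < cutoff] <- 0                     # per-sample low-abundance cut
  keep_reads <- mapped * (rel > 0)
  if (any(colSums(keep_reads) == 0))
    stop("sample(s) with zero mappable reads after cut-off: ",
         paste(colnames(cm)[colSums(keep_reads) == 0], collapse = ", "))
  ab <- sweep(keep_reads, 2, colSums(keep_reads), "/")
  ab <- ab[rowSums(ab) > 0, , drop = FALSE]
  structure(list(abundances = ab,
                 mapped_fraction = colSums(keep_reads) / total),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$abundances), " species x ",
      ncol(x$abundances), " samples; mean mapped_fraction ",
      round(mean(x$mapped_fraction), 4), "\n", sep = "")
  invisible(x)
}

#' Write / read an abundance table TSV
#'
#' The TSV carries a `#mapped_fraction` header row before the species rows.
#'
#' @param ab an `abundance_table`.
#' @param path file path.
#' @export
write_abundance_table <- function(ab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("species", colnames(ab$abundances)), collapse = "\t"), con)
  writeLines(paste(c("#mapped_fraction", format(ab$mapped_fraction, digits = 10)),
                   collapse = "\t"), con)
  utils::write.table(cbind(species = rownames(ab$abundances),
                           as.data.frame(ab$abundances)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  mf_line <- strsplit(lines[2], "\t")[[1]]
  stopifnot(mf_line[1] == "#mapped_fraction")
  body <- utils::read.delim(text = lines[-2], row.names = 1, check.names = FALSE)
  structure(list(abundances = as.matrix(body),
                 mapped_fraction = stats::setNames(as.numeric(mf_line[-1]),
                                                   hdr[-1])),
            class = "abundance_table")
}
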