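# Statistical analyses: PQN normalisation, detection filtering, covariate-
# adjusted robust regressions of the urine metabolome, fractional abundance
# regressions, gOTU log-ratio tests, and flux group regressions. Robust
# covariance is HC3 throughout; multiple testing is Benjamini-Hochberg
# within one screen; logs are natural.

#' Probabilistic quotient normalisation
#'
#' Divides each sample by its dilution factor: the median of its
#' metabolite-wise quotients against the reference spectrum (the median
#' across samples), taken over metabolites non-missing in both. Zeros are
#' treated as missing for factor estimation but scaled in the output.
#'
#' @param conc samples x metabolites matrix of nonnegative concentrations.
#' @return list with `conc` (normalised matrix) and `factors` (per-sample
#'   dilution factors).
#' @export
normalize_pqn <- function(conc) {
  conc <- as.matrix(conc)
  if (nrow(conc) < 2) stop("PQN needs at least two samples")
  work <- conc
  work[work == 0] <- NA
  all_missing <- rowSums(!is.na(work)) == 0
  if (any(all_missing))
    stop("sample(s) with no non-missing measurements: ",
         paste(rownames(conc)[all_missing], collapse = ", "))
  ref <- apply(work, 2, stats::median, na.rm = TRUE)
  q <- sweep(work, 2, ref, "/")
  f <- apply(q, 1, stats::median, na.rm = TRUE)
  list(conc = sweep(conc, 1, f, "/"), factors = f)
}

#' Detection filter for metabolome tables
#'
#' Keeps metabolites with non-zero measurements in strictly more than
#' `min_nonzero_frac` of the samples; in the surviving table zeros are
#' recoded as missing (`NA`), since a zero NMR quantification need not mean
#' absence.
#'
#' @param conc samples x metabolites matrix.
#' @param min_nonzero_frac detection threshold (default 0.5).
#' @return filtered matrix with zeros recoded `NA`.
#' @export
filter_detected <- function(conc, min_nonzero_frac = 0.5) {
  conc <- as.matrix(conc)
  stopifnot(min_nonzero_frac > 0, min_nonzero_frac <= 1)
  frac <- colMeans(conc != 0)
  out <- conc[, frac > min_nonzero_frac, drop = FALSE]
  out[out == 0] <- NA
  out
}

# HC3 Wald machinery shared by the regression screens. HC3 is undefined when
# a hat value equals 1 (an observation fully determines a coefficient, e.g.
# a covariate level with a single sample); fall back to HC1 there.
robust_vcov <- function(fit) {
  V <- suppressWarnings(sandwich::vcovHC(fit, type = "HC3"))
  if (!all(is.finite(V))) V <- sandwich::vcovHC(fit, type = "HC1")
  V
}

hc3_wald <- function(fit, terms) {
  V <- robust_vcov(fit)
  b <- stats::coef(fit)
  terms <- intersect(terms, names(b)[!is.na(b)])
  if (!length(terms)) return(list(stat = NA_real_, df = 0, p = NA_real_))
  idx <- match(terms, names(b))
  if (all(abs(b[idx]) < 1e-12))               # degenerate: nothing to test
    return(list(stat = 0, df = length(idx), p = 1))
  W <- tryCatch(drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx]),
                error = function(e) NA_real_)
  list(stat = W, df = length(idx),
       p = if (is.na(W)) NA_real_ else stats::pchisq(W, length(idx),
                                                     lower.tail = FALSE))
}

hc3_z <- function(fit, term) {
  ct <- lmtest::coeftest(fit, vcov. = robust_vcov(fit))
  if (!term %in% rownames(ct)) return(c(est = NA, se = NA, p = NA))
  c(est = ct[term, 1], se = ct[term, 2], p = ct[term, 4])
}

#' Covariate-adjusted group regressions of the urine metabolome
#'
#' Per metabolite: OLS of the log concentration on the study-group factor
#' plus age, sex and BMI; HC3 heteroscedasticity-robust covariance; a global
#' Wald test over the group dummies; the AD-vs-reference contrast; and
#' Benjamini-Hochberg FDR across metabolites (both for the global and the AD
#' p-values).
#'
#' @param conc samples x metabolites matrix (filtered, zeros as `NA`; see
#'   [filter_detected()]).
#' @param meta data.frame with columns `group` (factor, reference first),
#'   `age`, `sex`, `bmi`, aligned with `conc` rows.
#' @param min_obs minimal non-missing observations per metabolite (default
#'   10); metabolites below are skipped with a warning.
#' @return data.frame with one row per analysed metabolite: `coef_ad`,
#'   `se_robust`, `wald_stat`, `p_global`, `p_ad_vs_hc`, `q_global`, `q_ad`.
#' @export
metabolite_group_regression <- function(conc, meta, min_obs = 10) {
  conc <- as.matrix(conc)
  stopifnot(nrow(conc) == nrow(meta),
            all(c("group", "age", "sex", "bmi") %in% names(meta)))
  meta$group <- droplevels(as.factor(meta$group))
  glev <- levels(meta$group)
  rows <- list(); skipped <- character(0)
  for (mname in colnames(conc)) {
    y <- log(conc[, mname])
    ok <- is.finite(y)
    if (sum(ok) < min_obs) { skipped <- c(skipped, mname); next }
    d <- data.frame(y = y[ok], group = meta$group[ok], age = meta$age[ok],
                    sex = meta$sex[ok], bmi = meta$bmi[ok])
    d$group <- droplevels(d$group)
    fit <- stats::lm(y ~ group + age + sex + bmi, data = d)
    gterms <- paste0("group", setdiff(levels(d$group), levels(d$group)[1]))
    gw <- hc3_wald(fit, gterms)
    ad_term <- paste0("group", utils::tail(glev, 1))
    adz <- hc3_z(fit, ad_term)
    rows[[mname]] <- data.frame(
      metabolite = mname, n = sum(ok),
      coef_ad = adz[["est"]], se_robust = adz[["se"]],
      wald_stat = gw$stat, wald_df = gw$df, p_global = gw$p,
      p_ad_vs_hc = adz[["p"]], stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped metabolite(s) with fewer than ", min_obs,
            " observations: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_global <- stats::p.adjust(out$p_global, "BH")
  out$q_ad <- stats::p.adjust(out$p_ad_vs_hc, "BH")
  rownames(out) <- NULL
  out
}

#' Fractional regressions of relative microbial abundances
#'
#' Per taxon: quasi-binomial GLM with logit mean link of the relative
#' abundance on the health-status group, correcting for categorical APOE
#' genotype; HC3 sandwich standard errors. Taxa present (abundance > 0) in
#' fewer than `min_presence` of the samples are excluded first; constant
#' taxa are skipped.
#'
#' @param ab an `abundance_table` or species x samples matrix in `[0, 1]`.
#' @param meta data.frame aligned with samples, with columns `group`
#'   (factor, reference first) and `apoe`.
#' @param min_presence presence fraction below which a taxon is excluded
#'   (default 0.5: "present in at least half of the samples" is kept).
#' @return data.frame per analysed taxon: group coefficient (logit scale),
#'   robust SE, p, BH q, and direction (`"increased"`/`"decreased"` in the
#'   non-reference group).
#' @export
fractional_abundance_regression <- function(ab, meta, min_presence = 0.5) {
  m <- if (inherits(ab, "abundance_table")) ab$abundances else as.matrix(ab)
  stopifnot(ncol(m) == nrow(meta), all(c("group", "apoe") %in% names(meta)))
  meta$group <- droplevels(as.factor(meta$group))
  gterm <- paste0("group", utils::tail(levels(meta$group), 1))
  presence <- rowMeans(m > 0)
  m <- m[presence >= min_presence, , drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (tx in rownames(m)) {
    y <- m[tx, ]
    if (stats::sd(y) == 0) { skipped <- c(skipped, tx); next }
    d <- data.frame(y = y, group = meta$group, apoe = as.factor(meta$apoe))
    fit <- suppressWarnings(stats::glm(y ~ group + apoe, data = d,
                                       family = stats::quasibinomial("logit")))
    z <- hc3_z(fit, gterm)
    rows[[tx]] <- data.frame(
      taxon = tx, coef_group = z[["est"]], se_robust = z[["se"]],
      p = z[["p"]],
      direction = if (is.na(z[["est"]])) NA_character_ else
        if (z[["est"]] > 0) "increased" else "decreased",
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped constant taxon/taxa: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' gOTU log-ratio test between groups
#'
#' Per sample, computes `log(sum of counts over the increased species /
#' sum over the decreased species)` and compares groups with a Welch t-test.
#' Samples with a zero numerator or denominator sum are excluded and
#' reported (set `pseudocount = 1` to add one count to both sums instead).
#'
#' @param counts a species-level `count_table` or counts matrix.
#' @param up_set,down_set disjoint, nonempty species sets.
#' @param group two-level factor aligned with samples.
#' @param pseudocount count added to both sums (default 0 = exclusion mode).
#' @return list with `log_ratios`, `excluded` (sample ids), `statistic`,
#'   `p_value`, `estimate` (group means).
#' @export
logratio_test <- function(counts, up_set, down_set, group, pseudocount = 0) {
  cm <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (!length(up_set) || !length(down_set)) stop("both species sets must be nonempty")
  if (length(intersect(up_set, down_set))) stop("species sets must be disjoint")
  miss <- setdiff(c(up_set, down_set), rownames(cm))
  if (length(miss)) stop("species not in table: ", paste(miss, collapse = ", "))
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2, length(group) == ncol(cm))
  upsum <- colSums(cm[up_set, , drop = FALSE]) + pseudocount
  dnsum <- colSums(cm[down_set, , drop = FALSE]) + pseudocount
  ok <- upsum > 0 & dnsum > 0
  lr <- log(upsum[ok] / dnsum[ok])
  tt <- stats::t.test(lr ~ group[ok])
  list(log_ratios = lr, excluded = colnames(cm)[!ok],
       statistic = unname(tt$statistic), p_value = tt$p.value,
       estimate = tt$estimate)
}

#' Group regressions of predicted secretion fluxes
#'
#' Per flux variable: OLS of the flux on health status, correcting for
#' categorical APOE genotype and for sex (the host models being
#' sex-specific); HC3 robust standard errors. Constant fluxes are skipped;
#' aliased (rank-deficient) group terms are flagged.
#'
#' @param flux_table data.frame or matrix, samples x flux variables.
#' @param meta data.frame with columns `group`, `apoe`, `sex`.
#' @return data.frame per flux variable with coefficient, robust SE, p, q.
#' @export
flux_group_regression <- function(flux_table, meta) {
  fm <- as.matrix(flux_table)
  stopifnot(nrow(fm) == nrow(meta),
            all(c("group", "apoe", "sex") %in% names(meta)))
  meta$group <- droplevels(as.factor(meta$group))
  gterm <- paste0("group", utils::tail(levels(meta$group), 1))
  rows <- list(); skipped <- character(0)
  for (v in colnames(fm)) {
    y <- fm[, v]
    if (stats::sd(y) == 0) { skipped <- c(skipped, v); next }
    d <- data.frame(y = y, group = meta$group, apoe = as.factor(meta$apoe),
                    sex = as.factor(meta$sex))
    fit <- stats::lm(y ~ group + apoe + sex, data = d)
    # any aliased term means group and covariates are not separable
    aliased <- anyNA(stats::coef(fit))
    if (isTRUE(aliased)) {
      warning("group term aliased (rank-deficient design) for ", v)
      rows[[v]] <- data.frame(variable = v, coef_group = NA_real_,
                              se_robust = NA_real_, p = NA_real_,
                              note = "aliased", stringsAsFactors = FALSE)
      next
    }
    z <- hc3_z(fit, gterm)
    rows[[v]] <- data.frame(variable = v, coef_group = z[["est"]],
                            se_robust = z[["se"]], p = z[["p"]], note = "",
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped constant flux variable(s): ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Divide a metabolome table by its creatinine column
#'
#' Convenience helper for raw tables; the main pipeline assumes
#' creatinine-normalised input.
#'
#' @param conc samples x metabolites matrix including a `creatinine` column.
#' @param creatinine column name (default `"creatinine"`).
#' @return matrix of creatinine ratios, creatinine column removed.
#' @export
creatinine_normalise <- function(conc, creatinine = "creatinine") {
  conc <- as.matrix(conc)
  if (!creatinine %in% colnames(conc)) stop("no creatinine column")
  cr <- conc[, creatinine]
  if (any(cr <= 0)) stop("creatinine must be positive in all samples")
  sweep(conc[, setdiff(colnames(conc), creatinine), drop = FALSE], 1, cr, "/")
}

#' Cohort descriptive comparison
#'
#' One-call utility: Welch t-tests for metric covariates and Fisher's exact
#' test for categorical ones, between two groups.
#'
#' @param meta data.frame of covariates plus a `group` column.
#' @param metric,categorical column names to test.
#' @return data.frame of variable, test, p-value.
#' @export
cohort_comparison <- function(meta, metric = c("age", "bmi"),
                              categorical = c("sex", "apoe")) {
  g <- droplevels(as.factor(meta$group))
  stopifnot(nlevels(g) == 2)
  rows <- c(
    lapply(intersect(metric, names(meta)), function(v)
      data.frame(variable = v, test = "welch",
                 p = stats::t.test(meta[[v]] ~ g)$p.value)),
    lapply(intersect(categorical, names(meta)), function(v)
      data.frame(variable = v, test = "fisher",
                 p = stats::fisher.test(table(meta[[v]], g))$p.value)))
  do.call(rbind, rows)
}
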