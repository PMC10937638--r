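# Metabolome normalisation and regressions, abundance statistics, log-ratio
# test, flux regressions.

meta4 <- function(n_per = c(HC = 12, SCD = 12, MCI = 12, AD = 12), seed = 1) {
  set.seed(seed)
  n <- sum(n_per)
  data.frame(group = factor(rep(names(n_per), n_per), levels = names(n_per)),
             age = rnorm(n, 70, 6), sex = sample(c("male", "female"), n, TRUE),
             bmi = rnorm(n, 26, 4))
}

test_that("PQN leaves identical samples unchanged and undoes known dilutions", {
  set.seed(3)
  base <- matrix(rlnorm(5 * 20, 1, 0.5), 5, 20, byrow = TRUE,
                 dimnames = list(paste0("s", 1:5), paste0("m", 1:20)))
  base[] <- rep(base[1, ], each = 5)         # identical samples
  pq <- normalize_pqn(base)
  expect_equal(pq$factors, setNames(rep(1, 5), rownames(base)))
  expect_equal(pq$conc, base)

  # one sample diluted twofold is restored exactly
  sc <- base; sc[3, ] <- sc[3, ] * 2
  pq2 <- normalize_pqn(sc)
  expect_equal(unname(pq2$factors[3]), 2)
  expect_equal(pq2$conc[3, ], base[3, ])

  # planted per-sample dilution factors recovered within 5% at 50 metabolites
  set.seed(9)
  profile <- rlnorm(50, 1, 0.8)
  fac <- runif(30, 0.5, 2)
  noisy <- outer(fac, profile) * matrix(rlnorm(30 * 50, 0, 0.05), 30, 50)
  dimnames(noisy) <- list(paste0("s", 1:30), paste0("m", 1:50))
  pq3 <- normalize_pqn(noisy)
  rel <- pq3$factors / fac
  rel <- rel / median(rel)                   # factors identified up to scale
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("PQN is scale-equivariant per sample and rejects empty samples", {
  set.seed(5)
  m <- matrix(rlnorm(4 * 10), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  # the sample already dominates every metabolite, so further scaling leaves
  # the reference spectrum (and hence its normalised row) unchanged
  m[2, ] <- m[2, ] + apply(m, 2, max)
  k <- 3.7
  m2 <- m; m2[2, ] <- m2[2, ] * k
  expect_equal(normalize_pqn(m2)$conc[2, ], normalize_pqn(m)$conc[2, ],
               tolerance = 1e-12)
  m3 <- m; m3[1, ] <- 0
  expect_error(normalize_pqn(m3), "no non-missing")
})

test_that("the detection filter uses the strictly-more-than rule and recodes zeros", {
  conc <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  conc[1:6, "a"] <- 0                        # 40% non-zero -> removed
  conc[1:5, "b"] <- 0                        # exactly 50% -> removed
  conc[1, "c"] <- 0                          # 90% -> kept, zero recoded NA
  out <- filter_detected(conc, 0.5)
  expect_identical(colnames(out), "c")
  expect_true(is.na(out[1, "c"]))
  expect_equal(sum(is.na(out)), 1)
  # survivor count on planted detection rates equals direct counting
  set.seed(11)
  rates <- runif(49, 0.2, 0.95)
  big <- sapply(rates, function(r) ifelse(runif(200) < r, rlnorm(200), 0))
  colnames(big) <- sprintf("m%02d", 1:49)
  expect_equal(ncol(filter_detected(big, 0.5)),
               sum(colMeans(big != 0) > 0.5))
})

test_that("group regressions report robust Wald tests and handle degenerate input", {
  md <- meta4()
  conc <- matrix(rlnorm(nrow(md) * 3, 1, 0.4), nrow(md), 3,
                 dimnames = list(NULL, c("flat", "shifted", "sparse")))
  conc[, "flat"] <- 5                         # constant response
  conc[md$group == "AD", "shifted"] <- conc[md$group == "AD", "shifted"] * exp(-1.5)
  conc[-(1:5), "sparse"] <- 0                 # too few observations
  expect_warning(res <- metabolite_group_regression(conc, md), "skipped")
  expect_setequal(res$metabolite, c("flat", "shifted"))
  expect_equal(res$p_global[res$metabolite == "flat"], 1, tolerance = 1e-6)
  expect_lt(res$p_ad_vs_hc[res$metabolite == "shifted"], 0.01)
  expect_lt(res$coef_ad[res$metabolite == "shifted"], 0)
  expect_true(all(res$q_ad >= res$p_ad_vs_hc - 1e-12))
})

test_that("regression output is invariant to sample and metabolite order", {
  md <- meta4(seed = 2)
  set.seed(21)
  conc <- matrix(rlnorm(nrow(md) * 4, 1, 0.5), nrow(md), 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  r1 <- metabolite_group_regression(conc, md)
  perm <- sample(nrow(md))
  r2 <- metabolite_group_regression(conc[perm, c(3, 1, 4, 2)], md[perm, ])
  r2 <- r2[match(r1$metabolite, r2$metabolite), ]
  expect_equal(r1$coef_ad, r2$coef_ad, tolerance = 1e-9)
  expect_equal(r1$p_global, r2$p_global, tolerance = 1e-9)
})

test_that("fractional regression filters on presence and finds planted shifts", {
  cfg <- synth_config(seed = 7, n_samples_per_group = 24,
                      n_planted_up = 5, n_planted_down = 0, fold_change = 2)
  ad <- make_abundance_counts(cfg, n_taxa = 40)
  sp <- collapse_to_species(ad$counts)
  ab <- map_filter_normalise(sp, rownames(sp$counts))
  res <- suppressWarnings(fractional_abundance_regression(
    ab, ad$meta[, c("group", "apoe")]))
  planted <- ad$truth$species[ad$truth$direction == "up"]
  hit <- res[res$taxon %in% planted, ]
  expect_gte(sum(hit$p < 0.05 & hit$direction == "increased"), 4)

  # presence filter: a taxon present in 45% of samples is excluded
  m <- ab$abundances
  m["synthsp40", ] <- 0
  m["synthsp40", 1:21] <- 1e-4               # 21/48 ~= 44%
  m <- sweep(m, 2, colSums(m), "/")
  res2 <- suppressWarnings(fractional_abundance_regression(
    m, ad$meta[, c("group", "apoe")]))
  expect_false("synthsp40" %in% res2$taxon)

  # constant taxa are skipped with a warning
  m2 <- ab$abundances
  m2["synthsp39", ] <- 0.01
  expect_warning(res3 <- fractional_abundance_regression(
    m2, ad$meta[, c("group", "apoe")]), "constant")
  expect_false("synthsp39" %in% res3$taxon)
})

test_that("log-ratio test behaves at the null and under planted shifts", {
  set.seed(23)
  cm <- matrix(rpois(10 * 40, 200), 10, 40,
               dimnames = list(paste0("sp", 1:10), paste0("s", 1:40)))
  grp <- rep(c("HC", "AD"), each = 20)
  up <- paste0("sp", 1:3); dn <- paste0("sp", 4:6)
  null_res <- logratio_test(cm, up, dn, grp)
  expect_gt(null_res$p_value, 0.001)
  # equal sums in every sample give all-zero log-ratios
  cm2 <- cm; cm2[dn, ] <- cm2[up, ]
  eq <- logratio_test(cm2, up, dn, grp)
  expect_equal(unname(eq$log_ratios), rep(0, 40))
  # a planted 3x shift in the AD group is highly significant
  cm3 <- cm; cm3[up, grp == "AD"] <- cm3[up, grp == "AD"] * 3
  expect_lt(logratio_test(cm3, up, dn, grp)$p_value, 0.01)
  # zero-denominator samples are excluded and reported
  cm4 <- cm; cm4[dn, 1] <- 0
  zr <- logratio_test(cm4, up, dn, grp)
  expect_identical(zr$excluded, "s1")
  expect_equal(length(zr$log_ratios), 39)
  # pseudocount mode keeps every sample
  zr2 <- logratio_test(cm4, up, dn, grp, pseudocount = 1)
  expect_equal(length(zr2$log_ratios), 40)
  expect_error(logratio_test(cm, up, up, grp), "disjoint")
})

test_that("flux regressions recover planted group differences and flag aliasing", {
  set.seed(29)
  n <- 48
  meta <- data.frame(group = factor(rep(c("HC", "AD"), each = n / 2)),
                     apoe = sample(c("E33", "E34", "E44"), n, TRUE),
                     sex = sample(c("male", "female"), n, TRUE))
  flux <- cbind(shifted = rnorm(n, 100, 10) + 20 * (meta$group == "AD"),
                flat = rep(3, n))
  expect_warning(res <- flux_group_regression(flux, meta), "constant")
  expect_false("flat" %in% res$variable)
  expect_equal(res$coef_group[res$variable == "shifted"], 20, tolerance = 10)
  expect_lt(res$p[res$variable == "shifted"], 0.001)
  # sex fully confounded with group: aliased, flagged, no exception
  meta2 <- meta; meta2$sex <- ifelse(meta2$group == "AD", "male", "female")
  flux2 <- cbind(v = rnorm(n))
  expect_warning(res2 <- flux_group_regression(flux2, meta2), "aliased")
  expect_identical(res2$note, "aliased")
  expect_true(is.na(res2$coef_group))
})

test_that("creatinine normalisation and cohort comparison utilities work", {
  conc <- cbind(creatinine = c(2, 4), formate = c(10, 10))
  out <- creatinine_normalise(conc)
  expect_equal(unname(out[, "formate"]), c(5, 2.5))
  expect_error(creatinine_normalise(cbind(formate = 1:2)), "creatinine")
  md <- data.frame(group = rep(c("a", "b"), each = 10),
                   age = rnorm(20, 70), sex = rep(c("m", "f"), 10),
                   bmi = rnorm(20, 26), apoe = rep(c("E33", "E34"), 10))
  cc <- cohort_comparison(md)
  expect_setequal(cc$variable, c("age", "bmi", "sex", "apoe"))
  expect_true(all(cc$p >= 0 & cc$p <= 1))
})
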