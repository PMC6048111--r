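# build a minimal clinical frame realising given 2x2 counts for one covariate
clinical_from_counts <- function(covariate, levels, counts) {
  # counts: matrix rows = levels, cols = c(absent, present)
  n <- sum(counts)
  values <- rep(rep(levels, 2), as.vector(counts))
  fusion <- rep(rep(c(FALSE, TRUE), each = length(levels)),
                as.vector(counts))
  cl <- data.frame(
    sample = sprintf("T%03d", seq_len(n)), age = 60, size = 5, sex = "M",
    location = "right", histology = "moderately", invasion_depth = "T3",
    perineural = 0L, lymphovascular = 0L, lymph_node = 0L,
    msi_status = "MSS", os_months = 50, os_event = 0L,
    stringsAsFactors = FALSE)
  cl[[covariate]] <- values
  list(clinical = cl, fusion = fusion)
}

test_that("MSI association on the published counts is significant", {
  d <- clinical_from_counts("msi_status", c("MSS", "MSI-H"),
                            matrix(c(113, 15, 13, 6), 2))
  res <- contingency_association(d$clinical, "msi_status", d$fusion)
  expect_equal(res$test, "fisher")  # an expected cell is below 5
  expect_lt(res$p_value, 0.05)
  expect_equal(unname(res$table[, "present"]), c(13, 6))
  expect_equal(unname(res$row_pct[, "present"]), c(10.3, 28.6))
})

test_that("balanced and near-balanced tables are not significant", {
  d <- clinical_from_counts("sex", c("M", "F"),
                            matrix(c(50, 50, 50, 50), 2))
  expect_equal(contingency_association(d$clinical, "sex", d$fusion)$p_value,
               1)
  # the published sex table is non-significant
  d2 <- clinical_from_counts("sex", c("M", "F"),
                             matrix(c(68, 60, 9, 10), 2))
  res2 <- contingency_association(d2$clinical, "sex", d2$fusion)
  expect_equal(res2$test, "chisq")
  expect_gt(res2$p_value, 0.05)
})

test_that("covariates collapse to their conventional reporting groups", {
  cl <- clinical_from_counts("histology",
                             c("well", "moderately", "poorly", "mucinous"),
                             matrix(rep(3, 8), 4))$clinical
  g <- clinical_grouping(cl, "histology")
  expect_equal(levels(g), c("well+moderately", "poorly+mucinous"))
  expect_equal(sum(g == "well+moderately"), 12)
  cl$invasion_depth <- rep(c("T1", "T2", "T3", "T4"), 6)
  expect_equal(sum(clinical_grouping(cl, "invasion_depth") == "T1+T2"), 12)
  cl$msi_status <- rep(c("MSS", "MSI-L", "MSI-H"), 8)
  expect_equal(sum(clinical_grouping(cl, "msi_status") == "MSS+MSI-L"), 16)
  # a single-level covariate degenerates with a warning
  cl$location <- "right"
  expect_warning(res <- contingency_association(cl, "location",
                                                rep(c(TRUE, FALSE), 12)),
                 "single")
  expect_true(is.na(res$p_value))
})

test_that("continuous associations report group means and honour variance mode", {
  d <- clinical_from_counts("sex", c("M", "F"), matrix(c(30, 30, 8, 8), 2))
  set.seed(41)
  d$clinical$size <- ifelse(d$fusion, rnorm(76, 4.8, 0.8),
                            rnorm(76, 5.8, 2.5))
  res_s <- continuous_association(d$clinical, "size", d$fusion,
                                  var_equal = TRUE)
  res_w <- continuous_association(d$clinical, "size", d$fusion,
                                  var_equal = FALSE)
  expect_equal(res_s$group_stats$n, c(60, 16))
  expect_false(identical(res_s$p_value, res_w$p_value))
  # identical groups: p = 1 (same values in both groups, and the
  # degenerate all-constant case)
  d2 <- clinical_from_counts("sex", c("M", "F"), matrix(c(5, 5, 5, 5), 2))
  d2$clinical$size <- rep(c(3.1, 4.2, 5.3, 6.4, 7.5), 4)
  expect_equal(continuous_association(d2$clinical, "size",
                                      d2$fusion)$p_value, 1)
  d$clinical$size <- rep(5, 76)
  expect_equal(continuous_association(d$clinical, "size",
                                      d$fusion)$p_value, 1)
})

test_that("planted tumour-size difference is recovered from generated cohorts", {
  b <- generate(sim_config(seed = 5, n_genes = 30L, artifact_rate = 0.5,
                           noise_variants_per_patient = 1))
  carriers <- b$manifest$patients$carrier
  res <- continuous_association(b$clinical, "size",
                                stats::setNames(carriers,
                                                b$manifest$patients$sample))
  diff <- res$group_stats$mean[1] - res$group_stats$mean[2]
  se <- sqrt(sum(res$group_stats$se^2))
  expect_lt(abs(diff - 1.0), 2 * se)  # planted difference: 5.8 - 4.8 cm
})

test_that("product-limit estimates match a hand-computed worked example", {
  # five patients, deaths at 2, 4, 5; censored at 3 and 6
  cl <- data.frame(sample = sprintf("T%d", 1:5), age = 60, size = 5,
                   sex = "M", location = "right", histology = "well",
                   invasion_depth = "T3", perineural = 0L,
                   lymphovascular = 0L, lymph_node = 0L, msi_status = "MSS",
                   os_months = c(2, 3, 4, 5, 6),
                   os_event = c(1L, 0L, 1L, 1L, 0L),
                   stringsAsFactors = FALSE)
  res <- survival_comparison(rbind(cl, cl), c(rep(FALSE, 5), rep(TRUE, 5)))
  sf <- summary(res$fit)
  grp1 <- sf$surv[sf$strata == levels(sf$strata)[1]]
  # S(2) = 4/5; S(4) = 4/5 * 2/3; S(5) = 4/5 * 2/3 * 1/2
  expect_equal(grp1, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
  # identical groups: log-rank p = 1
  expect_equal(res$p_value, 1)
  expect_equal(res$means$rmean[1], res$means$rmean[2])
})

test_that("log-rank p-values are uniform under a null hazard ratio", {
  set.seed(43)
  ps <- replicate(200, {
    n <- 40
    cl <- data.frame(sample = sprintf("T%d", 1:n), age = 60, size = 5,
                     sex = "M", location = "right", histology = "well",
                     invasion_depth = "T3", perineural = 0L,
                     lymphovascular = 0L, lymph_node = 0L,
                     msi_status = "MSS",
                     os_months = 0, os_event = 0L,
                     stringsAsFactors = FALSE)
    t_ev <- rexp(n, 0.02)
    t_cn <- runif(n, 10, 100)
    cl$os_months <- round(pmin(t_ev, t_cn), 1)
    cl$os_event <- as.integer(t_ev <= t_cn)
    suppressWarnings(
      survival_comparison(cl, sample(c(TRUE, FALSE), n, TRUE))$p_value)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("no observed events leaves the comparison undefined with warning", {
  cl <- data.frame(sample = sprintf("T%d", 1:6), age = 60, size = 5,
                   sex = "M", location = "right", histology = "well",
                   invasion_depth = "T3", perineural = 0L,
                   lymphovascular = 0L, lymph_node = 0L, msi_status = "MSS",
                   os_months = c(10, 20, 30, 40, 50, 60), os_event = 0L,
                   stringsAsFactors = FALSE)
  expect_warning(res <- survival_comparison(cl, rep(c(TRUE, FALSE), 3)),
                 "no events")
  expect_true(is.na(res$p_value))
})
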