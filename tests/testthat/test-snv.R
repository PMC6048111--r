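mk_var <- function(sample = "P1", gene = "G1", pos = 100L, depth = 100L,
                   alt = 30L, effect = "non-synonymous", region = "exon",
                   fs = 2, qd = 10, maf = NA_real_, chrom = "c1",
                   ref = "A", altb = "G") {
  data.frame(sample = sample, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = altb, total_depth = depth, alt_depth = alt,
             effect = effect, region = region, fs = fs, qd = qd,
             pop_maf = maf, stringsAsFactors = FALSE)
}

test_that("each hard filter removes its violator, boundaries inclusive", {
  vars <- rbind(
    mk_var(pos = 1L),                                     # clean
    mk_var(pos = 2L, depth = 9L, alt = 5L),               # depth
    mk_var(pos = 3L, alt = 1L),                           # alt depth
    mk_var(pos = 4L, depth = 400L, alt = 3L),             # VAF < 3%
    mk_var(pos = 5L, region = "intron"),                  # region
    mk_var(pos = 6L, effect = "other"),                   # effect class
    mk_var(pos = 7L, maf = 0.02),                         # germline MAF
    mk_var(pos = 8L, fs = 45),                            # strand bias
    mk_var(pos = 9L, qd = 1),                             # qual by depth
    mk_var(pos = 10L)                                     # clean
  )
  res <- filter_snvs(vars, NULL)
  expect_equal(nrow(res$survivors), 2)
  expect_equal(res$survivors$pos, c(1L, 10L))
  att <- stats::setNames(res$attrition$removed, res$attrition$filter)
  expect_equal(att[["depth"]], 1L)
  expect_equal(att[["alt_depth"]], 1L)
  expect_equal(att[["vaf"]], 1L)
  expect_equal(att[["exonic"]], 1L)
  expect_equal(att[["effect"]], 1L)
  expect_equal(att[["pop_maf"]], 1L)
  expect_equal(att[["strand_quality"]], 2L)
  # conservation
  expect_equal(res$n_input,
               nrow(res$survivors) + sum(res$attrition$removed) +
                 nrow(res$unevaluable))
  # boundary: depth 10, alt 2, VAF exactly 3%, MAF exactly 1% all pass
  edge <- mk_var(depth = 100L, alt = 3L, maf = 0.01)
  expect_equal(nrow(filter_snvs(edge, NULL)$survivors), 1)
  exact10 <- mk_var(depth = 10L, alt = 2L)
  expect_equal(nrow(filter_snvs(exact10, NULL)$survivors), 1)
})

test_that("matched-normal sites are excluded and NA fields set aside", {
  somatic <- rbind(mk_var(pos = 1L), mk_var(pos = 2L))
  normal <- mk_var(sample = "N1", pos = 2L)
  res <- filter_snvs(somatic, normal)
  expect_equal(res$survivors$pos, 1L)
  att <- stats::setNames(res$attrition$removed, res$attrition$filter)
  expect_equal(att[["matched_normal"]], 1L)
  # a variant missing a needed score is unevaluable, not silently dropped
  res2 <- filter_snvs(rbind(mk_var(pos = 1L),
                            mk_var(pos = 2L, fs = NA_real_)), NULL)
  expect_equal(nrow(res2$unevaluable), 1)
  expect_equal(res2$n_input, nrow(res2$survivors) +
                 sum(res2$attrition$removed) + nrow(res2$unevaluable))
})

test_that("attrition conservation holds on generated variant tables", {
  for (seed in 1:3) {
    b <- generate(small_sim_cfg(seed, noise_variants_per_patient = 3))
    res <- filter_snvs(b$variants, b$normal_variants)
    expect_equal(res$n_input, nrow(res$survivors) +
                   sum(res$attrition$removed) + nrow(res$unevaluable))
  }
})

panels3 <- data.frame(gene = c("ONC1", "ONC2", "SUP1"),
                      panel = c("oncogene", "oncogene", "suppressor"),
                      stringsAsFactors = FALSE)

test_that("mutation matrix collapses variants per patient and gene", {
  vars <- rbind(mk_var(sample = "P1", gene = "ONC1", pos = 1L),
                mk_var(sample = "P1", gene = "ONC1", pos = 2L),
                mk_var(sample = "P1", gene = "ONC1", pos = 3L))
  mm <- build_matrix(vars, c("P1", "P2"), panels3, "P2")
  expect_equal(unname(mm$calls["P1", "ONC1"]), 1L)
  expect_equal(sum(mm$calls), 1L)
  expect_equal(unname(mm$fusion), c(FALSE, TRUE))
  mm0 <- build_matrix(vars[0, ], c("P1", "P2"), panels3, character(0))
  expect_true(all(mm0$calls == 0))
})

test_that("a cohort with a single fusion+oncogene patient mirrors the design", {
  # 19 patients; oncogene-panel mutations in the one exceptional carrier and
  # in many non-carriers
  pts <- sprintf("P%02d", 1:19)
  carriers <- pts[1:5]
  vars <- rbind(mk_var(sample = "P01", gene = "ONC1"),
                do.call(rbind, lapply(pts[6:15], function(p)
                  mk_var(sample = p, gene = "ONC2"))))
  mm <- build_matrix(vars, pts, panels3, carriers)
  onc_hits <- rowSums(mm$calls[, c("ONC1", "ONC2")]) > 0
  expect_equal(sum(onc_hits & mm$fusion), 1)
  res <- exclusivity_test(mm, n_perm = 2000, seed = 5)
  expect_equal(res$statistic, 1L)
  expect_lt(res$p_value, 0.2)
})

test_that("exclusivity test degenerates gracefully and is reproducible", {
  mm <- build_matrix(mk_var(sample = "P1", gene = "ONC1"),
                     c("P1", "P2"), panels3, character(0))
  expect_warning(res <- exclusivity_test(mm, n_perm = 100), "no fusion")
  expect_equal(res$p_value, 1)
  # seeded permutation stream is reproducible and reorder-invariant
  set.seed(33)
  pts <- sprintf("P%02d", 1:30)
  vars <- do.call(rbind, lapply(sample(pts, 12), function(p)
    mk_var(sample = p, gene = "ONC1")))
  mm1 <- build_matrix(vars, pts, panels3, pts[1:6])
  p1 <- exclusivity_test(mm1, n_perm = 500, seed = 7)$p_value
  p2 <- exclusivity_test(mm1, n_perm = 500, seed = 7)$p_value
  expect_identical(p1, p2)
  perm <- sample(pts)
  mm2 <- build_matrix(vars, perm, panels3, pts[1:6])
  p3 <- exclusivity_test(mm2, n_perm = 20000, seed = 7)$p_value
  expect_equal(p3, p1, tolerance = 0.15)
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  # 6-patient toy: enumerate all C(6, k) fusion-label placements
  pts <- sprintf("P%d", 1:6)
  vars <- do.call(rbind, lapply(c("P1", "P2", "P3"), function(p)
    mk_var(sample = p, gene = "ONC1")))
  for (k in c(2, 3)) {
    carriers <- pts[seq_len(k)]
    mm <- build_matrix(vars, pts, panels3, carriers)
    mut <- rowSums(mm$calls[, c("ONC1", "ONC2"), drop = FALSE]) > 0
    obs <- sum(mut[pts %in% carriers])
    combos <- utils::combn(6, k)
    stats_all <- apply(combos, 2, function(ii) sum(mut[ii]))
    p_exact <- mean(stats_all <= obs)
    n_perm <- 4000
    p_hat <- exclusivity_test(mm, n_perm = n_perm, seed = 11)$p_value
    mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(p_hat - p_exact), 3 * mc_se + 2 / n_perm)
  }
})
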