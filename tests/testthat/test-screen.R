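test_that("mid distance reproduces published breakpoint separations", {
  expect_equal(compute_mid_distance("chr2", 29446394, "chr2", 37143221),
               7696827)
  expect_equal(compute_mid_distance("chr13", 26923209, "chr13", 27999075),
               1075866)
  # symmetric, zero at identity, undefined across chromosomes
  expect_equal(compute_mid_distance("chr13", 27999075, "chr13", 26923209),
               1075866)
  expect_equal(compute_mid_distance("chrX", 100, "chrX", 100), 0)
  expect_true(is.na(compute_mid_distance("chr1", 500, "chr2", 500)))
})

test_that("normal-tissue exclusion matches on the ordered gene pair", {
  tumour <- mk_call(donor = "GA", acceptor = "GB")
  normals <- rbind(mk_call(sample = "N1", donor = "GA", acceptor = "GB"),
                   mk_call(sample = "N2", donor = "GX", acceptor = "GY"))
  expect_false(absent_in_normal(tumour, normals))
  expect_true(absent_in_normal(tumour, NULL))
  expect_true(absent_in_normal(tumour, normals[0, ]))
  # opposite orientation in normal: absent under the ordered-pair default,
  # present when orientation-insensitive matching is requested
  flipped <- mk_call(sample = "N1", donor = "GB", acceptor = "GA")
  expect_true(absent_in_normal(tumour, flipped))
  expect_false(absent_in_normal(tumour, flipped, orientation_sensitive = FALSE))
})

test_that("filter cascade audits every call and applies inclusive thresholds", {
  # six calls: one failing each filter, two passing everything
  calls <- rbind(
    mk_call(donor = "G01", acceptor = "G02", dp = 0L, ap = 0L),          # pass
    mk_call(donor = "G03", acceptor = "G04", dp = 1L, ap = 2L),          # frame
    mk_call(donor = "G05", acceptor = "G06", dp = 0L, ap = 0L),          # normal
    mk_call(donor = "G07", acceptor = "G08", dp = 0L, ap = 0L,
            spanning = 9L),                                              # reads
    mk_call(donor = "G09", acceptor = "G10", dp = 0L, ap = 0L,
            pos2 = 100999L),                                             # dist
    mk_call(donor = "G11", acceptor = "G12", dp = 2L, ap = 2L,
            chrom2 = "c9", pos2 = 500L)                                  # pass
  )
  normals <- mk_call(sample = "N1", donor = "G05", acceptor = "G06",
                     dp = 0L, ap = 0L)
  sc <- apply_screen(calls, normals)
  expect_equal(sum(sc$status == "survivor"), 2)
  expect_equal(sc$status[c(1, 6)], c("survivor", "survivor"))
  rejected <- sc$reject_reasons[sc$status == "rejected"]
  expect_setequal(rejected, c("in_frame", "absent_in_normal", "spanning",
                              "distance"))
  # conservation of counts
  expect_equal(sum(table(sc$status)), nrow(calls))
  # boundary inclusivity: spanning exactly 10 and distance exactly 100 kb pass
  edge <- rbind(mk_call(spanning = 10L, dp = 0L, ap = 0L, pos1 = 1000L,
                        pos2 = 101000L),
                mk_call(spanning = 9L, dp = 0L, ap = 0L, pos1 = 1000L,
                        pos2 = 100999L))
  sce <- apply_screen(edge, NULL)
  expect_equal(sce$status, c("survivor", "rejected"))
  expect_true(sce$spanning_pass[1] && sce$distance_pass[1])
  expect_false(sce$spanning_pass[2] || sce$distance_pass[2])
  # interchromosomal calls bypass the distance filter
  inter <- mk_call(chrom2 = "c9", pos2 = 5L, dp = 0L, ap = 0L)
  expect_true(apply_screen(inter, NULL)$distance_pass)
})

test_that("calls with genes missing from transcript models are unresolvable", {
  tx <- toy_tx_2exon(gene = "GA")
  txs <- structure(list(GA.t1 = tx), class = "transcript_set")
  calls <- rbind(mk_call(donor = "GA", acceptor = "GZ", pos1 = 125L),
                 mk_call(donor = "GQ", acceptor = "GA", pos2 = 125L))
  ann <- annotate_frames(calls, txs)
  expect_true(all(is.na(ann$in_frame)))
  expect_true(all(ann$frame_reason == "gene not in transcript models"))
  sc <- apply_screen(ann, NULL)
  expect_true(all(sc$status == "unresolvable"))
})

test_that("screen thresholds are monotone and filters order-invariant", {
  for (seed in 1:5) {
    b <- generate(small_sim_cfg(seed))
    calls <- annotate_frames(b$calls[[1]], b$transcripts)
    base <- apply_screen(calls, b$normal_calls)
    key <- function(sc) with(sc[sc$status == "survivor", ],
                             paste(sample_id, donor_gene, acceptor_gene,
                                   pos1, pos2))
    # raising either threshold never adds survivors
    for (cfg in list(screen_config(min_spanning = 15),
                     screen_config(min_intrachrom_distance = 200000))) {
      tight <- apply_screen(calls, b$normal_calls, cfg)
      expect_true(all(key(tight) %in% key(base)))
    }
    # row order never changes the survivor set
    shuf <- calls[sample(nrow(calls)), ]
    expect_setequal(key(apply_screen(shuf, b$normal_calls)), key(base))
    # conservation
    expect_equal(sum(table(base$status)), nrow(calls))
  }
})
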