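test_that("genomic-to-CDS conversion is strand-aware and exon-correct", {
  plus <- toy_tx_2exon("+")
  expect_equal(genomic_to_cds(plus, plus$cds_start)$offset, 0L)
  # exon1 contributes 10 coding bases; 3rd base of exon2's CDS -> offset 12
  expect_equal(genomic_to_cds(plus, 203L)$offset, 12L)
  expect_equal(genomic_to_cds(plus, plus$cds_end)$offset, 29L)
  minus <- toy_tx_2exon("-")
  expect_equal(genomic_to_cds(minus, minus$cds_end)$offset, 0L)
  expect_equal(genomic_to_cds(minus, minus$cds_start)$offset, 29L)
  # off-CDS classification
  expect_equal(genomic_to_cds(plus, 150L)$status, "intron")
  expect_equal(genomic_to_cds(plus, 150L)$nearest_exon, 1L)
  expect_equal(genomic_to_cds(plus, 110L)$status, "utr5")
  expect_equal(genomic_to_cds(plus, 230L)$status, "utr3")
  expect_equal(genomic_to_cds(minus, 110L)$status, "utr3")
  expect_equal(genomic_to_cds(plus, 50L)$status, "outside")
})

test_that("cds_to_genomic inverts genomic_to_cds on random transcripts", {
  set.seed(11)
  for (rep in 1:20) {
    tx <- rand_tx("G")
    for (off in sample(0:(tx$cds_length - 1L), 5)) {
      pos <- cds_to_genomic(tx, off)
      expect_equal(genomic_to_cds(tx, pos)$offset, off)
    }
  }
})

test_that("junction phases follow retained/discarded coding-length arithmetic", {
  set.seed(12)
  donor <- rand_tx("GD", strand = "+")
  acc <- rand_tx("GA", strand = "+")
  # donor retains 300 coding bases, acceptor discards 0 -> in frame (0, 0)
  jp <- junction_phases(donor, cds_to_genomic(donor, 299L),
                        acc, cds_to_genomic(acc, 0L))
  expect_equal(jp$donor_phase, 0L)
  expect_equal(jp$acceptor_phase, 0L)
  expect_true(jp$in_frame)
  # donor retains 301, acceptor discards 2 -> (1, 2), out of frame
  jp <- junction_phases(donor, cds_to_genomic(donor, 300L),
                        acc, cds_to_genomic(acc, 2L))
  expect_equal(jp$donor_phase, 1L)
  expect_equal(jp$acceptor_phase, 2L)
  expect_false(jp$in_frame)
  # intronic breakpoint: undefined phases with reason
  intron_pos <- donor$exons[1, "end"] + 1L
  jp <- junction_phases(donor, intron_pos, acc, cds_to_genomic(acc, 0L))
  expect_true(is.na(jp$donor_phase))
  expect_false(jp$in_frame)
  expect_match(jp$reason, "intron")
})

test_that("junction phases agree with the brute-force translation oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(13)
  n_cases <- 300  # the acceptance suite runs the full-size comparison
  for (i in seq_len(n_cases)) {
    dtx <- rand_tx("GD")
    atx <- rand_tx("GA", chrom = "cU")
    o_d <- sample(0:(dtx$cds_length - 1L), 1)
    o_a <- sample(0:(atx$cds_length - 24L), 1)
    jp <- junction_phases(dtx, cds_to_genomic(dtx, o_d),
                          atx, cds_to_genomic(atx, o_a))
    oracle <- frame_oracle(rand_cds_seq(dtx$cds_length),
                           rand_cds_seq(atx$cds_length),
                           retained_nt = o_d + 1L, discarded_nt = o_a)
    expect_identical(jp$in_frame, oracle)
  }
})

test_that("phases are invariant under reverse-complementing the locus", {
  set.seed(14)
  mirror <- function(tx, L) {
    transcript_model(tx$gene, tx$transcript_id, tx$chrom,
                     if (tx$strand == "+") "-" else "+",
                     cbind(L + 1L - rev(tx$exons[, "end"]),
                           L + 1L - rev(tx$exons[, "start"])),
                     L + 1L - tx$cds_end, L + 1L - tx$cds_start)
  }
  for (rep in 1:20) {
    dtx <- rand_tx("GD"); atx <- rand_tx("GA")
    o_d <- sample(0:(dtx$cds_length - 1L), 1)
    o_a <- sample(0:(atx$cds_length - 1L), 1)
    jp <- junction_phases(dtx, cds_to_genomic(dtx, o_d),
                          atx, cds_to_genomic(atx, o_a))
    L <- 1000000L
    dtx2 <- mirror(dtx, L); atx2 <- mirror(atx, L)
    jp2 <- junction_phases(dtx2, L + 1L - cds_to_genomic(dtx, o_d),
                           atx2, L + 1L - cds_to_genomic(atx, o_a))
    expect_equal(jp2[c("donor_phase", "acceptor_phase", "in_frame")],
                 jp[c("donor_phase", "acceptor_phase", "in_frame")])
  }
})

test_that("domain retention classifies and fractions domains correctly", {
  doms <- data.frame(gene = "G", name = c("SUP", "PK", "TM"),
                     start_aa = c(1L, 400L, 250L),
                     end_aa = c(325L, 500L, 350L))
  # 293 of a 325-aa region retained -> truncated, fraction 293/325
  r <- domain_retention(doms, 1L, 293L, 600L)
  expect_equal(r$status, c("truncated", "lost", "truncated"))
  expect_equal(r$fraction[1], 293 / 325)
  expect_equal(r$fraction[1], 0.902, tolerance = 1e-3)
  # 179 of a 253-aa region
  r2 <- domain_retention(data.frame(gene = "G", name = "SUP",
                                    start_aa = 1L, end_aa = 253L),
                         1L, 179L, 300L)
  expect_equal(r2$status, "truncated")
  expect_equal(r2$fraction, 179 / 253)
  expect_equal(r2$fraction, 0.708, tolerance = 1e-3)
  # acceptor-side kinase domain fully downstream of the junction
  r3 <- domain_retention(data.frame(gene = "G", name = "PK",
                                    start_aa = 400L, end_aa = 500L),
                         300L, 600L, 600L)
  expect_equal(r3$status, "retained")
  expect_equal(r3$fraction, 1.0)
  # statuses partition: retained/lost/truncated mutually exclusive, exhaustive
  set.seed(15)
  for (rep in 1:50) {
    plen <- sample(100:800, 1)
    d <- data.frame(gene = "G", name = "X",
                    start_aa = s <- sample(1:(plen - 1), 1),
                    end_aa = sample(s:plen, 1))
    cut <- sample(1:plen, 1)
    r <- domain_retention(d, 1L, cut, plen)
    expect_true(r$status %in% c("retained", "lost", "truncated"))
    expect_true((r$status == "retained") == (r$fraction == 1))
    expect_true((r$status == "lost") == (r$fraction == 0))
  }
  expect_error(domain_retention(doms, 1L, 100L, 450L), "beyond")
})

test_that("fusion protein bookkeeping satisfies its length invariant", {
  set.seed(16)
  doms <- data.frame(gene = c("GD", "GA"), name = c("SUP", "PK"),
                     start_aa = c(1L, 5L), end_aa = c(10L, 15L))
  for (rep in 1:30) {
    dtx <- rand_tx("GD"); atx <- rand_tx("GA")
    o_d <- sample(0:(dtx$cds_length - 1L), 1)
    o_a <- sample(0:(atx$cds_length - 1L), 1)
    fp <- fusion_protein(dtx, cds_to_genomic(dtx, o_d),
                         atx, cds_to_genomic(atx, o_a), doms)
    expect_identical(fp$in_frame, fp$donor_phase == fp$acceptor_phase)
    if (isTRUE(fp$in_frame)) {
      expect_equal(fp$total_aa, fp$donor_segment_aa + fp$acceptor_segment_aa)
      expect_true(all(fp$retained_domains$fraction >= 0 &
                        fp$retained_domains$fraction <= 1))
    }
  }
})

test_that("promoter-swap and UTR breakpoints get their dedicated flags", {
  plus <- toy_tx_2exon("+", gene = "GD")  # 5' UTR: 101-120
  acc <- rand_tx("GA", strand = "+")
  jp <- junction_phases(plus, 110L, acc, cds_to_genomic(acc, 0L))
  expect_equal(jp$flag, "promoter_swap")
  expect_equal(jp$donor_retained_nt, 0L)
  expect_true(jp$in_frame)  # acceptor ORF starts cleanly
  jp2 <- junction_phases(plus, 110L, acc, cds_to_genomic(acc, 1L))
  expect_false(jp2$in_frame)
  # donor breakpoint past the CDS: complete donor ORF retained
  jp3 <- junction_phases(plus, 230L, acc, cds_to_genomic(acc, 0L))
  expect_equal(jp3$flag, "donor_cds_complete")
  expect_equal(jp3$donor_phase, 0L)
})
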