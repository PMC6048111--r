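ann_tbl <- data.frame(
  gene = c("ALKx", "APCx", "KRASx", "PTENx"),
  categories = c("kinase,oncogene", "suppressor", "oncogene", "suppressor"),
  stringsAsFactors = FALSE)

mk_cls <- function(donor, acceptor, od = FALSE, oa = FALSE, sample = "S1") {
  data.frame(sample_id = sample, donor_gene = donor, acceptor_gene = acceptor,
             outlier_donor = od, outlier_acceptor = oa,
             stringsAsFactors = FALSE)
}

mk_fp <- function(cls, side, gene, status, fraction) {
  list(domains = data.frame(
    sample_id = cls$sample_id, donor_gene = cls$donor_gene,
    acceptor_gene = cls$acceptor_gene, gene = gene, side = side,
    name = "DOM", status = status, fraction = fraction,
    stringsAsFactors = FALSE))
}

test_that("kinase acceptor with retained kinase domain is oncogenic", {
  cls <- mk_cls("STRNx", "ALKx", oa = TRUE)
  fp <- mk_fp(cls, "acceptor", "ALKx", "retained", 1.0)
  out <- call_oncogenic(cls, ann_tbl, fp)
  expect_true(out$oncogenic)
  expect_match(out$reasons, "kinase_partner")
  expect_match(out$reasons, "outlier_expression")
  expect_match(out$function_category, "kinase")
})

test_that("suppressor donor losing domains fires the truncation clause", {
  cls <- mk_cls("APCx", "COMMD10x")
  fp <- mk_fp(cls, "donor", "APCx", c("truncated", "lost"), c(293 / 325, 0))
  out <- call_oncogenic(cls, ann_tbl, fp)
  expect_true(out$oncogenic)
  expect_equal(out$reasons, "suppressor_truncation")
  # a suppressor keeping every domain intact does not fire
  fp_ok <- mk_fp(cls, "donor", "APCx", "retained", 1.0)
  expect_false(call_oncogenic(cls, ann_tbl, fp_ok)$oncogenic)
  # mildly truncated (>= 0.9 retained) but nothing lost: no clause
  fp_mild <- mk_fp(cls, "donor", "APCx", "truncated", 0.95)
  expect_false(call_oncogenic(cls, ann_tbl, fp_mild)$oncogenic)
  # below the threshold: fires
  fp_deep <- mk_fp(cls, "donor", "APCx", "truncated", 179 / 253)
  expect_true(call_oncogenic(cls, ann_tbl, fp_deep)$oncogenic)
})

test_that("unannotated, non-outlier fusions are not oncogenic", {
  cls <- mk_cls("G1x", "G2x")
  out <- call_oncogenic(cls, ann_tbl, NULL)
  expect_false(out$oncogenic)
  expect_equal(out$reasons, "")
  expect_equal(out$function_category, "none")
})

test_that("verdicts carry reasons iff true and are monotone in evidence", {
  set.seed(31)
  for (rep in 1:40) {
    cls <- mk_cls(sample(c("G1x", "APCx", "KRASx"), 1),
                  sample(c("G2x", "ALKx", "PTENx"), 1),
                  od = runif(1) < 0.3, oa = runif(1) < 0.3)
    fp <- mk_fp(cls, "donor", cls$donor_gene,
                sample(c("retained", "truncated", "lost"), 1), runif(1))
    out <- call_oncogenic(cls, ann_tbl, fp)
    expect_identical(out$oncogenic, nzchar(out$reasons))
    # adding an outlier flag never turns a verdict off
    cls_plus <- cls; cls_plus$outlier_donor <- TRUE
    out_plus <- call_oncogenic(cls_plus, ann_tbl, fp)
    expect_gte(out_plus$oncogenic, out$oncogenic)
  }
})

test_that("a hand-labelled 24-fusion cohort yields exactly its 11 positives", {
  # 11 fusions engineered to satisfy a clause, 13 engineered to satisfy none
  pos <- rbind(
    mk_cls("D01", "ALKx", sample = "P01"),          # kinase+oncogene partner
    mk_cls("D02", "ALKx", oa = TRUE, sample = "P02"),
    mk_cls("KRASx", "A03", sample = "P03"),          # oncogene donor
    mk_cls("D04", "A04", od = TRUE, sample = "P04"), # outlier only
    mk_cls("D05", "A05", oa = TRUE, sample = "P05"),
    mk_cls("APCx", "A06", sample = "P06"),           # suppressor truncation
    mk_cls("PTENx", "A07", sample = "P07"),
    mk_cls("D08", "A08", od = TRUE, oa = TRUE, sample = "P08"),
    mk_cls("D09", "ALKx", sample = "P09"),
    mk_cls("KRASx", "A10", od = TRUE, sample = "P10"),
    mk_cls("D11", "A11", oa = TRUE, sample = "P11"))
  neg <- do.call(rbind, lapply(12:24, function(i)
    mk_cls(sprintf("D%02d", i), sprintf("A%02d", i),
           sample = sprintf("P%02d", i))))
  cohort <- rbind(pos, neg)
  fp <- list(domains = rbind(
    mk_fp(cohort[6, ], "donor", "APCx", "lost", 0)$domains,
    mk_fp(cohort[7, ], "donor", "PTENx", "truncated", 0.4)$domains))
  out <- call_oncogenic(cohort, ann_tbl, fp)
  expect_equal(sum(out$oncogenic), 11)
  expect_setequal(out$sample_id[out$oncogenic], sprintf("P%02d", 1:11))
})
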