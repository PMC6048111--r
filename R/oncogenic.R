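# Final oncogenicity verdict: combine expression outliers, gene-function
# annotation and protein-domain analysis into a per-fusion call with
# auditable reason codes.

ONCOGENIC_REASONS <- c("outlier_expression", "kinase_partner",
                       "oncogene_partner", "suppressor_truncation")

#' Classify fusions as oncogenic
#'
#' A fusion is called oncogenic when any of these clauses fires:
#' \itemize{
#'   \item \code{outlier_expression}: the carrier over-expresses the donor
#'     or acceptor gene (cohort outlier);
#'   \item \code{kinase_partner} / \code{oncogene_partner}: either partner
#'     gene is annotated kinase / oncogene;
#'   \item \code{suppressor_truncation}: a partner annotated tumour
#'     suppressor loses function in the fusion product — any of its domains
#'     has status \code{lost}, or is \code{truncated} with retained fraction
#'     below \code{truncation_threshold}.  The threshold defaults to 0.9:
#'     a suppressor region retaining ~90\% of its length can still be
#'     functionally dead when its downstream domains are lost entirely,
#'     which is why the \code{lost} clause fires independently of the
#'     fraction.
#' }
#' The combination is disjunctive by default (expression OR function); a
#' conjunctive variant (expression AND a function clause) is available for
#' sensitivity analyses.  Each verdict carries its reason codes: a TRUE
#' verdict always has at least one, a FALSE verdict none.  Adding evidence
#' (an outlier flag, a kinase/oncogene annotation) can only turn verdicts
#' on, never off.
#'
#' @param classifications data frame with \code{sample_id, donor_gene,
#'   acceptor_gene} plus the \code{outlier_donor}/\code{outlier_acceptor}
#'   flags from \code{\link{annotate_fusion_expression}} (missing flags are
#'   treated as FALSE).
#' @param annotations gene-function table (\code{gene}, \code{categories}
#'   comma string over kinase/oncogene/suppressor); genes absent from it
#'   simply contribute no function clause.
#' @param fp_report output of \code{\link{fusion_protein_report}} for the
#'   same fusions (needed for the suppressor-truncation clause; may be
#'   \code{NULL}, in which case that clause is skipped with a message for
#'   suppressor partners).
#' @param truncation_threshold retained-fraction cutoff (default 0.9).
#' @param rule \code{"disjunctive"} (default) or \code{"conjunctive"}.
#' @return \code{classifications} with columns \code{oncogenic},
#'   \code{reasons} (comma-separated codes) and \code{function_category}
#'   (comma-separated union of the partners' annotated categories, or
#'   \code{"none"}).
#' @export
call_oncogenic <- function(classifications, annotations, fp_report = NULL,
                           truncation_threshold = 0.9,
                           rule = c("disjunctive", "conjunctive")) {
  rule <- match.arg(rule)
  ann <- stats::setNames(annotations$categories, annotations$gene)
  cats_of <- function(g) {
    x <- ann[g]
    if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ",")[[1]])
  }
  dom <- if (!is.null(fp_report)) fp_report$domains else NULL
  n <- nrow(classifications)
  oncogenic <- logical(n)
  reasons <- character(n)
  fcat <- character(n)
  for (i in seq_len(n)) {
    dg <- classifications$donor_gene[i]
    ag <- classifications$acceptor_gene[i]
    sid <- classifications$sample_id[i]
    dcats <- cats_of(dg); acats <- cats_of(ag)
    rs <- character(0)
    if (isTRUE(classifications$outlier_donor[i]) ||
        isTRUE(classifications$outlier_acceptor[i]))
      rs <- c(rs, "outlier_expression")
    if ("kinase" %in% c(dcats, acats)) rs <- c(rs, "kinase_partner")
    if ("oncogene" %in% c(dcats, acats)) rs <- c(rs, "oncogene_partner")
    for (side in c("donor", "acceptor")) {
      g <- if (side == "donor") dg else ag
      if (!("suppressor" %in% cats_of(g))) next
      if (is.null(dom)) {
        message(sprintf(
          "fusion %s-%s: no protein report; suppressor clause skipped", dg, ag))
        next
      }
      d <- dom[dom$sample_id == sid & dom$donor_gene == dg &
                 dom$acceptor_gene == ag & dom$side == side &
                 dom$gene == g, , drop = FALSE]
      if (nrow(d) &&
          (any(d$status == "lost") ||
           any(d$status == "truncated" & d$fraction < truncation_threshold)))
        rs <- c(rs, "suppressor_truncation")
    }
    rs <- unique(rs)
    hit <- if (rule == "disjunctive") length(rs) > 0 else
      ("outlier_expression" %in% rs) && length(setdiff(rs, "outlier_expression"))
    oncogenic[i] <- as.logical(hit)
    reasons[i] <- if (oncogenic[i]) paste(rs, collapse = ",") else ""
    all_cats <- unique(c(dcats, acats))
    fcat[i] <- if (length(all_cats)) paste(sort(all_cats), collapse = ",")
               else "none"
  }
  classifications$function_category <- fcat
  classifications$oncogenic <- oncogenic
  classifications$reasons <- reasons
  classifications
}
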