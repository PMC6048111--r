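# Expression-outlier detection: does a fusion carrier over-express the
# donor or acceptor gene relative to the rest of the cohort?

#' Outlier-detection configuration
#'
#' The default criterion is the Tukey upper fence (value above
#' Q3 + k * IQR) computed over tumour samples only; a z-score alternative is
#' provided.  Both are scale-invariant, so rescaling all FPKM values leaves
#' the flags unchanged.  An optional log2(FPKM + 1) transform can be applied
#' before fencing (off by default: cohort FPKM strip plots are conventionally
#' read on the linear scale).
#'
#' @param method \code{"tukey"} (default) or \code{"zscore"}.
#' @param tukey_k fence multiplier (default 1.5).
#' @param z_cut z-score threshold (default 3).
#' @param reference_set \code{"tumours"} (default) or \code{"all_samples"} —
#'   which samples define the cohort distribution.
#' @param log_scale apply log2(x + 1) before testing (default FALSE).
#' @return list of class \code{"outlier_config"}.
#' @export
outlier_config <- function(method = c("tukey", "zscore"), tukey_k = 1.5,
                           z_cut = 3, reference_set = c("tumours",
                                                        "all_samples"),
                           log_scale = FALSE) {
  stopifnot(tukey_k > 0, z_cut > 0)
  structure(list(method = match.arg(method), tukey_k = tukey_k,
                 z_cut = z_cut, reference_set = match.arg(reference_set),
                 log_scale = isTRUE(log_scale)),
            class = "outlier_config")
}

#' Flag a sample as an expression outlier for one gene
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param gene gene symbol (must be a row of the matrix).
#' @param sample sample id (must be a column).
#' @param config an \code{\link{outlier_config}}.
#' @return list: \code{flag} (logical), \code{score} (distance above the
#'   fence for \code{tukey}; the z-score for \code{zscore}), \code{value},
#'   \code{threshold} and \code{method}.  A zero-variance gene under
#'   \code{zscore} is never flagged (with a warning).
#' @export
outlier_flag <- function(expr, gene, sample, config = outlier_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!(gene %in% rownames(expr$values)))
    fp_stop("gene '%s' not in expression matrix", gene)
  if (!(sample %in% colnames(expr$values)))
    fp_stop("sample '%s' not in expression matrix", sample)
  ref_cols <- if (config$reference_set == "tumours")
    names(expr$sample_class)[expr$sample_class == "tumour"] else
    colnames(expr$values)
  ref <- expr$values[gene, ref_cols]
  value <- expr$values[gene, sample]
  tr <- if (config$log_scale) function(x) log2(x + 1) else identity
  ref <- tr(ref); value <- tr(value)
  if (config$method == "tukey") {
    q <- stats::quantile(ref, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + config$tukey_k * (q[2] - q[1])
    list(flag = unname(value > fence), score = unname(value - fence),
         value = unname(value), threshold = unname(fence), method = "tukey")
  } else {
    s <- stats::sd(ref)
    if (is.na(s) || s == 0) {
      warning(sprintf("gene '%s': zero variance in reference set; not flagged",
                      gene))
      return(list(flag = FALSE, score = NA_real_, value = unname(value),
                  threshold = NA_real_, method = "zscore"))
    }
    z <- (value - mean(ref)) / s
    list(flag = unname(z > config$z_cut), score = unname(z),
         value = unname(value), threshold = config$z_cut, method = "zscore")
  }
}

#' Annotate fusions with donor/acceptor expression-outlier flags
#'
#' Sets \code{outlier_donor} and \code{outlier_acceptor} per fusion and a
#' \code{high_expression} summary label ("Donor and acceptor", "Donor",
#' "Acceptor" or "").  Genes absent from the expression matrix leave the
#' corresponding flag \code{NA} (with a message).
#'
#' @param classifications data frame with \code{sample_id, donor_gene,
#'   acceptor_gene} columns (e.g. screen survivors or validated groups).
#' @param expr an \code{\link{expression_matrix}}.
#' @param config an \code{\link{outlier_config}}.
#' @return \code{classifications} with the three columns added.
#' @export
annotate_fusion_expression <- function(classifications, expr,
                                       config = outlier_config()) {
  n <- nrow(classifications)
  od <- oa <- rep(NA, n)
  for (i in seq_len(n)) {
    for (side in c("donor", "acceptor")) {
      g <- classifications[[paste0(side, "_gene")]][i]
      s <- classifications$sample_id[i]
      if (!(g %in% rownames(expr$values)) ||
          !(s %in% colnames(expr$values))) {
        message(sprintf("fusion %s-%s in %s: %s gene/sample not in matrix",
                        classifications$donor_gene[i],
                        classifications$acceptor_gene[i], s, side))
        next
      }
      flag <- outlier_flag(expr, g, s, config)$flag
      if (side == "donor") od[i] <- flag else oa[i] <- flag
    }
  }
  classifications$outlier_donor <- od
  classifications$outlier_acceptor <- oa
  classifications$high_expression <- ifelse(
    od %in% TRUE & oa %in% TRUE, "Donor and acceptor",
    ifelse(od %in% TRUE, "Donor", ifelse(oa %in% TRUE, "Acceptor", "")))
  classifications
}

#' Strip plot of one gene's cohort expression
#'
#' Normal and tumour samples side by side, optionally highlighting carrier
#' samples, mirroring the conventional cohort FPKM outlier display.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param gene gene symbol.
#' @param highlight character vector of sample ids to mark.
#' @export
plot_expression_strip <- function(expr, gene, highlight = character(0)) {
  if (!(gene %in% rownames(expr$values)))
    fp_stop("gene '%s' not in expression matrix", gene)
  v <- expr$values[gene, ]
  cls <- factor(expr$sample_class[colnames(expr$values)],
                levels = c("normal", "tumour"))
  graphics::stripchart(split(v, cls), vertical = TRUE, method = "jitter",
                       pch = 16, col = c("skyblue3", "pink3"),
                       ylab = "FPKM", main = gene)
  hi <- intersect(highlight, names(v))
  if (length(hi))
    graphics::points(as.integer(cls[hi]), v[hi], col = "red", pch = 1,
                     cex = 2, lwd = 2)
  invisible(NULL)
}
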