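# Somatic-variant hard filtering, the patient x gene mutation matrix, and
# the permutation test of fusion/oncogene mutual exclusivity.

#' Somatic-variant filter configuration
#'
#' The hard-filter cascade for RNA-seq-derived somatic variants: minimum
#' total depth, minimum alt-supporting depth, minimum variant allele
#' fraction, exonic region, consequential effect class, population
#' minor-allele frequency (likely germline above 1\%), strand-bias /
#' quality exclusion (a variant with Fisher-strand above \code{fs_cut} or
#' qual-by-depth below \code{qd_cut} is removed, the standard GATK-style
#' hard-filter direction) and exclusion of sites also seen in matched
#' normal tissue.  All numeric thresholds are inclusive on the passing side
#' (depth of exactly 10, VAF of exactly 3\% pass).
#'
#' @param min_depth minimum read depth at the position (default 10).
#' @param min_alt_depth minimum alt-supporting reads (default 2).
#' @param min_vaf minimum allele fraction (default 0.03).
#' @param allowed_effects effect classes kept (default frameshift,
#'   non-synonymous, stop-gain, stop-loss).
#' @param require_exonic keep exonic variants only (default TRUE).
#' @param max_pop_maf maximum population MAF; above it the variant is
#'   treated as germline (default 0.01).  Variants absent from the
#'   population catalogue (\code{NA}) pass.
#' @param fs_cut Fisher-strand exclusion threshold (default 30).
#' @param qd_cut qual-by-depth exclusion threshold (default 2).
#' @param matched_normal_exclusion drop sites present in matched normal
#'   samples (default TRUE).
#' @return list of class \code{"snv_filter_config"}.
#' @export
snv_filter_config <- function(min_depth = 10L, min_alt_depth = 2L,
                              min_vaf = 0.03,
                              allowed_effects = c("frameshift",
                                                  "non-synonymous",
                                                  "stop-gain", "stop-loss"),
                              require_exonic = TRUE, max_pop_maf = 0.01,
                              fs_cut = 30, qd_cut = 2,
                              matched_normal_exclusion = TRUE) {
  stopifnot(min_depth >= 0, min_alt_depth >= 0,
            min_vaf >= 0, min_vaf <= 1, max_pop_maf >= 0)
  structure(list(min_depth = min_depth, min_alt_depth = min_alt_depth,
                 min_vaf = min_vaf, allowed_effects = allowed_effects,
                 require_exonic = isTRUE(require_exonic),
                 max_pop_maf = max_pop_maf, fs_cut = fs_cut, qd_cut = qd_cut,
                 matched_normal_exclusion = isTRUE(matched_normal_exclusion)),
            class = "snv_filter_config")
}

#' Hard-filter somatic variants
#'
#' Applies the cascade of \code{\link{snv_filter_config}} in a fixed order
#' (depth, alt depth, VAF, exonic, effect, population MAF, FS/QD,
#' matched-normal).  A variant survives iff it passes every enabled filter;
#' the attrition table attributes each removed variant to the first filter
#' it fails.  A variant with a missing value in a field an enabled filter
#' needs is set aside as \code{unevaluable} (counted separately, never
#' silently dropped), except \code{pop_maf}, where \code{NA} means "not in
#' the population catalogue" and passes.
#'
#' @param variants variant data frame (see \code{\link{read_variants}}).
#' @param normal_variants variants observed in matched normal samples
#'   (matched on chrom/pos/ref/alt), or \code{NULL}.
#' @param config an \code{\link{snv_filter_config}}.
#' @return list: \code{survivors} (data frame), \code{attrition} (data
#'   frame \code{filter}, \code{removed}, in cascade order),
#'   \code{unevaluable} (data frame of set-aside variants) and \code{n_input}.
#'   Always \code{n_input = nrow(survivors) + sum(removed) +
#'   nrow(unevaluable)}.
#' @export
filter_snvs <- function(variants, normal_variants = NULL,
                        config = snv_filter_config()) {
  stopifnot(inherits(config, "snv_filter_config"))
  n <- nrow(variants)
  alive <- rep(TRUE, n)
  uneval <- rep(FALSE, n)
  removed <- integer(0)

  site_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  norm_sites <- if (!is.null(normal_variants) && nrow(normal_variants))
    site_key(normal_variants) else character(0)

  filters <- list(
    depth = list(on = TRUE, need = "total_depth",
                 pass = function(d) d$total_depth >= config$min_depth),
    alt_depth = list(on = TRUE, need = "alt_depth",
                     pass = function(d) d$alt_depth >= config$min_alt_depth),
    vaf = list(on = TRUE, need = c("alt_depth", "total_depth"),
               pass = function(d) d$alt_depth / d$total_depth >= config$min_vaf),
    exonic = list(on = config$require_exonic, need = "region",
                  pass = function(d) d$region == "exon"),
    effect = list(on = TRUE, need = "effect",
                  pass = function(d) d$effect %in% config$allowed_effects),
    pop_maf = list(on = TRUE, need = character(0),  # NA passes by design
                   pass = function(d) is.na(d$pop_maf) |
                     d$pop_maf <= config$max_pop_maf),
    strand_quality = list(on = TRUE, need = c("fs", "qd"),
                          pass = function(d) d$fs <= config$fs_cut &
                            d$qd >= config$qd_cut),
    matched_normal = list(on = config$matched_normal_exclusion,
                          need = character(0),
                          pass = function(d) !(site_key(d) %in% norm_sites))
  )
  for (fname in names(filters)) {
    f <- filters[[fname]]
    if (!f$on) { removed[fname] <- 0L; next }
    idx <- which(alive & !uneval)
    d <- variants[idx, , drop = FALSE]
    missing_field <- if (length(f$need))
      Reduce(`|`, lapply(f$need, function(col) is.na(d[[col]]))) else
      rep(FALSE, nrow(d))
    uneval[idx[missing_field]] <- TRUE
    ok <- f$pass(d)
    fail <- !missing_field & !(ok %in% TRUE)
    alive[idx[fail]] <- FALSE
    removed[fname] <- sum(fail)
  }
  survivors <- variants[alive & !uneval, , drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors,
       attrition = data.frame(filter = names(removed),
                              removed = unname(removed),
                              stringsAsFactors = FALSE),
       unevaluable = variants[uneval, , drop = FALSE],
       n_input = n)
}

#' Build the patient x gene mutation matrix
#'
#' Entry (p, g) is 1 iff patient p has at least one surviving variant in
#' gene g.  Genes are grouped into oncogene / suppressor / other panels, and
#' the fusion indicator marks fusion-positive patients.
#'
#' @param variants filtered variants (\code{survivors} of
#'   \code{\link{filter_snvs}}).
#' @param patients character vector of all patient ids (columns with no
#'   variants are kept as zero rows).
#' @param panels data frame \code{gene}, \code{panel}
#'   (\code{oncogene}/\code{suppressor}/\code{other}); variant genes not
#'   listed default to \code{other}.
#' @param fusion_positive character vector of fusion-positive patient ids.
#' @return object of class \code{"mutation_matrix"}: \code{calls} (binary
#'   patients x genes matrix), \code{panels} (named vector gene -> panel)
#'   and \code{fusion} (named logical per patient).
#' @export
build_matrix <- function(variants, patients, panels, fusion_positive) {
  genes <- sort(unique(c(panels$gene, variants$gene)))
  m <- matrix(0L, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  if (nrow(variants)) {
    keep <- variants$sample %in% patients
    idx <- cbind(match(variants$sample[keep], patients),
                 match(variants$gene[keep], genes))
    m[idx] <- 1L
  }
  panel_vec <- stats::setNames(rep("other", length(genes)), genes)
  panel_vec[panels$gene] <- panels$panel
  structure(list(calls = m, panels = panel_vec,
                 fusion = stats::setNames(patients %in% fusion_positive,
                                          patients)),
            class = "mutation_matrix")
}

#' Permutation test of fusion/oncogene mutual exclusivity
#'
#' Observed statistic: the number of fusion-positive patients carrying at
#' least one mutation in a panel gene.  Mutual exclusivity predicts a small
#' statistic, so the one-sided p-value is the (add-one smoothed) fraction of
#' label permutations with a statistic at most the observed one:
#' \code{p = (1 + #\{perm <= obs\}) / (1 + n_perm)}.  Permuting the fusion
#' labels across patients preserves the mutation matrix marginals exactly.
#'
#' @param matrix a \code{\link{build_matrix}} object.
#' @param panel which panel to test against (default \code{"oncogene"}).
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional RNG seed for a reproducible permutation stream.
#' @return list of class \code{"exclusivity_test"}: \code{statistic},
#'   \code{p_value}, \code{n_perm}, \code{n_fusion},
#'   \code{n_mutated} (patients with a panel mutation), \code{panel}.
#'   With no fusion-positive patients the statistic is 0 and p = 1 (with a
#'   warning).
#' @export
exclusivity_test <- function(matrix, panel = "oncogene", n_perm = 10000L,
                             seed = NULL) {
  stopifnot(inherits(matrix, "mutation_matrix"), n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  panel_genes <- names(matrix$panels)[matrix$panels == panel]
  mut <- if (length(panel_genes))
    as.integer(rowSums(matrix$calls[, panel_genes, drop = FALSE]) > 0) else
    integer(nrow(matrix$calls))
  fus <- matrix$fusion
  k <- sum(fus)
  obs <- sum(mut[fus])
  if (k < 1) {
    warning("no fusion-positive patients; p = 1")
    return(structure(list(statistic = 0L, p_value = 1, n_perm = n_perm,
                          n_fusion = 0L, n_mutated = sum(mut), panel = panel),
                     class = "exclusivity_test"))
  }
  n <- length(fus)
  perm <- vapply(seq_len(n_perm),
                 function(i) sum(mut[sample.int(n, k)]), numeric(1))
  p <- (1 + sum(perm <= obs)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                 n_fusion = k, n_mutated = sum(mut), panel = panel),
            class = "exclusivity_test")
}

#' @export
print.exclusivity_test <- function(x, ...) {
  cat(sprintf(paste0("<exclusivity_test> panel '%s': %d of %d ",
                     "fusion-positive patients mutated (cohort: %d mutated)\n",
                     "  one-sided permutation p = %.4g (%d permutations)\n"),
              x$panel, x$statistic, x$n_fusion, x$n_mutated,
              x$p_value, x$n_perm))
  invisible(x)
}

#' Oncoprint-style display of the mutation matrix
#'
#' Patients (columns) x genes (rows) grid; fusion-positive patients are
#' marked along the top axis.
#'
#' @param matrix a \code{\link{build_matrix}} object.
#' @param panel restrict to one panel (default all genes).
#' @export
plot_mutation_matrix <- function(matrix, panel = NULL) {
  genes <- if (is.null(panel)) colnames(matrix$calls) else
    names(matrix$panels)[matrix$panels == panel]
  m <- t(matrix$calls[, genes, drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                  drop = FALSE]), col = c("grey90", "firebrick"),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.6)
  fus <- which(matrix$fusion)
  if (length(fus))
    graphics::axis(3, at = fus, labels = names(fus), las = 2, cex.axis = 0.5)
  invisible(NULL)
}
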