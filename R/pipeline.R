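# End-to-end orchestration: screen -> consensus -> protein/domains ->
# expression outliers -> oncogenicity -> SNV exclusivity -> clinical stats,
# with a funnel summary and reproducible report files.

#' Read a full input bundle from a directory
#'
#' Expects the file layout written by \code{\link{generate}} /
#' \code{\link{write_bundle}}: per-caller \code{calls_<caller>.tsv},
#' \code{normal_calls.tsv}, \code{transcripts.gtf}, \code{domains.tsv},
#' \code{gene_functions.tsv}, \code{panels.tsv}, \code{expression.tsv},
#' \code{samples.tsv}, \code{variants.tsv}, \code{normal_variants.tsv},
#' \code{clinical.tsv}.
#'
#' @param dir directory path.
#' @return bundle list usable by \code{\link{run_all}}.
#' @export
read_bundle <- function(dir) {
  call_files <- list.files(dir, pattern = "^calls_.*\\.tsv$",
                           full.names = TRUE)
  if (!length(call_files)) fp_stop("no calls_<caller>.tsv files in '%s'", dir)
  callers <- sub("^calls_(.*)\\.tsv$", "\\1", basename(call_files))
  calls <- stats::setNames(lapply(call_files, read_fusion_calls), callers)
  list(
    calls = calls,
    normal_calls = read_fusion_calls(file.path(dir, "normal_calls.tsv")),
    transcripts = read_transcripts(file.path(dir, "transcripts.gtf")),
    domains = read_domains(file.path(dir, "domains.tsv")),
    gene_functions = read_gene_functions(file.path(dir, "gene_functions.tsv")),
    panels = utils::read.delim(file.path(dir, "panels.tsv"),
                               colClasses = "character"),
    expression = read_expression(file.path(dir, "expression.tsv"),
                                 file.path(dir, "samples.tsv")),
    variants = read_variants(file.path(dir, "variants.tsv")),
    normal_variants = read_variants(file.path(dir, "normal_variants.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv"))
  )
}

#' Run the full fusion-prioritisation analysis
#'
#' Stages, in order: (1) junction phases recomputed for the primary caller's
#' calls and the filter cascade applied; (2) survivors matched against all
#' callers' calls and cross-validated (2-of-3 by default); (3) fusion
#' proteins reconstructed and domain retention scored; (4) donor/acceptor
#' expression-outlier flags; (5) oncogenicity verdicts; (6) somatic-variant
#' hard filtering, mutation matrix and the fusion/oncogene exclusivity
#' permutation test; (7) clinicopathological associations and the survival
#' comparison.  A funnel summary reports the count entering and surviving
#' each stage.
#'
#' @param bundle input bundle (from \code{\link{generate}} or
#'   \code{\link{read_bundle}}).
#' @param primary_caller caller whose calls feed the screen (default: first
#'   in \code{bundle$calls}).
#' @param screen a \code{\link{screen_config}}.
#' @param tolerance consensus breakpoint tolerance, bp (default 50).
#' @param min_support cross-validation support threshold (default 2).
#' @param outlier an \code{\link{outlier_config}}.
#' @param snv an \code{\link{snv_filter_config}}.
#' @param truncation_threshold suppressor retained-fraction cutoff
#'   (default 0.9).
#' @param n_perm permutations for the exclusivity test (default 10,000).
#' @param seed seed for the permutation stream (default 1).
#' @param out_dir optional directory for report files (survivor audit,
#'   consensus table, fusion report, attrition, associations, funnel,
#'   run log).
#' @return list of class \code{"fusion_run"}: \code{funnel},
#'   \code{screened}, \code{validated} (consensus groups),
#'   \code{protein}, \code{classifications} (final per-fusion report with
#'   verdicts), \code{snv} (filter output), \code{mutation_matrix},
#'   \code{exclusivity}, \code{associations}, \code{survival},
#'   \code{fusion_positive} (named logical per patient), the configs, and
#'   \code{seed} / \code{bundle_seed}.
#' @export
run_all <- function(bundle, primary_caller = names(bundle$calls)[1],
                    screen = screen_config(), tolerance = 50,
                    min_support = 2L, outlier = outlier_config(),
                    snv = snv_filter_config(), truncation_threshold = 0.9,
                    n_perm = 10000L, seed = 1L, out_dir = NULL) {
  primary <- bundle$calls[[primary_caller]]
  if (is.null(primary)) fp_stop("no calls for primary caller '%s'",
                                primary_caller)

  # 1. screen
  annotated <- annotate_frames(primary, bundle$transcripts)
  screened <- apply_screen(annotated, bundle$normal_calls, screen)
  survivors <- screen_survivors(screened)

  # 2. consensus across callers, restricted to surviving fusions
  all_calls <- do.call(rbind, lapply(bundle$calls, as.data.frame))
  skey <- paste(survivors$sample_id, survivors$donor_gene,
                survivors$acceptor_gene, sep = "\r")
  akey <- paste(all_calls$sample_id, all_calls$donor_gene,
                all_calls$acceptor_gene, sep = "\r")
  pool <- all_calls[akey %in% skey, , drop = FALSE]
  groups <- group_calls(pool, tolerance)
  validated <- cross_validate(groups, min_support)

  # 3. protein / domain report.  Uses the screened (primary-caller)
  # breakpoints, not the group representative: a cross-validator's jittered
  # coordinates must not perturb the phase/domain analysis of a fusion the
  # screen validated on the primary call.
  gdf <- validated$groups
  vkey <- paste(gdf$sample_id, gdf$donor_gene, gdf$acceptor_gene, sep = "\r")
  surv_rep <- survivors[!duplicated(skey) & skey %in% vkey, , drop = FALSE]
  protein <- fusion_protein_report(surv_rep, bundle$transcripts,
                                   bundle$domains)

  # 4 + 5. expression outliers and oncogenicity verdicts
  cls <- merge(gdf, protein$proteins,
               by = c("sample_id", "donor_gene", "acceptor_gene"),
               sort = FALSE)
  cls <- annotate_fusion_expression(cls, bundle$expression, outlier)
  cls <- call_oncogenic(cls, bundle$gene_functions, protein,
                        truncation_threshold = truncation_threshold)
  cls <- cls[order(cls$donor_gene, cls$acceptor_gene, cls$sample_id), ]
  rownames(cls) <- NULL

  # 6. somatic variants and mutual exclusivity
  snv_res <- filter_snvs(bundle$variants, bundle$normal_variants, snv)
  fusion_positive <- unique(gdf$sample_id)
  mm <- build_matrix(snv_res$survivors, bundle$clinical$sample,
                     bundle$panels, fusion_positive)
  excl <- exclusivity_test(mm, panel = "oncogene", n_perm = n_perm,
                           seed = seed)

  # 7. clinical associations and survival
  fus_vec <- stats::setNames(bundle$clinical$sample %in% fusion_positive,
                             bundle$clinical$sample)
  cat_covs <- c("sex", "location", "histology", "invasion_depth",
                "perineural", "lymphovascular", "lymph_node", "msi_status")
  associations <- c(
    lapply(stats::setNames(cat_covs, cat_covs), function(cv)
      contingency_association(bundle$clinical, cv, fus_vec)),
    lapply(stats::setNames(c("age", "size"), c("age", "size")), function(cv)
      continuous_association(bundle$clinical, cv, fus_vec))
  )
  surv <- survival_comparison(bundle$clinical, fus_vec)

  funnel <- data.frame(
    stage = c("input_calls", "screen_survivors", "cross_validated",
              "oncogenic"),
    n = c(nrow(primary), nrow(survivors), nrow(validated$groups),
          sum(cls$oncogenic)),
    stringsAsFactors = FALSE
  )

  run <- structure(list(
    funnel = funnel, screened = screened, validated = validated,
    protein = protein, classifications = cls, snv = snv_res,
    mutation_matrix = mm, exclusivity = excl, associations = associations,
    survival = surv, fusion_positive = fus_vec,
    config = list(primary_caller = primary_caller, screen = screen,
                  tolerance = tolerance, min_support = min_support,
                  outlier = outlier, snv = snv,
                  truncation_threshold = truncation_threshold,
                  n_perm = n_perm),
    seed = seed,
    bundle_seed = bundle$manifest$seed
  ), class = "fusion_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

#' Final fusion report table
#'
#' One row per validated fusion in the style of a cohort characterisation
#' table: gene pair, junction-phase label, breakpoints and strands,
#' breakpoint separation, supporting callers, high-expression label,
#' function categories, verdict and reasons.
#'
#' @param run a \code{fusion_run}.
#' @return data frame.
#' @export
report_fusion_table <- function(run) {
  cls <- run$classifications
  data.frame(
    donor_gene = cls$donor_gene, acceptor_gene = cls$acceptor_gene,
    sample = cls$sample_id,
    in_frame_shift = format_frame_label(cls$donor_phase, cls$acceptor_phase),
    mid_distance = compute_mid_distance(cls$chrom1, cls$pos1,
                                        cls$chrom2, cls$pos2),
    strands = paste0(cls$strand1, cls$strand2),
    breakpoint1 = paste0(cls$chrom1, ":", cls$pos1),
    breakpoint2 = paste0(cls$chrom2, ":", cls$pos2),
    callers = cls$callers, support = cls$support,
    high_expression = cls$high_expression,
    function_category = cls$function_category,
    oncogenic = cls$oncogenic, reasons = cls$reasons,
    stringsAsFactors = FALSE
  )
}

#' @rdname run_all
#' @param run a \code{fusion_run}.
#' @export
write_run_reports <- function(run, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    fp_stop("cannot create output directory '%s'", out_dir)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  wt(run$funnel, "funnel.tsv")
  wt(as.data.frame(run$screened), "screen_audit.tsv")
  wt(run$validated$groups, "consensus.tsv")
  wt(report_fusion_table(run), "fusion_report.tsv")
  wt(run$snv$attrition, "snv_attrition.tsv")
  assoc <- do.call(rbind, lapply(run$associations, function(a)
    data.frame(covariate = a$covariate, test = a$test,
               statistic = if (is.null(a$statistic)) NA else a$statistic,
               p_value = a$p_value, n = a$n, stringsAsFactors = FALSE)))
  wt(assoc, "associations.tsv")
  log <- list(
    primary_caller = run$config$primary_caller,
    screen = unclass(run$config$screen),
    consensus = list(tolerance = run$config$tolerance,
                     min_support = run$config$min_support),
    outlier = unclass(run$config$outlier),
    snv = unclass(run$config$snv),
    truncation_threshold = run$config$truncation_threshold,
    n_perm = run$config$n_perm,
    seed = run$seed,
    bundle_seed = run$bundle_seed,
    exclusivity = unclass(run$exclusivity),
    survival = list(logrank_chisq = run$survival$logrank_chisq,
                    p_value = run$survival$p_value,
                    means = run$survival$means)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fusion_run <- function(x, ...) {
  cat("<fusion_run>\n")
  print(x$funnel, row.names = FALSE)
  cat(sprintf("exclusivity p = %.4g; log-rank p = %s\n",
              x$exclusivity$p_value, format(x$survival$p_value, digits = 3)))
  invisible(x)
}
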