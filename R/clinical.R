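# Clinicopathological association analyses and the fusion-positive vs
# fusion-negative survival comparison.

#' Group a clinical covariate the way cohort tables report it
#'
#' Categorical covariates are collapsed to the conventional reporting
#' groups: histology to well+moderately vs poorly+mucinous differentiation,
#' invasion depth to T1+T2 vs T3+T4, microsatellite status to MSS+MSI-L vs
#' MSI-H; binary covariates become negative/positive.
#'
#' @param clinical clinical data frame (see \code{\link{read_clinical}}).
#' @param covariate one of \code{sex, location, histology, invasion_depth,
#'   perineural, lymphovascular, lymph_node, msi_status}.
#' @return factor of group labels (per patient), \code{NA} preserved.
#' @export
clinical_grouping <- function(clinical, covariate) {
  x <- clinical[[covariate]]
  switch(covariate,
    sex = factor(x, levels = c("M", "F")),
    location = factor(x, levels = c("right", "left")),
    histology = factor(ifelse(is.na(x), NA,
                       ifelse(x %in% c("well", "moderately"),
                              "well+moderately", "poorly+mucinous")),
                       levels = c("well+moderately", "poorly+mucinous")),
    invasion_depth = factor(ifelse(is.na(x), NA,
                            ifelse(x %in% c("T1", "T2"), "T1+T2", "T3+T4")),
                            levels = c("T1+T2", "T3+T4")),
    msi_status = factor(ifelse(is.na(x), NA,
                        ifelse(x == "MSI-H", "MSI-H", "MSS+MSI-L")),
                        levels = c("MSS+MSI-L", "MSI-H")),
    perineural = ,
    lymphovascular = ,
    lymph_node = factor(ifelse(is.na(x), NA,
                        ifelse(x == 1, "positive", "negative")),
                        levels = c("negative", "positive")),
    fp_stop("no grouping defined for covariate '%s'", covariate)
  )
}

#' Association between a categorical covariate and fusion status
#'
#' Builds the groups x fusion (absent/present) contingency table and tests
#' it.  \code{test = "auto"} (default) uses Fisher's exact test when any
#' expected cell count is below 5 and the Pearson chi-square test otherwise
#' (2x2 chi-square with continuity correction, the common reporting
#' convention).  Row percentages are reported alongside the counts.
#'
#' @param clinical clinical data frame.
#' @param covariate covariate name (see \code{\link{clinical_grouping}}).
#' @param fusion logical vector of fusion positivity, aligned with
#'   \code{clinical} rows, or a named logical indexed by sample id.
#' @param test \code{"auto"}, \code{"fisher"} or \code{"chisq"}.
#' @return list of class \code{"association_result"}: \code{covariate},
#'   \code{grouping}, \code{test}, \code{statistic} (chi-square statistic,
#'   \code{NA} for the exact test), \code{p_value}, \code{table},
#'   \code{row_pct}, \code{n}.  A covariate with a single observed level
#'   returns \code{p_value = NA} with a warning.
#' @export
contingency_association <- function(clinical, covariate, fusion,
                                    test = c("auto", "fisher", "chisq")) {
  test <- match.arg(test)
  fusion <- align_fusion(clinical, fusion)
  grp <- clinical_grouping(clinical, covariate)
  keep <- !is.na(grp) & !is.na(fusion)
  tab <- table(grp[keep],
               factor(ifelse(fusion[keep], "present", "absent"),
                      levels = c("absent", "present")))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) {
    warning(sprintf("covariate '%s' has a single observed level", covariate))
    return(structure(list(covariate = covariate, grouping = rownames(tab),
                          test = test, statistic = NA_real_,
                          p_value = NA_real_, table = tab,
                          row_pct = NULL, n = sum(tab)),
                     class = "association_result"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- if (test == "auto") {
    if (any(expected < 5)) "fisher" else "chisq"
  } else test
  if (use == "fisher") {
    ht <- stats::fisher.test(tab)
    statistic <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab))
    statistic <- unname(ht$statistic)
  }
  structure(list(covariate = covariate, grouping = rownames(tab),
                 test = use, statistic = statistic,
                 p_value = unname(ht$p.value), table = tab,
                 row_pct = round(100 * prop.table(tab, 1), 1),
                 n = sum(tab)),
            class = "association_result")
}

#' Association between a continuous covariate and fusion status
#'
#' Two-sample t test (Student's by default, Welch optionally) with group
#' means and standard errors reported in the "mean +/- SE" style of cohort
#' tables.
#'
#' @param clinical clinical data frame.
#' @param covariate \code{"age"} or \code{"size"} (any numeric column).
#' @param fusion as in \code{\link{contingency_association}}.
#' @param var_equal assume equal variances (classical Student's t test,
#'   default TRUE).
#' @return \code{association_result} with \code{statistic} (t),
#'   \code{p_value} and \code{group_stats} (n, mean, se per group).  A group
#'   with fewer than 2 observations yields \code{p_value = NA} with a
#'   warning.
#' @export
continuous_association <- function(clinical, covariate, fusion,
                                   var_equal = TRUE) {
  fusion <- align_fusion(clinical, fusion)
  x <- clinical[[covariate]]
  keep <- !is.na(x) & !is.na(fusion)
  g <- factor(ifelse(fusion[keep], "present", "absent"),
              levels = c("absent", "present"))
  xs <- split(x[keep], g)
  stats_df <- data.frame(
    group = names(xs),
    n = vapply(xs, length, integer(1)),
    mean = vapply(xs, mean, numeric(1)),
    se = vapply(xs, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    row.names = NULL
  )
  if (any(stats_df$n < 2)) {
    warning(sprintf("covariate '%s': a group has n < 2; p undefined",
                    covariate))
    return(structure(list(covariate = covariate, test = "t",
                          statistic = NA_real_, p_value = NA_real_,
                          group_stats = stats_df, n = sum(keep)),
                     class = "association_result"))
  }
  if (stats::sd(x[keep]) == 0) {
    # identical values everywhere: no evidence of a difference
    return(structure(list(covariate = covariate, test = "t", statistic = 0,
                          p_value = 1, group_stats = stats_df,
                          n = sum(keep)),
                     class = "association_result"))
  }
  ht <- stats::t.test(x[keep] ~ g, var.equal = var_equal)
  structure(list(covariate = covariate,
                 test = if (var_equal) "t" else "welch",
                 statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 group_stats = stats_df, n = sum(keep)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s (%s test): p = %s\n",
              x$covariate, x$test,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3)))
  if (!is.null(x$table)) print(x$table)
  if (!is.null(x$group_stats)) print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Survival comparison between fusion-positive and -negative patients
#'
#' Kaplan-Meier product-limit estimates per group, the log-rank test, and
#' the restricted mean survival time with its standard error (the "mean
#' months +/- SE" convention; the restriction horizon is the largest
#' observed time).
#'
#' @param clinical clinical data frame with \code{os_months},
#'   \code{os_event}.
#' @param fusion as in \code{\link{contingency_association}}.
#' @return list of class \code{"survival_comparison"}: \code{fit} (a
#'   \code{survfit} object), \code{logrank_chisq}, \code{p_value} and
#'   \code{means} (per group: n, events, restricted mean, se).  With no
#'   events in either group the p-value is \code{NA} with a warning.
#' @export
survival_comparison <- function(clinical, fusion) {
  fusion <- align_fusion(clinical, fusion)
  keep <- !is.na(clinical$os_months) & !is.na(clinical$os_event) &
    !is.na(fusion)
  d <- data.frame(time = clinical$os_months[keep],
                  event = clinical$os_event[keep],
                  group = factor(ifelse(fusion[keep], "present", "absent"),
                                 levels = c("absent", "present")))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  horizon <- max(d$time)
  tab <- summary(fit, rmean = horizon)$table
  means <- data.frame(group = sub("^group=", "", rownames(tab)),
                      n = tab[, "records"], events = tab[, "events"],
                      rmean = tab[, "rmean"], se = tab[, "se(rmean)"],
                      row.names = NULL)
  if (sum(d$event) == 0) {
    warning("no events in either group; log-rank p undefined")
    return(structure(list(fit = fit, logrank_chisq = NA_real_,
                          p_value = NA_real_, means = means),
                     class = "survival_comparison"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  structure(list(fit = fit, logrank_chisq = unname(sd$chisq), p_value = p,
                 means = means),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> log-rank chisq = %s, p = %s\n",
              format(x$logrank_chisq, digits = 4),
              format(x$p_value, digits = 3)))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier plot of the survival comparison
#'
#' @param comparison a \code{\link{survival_comparison}} result.
#' @export
plot_survival <- function(comparison) {
  plot(comparison$fit, col = c("steelblue", "firebrick"), lwd = 2,
       xlab = "Months", ylab = "Overall survival")
  graphics::legend("bottomleft", legend = c("fusion absent", "fusion present"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(NULL)
}

# fusion may be a plain logical aligned to rows or a named logical by sample
align_fusion <- function(clinical, fusion) {
  if (!is.null(names(fusion)))
    return(unname(fusion[clinical$sample]))
  if (length(fusion) != nrow(clinical))
    fp_stop("fusion vector length does not match clinical records")
  fusion
}
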