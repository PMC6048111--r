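# Synthetic cohort generator.  Produces a complete, internally consistent
# input bundle — toy genome and transcript models, per-caller fusion-call
# tables with jittered breakpoints, FPKM expression with planted carrier
# outliers, somatic variants with planted fusion/oncogene exclusivity, and
# clinical/survival records with a planted MSI association — plus a
# ground-truth manifest, so every pipeline stage is testable without access
# to patient data.

#' Simulation configuration
#'
#' Defaults emulate the structure of a mid-size colorectal tumour RNA-seq
#' cohort: 147 tumours with 47 matched normals, 25 genuine fusion events
#' spread over 19 carrier patients, detected by one primary caller and two
#' cross-validating callers; read-through artifacts between neighbouring
#' genes for the distance filter to remove; a handful of chimeras also
#' present in normal tissue for the normal filter; carrier over-expression
#' of fusion partner genes at 10x the cohort median; near-mutual exclusivity
#' between fusions and oncogene point mutations (carrier rate 0.05 vs
#' background 0.4); an MSI-H enrichment of fusions at an odds ratio of 3.5;
#' and exponential survival with no fusion effect (hazard ratio 1).
#'
#' @param seed RNG seed; fixes the entire bundle.
#' @param n_patients,n_normals tumour and matched-normal sample counts.
#' @param n_chroms,n_genes toy-genome size (multi-exon coding genes placed
#'   on synthetic chromosomes of a few Mb).
#' @param n_true_fusions,n_fusion_patients genuine fusion events and the
#'   carrier patients they are spread over.
#' @param caller_ids,caller_sensitivity detection algorithms and their
#'   per-event detection probabilities (first = primary caller).
#' @param breakpoint_jitter_sd Gaussian jitter (bp, rounded) applied to the
#'   non-primary callers' reported breakpoints.
#' @param artifact_rate expected read-through artifact calls per tumour
#'   sample (Poisson).
#' @param n_normal_chimeras gene pairs also called in normal samples.
#' @param frac_in_frame fraction of genuine fusions planted in frame.
#' @param spanning_mu,spanning_size negative-binomial junction-spanning
#'   read counts for genuine fusions.
#' @param artifact_spanning_mu mean spanning reads of artifacts.
#' @param p_outlier probability a genuine fusion gets a planted carrier
#'   expression outlier (acceptor always; donor additionally with
#'   probability 0.3).
#' @param outlier_multiplier planted outlier FPKM as a multiple of the
#'   gene's cohort median (default 10).
#' @param expr_sdlog log-normal spread of baseline FPKM.
#' @param n_oncogene_panel,n_suppressor_panel,n_kinase genes annotated per
#'   function category (kinases drawn partly from the oncogene panel).
#' @param exclusivity_strength probability a fusion carrier also receives an
#'   oncogene-panel mutation (default 0.05).
#' @param background_mutation_rate same probability for non-carriers
#'   (default 0.4).
#' @param suppressor_mutation_rate probability of a suppressor-panel
#'   mutation, both groups.
#' @param noise_variants_per_patient expected filter-violating variants per
#'   patient (Poisson), one planted violation each.
#' @param msi_base_rate non-carrier MSI-H probability.
#' @param msi_enrichment odds multiplier for MSI-H among carriers.
#' @param msi_l_frac MSI-L fraction among non-MSI-H patients.
#' @param surv_rate exponential event hazard (per month).
#' @param fusion_hr carrier hazard ratio.
#' @param censor_min,censor_max uniform censoring window (months).
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_patients = 147L, n_normals = 47L,
                       n_chroms = 20L, n_genes = 60L,
                       n_true_fusions = 25L, n_fusion_patients = 19L,
                       caller_ids = c("GFP", "deFuse", "FusionMap"),
                       caller_sensitivity = c(1.0, 0.9, 0.9),
                       breakpoint_jitter_sd = 10,
                       artifact_rate = 1.5, n_normal_chimeras = 3L,
                       frac_in_frame = 0.7,
                       spanning_mu = 30, spanning_size = 5,
                       artifact_spanning_mu = 6,
                       p_outlier = 0.5, outlier_multiplier = 10,
                       expr_sdlog = 0.6,
                       n_oncogene_panel = 8L, n_suppressor_panel = 8L,
                       n_kinase = 5L,
                       exclusivity_strength = 0.05,
                       background_mutation_rate = 0.4,
                       suppressor_mutation_rate = 0.5,
                       noise_variants_per_patient = 3,
                       msi_base_rate = 0.12, msi_enrichment = 3.5,
                       msi_l_frac = 0.1,
                       surv_rate = 0.01, fusion_hr = 1.0,
                       censor_min = 60, censor_max = 120) {
  cfg <- as.list(environment())
  probs <- c(cfg$caller_sensitivity, frac_in_frame, p_outlier,
             exclusivity_strength, background_mutation_rate,
             suppressor_mutation_rate, msi_base_rate, msi_l_frac)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_patients > 0, n_normals >= 0, n_genes > 1,
            n_true_fusions > 0, n_fusion_patients > 0,
            length(caller_ids) == length(caller_sensitivity))
  class(cfg) <- "sim_config"
  cfg
}

# one multi-exon coding gene; returns a transcript_model
sim_gene <- function(gene, chrom, start) {
  n_ex <- sample(3:8, 1)
  ex_len <- sample(150:400, n_ex, replace = TRUE)
  introns <- if (n_ex > 1) sample(500:5000, n_ex - 1, replace = TRUE) else
    integer(0)
  starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
  ends <- starts + ex_len - 1L
  L <- sum(ex_len)
  utr5 <- sample(0:80, 1)
  utr3 <- sample(0:80, 1)
  utr3 <- utr3 + (L - utr5 - utr3) %% 3L
  strand <- sample(c("+", "-"), 1)
  exonic <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
  # coding bases occupy transcript positions (utr5+1)..(L-utr3)
  if (strand == "+") {
    cds_start <- exonic[utr5 + 1L]; cds_end <- exonic[L - utr3]
  } else {
    cds_start <- exonic[utr3 + 1L]; cds_end <- exonic[L - utr5]
  }
  transcript_model(gene, paste0(gene, ".t1"), chrom, strand,
                   cbind(starts, ends), cds_start, cds_end)
}

# sample an acceptor CDS offset with a prescribed residue class mod 3
sim_offset_with_residue <- function(cds_len, residue, lo, hi) {
  cand <- seq.int(lo, hi)
  cand <- cand[cand %% 3L == residue]
  cand[sample.int(length(cand), 1)]
}

#' Generate a synthetic cohort bundle
#'
#' Draws the toy genome, fusion events, call tables, expression, variants
#' and clinical records described in \code{\link{sim_config}}.  The same
#' seed always yields the identical bundle.  When \code{out_dir} is given,
#' every table is also written in the package's external formats
#' (per-caller \code{calls_<caller>.tsv}, \code{normal_calls.tsv},
#' \code{transcripts.gtf}, \code{domains.tsv}, \code{gene_functions.tsv},
#' \code{panels.tsv}, \code{expression.tsv} + \code{samples.tsv},
#' \code{variants.tsv}, \code{normal_variants.tsv}, \code{clinical.tsv})
#' together with \code{manifest.json}, the ground-truth record.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory (created if missing).
#' @return the bundle: a list with the generated objects and
#'   \code{manifest} (planted truths: per-event filter outcomes, caller
#'   support, outlier flags, oncogenicity labels; per-patient carrier,
#'   mutation and MSI status).
#' @export
generate <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  # ---- genome and genes --------------------------------------------------
  chroms <- sprintf("chrS%02d", seq_len(config$n_chroms))
  gene_names <- sprintf("G%03d", seq_len(config$n_genes))
  gene_chrom <- sort(sample(seq_len(config$n_chroms), config$n_genes,
                            replace = TRUE))
  txs <- list()
  gene_tbl <- NULL
  for (ci in unique(gene_chrom)) {
    idx <- which(gene_chrom == ci)
    cursor <- sample(50000:200000, 1)
    for (gi in idx) {
      tx <- sim_gene(gene_names[gi], chroms[ci], cursor)
      txs[[tx$transcript_id]] <- tx
      span_end <- max(tx$exons[, "end"])
      gene_tbl <- rbind(gene_tbl, data.frame(
        gene = gene_names[gi], chrom = chroms[ci],
        start = cursor, end = span_end, stringsAsFactors = FALSE))
      gap <- if (stats::runif(1) < 0.3) sample(5000:80000, 1) else
        sample(120000:600000, 1)
      cursor <- span_end + gap
    }
  }
  class(txs) <- "transcript_set"
  rep_tx <- representative_transcripts(txs)

  # ---- domains and function annotation ----------------------------------
  dom_pool <- c("PK", "SUP", "TM", "Ig", "FN3", "ZF", "SH2", "SH3", "PH",
                "C2", "WD40", "RING")
  domains <- do.call(rbind, lapply(gene_names, function(g) {
    plen <- rep_tx[[g]]$cds_length %/% 3L
    nd <- sample(1:3, 1)
    start <- sort(sample(seq_len(max(1L, plen - 15L)), nd))
    end <- pmin(plen, start + sample(15:max(16, plen %/% 2), nd,
                                     replace = TRUE))
    data.frame(gene = g, name = sample(dom_pool, nd), start_aa = start,
               end_aa = end, stringsAsFactors = FALSE)
  }))
  onc_panel <- sample(gene_names, config$n_oncogene_panel)
  sup_panel <- sample(setdiff(gene_names, onc_panel),
                      config$n_suppressor_panel)
  n_kin_onc <- min(config$n_kinase, max(1L, config$n_kinase - 2L))
  kinases <- c(sample(onc_panel, min(n_kin_onc, length(onc_panel))),
               sample(setdiff(gene_names, c(onc_panel, sup_panel)),
                      config$n_kinase - min(n_kin_onc, length(onc_panel))))
  categories <- vapply(gene_names, function(g) {
    paste(c(if (g %in% kinases) "kinase",
            if (g %in% onc_panel) "oncogene",
            if (g %in% sup_panel) "suppressor"), collapse = ",")
  }, character(1))
  gene_functions <- data.frame(gene = gene_names,
                               categories = unname(categories),
                               stringsAsFactors = FALSE)
  panels <- data.frame(
    gene = gene_names,
    panel = ifelse(gene_names %in% onc_panel, "oncogene",
                   ifelse(gene_names %in% sup_panel, "suppressor", "other")),
    stringsAsFactors = FALSE)

  # ---- samples and carriers ---------------------------------------------
  patients <- sprintf("T%03d", seq_len(config$n_patients))
  normals <- sprintf("N%03d", seq_len(config$n_normals))
  carriers <- sample(patients, config$n_fusion_patients)

  # ---- candidate gene pairs ---------------------------------------------
  far_pairs <- NULL   # intrachromosomal, >= 100 kb apart
  near_pairs <- NULL  # read-through candidates, < 100 kb apart
  for (ch in unique(gene_tbl$chrom)) {
    g <- gene_tbl[gene_tbl$chrom == ch, ]
    if (nrow(g) < 2) next
    cmb <- utils::combn(nrow(g), 2)
    gap <- g$start[cmb[2, ]] - g$end[cmb[1, ]]
    pr <- data.frame(a = g$gene[cmb[1, ]], b = g$gene[cmb[2, ]], gap = gap,
                     stringsAsFactors = FALSE)
    far_pairs <- rbind(far_pairs, pr[pr$gap >= 100000, ])
    near_pairs <- rbind(near_pairs, pr[pr$gap > 0 & pr$gap < 100000, ])
  }
  inter_pairs <- NULL
  for (i in seq_len(config$n_true_fusions)) {
    gs <- sample(gene_names, 2)
    if (gene_tbl$chrom[match(gs[1], gene_tbl$gene)] !=
        gene_tbl$chrom[match(gs[2], gene_tbl$gene)])
      inter_pairs <- rbind(inter_pairs,
                           data.frame(a = gs[1], b = gs[2], gap = NA,
                                      stringsAsFactors = FALSE))
  }

  used_pairs <- character(0)
  take_pair <- function(pool) {
    key <- paste(pool$a, pool$b)
    pool <- pool[!(key %in% used_pairs), , drop = FALSE]
    if (!nrow(pool)) return(NULL)
    p <- pool[sample.int(nrow(pool), 1), ]
    used_pairs <<- c(used_pairs, paste(p$a, p$b))
    p
  }

  # ---- planted fusion events --------------------------------------------
  plant_event <- function(type, sample_id, pair, in_frame_p, spanning) {
    two <- sample(c(pair$a, pair$b))  # random donor/acceptor orientation
    dtx <- rep_tx[[two[1]]]; atx <- rep_tx[[two[2]]]
    o_d <- sample(30:(dtx$cds_length - 31L), 1)
    target <- if (stats::runif(1) < in_frame_p) (o_d + 1L) %% 3L else
      sample(setdiff(0:2, (o_d + 1L) %% 3L), 1)
    o_a <- sim_offset_with_residue(atx$cds_length, target, 30L,
                                   atx$cds_length - 61L)
    data.frame(type = type, sample_id = sample_id,
               donor_gene = dtx$gene, acceptor_gene = atx$gene,
               chrom1 = dtx$chrom, pos1 = cds_to_genomic(dtx, o_d),
               strand1 = dtx$strand,
               chrom2 = atx$chrom, pos2 = cds_to_genomic(atx, o_a),
               strand2 = atx$strand,
               donor_offset = o_d, acceptor_offset = o_a,
               donor_phase = (o_d + 1L) %% 3L, acceptor_phase = o_a %% 3L,
               spanning_reads = spanning, stringsAsFactors = FALSE)
  }

  events <- NULL
  for (i in seq_len(config$n_true_fusions)) {
    pair <- if (stats::runif(1) < 0.8) take_pair(far_pairs) else
      take_pair(inter_pairs)
    if (is.null(pair)) pair <- take_pair(far_pairs)
    if (is.null(pair)) pair <- take_pair(inter_pairs)
    if (is.null(pair)) break
    carrier <- if (i <= length(carriers)) carriers[i] else sample(carriers, 1)
    events <- rbind(events, plant_event(
      "true", carrier, pair, config$frac_in_frame,
      stats::rnbinom(1, mu = config$spanning_mu, size = config$spanning_size)))
  }
  chim_normal_samples <- list()
  for (i in seq_len(config$n_normal_chimeras)) {
    pair <- take_pair(far_pairs)
    if (is.null(pair)) break
    ev <- plant_event("normal_chimera", sample(patients, 1), pair, 1,
                      stats::rnbinom(1, mu = config$spanning_mu,
                                     size = config$spanning_size))
    events <- rbind(events, ev)
    chim_normal_samples[[nrow(events)]] <-
      sample(normals, sample(1:min(3, length(normals)), 1))
  }
  n_art <- stats::rpois(config$n_patients, config$artifact_rate)
  if (nrow(near_pairs %||% data.frame()) > 0) {
    for (p in which(n_art > 0)) {
      for (j in seq_len(n_art[p])) {
        pr <- near_pairs[sample.int(nrow(near_pairs), 1), ]
        events <- rbind(events, plant_event(
          "artifact", patients[p], pr, 1 / 3,
          stats::rnbinom(1, mu = config$artifact_spanning_mu, size = 3)))
      }
    }
  }
  n_ev <- nrow(events)
  events$event_id <- sprintf("F%03d", seq_len(n_ev))
  events$in_frame <- events$donor_phase == events$acceptor_phase
  events$mid_distance <- compute_mid_distance(events$chrom1, events$pos1,
                                              events$chrom2, events$pos2)
  events$in_normal <- events$type == "normal_chimera"

  # ---- caller detection -------------------------------------------------
  n_callers <- length(config$caller_ids)
  det <- matrix(FALSE, n_ev, n_callers,
                dimnames = list(NULL, config$caller_ids))
  for (k in seq_len(n_callers)) {
    # artifacts are caller-idiosyncratic: cross-validators rarely agree
    pdet <- ifelse(events$type == "artifact" & k > 1, 0.3,
                   config$caller_sensitivity[k])
    det[, k] <- stats::runif(n_ev) < pdet
  }
  events$detected_by <- apply(det, 1, function(r)
    paste(config$caller_ids[r], collapse = ","))
  events$support <- rowSums(det)

  # ---- per-caller call tables -------------------------------------------
  jitter_pos <- function(pos, primary) {
    if (primary || config$breakpoint_jitter_sd == 0) return(pos)
    pmax(1L, as.integer(pos + round(stats::rnorm(length(pos), 0,
                                    config$breakpoint_jitter_sd))))
  }
  calls <- stats::setNames(vector("list", n_callers), config$caller_ids)
  for (k in seq_len(n_callers)) {
    ii <- which(det[, k])
    if (!length(ii)) {
      calls[[k]] <- fusion_calls(character(0), character(0), character(0),
                                 character(0), character(0), integer(0),
                                 character(0), character(0), integer(0),
                                 character(0), integer(0))
      next
    }
    e <- events[ii, ]
    calls[[k]] <- fusion_calls(
      sample_id = e$sample_id, caller_id = config$caller_ids[k],
      donor_gene = e$donor_gene, acceptor_gene = e$acceptor_gene,
      chrom1 = e$chrom1, pos1 = jitter_pos(e$pos1, k == 1),
      strand1 = e$strand1,
      chrom2 = e$chrom2, pos2 = jitter_pos(e$pos2, k == 1),
      strand2 = e$strand2,
      spanning_reads = if (k == 1) e$spanning_reads else
        stats::rnbinom(length(ii), mu = config$spanning_mu,
                       size = config$spanning_size),
      donor_phase = e$donor_phase, acceptor_phase = e$acceptor_phase)
  }
  chim_idx <- which(events$type == "normal_chimera")
  normal_calls <- if (length(chim_idx)) {
    do.call(rbind, lapply(chim_idx, function(i) {
      ns <- chim_normal_samples[[i]]
      e <- events[i, ]
      fusion_calls(sample_id = ns, caller_id = config$caller_ids[1],
                   donor_gene = e$donor_gene, acceptor_gene = e$acceptor_gene,
                   chrom1 = e$chrom1, pos1 = e$pos1, strand1 = e$strand1,
                   chrom2 = e$chrom2, pos2 = e$pos2, strand2 = e$strand2,
                   spanning_reads = stats::rnbinom(length(ns),
                     mu = config$spanning_mu, size = config$spanning_size),
                   donor_phase = e$donor_phase,
                   acceptor_phase = e$acceptor_phase)
    }))
  } else {
    calls[[1]][0, ]
  }

  # ---- expression with planted outliers ---------------------------------
  all_samples <- c(patients, normals)
  meanlog <- stats::runif(config$n_genes, log(0.5), log(30))
  expr_vals <- matrix(
    stats::rlnorm(config$n_genes * length(all_samples),
                  meanlog = rep(meanlog, length(all_samples)),
                  sdlog = config$expr_sdlog),
    nrow = config$n_genes,
    dimnames = list(gene_names, all_samples))
  events$outlier_donor <- FALSE
  events$outlier_acceptor <- FALSE
  true_idx <- which(events$type == "true")
  for (i in true_idx) {
    if (stats::runif(1) >= config$p_outlier) next
    plant <- function(gene) {
      med <- exp(meanlog[match(gene, gene_names)])
      expr_vals[gene, events$sample_id[i]] <<-
        config$outlier_multiplier * med * stats::rlnorm(1, 0, 0.1)
    }
    plant(events$acceptor_gene[i])
    events$outlier_acceptor[i] <- TRUE
    if (stats::runif(1) < 0.3) {
      plant(events$donor_gene[i])
      events$outlier_donor[i] <- TRUE
    }
  }
  expr <- expression_matrix(
    expr_vals,
    stats::setNames(rep(c("tumour", "normal"),
                        c(length(patients), length(normals))), all_samples),
    pairing = stats::setNames(normals,
                              patients[seq_len(config$n_normals)]))

  # ---- somatic variants with planted exclusivity ------------------------
  carrier_flag <- patients %in% carriers
  clean_variant <- function(sample_id, gene) {
    gt <- gene_tbl[match(gene, gene_tbl$gene), ]
    depth <- 20L + stats::rpois(1, 80)
    alt <- max(2L, stats::rbinom(1, depth, stats::runif(1, 0.15, 0.6)))
    alleles <- sample(c("A", "C", "G", "T"), 2)
    data.frame(sample = sample_id, gene = gene, chrom = gt$chrom,
               pos = sample(gt$start:gt$end, 1),
               ref = alleles[1], alt = alleles[2],
               total_depth = depth, alt_depth = min(alt, depth),
               effect = sample(c("frameshift", "non-synonymous",
                                 "stop-gain", "stop-loss"), 1,
                               prob = c(0.1, 0.75, 0.1, 0.05)),
               region = "exon",
               fs = round(stats::runif(1, 0, 15), 2),
               qd = round(stats::runif(1, 3, 25), 2),
               pop_maf = if (stats::runif(1) < 0.8) NA_real_ else
                 round(stats::runif(1, 0, 0.008), 4),
               stringsAsFactors = FALSE)
  }
  variants <- NULL
  normal_variants <- NULL
  onc_mut <- logical(config$n_patients)
  for (p in seq_len(config$n_patients)) {
    sid <- patients[p]
    p_onc <- if (carrier_flag[p]) config$exclusivity_strength else
      config$background_mutation_rate
    if (stats::runif(1) < p_onc) {
      onc_mut[p] <- TRUE
      for (g in sample(onc_panel, sample(1:2, 1)))
        variants <- rbind(variants, clean_variant(sid, g))
    }
    if (stats::runif(1) < config$suppressor_mutation_rate) {
      for (g in sample(sup_panel, sample(1:2, 1)))
        variants <- rbind(variants, clean_variant(sid, g))
    }
    for (j in seq_len(stats::rpois(1, config$noise_variants_per_patient))) {
      v <- clean_variant(sid, sample(gene_names, 1))
      kind <- sample(c("low_depth", "low_alt", "low_vaf", "intron",
                       "silent", "germline_maf", "bad_fs", "bad_qd",
                       "in_normal"), 1)
      if (kind == "low_depth") { v$total_depth <- 5L
                                 v$alt_depth <- min(v$alt_depth, 5L) }
      if (kind == "low_alt") v$alt_depth <- 1L
      if (kind == "low_vaf") { v$total_depth <- 400L; v$alt_depth <- 3L }
      if (kind == "intron") v$region <- "intron"
      if (kind == "silent") v$effect <- "other"
      if (kind == "germline_maf") v$pop_maf <- round(stats::runif(1, 0.02,
                                                                  0.3), 3)
      if (kind == "bad_fs") v$fs <- round(stats::runif(1, 31, 60), 2)
      if (kind == "bad_qd") v$qd <- round(stats::runif(1, 0.1, 1.9), 2)
      if (kind == "in_normal") {
        nv <- v
        nv$sample <- if (p <= config$n_normals) normals[p] else
          sample(normals, 1)
        normal_variants <- rbind(normal_variants, nv)
      }
      variants <- rbind(variants, v)
    }
  }

  # ---- clinical records --------------------------------------------------
  p_msih <- ifelse(carrier_flag,
                   stats::plogis(stats::qlogis(config$msi_base_rate) +
                                   log(config$msi_enrichment)),
                   config$msi_base_rate)
  msi_h <- stats::runif(config$n_patients) < p_msih
  msi_status <- ifelse(msi_h, "MSI-H",
                       ifelse(stats::runif(config$n_patients) <
                                config$msi_l_frac, "MSI-L", "MSS"))
  size <- round(pmax(0.5, stats::rnorm(
    config$n_patients,
    ifelse(carrier_flag, 4.8, 5.8),
    ifelse(carrier_flag, 1.5, 2.0))), 1)
  event_time <- stats::rexp(config$n_patients,
                            config$surv_rate *
                              ifelse(carrier_flag, config$fusion_hr, 1))
  censor_time <- stats::runif(config$n_patients, config$censor_min,
                              config$censor_max)
  clinical <- data.frame(
    sample = patients,
    age = pmin(90, pmax(25, round(stats::rnorm(config$n_patients, 60, 12)))),
    size = size,
    sex = sample(c("M", "F"), config$n_patients, replace = TRUE,
                 prob = c(0.52, 0.48)),
    location = sample(c("right", "left"), config$n_patients, replace = TRUE,
                      prob = c(0.38, 0.62)),
    histology = sample(c("well", "moderately", "poorly", "mucinous"),
                       config$n_patients, replace = TRUE,
                       prob = c(0.18, 0.75, 0.05, 0.02)),
    invasion_depth = sample(c("T1", "T2", "T3", "T4"), config$n_patients,
                            replace = TRUE, prob = c(0.01, 0.11, 0.73, 0.15)),
    perineural = stats::rbinom(config$n_patients, 1, 0.4),
    lymphovascular = stats::rbinom(config$n_patients, 1, 0.21),
    lymph_node = stats::rbinom(config$n_patients, 1, 0.51),
    msi_status = msi_status,
    os_months = round(pmin(event_time, censor_time), 1),
    os_event = as.integer(event_time <= censor_time),
    stringsAsFactors = FALSE
  )

  # ---- ground truth ------------------------------------------------------
  ann_lookup <- stats::setNames(gene_functions$categories,
                                gene_functions$gene)
  dom_by_gene <- split(domains, domains$gene)
  sup_trunc <- function(i) {
    fired <- FALSE
    for (side in c("donor", "acceptor")) {
      g <- events[[paste0(side, "_gene")]][i]
      if (!grepl("suppressor", ann_lookup[g])) next
      plen <- rep_tx[[g]]$cds_length %/% 3L
      if (side == "donor") {
        ret_lo <- 1L; ret_hi <- (events$donor_offset[i] + 1L) %/% 3L
      } else {
        ret_lo <- events$acceptor_offset[i] %/% 3L + 1L; ret_hi <- plen
      }
      d <- dom_by_gene[[g]]
      len <- d$end_aa - d$start_aa + 1L
      ov <- pmax(0L, pmin(d$end_aa, ret_hi) - pmax(d$start_aa, ret_lo) + 1L)
      if (any(ov == 0L) || any(ov > 0L & ov < len & ov / len < 0.9))
        fired <- TRUE
    }
    fired
  }
  events$suppressor_truncated <- vapply(seq_len(n_ev), sup_trunc, logical(1))
  has_cat <- function(gene, cat) grepl(cat, ann_lookup[gene])
  events$oncogenic_features <- (events$outlier_donor |
                                  events$outlier_acceptor) |
    has_cat(events$donor_gene, "kinase") |
    has_cat(events$acceptor_gene, "kinase") |
    has_cat(events$donor_gene, "oncogene") |
    has_cat(events$acceptor_gene, "oncogene") |
    events$suppressor_truncated
  events$screen_pass <- det[, 1] & events$in_frame & !events$in_normal &
    events$spanning_reads >= 10 &
    (is.na(events$mid_distance) | events$mid_distance >= 100000)
  events$validated_truth <- events$screen_pass & events$support >= 2
  events$oncogenic_truth <- events$validated_truth &
    events$oncogenic_features

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    patients = data.frame(sample = patients, carrier = carrier_flag,
                          oncogene_mutation = onc_mut,
                          msi_status = msi_status, stringsAsFactors = FALSE),
    fusions = events
  )

  bundle <- list(
    config = config,
    transcripts = txs,
    gene_table = gene_tbl,
    domains = domains,
    gene_functions = gene_functions,
    panels = panels,
    calls = calls,
    normal_calls = normal_calls,
    expression = expr,
    variants = variants,
    normal_variants = normal_variants,
    clinical = clinical,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a generated bundle to disk
#'
#' @param bundle output of \code{\link{generate}}.
#' @param out_dir directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    fp_stop("cannot create output directory '%s'", out_dir)
  for (cid in names(bundle$calls))
    write_fusion_calls(bundle$calls[[cid]],
                       file.path(out_dir, paste0("calls_", cid, ".tsv")))
  write_fusion_calls(bundle$normal_calls,
                     file.path(out_dir, "normal_calls.tsv"))
  write_transcripts_gtf(bundle$transcripts,
                        file.path(out_dir, "transcripts.gtf"))
  write_domains(bundle$domains, file.path(out_dir, "domains.tsv"))
  write_gene_functions(bundle$gene_functions,
                       file.path(out_dir, "gene_functions.tsv"))
  utils::write.table(bundle$panels, file.path(out_dir, "panels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(bundle$expression, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "samples.tsv"))
  write_variants(bundle$variants, file.path(out_dir, "variants.tsv"))
  write_variants(bundle$normal_variants,
                 file.path(out_dir, "normal_variants.tsv"))
  write_clinical(bundle$clinical, file.path(out_dir, "clinical.tsv"))
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare pipeline output against the generator's ground truth
#'
#' Stage-wise confusion counts between a \code{\link{run_all}} result and
#' the manifest of the bundle it was run on: screening (calls that should
#' survive the filter cascade), consensus (screen survivors with >= 2
#' caller support) and oncogenicity (validated fusions with planted
#' oncogenic features).  Refuses to compare a run and a manifest from
#' different bundles (seed mismatch).
#'
#' @param results a \code{\link{run_all}} result.
#' @param manifest the \code{manifest} element of a generated bundle.
#' @return data frame: stage, tp, fp, fn, sensitivity, precision.
#' @export
ground_truth_compare <- function(results, manifest) {
  if (!is.null(results$bundle_seed) && !is.null(manifest$seed) &&
      results$bundle_seed != manifest$seed)
    fp_stop("results (bundle seed %s) and manifest (seed %s) come from different bundles",
            results$bundle_seed, manifest$seed)
  ev <- manifest$fusions
  key <- function(s, d, a) paste(s, d, a, sep = "\r")
  truth_key <- key(ev$sample_id, ev$donor_gene, ev$acceptor_gene)
  stages <- list(
    screening = list(
      truth = unique(truth_key[ev$screen_pass]),
      pred = unique(key(results$screened$sample_id[
                          results$screened$status == "survivor"],
                        results$screened$donor_gene[
                          results$screened$status == "survivor"],
                        results$screened$acceptor_gene[
                          results$screened$status == "survivor"]))),
    consensus = list(
      truth = unique(truth_key[ev$validated_truth]),
      pred = unique(key(results$validated$groups$sample_id,
                        results$validated$groups$donor_gene,
                        results$validated$groups$acceptor_gene))),
    oncogenicity = list(
      truth = unique(truth_key[ev$oncogenic_truth]),
      pred = unique(key(
        results$classifications$sample_id[results$classifications$oncogenic],
        results$classifications$donor_gene[results$classifications$oncogenic],
        results$classifications$acceptor_gene[
          results$classifications$oncogenic])))
  )
  do.call(rbind, lapply(names(stages), function(nm) {
    s <- stages[[nm]]
    tp <- length(intersect(s$truth, s$pred))
    fp <- length(setdiff(s$pred, s$truth))
    fn <- length(setdiff(s$truth, s$pred))
    data.frame(stage = nm, tp = tp, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
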