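# The fusion-call filter cascade: reading frame, absence from matched
# normals, junction-spanning read support, and intrachromosomal breakpoint
# distance.  Filters are evaluated independently (never short-circuited) so
# every call leaves with a complete audit record, and the survivor set is
# invariant to filter order by construction.

#' Screening configuration
#'
#' Thresholds of the filter cascade.  The distance filter applies only to
#' intrachromosomal calls (read-through chimeras between neighbouring genes
#' are its target; interchromosomal rearrangements bypass it) and both
#' numeric thresholds are inclusive: spanning reads of exactly
#' \code{min_spanning}, or a breakpoint separation of exactly
#' \code{min_intrachrom_distance}, pass.
#'
#' @param min_spanning minimum junction-spanning reads (default 10).
#' @param min_intrachrom_distance minimum breakpoint separation in bp for
#'   intrachromosomal calls (default 100,000).
#' @param require_in_frame drop out-of-frame fusions (default TRUE).
#' @param require_absent_in_normal drop fusions whose gene pair is also
#'   called in any normal sample (default TRUE).
#' @param orientation_sensitive whether normal-tissue exclusion matches the
#'   ordered (donor, acceptor) pair (default TRUE) or either orientation.
#' @return list of class \code{"screen_config"}.
#' @export
screen_config <- function(min_spanning = 10L,
                          min_intrachrom_distance = 100000L,
                          require_in_frame = TRUE,
                          require_absent_in_normal = TRUE,
                          orientation_sensitive = TRUE) {
  stopifnot(min_spanning >= 0, min_intrachrom_distance >= 0)
  structure(list(min_spanning = as.integer(min_spanning),
                 min_intrachrom_distance = as.integer(min_intrachrom_distance),
                 require_in_frame = isTRUE(require_in_frame),
                 require_absent_in_normal = isTRUE(require_absent_in_normal),
                 orientation_sensitive = isTRUE(orientation_sensitive)),
            class = "screen_config")
}

#' Breakpoint separation ("mid distance") of a fusion
#'
#' The genomic distance between the two breakpoints of an intrachromosomal
#' fusion, \code{|pos1 - pos2|}; undefined (\code{NA}) for interchromosomal
#' fusions.  Symmetric in its arguments and non-negative.  E.g. breakpoints
#' chr2:29446394 and chr2:37143221 are separated by 7,696,827 bp.
#'
#' @param chrom1,pos1 first breakpoint (chromosome, 1-based position).
#' @param chrom2,pos2 second breakpoint.
#' @return numeric vector of distances in bp (\code{NA} when chromosomes
#'   differ).
#' @export
compute_mid_distance <- function(chrom1, pos1, chrom2, pos2) {
  ifelse(as.character(chrom1) == as.character(chrom2),
         abs(as.numeric(pos1) - as.numeric(pos2)), NA_real_)
}

#' Is a fusion absent from all normal-sample calls?
#'
#' A tumour fusion fails the normal-tissue filter when any normal-sample
#' call involves the same gene pair.  Matching is at the gene-pair level
#' (not breakpoint-exact), because breakpoint jitter between samples and
#' callers would otherwise defeat the filter; with
#' \code{orientation_sensitive = TRUE} (default) only the same ordered
#' (donor, acceptor) pair matches.
#'
#' @param calls \code{fusion_calls} from tumour samples.
#' @param normal_calls \code{fusion_calls} from normal samples (possibly
#'   empty or \code{NULL}).
#' @param orientation_sensitive match ordered pairs only (default TRUE).
#' @return logical vector, one element per row of \code{calls}: \code{TRUE}
#'   if no normal call matches.
#' @export
absent_in_normal <- function(calls, normal_calls,
                             orientation_sensitive = TRUE) {
  if (is.null(normal_calls) || nrow(normal_calls) == 0)
    return(rep(TRUE, nrow(calls)))
  pair <- function(d, a) paste(d, a, sep = "\r")
  norm <- pair(normal_calls$donor_gene, normal_calls$acceptor_gene)
  hit <- pair(calls$donor_gene, calls$acceptor_gene) %in% norm
  if (!orientation_sensitive)
    hit <- hit | pair(calls$acceptor_gene, calls$donor_gene) %in% norm
  !hit
}

#' Annotate fusion calls with recomputed junction phases
#'
#' Resolves each partner gene to its representative transcript and
#' recomputes the junction phases from the breakpoints
#' (\code{\link{junction_phases}}), overwriting the caller-reported
#' \code{donor_phase}/\code{acceptor_phase} columns and adding
#' \code{in_frame}, \code{frame_flag}, \code{frame_reason} and
#' \code{phase_mismatch} (TRUE when the caller reported phases and they
#' disagree with the recomputation).  Calls whose genes are missing from the
#' transcript models keep \code{in_frame = NA} with
#' \code{frame_reason = "gene not in transcript models"}.
#'
#' @param calls a \code{fusion_calls} data frame.
#' @param transcripts a \code{transcript_set}.
#' @return \code{calls} with the frame columns added/updated.
#' @export
annotate_frames <- function(calls, transcripts) {
  rep_tx <- representative_transcripts(transcripts)
  n <- nrow(calls)
  dp <- ap <- rep(NA_integer_, n)
  inf <- rep(NA, n)
  flag <- reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    dtx <- rep_tx[[calls$donor_gene[i]]]
    atx <- rep_tx[[calls$acceptor_gene[i]]]
    if (is.null(dtx) || is.null(atx)) {
      reason[i] <- "gene not in transcript models"
      next
    }
    jp <- junction_phases(dtx, calls$pos1[i], atx, calls$pos2[i])
    dp[i] <- jp$donor_phase; ap[i] <- jp$acceptor_phase
    inf[i] <- jp$in_frame; flag[i] <- jp$flag; reason[i] <- jp$reason
  }
  mismatch <- !is.na(calls$donor_phase) & !is.na(dp) &
    (calls$donor_phase != dp | calls$acceptor_phase != ap)
  calls$donor_phase <- dp
  calls$acceptor_phase <- ap
  calls$in_frame <- inf
  calls$frame_flag <- flag
  calls$frame_reason <- reason
  calls$phase_mismatch <- mismatch
  calls
}

#' Apply the filter cascade to fusion calls
#'
#' Every input call receives a full audit record: the four filter flags
#' (\code{in_frame}, \code{absent_in_normal}, \code{spanning_pass},
#' \code{distance_pass}), the breakpoint separation (\code{mid_distance}),
#' a \code{status} of \code{"survivor"}, \code{"rejected"} or
#' \code{"unresolvable"} (frame requested but not computable, e.g. gene
#' missing from the transcript models) and the comma-separated
#' \code{reject_reasons}.  Disabled filters still have their flags recorded
#' but do not reject.  Survivors + rejected + unresolvable always equals the
#' input count, and the survivor set does not depend on any filter order.
#'
#' @param calls \code{fusion_calls}, ideally pre-annotated with
#'   \code{\link{annotate_frames}}; otherwise \code{in_frame} is derived
#'   from the caller-reported phases.
#' @param normal_calls \code{fusion_calls} from normal samples, or
#'   \code{NULL}.
#' @param config a \code{\link{screen_config}}.
#' @return \code{calls} with audit columns, class \code{"fusion_screen"}.
#' @export
apply_screen <- function(calls, normal_calls = NULL, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  out <- as.data.frame(calls)
  if (is.null(out$in_frame))
    out$in_frame <- ifelse(is.na(out$donor_phase) | is.na(out$acceptor_phase),
                           NA, out$donor_phase == out$acceptor_phase)
  out$absent_in_normal <- absent_in_normal(out, normal_calls,
                                           config$orientation_sensitive)
  out$spanning_pass <- out$spanning_reads >= config$min_spanning
  out$mid_distance <- compute_mid_distance(out$chrom1, out$pos1,
                                           out$chrom2, out$pos2)
  out$distance_pass <- is.na(out$mid_distance) |
    out$mid_distance >= config$min_intrachrom_distance

  unresolvable <- config$require_in_frame & is.na(out$in_frame)
  checks <- cbind(
    in_frame = if (config$require_in_frame) out$in_frame else TRUE,
    absent_in_normal = if (config$require_absent_in_normal)
      out$absent_in_normal else TRUE,
    spanning = out$spanning_pass,
    distance = out$distance_pass
  )
  pass <- !unresolvable & apply(checks, 1, function(x) all(x %in% TRUE))
  reasons <- apply(checks, 1, function(x)
    paste(colnames(checks)[!(x %in% TRUE)], collapse = ","))
  out$status <- ifelse(unresolvable, "unresolvable",
                       ifelse(pass, "survivor", "rejected"))
  out$reject_reasons <- ifelse(out$status == "rejected", reasons, "")
  class(out) <- c("fusion_screen", "data.frame")
  attr(out, "config") <- config
  out
}

#' @rdname apply_screen
#' @param screened output of \code{apply_screen}.
#' @export
screen_survivors <- function(screened) {
  out <- screened[screened$status == "survivor", , drop = FALSE]
  rownames(out) <- NULL
  out
}
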