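# Fusion coding-sequence reconstruction: genomic <-> CDS coordinate
# conversion, junction reading-frame phases, and protein-domain retention.
#
# Conventions used throughout (recorded here because they are the package's
# reading of common but under-specified practice):
#   * the donor breakpoint is the LAST retained base of the donor transcript,
#     the acceptor breakpoint the FIRST retained base of the acceptor (both
#     1-based inclusive genomic positions);
#   * the donor junction phase is (number of retained donor coding bases)
#     mod 3; the acceptor junction phase is (number of discarded acceptor
#     5' coding bases) mod 3; a fusion is in frame iff the phases are equal,
#     which is exactly the condition for downstream acceptor codons to be
#     translated in their native frame;
#   * a "0->1"-style label therefore reads (donor phase -> acceptor phase).

#' Map a genomic position to a CDS offset
#'
#' Converts a genomic coordinate to a 0-based offset into the coding
#' sequence of a transcript, counting coding bases 5' to 3' in transcript
#' orientation (strand-aware).  Positions not inside the CDS are classified
#' rather than errored: \code{"utr5"}/\code{"utr3"} (exonic but outside the
#' coding bounds, named relative to transcript orientation), \code{"intron"}
#' (with the nearest exon index) or \code{"outside"} the transcript span.
#'
#' @param tx a \code{\link{transcript_model}}.
#' @param pos 1-based genomic position on \code{tx}'s chromosome.
#' @return list with \code{offset} (0-based integer, \code{NA} when not in
#'   the CDS), \code{status} (\code{"cds"}, \code{"utr5"}, \code{"utr3"},
#'   \code{"intron"}, \code{"outside"}) and, for introns,
#'   \code{nearest_exon} (index into \code{tx$exons}, genomic order).
#' @export
genomic_to_cds <- function(tx, pos) {
  stopifnot(inherits(tx, "transcript_model"), length(pos) == 1, !is.na(pos))
  segs <- tx$cds_segments
  lens <- segs[, "end"] - segs[, "start"] + 1L
  hit <- which(pos >= segs[, "start"] & pos <= segs[, "end"])
  if (length(hit) == 1) {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1L)]) else 0L
    plus_off <- before + (pos - segs[hit, "start"])
    off <- if (tx$strand == "+") plus_off else tx$cds_length - 1L - plus_off
    return(list(offset = as.integer(off), status = "cds"))
  }
  ex <- tx$exons
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (in_exon) {
    left_of_cds <- pos < tx$cds_start
    status <- if (tx$strand == "+") {
      if (left_of_cds) "utr5" else "utr3"
    } else {
      if (left_of_cds) "utr3" else "utr5"
    }
    return(list(offset = NA_integer_, status = status))
  }
  if (pos < min(ex[, "start"]) || pos > max(ex[, "end"]))
    return(list(offset = NA_integer_, status = "outside"))
  dist <- pmin(abs(pos - ex[, "start"]), abs(pos - ex[, "end"]))
  list(offset = NA_integer_, status = "intron",
       nearest_exon = which.min(dist))
}

#' Map a CDS offset back to its genomic position
#'
#' Inverse of \code{\link{genomic_to_cds}} for in-CDS offsets; used by the
#' synthetic-data generator to place breakpoints with a prescribed phase.
#'
#' @param tx a \code{\link{transcript_model}}.
#' @param offset 0-based coding offset in \code{[0, cds_length - 1]}.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, offset) {
  stopifnot(inherits(tx, "transcript_model"),
            length(offset) == 1, offset >= 0, offset < tx$cds_length)
  plus_off <- if (tx$strand == "+") offset else tx$cds_length - 1L - offset
  segs <- tx$cds_segments
  lens <- segs[, "end"] - segs[, "start"] + 1L
  cum <- cumsum(lens)
  seg <- which(plus_off < cum)[1]
  within <- plus_off - (if (seg > 1) cum[seg - 1L] else 0L)
  as.integer(segs[seg, "start"] + within)
}

#' Junction reading-frame phases of a candidate fusion
#'
#' Computes the donor and acceptor junction phases and the in-frame verdict
#' for a fusion defined by two breakpoints on two transcripts.  Breakpoints
#' falling outside the coding sequence are handled explicitly:
#' \itemize{
#'   \item donor breakpoint in the 5' UTR: the donor contributes no coding
#'     sequence; phase 0 with flag \code{"promoter_swap"} (in frame only if
#'     the acceptor phase is also 0, i.e. the acceptor ORF starts cleanly);
#'   \item donor breakpoint in the 3' UTR: the full donor CDS (a multiple of
#'     3) is retained; phase 0 with flag \code{"donor_cds_complete"};
#'   \item acceptor breakpoint in the 5' UTR: nothing coding is discarded;
#'     phase 0;
#'   \item acceptor breakpoint in the 3' UTR, or either breakpoint intronic
#'     or outside the transcript: phases undefined, fusion marked not in
#'     frame with the reason.
#' }
#'
#' @param donor_tx,acceptor_tx \code{\link{transcript_model}} objects.
#' @param donor_bp,acceptor_bp 1-based genomic breakpoint positions (last
#'   retained donor base / first retained acceptor base).
#' @return list: \code{donor_phase}, \code{acceptor_phase} (integers or
#'   \code{NA}), \code{in_frame} (logical), \code{donor_retained_nt},
#'   \code{acceptor_discarded_nt}, \code{flag} (\code{NA},
#'   \code{"promoter_swap"} or \code{"donor_cds_complete"}) and
#'   \code{reason} (why phases are undefined, else \code{NA}).
#' @export
junction_phases <- function(donor_tx, donor_bp, acceptor_tx, acceptor_bp) {
  out <- list(donor_phase = NA_integer_, acceptor_phase = NA_integer_,
              in_frame = FALSE, donor_retained_nt = NA_integer_,
              acceptor_discarded_nt = NA_integer_,
              flag = NA_character_, reason = NA_character_)
  d <- genomic_to_cds(donor_tx, donor_bp)
  a <- genomic_to_cds(acceptor_tx, acceptor_bp)

  if (d$status == "cds") {
    out$donor_retained_nt <- d$offset + 1L
  } else if (d$status == "utr5") {
    out$donor_retained_nt <- 0L
    out$flag <- "promoter_swap"
  } else if (d$status == "utr3") {
    out$donor_retained_nt <- donor_tx$cds_length
    out$flag <- "donor_cds_complete"
  } else {
    out$reason <- paste0("donor breakpoint ", d$status)
    return(out)
  }

  if (a$status == "cds") {
    out$acceptor_discarded_nt <- a$offset
  } else if (a$status == "utr5") {
    out$acceptor_discarded_nt <- 0L
  } else if (a$status == "utr3") {
    out$reason <- "acceptor breakpoint after CDS end"
    return(out)
  } else {
    out$reason <- paste0("acceptor breakpoint ", a$status)
    return(out)
  }

  out$donor_phase <- out$donor_retained_nt %% 3L
  out$acceptor_phase <- out$acceptor_discarded_nt %% 3L
  out$in_frame <- out$donor_phase == out$acceptor_phase
  out
}

#' Domain retention in a retained protein segment
#'
#' Given the interval of a native protein that survives in the fusion
#' product, classifies each annotated domain of that protein as
#' \code{retained} (entirely inside the retained segment), \code{lost}
#' (entirely outside) or \code{truncated} (straddling the breakpoint), with
#' the retained fraction of the domain's length.  E.g. a 325-aa region of
#' which 293 aa survive is \code{truncated} with fraction 293/325.
#'
#' @param domains data frame with columns \code{name}, \code{start_aa},
#'   \code{end_aa} (1-based inclusive, native protein coordinates).
#' @param retained_start,retained_end the retained interval (aa); use
#'   \code{retained_start = 1} for the donor side and
#'   \code{retained_end = protein_length} for the acceptor side.
#' @param protein_length native protein length in aa; domains extending
#'   beyond it raise an annotation error.
#' @return data frame \code{name, status, fraction}.
#' @export
domain_retention <- function(domains, retained_start, retained_end,
                             protein_length) {
  if (any(domains$end_aa > protein_length))
    fp_stop("domain '%s' extends beyond protein length %d",
            domains$name[domains$end_aa > protein_length][1], protein_length)
  len <- domains$end_aa - domains$start_aa + 1L
  ov <- pmax(0L, pmin(domains$end_aa, retained_end) -
                   pmax(domains$start_aa, retained_start) + 1L)
  status <- ifelse(ov == len, "retained", ifelse(ov == 0L, "lost", "truncated"))
  data.frame(name = domains$name, status = status,
             fraction = ov / len, stringsAsFactors = FALSE)
}

#' Reconstruct a fusion protein and score domain retention
#'
#' Combines \code{\link{junction_phases}} with per-side
#' \code{\link{domain_retention}}.  Amino-acid bookkeeping: the donor
#' contributes its complete codons (\code{floor(retained_nt / 3)} aa); when
#' the fusion is in frame the total protein length is (retained donor nt +
#' retained acceptor nt) / 3 and the acceptor segment is the remainder, so
#' the junction codon (when split between partners) is attributed to the
#' acceptor side.  Native-protein lengths are \code{cds_length / 3}.
#'
#' @inheritParams junction_phases
#' @param domains optional domain table (\code{gene, name, start_aa,
#'   end_aa}) covering either partner.
#' @return object of class \code{"fusion_protein"}: the
#'   \code{junction_phases} fields plus \code{donor_segment_aa},
#'   \code{acceptor_segment_aa}, \code{total_aa} (\code{NA} unless in
#'   frame), \code{donor_retained_interval}, \code{acceptor_retained_interval}
#'   (aa intervals on the native proteins) and \code{retained_domains}
#'   (data frame \code{gene, side, name, status, fraction}).
#' @export
fusion_protein <- function(donor_tx, donor_bp, acceptor_tx, acceptor_bp,
                           domains = NULL) {
  jp <- junction_phases(donor_tx, donor_bp, acceptor_tx, acceptor_bp)
  donor_plen <- donor_tx$cds_length %/% 3L
  acc_plen <- acceptor_tx$cds_length %/% 3L
  res <- jp
  res$donor_gene <- donor_tx$gene
  res$acceptor_gene <- acceptor_tx$gene
  if (!is.na(jp$donor_retained_nt)) {
    res$donor_segment_aa <- jp$donor_retained_nt %/% 3L
    res$donor_retained_interval <- c(1L, res$donor_segment_aa)
  } else {
    res$donor_segment_aa <- NA_integer_
    res$donor_retained_interval <- c(NA_integer_, NA_integer_)
  }
  if (!is.na(jp$acceptor_discarded_nt)) {
    first_aa <- jp$acceptor_discarded_nt %/% 3L + 1L
    res$acceptor_retained_interval <- c(first_aa, acc_plen)
  } else {
    first_aa <- NA_integer_
    res$acceptor_retained_interval <- c(NA_integer_, NA_integer_)
  }
  if (isTRUE(jp$in_frame)) {
    total_nt <- jp$donor_retained_nt +
      (acceptor_tx$cds_length - jp$acceptor_discarded_nt)
    res$total_aa <- total_nt %/% 3L
    res$acceptor_segment_aa <- res$total_aa - res$donor_segment_aa
  } else {
    res$total_aa <- NA_integer_
    res$acceptor_segment_aa <- NA_integer_
  }
  ret <- NULL
  if (!is.null(domains) && nrow(domains)) {
    dd <- domains[domains$gene == donor_tx$gene, , drop = FALSE]
    if (nrow(dd) && !is.na(res$donor_segment_aa)) {
      r <- domain_retention(dd, 1L, res$donor_retained_interval[2], donor_plen)
      ret <- rbind(ret, cbind(gene = donor_tx$gene, side = "donor", r))
    }
    da <- domains[domains$gene == acceptor_tx$gene, , drop = FALSE]
    if (nrow(da) && !is.na(first_aa)) {
      r <- domain_retention(da, first_aa, acc_plen, acc_plen)
      ret <- rbind(ret, cbind(gene = acceptor_tx$gene, side = "acceptor", r))
    }
  }
  res$retained_domains <- ret
  class(res) <- "fusion_protein"
  res
}

#' @export
print.fusion_protein <- function(x, ...) {
  cat(sprintf("<fusion_protein> %s-%s  phases %s->%s  %s\n",
              x$donor_gene, x$acceptor_gene,
              x$donor_phase, x$acceptor_phase,
              if (isTRUE(x$in_frame)) "in frame" else "out of frame"))
  if (!is.na(x$total_aa))
    cat(sprintf("  %d aa (%d donor + %d acceptor)\n",
                x$total_aa, x$donor_segment_aa, x$acceptor_segment_aa))
  if (!is.null(x$retained_domains)) {
    cat("  domains:\n")
    print(x$retained_domains, row.names = FALSE)
  }
  invisible(x)
}

#' Frame and domain report for a set of fusion calls
#'
#' Runs \code{\link{fusion_protein}} for every call, resolving each gene to
#' its representative transcript (longest CDS).  Calls whose partner genes
#' are absent from the transcript models are reported as unresolvable.
#'
#' @param calls a \code{fusion_calls} data frame.
#' @param transcripts a \code{transcript_set} (see
#'   \code{\link{read_transcripts}}).
#' @param domains optional domain table.
#' @return list with \code{proteins} (one row per call: key columns, phases,
#'   in-frame flag, segment lengths, flag/reason) and \code{domains} (one
#'   row per call x domain: key columns plus \code{gene, side, name, status,
#'   fraction}).
#' @export
fusion_protein_report <- function(calls, transcripts, domains = NULL) {
  rep_tx <- representative_transcripts(transcripts)
  prot <- vector("list", nrow(calls))
  doms <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    key <- data.frame(sample_id = calls$sample_id[i],
                      donor_gene = calls$donor_gene[i],
                      acceptor_gene = calls$acceptor_gene[i],
                      stringsAsFactors = FALSE)
    dtx <- rep_tx[[calls$donor_gene[i]]]
    atx <- rep_tx[[calls$acceptor_gene[i]]]
    if (is.null(dtx) || is.null(atx)) {
      prot[[i]] <- cbind(key, donor_phase = NA_integer_,
                         acceptor_phase = NA_integer_, in_frame = NA,
                         donor_segment_aa = NA_integer_,
                         acceptor_segment_aa = NA_integer_,
                         total_aa = NA_integer_, flag = NA_character_,
                         reason = "gene not in transcript models")
      next
    }
    fp <- fusion_protein(dtx, calls$pos1[i], atx, calls$pos2[i], domains)
    prot[[i]] <- cbind(key, donor_phase = fp$donor_phase,
                       acceptor_phase = fp$acceptor_phase,
                       in_frame = fp$in_frame,
                       donor_segment_aa = fp$donor_segment_aa,
                       acceptor_segment_aa = fp$acceptor_segment_aa,
                       total_aa = fp$total_aa,
                       flag = fp$flag, reason = fp$reason)
    if (!is.null(fp$retained_domains))
      doms[[i]] <- cbind(key, fp$retained_domains, row.names = NULL)
  }
  list(proteins = do.call(rbind, prot),
       domains = if (any(!vapply(doms, is.null, logical(1))))
         do.call(rbind, doms) else
         data.frame(sample_id = character(0), donor_gene = character(0),
                    acceptor_gene = character(0), gene = character(0),
                    side = character(0), name = character(0),
                    status = character(0), fraction = numeric(0)))
}
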