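# Breakpoint-tolerant grouping of fusion calls across detection algorithms
# and the 2-of-3 cross-validation rule.

#' Group fusion calls across callers
#'
#' Calls from the same sample with the same ordered (donor, acceptor) gene
#' pair merge into one consensus group when their breakpoints agree within
#' \code{tolerance} bp on both sides.  Groups are the connected components
#' of the "within tolerance" relation (transitive closure), which makes the
#' grouping deterministic and independent of input order; at
#' \code{tolerance = 0} this reduces to exact breakpoint matching, and
#' grouping at a smaller tolerance always refines grouping at a larger one.
#'
#' @param calls a \code{fusion_calls} data frame (any mix of callers).
#' @param tolerance maximum per-breakpoint disagreement in bp (default 50,
#'   sized for sub-exon jitter between algorithms; cross-sample matching is
#'   already at the gene-pair level).
#' @return list of class \code{"consensus_groups"} with
#'   \code{groups} — one row per group: \code{group_id, sample_id,
#'   donor_gene, acceptor_gene, support} (number of distinct callers),
#'   \code{callers} (comma-separated), \code{n_members},
#'   \code{breakpoint_spread} (max pairwise breakpoint distance within the
#'   group, bp) and the representative breakpoints (member with the most
#'   spanning reads) — and \code{members}, the input calls with a
#'   \code{group_id} column.
#' @export
group_calls <- function(calls, tolerance = 50) {
  stopifnot(tolerance >= 0)
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  key <- paste(calls$sample_id, calls$donor_gene, calls$acceptor_gene,
               sep = "\r")
  group_id <- integer(n)
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    m <- length(idx)
    # union-find over the members of one (sample, gene-pair) key
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (m > 1) {
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        a <- idx[i]; b <- idx[j]
        if (calls$chrom1[a] == calls$chrom1[b] &&
            calls$chrom2[a] == calls$chrom2[b] &&
            abs(calls$pos1[a] - calls$pos1[b]) <= tolerance &&
            abs(calls$pos2[a] - calls$pos2[b]) <= tolerance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(m), find, integer(1))
    # stable component numbering: by smallest breakpoint pair in the group
    for (r in unique(roots)) {
      next_id <- next_id + 1L
      group_id[idx[roots == r]] <- next_id
    }
  }
  calls$group_id <- group_id
  groups <- do.call(rbind, lapply(split(seq_len(n), group_id), function(ii) {
    g <- calls[ii, , drop = FALSE]
    spread <- if (length(ii) > 1)
      max(vapply(seq_along(ii), function(i) {
        max(abs(g$pos1[i] - g$pos1), abs(g$pos2[i] - g$pos2))
      }, numeric(1))) else 0
    best <- ii[order(-g$spanning_reads, g$caller_id)[1]]
    data.frame(group_id = g$group_id[1], sample_id = g$sample_id[1],
               donor_gene = g$donor_gene[1], acceptor_gene = g$acceptor_gene[1],
               support = length(unique(g$caller_id)),
               callers = paste(sort(unique(g$caller_id)), collapse = ","),
               n_members = length(ii), breakpoint_spread = spread,
               chrom1 = calls$chrom1[best], pos1 = calls$pos1[best],
               strand1 = calls$strand1[best],
               chrom2 = calls$chrom2[best], pos2 = calls$pos2[best],
               strand2 = calls$strand2[best],
               spanning_reads = calls$spanning_reads[best],
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(groups = groups, members = calls, tolerance = tolerance),
            class = "consensus_groups")
}

#' Cross-validate consensus groups
#'
#' Retains groups supported by at least \code{min_support} distinct callers
#' (the 2-of-3 rule by default); each retained group reports which callers
#' supported it in its \code{callers} column.
#'
#' @param groups a \code{consensus_groups} object from
#'   \code{\link{group_calls}}.
#' @param min_support minimum number of distinct supporting callers
#'   (default 2).
#' @return a \code{consensus_groups} object containing only the validated
#'   groups (and their member calls).
#' @export
cross_validate <- function(groups, min_support = 2L) {
  stopifnot(inherits(groups, "consensus_groups"), min_support >= 1)
  keep <- groups$groups$support >= min_support
  g <- groups$groups[keep, , drop = FALSE]
  rownames(g) <- NULL
  m <- groups$members[groups$members$group_id %in% g$group_id, , drop = FALSE]
  rownames(m) <- NULL
  structure(list(groups = g, members = m, tolerance = groups$tolerance,
                 min_support = min_support),
            class = "consensus_groups")
}

#' @export
print.consensus_groups <- function(x, ...) {
  cat(sprintf("<consensus_groups> %d group(s), tolerance %g bp\n",
              nrow(x$groups), x$tolerance))
  print(utils::head(x$groups, 10), row.names = FALSE)
  if (nrow(x$groups) > 10) cat("...\n")
  invisible(x)
}
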