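# Readers, writers and validating constructors for every external table the
# pipeline touches.  All genomic coordinates are 1-based inclusive; inputs in
# 0-based half-open convention must be shifted at this boundary.  Loading is
# never silent about bad rows: every reader either stops at the first
# malformed record (on_error = "stop") or drops it and attaches an `errors`
# attribute with the line number and reason (on_error = "report"), so that
# input rows = parsed rows + reported errors.

FUSION_CALL_FILE_COLS <- c("sample", "caller", "donor_gene", "acceptor_gene",
                           "chrom1", "pos1", "strand1",
                           "chrom2", "pos2", "strand2",
                           "spanning_reads", "frame")

# ---------------------------------------------------------------------------
# Fusion calls
# ---------------------------------------------------------------------------

#' Construct a table of fusion calls
#'
#' A fusion call is one detection algorithm's claim that, in one sample, the
#' 5' (donor) gene is joined to the 3' (acceptor) gene at a pair of genomic
#' breakpoints.  The breakpoint on each side is the last retained base of the
#' donor and the first retained base of the acceptor (1-based, inclusive).
#' The optional junction phases are the donor/acceptor reading-frame phases
#' (coding bases modulo 3) as reported by the caller, e.g. the "0->1" labels
#' of fusion-call tables.
#'
#' @param sample_id,caller_id,donor_gene,acceptor_gene character vectors.
#' @param chrom1,pos1,strand1 donor breakpoint (chromosome, 1-based position,
#'   transcription strand \code{"+"} or \code{"-"}).
#' @param chrom2,pos2,strand2 acceptor breakpoint.
#' @param spanning_reads non-negative integer junction-spanning read counts.
#' @param donor_phase,acceptor_phase optional integer phases in \{0,1,2\}.
#' @return a \code{data.frame} of class \code{"fusion_calls"}.
#' @export
fusion_calls <- function(sample_id, caller_id, donor_gene, acceptor_gene,
                         chrom1, pos1, strand1, chrom2, pos2, strand2,
                         spanning_reads,
                         donor_phase = NA_integer_,
                         acceptor_phase = NA_integer_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    caller_id = as.character(caller_id),
    donor_gene = as.character(donor_gene),
    acceptor_gene = as.character(acceptor_gene),
    chrom1 = as.character(chrom1),
    pos1 = as.integer(pos1),
    strand1 = normalize_strand(strand1),
    chrom2 = as.character(chrom2),
    pos2 = as.integer(pos2),
    strand2 = normalize_strand(strand2),
    spanning_reads = as.integer(spanning_reads),
    donor_phase = as.integer(donor_phase),
    acceptor_phase = as.integer(acceptor_phase),
    stringsAsFactors = FALSE
  )
  errs <- validate_fusion_calls(df)
  if (nrow(errs))
    fp_stop("invalid fusion call (row %d): %s", errs$row[1], errs$reason[1])
  class(df) <- c("fusion_calls", "data.frame")
  df
}

# one reason per offending row; row index is into the data frame
validate_fusion_calls <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) reason[is.na(reason) & bad] <<- msg
  flag(is.na(df$sample_id) | !nzchar(df$sample_id), "empty sample id")
  flag(is.na(df$donor_gene) | !nzchar(df$donor_gene) |
       is.na(df$acceptor_gene) | !nzchar(df$acceptor_gene), "empty gene symbol")
  flag(df$donor_gene == df$acceptor_gene, "donor and acceptor gene identical")
  flag(is.na(df$chrom1) | !nzchar(df$chrom1) |
       is.na(df$chrom2) | !nzchar(df$chrom2), "empty chromosome")
  flag(is.na(df$pos1) | df$pos1 < 1 | is.na(df$pos2) | df$pos2 < 1,
       "breakpoint position not a positive integer")
  flag(!(df$strand1 %in% c("+", "-")) | !(df$strand2 %in% c("+", "-")),
       "strand not '+' or '-'")
  flag(is.na(df$spanning_reads) | df$spanning_reads < 0,
       "spanning_reads not a non-negative integer")
  ph_bad <- function(p, raw) !is.na(raw) & (is.na(p) | !(p %in% 0:2))
  flag((!is.na(df$donor_phase) & !(df$donor_phase %in% 0:2)) |
       (!is.na(df$acceptor_phase) & !(df$acceptor_phase %in% 0:2)),
       "junction phase not in {0,1,2}")
  bad <- which(!is.na(reason))
  data.frame(row = bad, reason = reason[bad], stringsAsFactors = FALSE)
}

#' Read a fusion-call table
#'
#' Tab-separated with header columns \code{sample, caller, donor_gene,
#' acceptor_gene, chrom1, pos1, strand1, chrom2, pos2, strand2,
#' spanning_reads, frame}.  \code{frame} holds a junction-phase label such as
#' \code{"0->1"} (empty when the caller reports none).  A \code{caller_id}
#' argument stamps every row, overriding the file's \code{caller} column.
#'
#' @param path file path.
#' @param caller_id optional caller label applied to all rows.
#' @param on_error \code{"stop"} (default) aborts at the first malformed row,
#'   naming its line; \code{"report"} drops malformed rows and attaches an
#'   \code{errors} attribute (data frame of \code{line}, \code{reason}).
#' @return a \code{fusion_calls} data frame.
#' @export
read_fusion_calls <- function(path, caller_id = NULL,
                              on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(FUSION_CALL_FILE_COLS, names(raw))
  if (length(missing_cols))
    fp_stop("fusion-call file %s lacks mandatory column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  ph <- parse_frame_label(raw$frame)
  df <- data.frame(
    sample_id = raw$sample,
    caller_id = if (is.null(caller_id)) raw$caller else caller_id,
    donor_gene = raw$donor_gene,
    acceptor_gene = raw$acceptor_gene,
    chrom1 = raw$chrom1,
    pos1 = suppressWarnings(as.integer(raw$pos1)),
    strand1 = normalize_strand(raw$strand1),
    chrom2 = raw$chrom2,
    pos2 = suppressWarnings(as.integer(raw$pos2)),
    strand2 = normalize_strand(raw$strand2),
    spanning_reads = suppressWarnings(as.integer(raw$spanning_reads)),
    donor_phase = ph[, "donor_phase"],
    acceptor_phase = ph[, "acceptor_phase"],
    stringsAsFactors = FALSE
  )
  errs <- validate_fusion_calls(df)
  if (length(attr(ph, "bad"))) {
    extra <- setdiff(attr(ph, "bad"), errs$row)
    if (length(extra))
      errs <- rbind(errs, data.frame(row = extra,
                                     reason = "unparseable frame label"))
  }
  errs <- errs[order(errs$row), , drop = FALSE]
  errs$line <- errs$row + 1L  # header occupies line 1
  if (nrow(errs) && on_error == "stop")
    fp_stop("%s line %d: %s", path, errs$line[1], errs$reason[1])
  keep <- df[setdiff(seq_len(nrow(df)), errs$row), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("fusion_calls", "data.frame")
  attr(keep, "errors") <- errs[, c("line", "reason"), drop = FALSE]
  keep
}

#' Write a fusion-call table
#'
#' Inverse of \code{\link{read_fusion_calls}}; a write/read round trip
#' reproduces the table field for field.
#'
#' @param calls a \code{fusion_calls} data frame.
#' @param path output file path.
#' @export
write_fusion_calls <- function(calls, path) {
  out <- data.frame(
    sample = calls$sample_id, caller = calls$caller_id,
    donor_gene = calls$donor_gene, acceptor_gene = calls$acceptor_gene,
    chrom1 = calls$chrom1, pos1 = calls$pos1, strand1 = calls$strand1,
    chrom2 = calls$chrom2, pos2 = calls$pos2, strand2 = calls$strand2,
    spanning_reads = calls$spanning_reads,
    frame = format_frame_label(calls$donor_phase, calls$acceptor_phase),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Transcript models
# ---------------------------------------------------------------------------

#' Construct a transcript model
#'
#' Exon/CDS structure of one transcript, enabling genomic <-> CDS <-> protein
#' coordinate conversion.  Exons are 1-based inclusive genomic intervals,
#' non-overlapping; the coding region is the genomic interval
#' \code{[cds_start, cds_end]} intersected with the exons, and its total
#' length must be a positive multiple of 3 (stop codon excluded or included
#' consistently by the annotation source — only divisibility is enforced).
#'
#' @param gene gene symbol.
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons two-column matrix or data frame of exon \code{start},
#'   \code{end} (1-based inclusive).
#' @param cds_start,cds_end genomic bounds of the coding region.
#' @return an object of class \code{"transcript_model"}.
#' @export
transcript_model <- function(gene, transcript_id, chrom, strand,
                             exons, cds_start, cds_end) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  tx <- structure(list(
    gene = as.character(gene),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = normalize_strand(strand),
    exons = exons,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  ), class = "transcript_model")
  validate_transcript(tx)
  tx$cds_segments <- cds_segments(tx)
  tx$cds_length <- sum(tx$cds_segments[, "end"] - tx$cds_segments[, "start"] + 1L)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (!nrow(ex)) fp_stop("transcript %s: no exons", tx$transcript_id)
  if (any(ex[, "end"] < ex[, "start"]))
    fp_stop("transcript %s: exon end < start", tx$transcript_id)
  if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"]))
    fp_stop("transcript %s: exons overlap or are unsorted", tx$transcript_id)
  if (!(tx$strand %in% c("+", "-")))
    fp_stop("transcript %s: strand not '+'/'-'", tx$transcript_id)
  if (is.na(tx$cds_start) || is.na(tx$cds_end) || tx$cds_start > tx$cds_end)
    fp_stop("transcript %s: invalid CDS bounds", tx$transcript_id)
  inside <- function(p) any(p >= ex[, "start"] & p <= ex[, "end"])
  if (!inside(tx$cds_start) || !inside(tx$cds_end))
    fp_stop("transcript %s: CDS bounds outside exons", tx$transcript_id)
  segs <- cds_segments(tx)
  len <- sum(segs[, "end"] - segs[, "start"] + 1L)
  if (len < 3L)
    fp_stop("transcript %s: CDS shorter than one codon", tx$transcript_id)
  if (len %% 3L != 0L)
    fp_stop("transcript %s: CDS length %d not a multiple of 3",
            tx$transcript_id, len)
  invisible(tx)
}

# exon intervals clipped to [cds_start, cds_end], genomic order
cds_segments <- function(tx) {
  s <- pmax(tx$exons[, "start"], tx$cds_start)
  e <- pmin(tx$exons[, "end"], tx$cds_end)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s\n",
              x$transcript_id, x$gene, x$chrom,
              paste(range(x$exons), collapse = "-"), x$strand))
  cat(sprintf("  %d exon(s); CDS %d-%d (%d coding bases)\n",
              nrow(x$exons), x$cds_start, x$cds_end, x$cds_length))
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Uses \code{rtracklayer} to parse the GTF and assembles one
#' \code{\link{transcript_model}} per transcript from its \code{exon} and
#' \code{CDS} features.  Transcripts without CDS features are skipped (the
#' pipeline only needs coding transcripts).  Gene symbols are taken from
#' \code{gene_name} when present, else \code{gene_id}.
#'
#' @param path GTF file path.
#' @return named list of \code{transcript_model} objects (by transcript id),
#'   with class \code{"transcript_set"}.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  gene <- if ("gene_name" %in% names(meta) && !all(is.na(meta$gene_name)))
    ifelse(is.na(meta$gene_name), meta$gene_id, meta$gene_name) else meta$gene_id
  meta$.gene <- gene
  txs <- list()
  for (tid in unique(stats::na.omit(meta$transcript_id))) {
    rows <- meta[!is.na(meta$transcript_id) & meta$transcript_id == tid, ]
    cds <- rows[rows$type == "CDS", ]
    if (!nrow(cds)) next
    ex <- rows[rows$type == "exon", ]
    if (!nrow(ex)) ex <- cds  # CDS-only annotations
    txs[[tid]] <- transcript_model(
      gene = rows$.gene[1], transcript_id = tid,
      chrom = as.character(rows$seqnames[1]),
      strand = as.character(rows$strand[1]),
      exons = cbind(ex$start, ex$end),
      cds_start = min(cds$start), cds_end = max(cds$end)
    )
  }
  structure(txs, class = "transcript_set")
}

#' Write transcript models as GTF
#'
#' Emits \code{exon} and \code{CDS} features per transcript in standard GTF
#' attribute syntax, readable by \code{\link{read_transcripts}} (and any GTF
#' consumer).
#'
#' @param txs list of \code{transcript_model} objects.
#' @param path output file path.
#' @export
write_transcripts_gtf <- function(txs, path) {
  lines <- character(0)
  for (tx in txs) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                     tx$gene, tx$gene, tx$transcript_id)
    ex <- tx$exons
    lines <- c(lines,
      sprintf("%s\tfusionprio\texon\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom, ex[, "start"], ex[, "end"], tx$strand, attrs))
    segs <- cds_segments(tx)
    lines <- c(lines,
      sprintf("%s\tfusionprio\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              tx$chrom, segs[, "start"], segs[, "end"], tx$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Pick one representative transcript per gene
#'
#' Cohort fusion tables identify partners by gene symbol only, so a single
#' transcript must represent each gene in coordinate conversions.  The
#' default rule takes the transcript with the longest CDS; ties break on
#' transcript id (alphabetical) for determinism.
#'
#' @param txs a \code{transcript_set} (list of \code{transcript_model}).
#' @return named list mapping gene symbol to one \code{transcript_model}.
#' @export
representative_transcripts <- function(txs) {
  genes <- vapply(txs, `[[`, character(1), "gene")
  out <- list()
  for (g in unique(genes)) {
    cand <- txs[genes == g]
    lens <- vapply(cand, `[[`, integer(1), "cds_length")
    ids <- vapply(cand, `[[`, character(1), "transcript_id")
    out[[g]] <- cand[[order(-lens, ids)[1]]]
  }
  out
}

# ---------------------------------------------------------------------------
# Protein domains and gene function annotation
# ---------------------------------------------------------------------------

#' Read a protein-domain table
#'
#' TSV with columns \code{gene, name, start_aa, end_aa}; 1-based inclusive
#' amino-acid coordinates on the native (unfused) protein.
#'
#' @param path file path.
#' @return data frame with the four columns, validated.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "character",
                                              "integer", "integer"))
  need <- c("gene", "name", "start_aa", "end_aa")
  if (!all(need %in% names(d)))
    fp_stop("domain file %s lacks column(s): %s", path,
            paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(is.na(d$start_aa) | is.na(d$end_aa) |
                 d$start_aa < 1 | d$end_aa < d$start_aa)
  if (length(bad))
    fp_stop("%s line %d: invalid amino-acid interval", path, bad[1] + 1L)
  d
}

#' @rdname read_domains
#' @param domains domain data frame.
#' @export
write_domains <- function(domains, path) {
  utils::write.table(domains[, c("gene", "name", "start_aa", "end_aa")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-function annotation table
#'
#' TSV with columns \code{gene, categories}; \code{categories} is a
#' comma-separated subset of \code{kinase}, \code{oncogene},
#' \code{suppressor} (a gene may carry several, e.g. a kinase oncogene).
#'
#' @param path file path.
#' @return data frame \code{gene}, \code{categories} (comma string).
#' @export
read_gene_functions <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("gene", "categories") %in% names(d)))
    fp_stop("gene-function file %s needs columns gene, categories", path)
  cats <- strsplit(d$categories, ",", fixed = TRUE)
  ok <- vapply(cats, function(x) all(trimws(x) %in%
                 c("kinase", "oncogene", "suppressor", "")), logical(1))
  if (!all(ok))
    fp_stop("%s line %d: unknown function category", path, which(!ok)[1] + 1L)
  d
}

#' @rdname read_gene_functions
#' @param annotations annotation data frame.
#' @export
write_gene_functions <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "categories")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Somatic variants
# ---------------------------------------------------------------------------

VARIANT_COLS <- c("sample", "gene", "chrom", "pos", "ref", "alt",
                  "total_depth", "alt_depth", "effect", "region",
                  "fs", "qd", "pop_maf")

#' Read a somatic-variant table (flat TSV)
#'
#' Columns: \code{sample, gene, chrom, pos, ref, alt, total_depth,
#' alt_depth, effect, region, fs, qd, pop_maf}.  \code{effect} is one of
#' \code{frameshift, non-synonymous, stop-gain, stop-loss, other};
#' \code{region} one of \code{exon, intron, UTR}.  \code{fs}/\code{qd} are
#' the Fisher-strand and qual-by-depth scores; \code{pop_maf} the population
#' minor-allele frequency as a fraction (empty = not catalogued).
#'
#' @param path file path.
#' @return validated data frame of variants.
#' @export
read_variants <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""))
  miss <- setdiff(VARIANT_COLS, names(d))
  if (length(miss))
    fp_stop("variant file %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  for (col in c("pos", "total_depth", "alt_depth"))
    d[[col]] <- suppressWarnings(as.integer(d[[col]]))
  for (col in c("fs", "qd", "pop_maf"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  validate_variants(d, path)
  d
}

validate_variants <- function(d, src = "variant table") {
  bad <- which(is.na(d$alt_depth) | is.na(d$total_depth) |
                 d$alt_depth < 0 | d$alt_depth > d$total_depth)
  if (length(bad))
    fp_stop("%s line %d: alt_depth outside [0, total_depth]", src, bad[1] + 1L)
  bad <- which(!is.na(d$pop_maf) & (d$pop_maf < 0 | d$pop_maf > 1))
  if (length(bad))
    fp_stop("%s line %d: pop_maf outside [0,1]", src, bad[1] + 1L)
  bad <- which(!(d$effect %in% c("frameshift", "non-synonymous",
                                 "stop-gain", "stop-loss", "other")))
  if (length(bad))
    fp_stop("%s line %d: unknown effect '%s'", src, bad[1] + 1L, d$effect[bad[1]])
  invisible(d)
}

#' @rdname read_variants
#' @param variants variant data frame.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants[, VARIANT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read somatic variants from a VCF file
#'
#' Thin adapter over \code{vcfR}: expects INFO keys \code{GENE}, \code{EFF}
#' (effect), \code{REG} (region), \code{DP} (total depth), \code{AD} (alt
#' depth), \code{FS}, \code{QD} and optional \code{MAF}, and returns the same
#' flat variant table as \code{\link{read_variants}}.
#'
#' @param path VCF path.
#' @param sample_id sample label to stamp on every record.
#' @return validated data frame of variants.
#' @export
read_variants_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    fp_stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info1 <- function(key) vcfR::extract.info(v, element = key)
  d <- data.frame(
    sample = sample_id,
    gene = info1("GENE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    total_depth = as.integer(info1("DP")),
    alt_depth = as.integer(info1("AD")),
    effect = info1("EFF"),
    region = info1("REG"),
    fs = as.numeric(info1("FS")),
    qd = as.numeric(info1("QD")),
    pop_maf = suppressWarnings(as.numeric(info1("MAF"))),
    stringsAsFactors = FALSE
  )
  validate_variants(d, path)
  d
}

# ---------------------------------------------------------------------------
# Expression matrix
# ---------------------------------------------------------------------------

#' Construct an expression matrix object
#'
#' FPKM values (gene x sample, non-negative) together with each sample's
#' class (\code{tumour} or \code{normal}) and an optional pairing of tumour
#' samples to their matched normals.
#'
#' @param values numeric matrix, rownames = genes, colnames = samples.
#' @param sample_class named character vector mapping every column of
#'   \code{values} to \code{"tumour"} or \code{"normal"}.
#' @param pairing optional named character vector: tumour sample -> matched
#'   normal sample.
#' @return object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, sample_class, pairing = NULL) {
  values <- as.matrix(values)
  if (any(is.na(values)) || any(values < 0))
    fp_stop("expression matrix contains negative or missing values")
  miss <- setdiff(colnames(values), names(sample_class))
  if (length(miss))
    fp_stop("samples without a class: %s", paste(miss, collapse = ", "))
  if (!all(sample_class %in% c("tumour", "normal")))
    fp_stop("sample classes must be 'tumour' or 'normal'")
  structure(list(values = values,
                 sample_class = sample_class[colnames(values)],
                 pairing = pairing),
            class = "expression_matrix")
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix is TSV with the gene symbol in the first column (\code{gene})
#' and one column per sample.  The sample sheet is TSV with columns
#' \code{sample, class} (\code{tumour}/\code{normal}) and optional
#' \code{paired_normal}.
#'
#' @param path matrix TSV path.
#' @param samples_path sample-sheet TSV path.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, samples_path) {
  d <- utils::read.delim(path, check.names = FALSE)
  if (names(d)[1] != "gene")
    fp_stop("expression matrix %s must have 'gene' as its first column", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  ss <- utils::read.delim(samples_path, colClasses = "character",
                          na.strings = c("NA", ""))
  cls <- stats::setNames(ss$class, ss$sample)
  pairing <- NULL
  if ("paired_normal" %in% names(ss)) {
    has <- !is.na(ss$paired_normal)
    if (any(has)) pairing <- stats::setNames(ss$paired_normal[has], ss$sample[has])
  }
  expression_matrix(m, cls, pairing)
}

#' @rdname read_expression
#' @param expr an \code{expression_matrix}.
#' @export
write_expression <- function(expr, path, samples_path) {
  out <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample = names(expr$sample_class),
                   class = unname(expr$sample_class),
                   stringsAsFactors = FALSE)
  ss$paired_normal <- if (is.null(expr$pairing)) NA_character_ else
    unname(expr$pairing[ss$sample])
  utils::write.table(ss, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Clinical records
# ---------------------------------------------------------------------------

CLINICAL_COLS <- c("sample", "age", "size", "sex", "location", "histology",
                   "invasion_depth", "perineural", "lymphovascular",
                   "lymph_node", "msi_status", "os_months", "os_event")

CLINICAL_LEVELS <- list(
  sex = c("M", "F"),
  location = c("right", "left"),
  histology = c("well", "moderately", "poorly", "mucinous"),
  invasion_depth = c("T1", "T2", "T3", "T4"),
  msi_status = c("MSS", "MSI-L", "MSI-H")
)

#' Read a clinical covariate/survival table
#'
#' TSV with columns \code{sample, age} (years), \code{size} (tumour size,
#' cm), \code{sex} (M/F), \code{location} (right/left colon),
#' \code{histology} (well/moderately/poorly/mucinous differentiation),
#' \code{invasion_depth} (T1-T4), \code{perineural}, \code{lymphovascular},
#' \code{lymph_node} (0/1), \code{msi_status} (MSS/MSI-L/MSI-H),
#' \code{os_months} (overall-survival follow-up) and \code{os_event}
#' (1 = death observed).
#'
#' @param path file path.
#' @return validated clinical data frame.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""))
  miss <- setdiff(CLINICAL_COLS, names(d))
  if (length(miss))
    fp_stop("clinical file %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  for (col in c("age", "size", "os_months"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  for (col in c("perineural", "lymphovascular", "lymph_node", "os_event"))
    d[[col]] <- suppressWarnings(as.integer(d[[col]]))
  validate_clinical(d, path)
  d
}

validate_clinical <- function(d, src = "clinical table") {
  for (col in names(CLINICAL_LEVELS)) {
    bad <- which(!is.na(d[[col]]) & !(d[[col]] %in% CLINICAL_LEVELS[[col]]))
    if (length(bad))
      fp_stop("%s line %d: %s level '%s' not recognised",
              src, bad[1] + 1L, col, d[[col]][bad[1]])
  }
  bad <- which(!is.na(d$os_months) & d$os_months < 0)
  if (length(bad)) fp_stop("%s line %d: negative os_months", src, bad[1] + 1L)
  bad <- which(!is.na(d$os_event) & !(d$os_event %in% 0:1))
  if (length(bad)) fp_stop("%s line %d: os_event must be 0/1", src, bad[1] + 1L)
  invisible(d)
}

#' @rdname read_clinical
#' @param clinical clinical data frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical[, CLINICAL_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
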