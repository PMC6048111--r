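# Shared fixtures: deterministic toy transcripts, random transcript/coding
# sequence generators, and the brute-force translation oracle used to verify
# junction-phase arithmetic independently.

# Two-exon toy: exon1 101-130 (CDS tail 121-130, 10 coding bases), exon2
# 201-260 (CDS head 201-220, 20 coding bases).  30 coding bases total.
toy_tx_2exon <- function(strand = "+", gene = "TOY") {
  transcript_model(gene, paste0(gene, ".t1"), "c1", strand,
                   cbind(c(101L, 201L), c(130L, 260L)), 121L, 220L)
}

# random multi-exon coding transcript (structure only; no sequence attached)
rand_tx <- function(gene, chrom = "cT", strand = sample(c("+", "-"), 1)) {
  n_ex <- sample(2:6, 1)
  ex_len <- sample(60:300, n_ex, replace = TRUE)
  introns <- sample(200:2000, n_ex - 1, replace = TRUE)
  start <- sample(1000:100000, 1)
  starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
  ends <- starts + ex_len - 1L
  L <- sum(ex_len)
  utr5 <- sample(0:30, 1)
  utr3 <- sample(0:30, 1)
  utr3 <- utr3 + (L - utr5 - utr3) %% 3L
  exonic <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
  if (strand == "+") {
    cs <- exonic[utr5 + 1L]; ce <- exonic[L - utr3]
  } else {
    cs <- exonic[utr3 + 1L]; ce <- exonic[L - utr5]
  }
  transcript_model(gene, paste0(gene, ".t1"), chrom, strand,
                   cbind(starts, ends), cs, ce)
}

# random coding sequence: non-stop codons, terminal TAA
rand_cds_seq <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0, n_nt >= 3)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0(paste(sample(codons, n_nt / 3 - 1, replace = TRUE), collapse = ""),
         "TAA")
}

translate_str <- function(s)
  as.character(Biostrings::translate(Biostrings::DNAString(s)))

# Independent frame oracle: build the fusion nucleotide sequence, translate
# it, and ask whether the native acceptor protein tail survives intact at
# the end of the fusion protein.  True exactly when the junction preserves
# the acceptor reading frame.
frame_oracle <- function(donor_seq, acceptor_seq, retained_nt, discarded_nt) {
  fus <- paste0(substr(donor_seq, 1, retained_nt),
                substr(acceptor_seq, discarded_nt + 1, nchar(acceptor_seq)))
  fus <- substr(fus, 1, 3 * (nchar(fus) %/% 3))
  if (nchar(fus) < 3) return(FALSE)
  fus_aa <- translate_str(fus)
  acc_aa <- translate_str(acceptor_seq)
  j0 <- discarded_nt %/% 3 + 2  # first acceptor codon fully 3' of junction
  if (j0 > nchar(acc_aa)) return(NA)
  endsWith(fus_aa, substr(acc_aa, j0, nchar(acc_aa)))
}

# concise single fusion-call constructor for toy tests
mk_call <- function(sample = "S1", caller = "GFP", donor = "GA",
                    acceptor = "GB", chrom1 = "c1", pos1 = 1000L,
                    strand1 = "+", chrom2 = "c1", pos2 = 200000L,
                    strand2 = "+", spanning = 20L, dp = NA_integer_,
                    ap = NA_integer_) {
  fusion_calls(sample, caller, donor, acceptor, chrom1, pos1, strand1,
               chrom2, pos2, strand2, spanning, dp, ap)
}

# light-weight simulation settings for property loops (cohort scale is
# exercised by the acceptance suite; these keep per-seed cost small)
small_sim_cfg <- function(seed, ...) {
  defaults <- list(seed = seed, n_patients = 30L, n_normals = 10L,
                   n_chroms = 8L, n_genes = 24L, n_true_fusions = 8L,
                   n_fusion_patients = 6L, artifact_rate = 1,
                   n_normal_chimeras = 2L, noise_variants_per_patient = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
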