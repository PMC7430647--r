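## Alignment records and CIGAR geometry.
##
## Internally a set of alignments is a plain data frame; `seq` is always
## the adapter-trimmed read 5'->3' of the original RNA (for minus-strand
## alignments this is the reverse complement of the SAM SEQ field), while
## `cigar` and `genomic_start` follow SAM reference-orientation
## conventions.

CIGAR_OPS <- c("M", "I", "D", "N", "S")

#' Build an alignment-record table
#'
#' @param read_id Read identifiers.
#' @param seq Adapter-trimmed read sequences, 5' to 3' of the original RNA.
#' @param contig,strand,genomic_start,cigar SAM-style placement: 1-based
#'   leftmost reference position and reference-orientation CIGAR using ops
#'   M/I/D/N/S.
#' @param is_primary Logical; exactly one primary alignment per read.
#' @param has_adapter Logical; was the 3' adapter found on the raw read.
#' @param nh Number of reported alignments for the read.
#' @return A data frame with one row per alignment record.
#' @export
alignment_records <- function(read_id, seq, contig, strand, genomic_start,
                              cigar, is_primary = TRUE, has_adapter = TRUE,
                              nh = 1L) {
  df <- data.frame(read_id = as.character(read_id),
                   seq = toupper(as.character(seq)),
                   contig = as.character(contig),
                   strand = as.character(strand),
                   genomic_start = as.integer(genomic_start),
                   cigar = as.character(cigar),
                   is_primary = as.logical(is_primary),
                   has_adapter = as.logical(has_adapter),
                   nh = as.integer(nh),
                   row.names = NULL)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  qlen <- vapply(df$cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S")])
  }, integer(1L), USE.NAMES = FALSE)
  bad <- which(qlen != nchar(df$seq))
  if (length(bad))
    stop("CIGAR/sequence length mismatch for read(s): ",
         paste(head(df$read_id[bad], 5L), collapse = ", "))
  df
}

## Parse a CIGAR string into op/length vectors; ops restricted to MIDNS.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty CIGAR")
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
  if (paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR: ", cigar)
  op <- substring(toks, nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  if (!all(op %in% CIGAR_OPS))
    stop("unsupported CIGAR op in: ", cigar)
  if (any(len < 1L)) stop("zero-length CIGAR op in: ", cigar)
  if (!any(op == "M")) stop("CIGAR without alignment match: ", cigar)
  list(op = op, len = len)
}

## Vectorized genomic -> transcript coordinate mapping (NA outside blocks).
g2t_vec <- function(gene, g) {
  t <- rep(NA_integer_, length(g))
  b <- gene$blocks
  off <- 0L
  for (i in seq_len(nrow(b))) {
    s <- b[i, 1L]; e <- b[i, 2L]
    sel <- !is.na(g) & g >= s & g <= e
    t[sel] <- off + if (gene$strand == "+") g[sel] - s + 1L else e - g[sel] + 1L
    off <- off + (e - s + 1L)
  }
  t
}

## Core per-read geometry against one gene.  Returns the mature-transcript
## span of the aligned (M) bases, the observed 3' tail (genome-templated
## beyond-annotation M bases plus the 3' soft clip, in RNA orientation),
## indel/intron diagnostics and outside-annotation overlap counts.
align_info <- function(aln, gene) {
  ops <- parse_cigar(aln$cigar)
  seq_ref <- if (aln$strand == "-") revcomp_chr(aln$seq) else aln$seq
  rpos <- aln$genomic_start
  qpos <- 1L
  m_g <- integer(0L)   # reference positions of M bases, ascending
  m_q <- integer(0L)   # matching read (seq_ref) positions
  n_iv <- matrix(integer(0L), ncol = 2L)
  s_lead <- 0L; s_trail <- 0L
  seen_m <- FALSE
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "M") {
      m_g <- c(m_g, rpos:(rpos + len - 1L))
      m_q <- c(m_q, qpos:(qpos + len - 1L))
      rpos <- rpos + len; qpos <- qpos + len
      seen_m <- TRUE
    } else if (op == "I") {
      qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else if (op == "N") {
      n_iv <- rbind(n_iv, c(rpos, rpos + len - 1L))
      rpos <- rpos + len
    } else if (op == "S") {
      if (seen_m) s_trail <- s_trail + len else s_lead <- s_lead + len
      qpos <- qpos + len
    }
  }
  tvec <- g2t_vec(gene, m_g)
  inside <- !is.na(tvec)
  span <- gene$span
  in_intron <- logical(length(m_g))
  if (nrow(gene$introns) > 0L) {
    for (i in seq_len(nrow(gene$introns))) {
      in_intron <- in_intron |
        (m_g >= gene$introns[i, 1L] & m_g <= gene$introns[i, 2L])
    }
    in_intron <- in_intron & !inside
  }
  beyond_lo <- m_g < span[1L]
  beyond_hi <- m_g > span[2L]
  if (aln$strand == "+") {
    out5 <- beyond_lo; out3 <- beyond_hi
  } else {
    out5 <- beyond_hi; out3 <- beyond_lo
  }
  ## 3' soft clip and beyond-annotation M bases, RNA orientation
  chars_at <- function(q) {
    if (!length(q)) return("")
    s <- paste(strsplit(seq_ref, "", fixed = TRUE)[[1L]][q], collapse = "")
    s
  }
  if (aln$strand == "+") {
    clip3 <- if (s_trail > 0L)
      substring(seq_ref, nchar(seq_ref) - s_trail + 1L) else ""
    clip5_len <- s_lead
    beyond3 <- chars_at(m_q[out3])
  } else {
    clip3 <- if (s_lead > 0L) revcomp_chr(substring(seq_ref, 1L, s_lead)) else ""
    clip5_len <- s_trail
    beyond3 <- if (any(out3)) revcomp_chr(chars_at(m_q[out3])) else ""
  }
  list(
    tstart = if (any(inside)) min(tvec[inside]) else NA_integer_,
    tend = if (any(inside)) max(tvec[inside]) else NA_integer_,
    tail = paste0(beyond3, clip3),
    sum_m = length(m_g),
    clip3_len = nchar(clip3),
    clip5_len = clip5_len,
    has_indel = any(ops$op %in% c("I", "D")),
    n_intervals = n_iv,
    n_intron_overlap = sum(in_intron),
    n_out5 = sum(out5),
    n_out3 = sum(out3),
    read_len = nchar(aln$seq))
}

## TRUE when every N op coincides exactly with an annotated intron.
n_ops_match_introns <- function(info, gene) {
  if (nrow(info$n_intervals) == 0L) return(TRUE)
  intr <- gene$introns
  if (nrow(intr) == 0L) return(FALSE)
  for (i in seq_len(nrow(info$n_intervals))) {
    hit <- any(intr[, 1L] == info$n_intervals[i, 1L] &
               intr[, 2L] == info$n_intervals[i, 2L])
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Write alignment records as SAM
#'
#' @param alns Alignment-record data frame (see [alignment_records()]).
#' @param genome Named [Biostrings::DNAStringSet]; provides `@SQ` headers.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  flag <- ifelse(alns$strand == "-", 16L, 0L) +
    ifelse(alns$is_primary, 0L, 256L)
  seq_ref <- ifelse(alns$strand == "-",
                    vapply(alns$seq, revcomp_chr, character(1L),
                           USE.NAMES = FALSE),
                    alns$seq)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d\tZA:i:%d",
                 alns$read_id, flag, alns$contig, alns$genomic_start,
                 alns$cigar, seq_ref, strrep("I", nchar(seq_ref)),
                 alns$nh, as.integer(alns$has_adapter))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read alignment records from SAM/BAM
#'
#' Reads mapped records (SAM is converted on the fly with
#' [Rsamtools::asBam()]) into the package's alignment-record data frame.
#' The adapter flag is taken from the `ZA` integer tag when present
#' (defaulting to `TRUE`), `NH` from the standard tag, and primariness
#' from SAM flag 0x100.  Minus-strand SEQ fields are reverse complemented
#' back into RNA orientation.
#'
#' @param path Path to a SAM or BAM file.
#' @return Alignment-record data frame.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"),
    tag = c("NH", "ZA"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  df <- as.data.frame(gal)
  md <- S4Vectors::mcols(gal)
  strand <- as.character(df$strand)
  seqs <- as.character(md$seq)
  minus <- strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  nh <- md$NH
  if (is.null(nh)) nh <- rep(1L, length(gal))
  za <- md$ZA
  if (is.null(za)) za <- rep(1L, length(gal))
  za[is.na(za)] <- 1L
  nh[is.na(nh)] <- 1L
  alignment_records(
    read_id = md$qname,
    seq = seqs,
    contig = as.character(df$seqnames),
    strand = strand,
    genomic_start = df$start,
    cigar = df$cigar,
    is_primary = bitwAnd(md$flag, 256L) == 0L,
    has_adapter = za == 1L,
    nh = nh)
}

#' Write raw reads as FASTQ
#'
#' @param reads Data frame with columns `read_id` and `raw` (raw read
#'   sequence including adapter and randomized adapter-end bases).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$raw)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$raw)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
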