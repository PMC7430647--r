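## Read qualification: the exclusion cascade deciding which alignments
## enter the tRNA fragment analysis, and nontemplated-tail calling.

QUALIFY_REASONS <- c("ok", "mito", "indel_or_intron", "no_adapter",
                     "length_mismatch", "pre_trna", "not_primary", "no_gene")
TAIL_LEVELS <- c("NOT_TAILED", "NONE", "C", "CC", "CCA", "OTHER")
TAIL_STATUSES <- c("NONE", "C", "CC", "CCA")

#' Detect and trim a 3' adapter
#'
#' Deterministic adapter detection: the read carries the adapter when an
#' exact prefix of the adapter of at least `min_match` nt occurs in the raw
#' sequence; the trimmed sequence is everything before the leftmost such
#' occurrence.  This emulates aligner-side adapter clipping on synthetic
#' reads; mismatch-tolerant clipping is deliberately not reproduced.
#'
#' @param raw_seq Character vector of raw read sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_match Minimum matched adapter prefix length (>= 1).
#' @return A data frame with columns `trimmed_seq` and `has_adapter`.
#' @examples
#' detect_adapter(c("ACGTACGTTGGAATTCTC", "ACGTACGT"), "TGGAATTCTC", 6)
#' @export
detect_adapter <- function(raw_seq, adapter, min_match = 6L) {
  stopifnot(nzchar(adapter), min_match >= 1L)
  key <- substr(adapter, 1L, min(min_match, nchar(adapter)))
  hit <- regexpr(key, raw_seq, fixed = TRUE)
  has <- hit > 0L
  data.frame(
    trimmed_seq = ifelse(has, substr(raw_seq, 1L, hit - 1L), raw_seq),
    has_adapter = has)
}

classify_tail_string <- function(tail) {
  ifelse(tail == "", "NONE",
         ifelse(tail %in% c("C", "CC", "CCA"), tail, "OTHER"))
}

#' Call the 3' tail status of one alignment
#'
#' A read is "tailed" when its aligned (M) bases reach the annotated 3'
#' end of the mature tRNA.  The tail is then the read sequence following
#' the annotated end: 3' soft-clipped bases plus any aligned bases lying
#' beyond the annotation end (the genome-templated case, which arises when
#' the gene happens to be followed by C, CC or CCA in the genome).
#'
#' @param aln One alignment record (one-row data frame or list).
#' @param gene The gene the alignment is assigned to ([gene_model()]).
#' @param genome Unused; accepted for call-site symmetry.
#' @return One of `"NOT_TAILED"`, `"NONE"`, `"C"`, `"CC"`, `"CCA"`,
#'   `"OTHER"`.
#' @export
tail_call <- function(aln, gene, genome = NULL) {
  info <- align_info(aln, gene)
  if (is.na(info$tend)) stop("alignment does not overlap gene '",
                             gene$gene_id, "'")
  if (info$tend < gene$mature_length) return("NOT_TAILED")
  classify_tail_string(info$tail)
}

## The cascade, given precomputed geometry.  Returns reason + tail.
qualify_from_info <- function(aln, gene, info) {
  if (!isTRUE(aln$is_primary))
    return(list(reason = "not_primary", tail = NA_character_))
  if (gene$gene_class == "tRNA_mito")
    return(list(reason = "mito", tail = NA_character_))
  if (info$has_indel || !n_ops_match_introns(info, gene))
    return(list(reason = "indel_or_intron", tail = NA_character_))
  if (!isTRUE(aln$has_adapter))
    return(list(reason = "no_adapter", tail = NA_character_))
  tailed <- !is.na(info$tend) && info$tend >= gene$mature_length
  tail <- if (tailed) classify_tail_string(info$tail) else "NOT_TAILED"
  ## end-to-end length rule: trimmed length must equal the sum of CIGAR
  ## matches, except that a C/CC/CCA tail may add its non-genome-matching
  ## (soft-clipped) bases
  excess <- info$read_len - info$sum_m
  allowed <- if (tailed && tail %in% TAIL_STATUSES)
    info$clip3_len else 0L
  if (excess != allowed || info$clip5_len > 0L)
    return(list(reason = "length_mismatch", tail = tail))
  ## pre-tRNA rule: >= 1 nt overlap with an intron or with sequence
  ## outside the mature annotation, except genome-templated tail bases
  out3_ok <- tailed && tail %in% TAIL_STATUSES
  if (info$n_intron_overlap > 0L || info$n_out5 > 0L ||
      (info$n_out3 > 0L && !out3_ok))
    return(list(reason = "pre_trna", tail = tail))
  list(reason = "ok", tail = tail)
}

#' Qualify one read for the tRNA fragment analysis
#'
#' Applies the exclusion cascade in fixed order: secondary alignment,
#' mitochondrial tRNA, insertions/deletions/unannotated introns, missing
#' 3' adapter, trimmed-length vs CIGAR-match mismatch (with the C/CC/CCA
#' tail exception), and pre-tRNA overlap (with the genome-templated tail
#' exception).  The first failing rule determines the reason.
#'
#' @inheritParams tail_call
#' @return A list with `passed` (flag), `reason` (one of `"ok"`, `"mito"`,
#'   `"indel_or_intron"`, `"no_adapter"`, `"length_mismatch"`,
#'   `"pre_trna"`, `"not_primary"`, `"no_gene"`) and `tail`.
#' @export
qualify_read <- function(aln, gene, genome = NULL) {
  if (is.null(gene))
    return(list(passed = FALSE, reason = "no_gene", tail = NA_character_))
  info <- align_info(aln, gene)
  q <- qualify_from_info(aln, gene, info)
  list(passed = q$reason == "ok", reason = q$reason, tail = q$tail)
}

## Strand-specific assignment of alignments to tRNA genes (cytosolic and
## mitochondrial) by >=1 nt overlap with mature blocks; ties broken by
## largest overlap, then lexicographic gene_id.
assign_gene_by_overlap <- function(alns, ann, classes) {
  sel <- ann$gene_table$gene_id[ann$gene_table$gene_class %in% classes]
  if (!length(sel) || !nrow(alns))
    return(rep(NA_character_, nrow(alns)))
  blk <- do.call(rbind, lapply(ann$genes[sel], function(g) {
    data.frame(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
               start = g$blocks[, 1L], end = g$blocks[, 2L])
  }))
  gr_blk <- GenomicRanges::GRanges(blk$contig,
                                   IRanges::IRanges(blk$start, blk$end),
                                   strand = blk$strand)
  ref_end <- alns$genomic_start + vapply(alns$cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE) - 1L
  gr_aln <- GenomicRanges::GRanges(alns$contig,
                                   IRanges::IRanges(alns$genomic_start,
                                                    ref_end),
                                   strand = alns$strand)
  hits <- IRanges::findOverlaps(gr_aln, gr_blk)
  if (!length(hits)) return(rep(NA_character_, nrow(alns)))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ow <- pmin(ref_end[qi], blk$end[si]) -
    pmax(alns$genomic_start[qi], blk$start[si]) + 1L
  hdf <- data.frame(qi = qi, gene_id = blk$gene_id[si], ow = ow)
  ## aggregate multi-block overlaps per (read, gene)
  key <- paste(hdf$qi, hdf$gene_id)
  agg <- rowsum(hdf$ow, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  adf <- data.frame(qi = as.integer(vapply(parts, `[[`, "", 1L)),
                    gene_id = vapply(parts, `[[`, "", 2L),
                    ow = agg[, 1L])
  adf <- adf[order(adf$qi, -adf$ow, adf$gene_id), ]
  adf <- adf[!duplicated(adf$qi), ]
  out <- rep(NA_character_, nrow(alns))
  out[adf$qi] <- adf$gene_id
  out
}

#' Qualify all reads in an alignment table
#'
#' Assigns each record to a tRNA gene (strand-specific, largest overlap)
#' and runs the qualification cascade.  Records overlapping no tRNA gene
#' get reason `"no_gene"`; secondary alignments get `"not_primary"`.
#'
#' @param alns Alignment-record data frame.
#' @param ann An [annotation_set()].
#' @return A data frame with one row per input record: `read_id`,
#'   `gene_id`, `reason`, `passed`, `tail`, plus the mature-transcript
#'   span `tstart`/`tend` and `trimmed_length` for downstream
#'   classification.
#' @export
qualify_reads <- function(alns, ann) {
  gene_id <- assign_gene_by_overlap(alns, ann, c("tRNA", "tRNA_mito"))
  n <- nrow(alns)
  reason <- character(n); tail <- rep(NA_character_, n)
  tstart <- rep(NA_integer_, n); tend <- rep(NA_integer_, n)
  cols <- as.list(alns[c("read_id", "seq", "contig", "strand",
                         "genomic_start", "cigar", "is_primary",
                         "has_adapter")])
  for (i in seq_len(n)) {
    aln <- lapply(cols, `[[`, i)
    if (is.na(gene_id[i])) {
      reason[i] <- if (isTRUE(aln$is_primary)) "no_gene" else "not_primary"
      next
    }
    gene <- ann$genes[[gene_id[i]]]
    info <- align_info(aln, gene)
    q <- qualify_from_info(aln, gene, info)
    reason[i] <- q$reason
    tail[i] <- q$tail
    tstart[i] <- info$tstart
    tend[i] <- min(info$tend, gene$mature_length)
  }
  data.frame(read_id = alns$read_id, gene_id = gene_id, reason = reason,
             passed = reason == "ok", tail = tail, tstart = tstart,
             tend = tend, trimmed_length = nchar(alns$seq),
             row.names = NULL)
}
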