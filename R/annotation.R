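## Annotation model: tRNA / Y RNA gene structures on a toy or real genome,
## spliced (mature) transcript coordinates, identity grouping of tRNA genes.

GENE_CLASSES <- c("tRNA", "tRNA_mito", "yRNA_gene", "yRNA_pseudogene",
                  "yRNA_repeat")

## RepeatMasker HY families -> Y RNA genes
HY_FAMILY_MAP <- c(HY1 = "RNY1", HY3 = "RNY3", HY4 = "RNY4", HY5 = "RNY5")

#' Construct a gene model
#'
#' A `GeneModel` describes one tRNA or Y RNA feature: its genomic exon
#' blocks (the mature transcript), strand, class and family.  Blocks are
#' 1-based inclusive genomic intervals ordered 5' to 3' in *transcript*
#' orientation, so for a minus-strand gene the first block has the largest
#' genomic coordinates.  Gaps between consecutive blocks are introns.  The
#' nontemplated CCA tail of mature tRNAs is not genome-encoded and is never
#' part of the mature length.
#'
#' @param gene_id Unique gene identifier.
#' @param contig Contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param blocks Two-column matrix of `(start, end)` genomic intervals,
#'   1-based inclusive, ordered in transcript orientation.
#' @param gene_class One of `"tRNA"`, `"tRNA_mito"`, `"yRNA_gene"`,
#'   `"yRNA_pseudogene"`, `"yRNA_repeat"`.
#' @param family Family label: amino acid + anticodon for tRNAs (e.g.
#'   `"Gly-GCC"`), `RNY1`/`RNY3`/`RNY4`/`RNY5` for Y RNA features.
#' @return An object of class `GeneModel`.
#' @examples
#' g <- gene_model("tRNA-Gly-GCC-1", "chr1", "+",
#'                 cbind(1001L, 1076L), "tRNA", "Gly-GCC")
#' g$mature_length
#' @export
gene_model <- function(gene_id, contig, strand, blocks, gene_class, family) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(contig), length(contig) == 1L)
  if (!strand %in% c("+", "-"))
    stop("malformed strand for gene '", gene_id, "': ", strand)
  gene_class <- match.arg(gene_class, GENE_CLASSES)
  blocks <- matrix(as.integer(blocks), ncol = 2L)
  if (any(is.na(blocks)) || any(blocks[, 2L] < blocks[, 1L]))
    stop("invalid blocks for gene '", gene_id, "'")
  if (nrow(blocks) > 1L) {
    starts <- blocks[, 1L]
    ord_ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ord_ok)
      stop("blocks of gene '", gene_id,
           "' are not ordered 5'->3' in transcript orientation")
    ## non-overlap
    lo <- blocks[order(blocks[, 1L]), , drop = FALSE]
    if (any(lo[-1L, 1L] <= lo[-nrow(lo), 2L]))
      stop("overlapping blocks for gene '", gene_id, "'")
  }
  mature_length <- sum(blocks[, 2L] - blocks[, 1L] + 1L)
  if (gene_class == "tRNA" && (mature_length < 60L || mature_length > 100L))
    stop("cytosolic tRNA '", gene_id, "' has implausible mature length ",
         mature_length, " nt (expected 60-100)")
  structure(
    list(gene_id = gene_id, contig = contig, strand = strand,
         blocks = blocks, gene_class = gene_class, family = family,
         mature_length = mature_length),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s [%s] %s:%d-%d(%s) %d blocks, mature %d nt\n",
              x$gene_id, x$gene_class, x$contig, min(x$blocks),
              max(x$blocks), x$strand, nrow(x$blocks), x$mature_length))
  invisible(x)
}

## Intron intervals (genomic, 1-based inclusive), one row per intron.
gene_introns <- function(gene) {
  b <- gene$blocks
  if (nrow(b) < 2L) return(matrix(integer(0), ncol = 2L))
  g <- b[order(b[, 1L]), , drop = FALSE]
  cbind(g[-nrow(g), 2L] + 1L, g[-1L, 1L] - 1L)
}

## Genomic span (min, max) over blocks.
gene_span <- function(gene) c(min(gene$blocks), max(gene$blocks))

## Map one genomic position to a 1-based mature-transcript coordinate.
## Returns NA for positions outside the blocks (introns/flanks).
genomic_to_transcript <- function(gene, gpos) {
  b <- gene$blocks
  off <- 0L
  for (i in seq_len(nrow(b))) {
    s <- b[i, 1L]; e <- b[i, 2L]
    if (gpos >= s && gpos <= e) {
      return(off + if (gene$strand == "+") gpos - s + 1L else e - gpos + 1L)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

## Inverse of genomic_to_transcript; tpos must be in 1..mature_length.
transcript_to_genomic <- function(gene, tpos) {
  b <- gene$blocks
  off <- 0L
  for (i in seq_len(nrow(b))) {
    w <- b[i, 2L] - b[i, 1L] + 1L
    if (tpos <= off + w) {
      d <- tpos - off
      return(if (gene$strand == "+") b[i, 1L] + d - 1L else b[i, 2L] - d + 1L)
    }
    off <- off + w
  }
  stop("transcript position ", tpos, " outside gene '", gene$gene_id, "'")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

contig_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome))
    stop("unknown contig '", contig, "'")
  as.character(Biostrings::subseq(genome[[contig]], start = start, end = end))
}

#' Spliced mature sequence of a gene
#'
#' Concatenates the gene's blocks in transcript orientation, reverse
#' complementing minus-strand genes, yielding the mature transcript
#' sequence (introns excised; no CCA tail).
#'
#' @param gene A [gene_model()].
#' @param genome A named [Biostrings::DNAStringSet] of contigs.
#' @return Character scalar, the mature sequence 5' to 3'.
#' @export
spliced_sequence <- function(gene, genome) {
  parts <- vapply(seq_len(nrow(gene$blocks)), function(i) {
    s <- contig_subseq(genome, gene$contig,
                       gene$blocks[i, 1L], gene$blocks[i, 2L])
    if (gene$strand == "-") revcomp_chr(s) else s
  }, character(1L))
  paste(parts, collapse = "")
}

#' Genomic sequence immediately 3' of the mature annotation end
#'
#' Strand-aware downstream context: for a plus-strand gene the `k` bases
#' after the last block; for a minus-strand gene the reverse complement of
#' the `k` bases before the genomically first block.  Used to decide
#' whether a CCA/CC/C tail is genome-templated.
#'
#' @param gene A [gene_model()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @param k Number of downstream bases (>= 1).
#' @return Character scalar of length up to `k`; truncated with a warning
#'   when the context runs off the contig.
#' @export
downstream_context <- function(gene, genome, k = 3L) {
  stopifnot(k >= 1L)
  clen <- length(genome[[gene$contig]])
  if (gene$strand == "+") {
    s <- max(gene$blocks) + 1L
    e <- min(s + k - 1L, clen)
    if (s > clen) {
      warning("downstream context of '", gene$gene_id, "' runs off contig")
      return("")
    }
    if (e < s + k - 1L)
      warning("downstream context of '", gene$gene_id,
              "' truncated at contig end")
    contig_subseq(genome, gene$contig, s, e)
  } else {
    e <- min(gene$blocks) - 1L
    s <- max(1L, e - k + 1L)
    if (e < 1L) {
      warning("downstream context of '", gene$gene_id, "' runs off contig")
      return("")
    }
    if (s > e - k + 1L)
      warning("downstream context of '", gene$gene_id,
              "' truncated at contig end")
    revcomp_chr(contig_subseq(genome, gene$contig, s, e))
  }
}

#' Build an annotation set
#'
#' Bundles gene models with the genome, computes identity groups of
#' cytosolic tRNA genes whose spliced mature sequences are character
#' identical (reads mapped to any copy of a group are counted together),
#' and indexes genes by family.
#'
#' @param genes A list of [gene_model()] objects.
#' @param genome A named [Biostrings::DNAStringSet] of contigs (alphabet
#'   A/C/G/T/N).
#' @return An object of class `AnnotationSet` with elements `genes` (named
#'   list of enriched gene models, each carrying its cached `spliced`
#'   sequence, `down3` context and `introns`), `gene_table` (data frame),
#'   `identity_groups` (named list of gene_id vectors; each group is named
#'   after its lexicographically first member), `group_of` (gene_id ->
#'   group), `family_index`, and `genome`.
#' @export
annotation_set <- function(genes, genome) {
  stopifnot(is.list(genes), length(genes) > 0L,
            methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome contigs must be uniquely named")
  if (any(grepl("[^ACGTN]", as.character(genome))))
    stop("genome alphabet restricted to A/C/G/T/N")
  ids <- vapply(genes, `[[`, character(1L), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id in annotation")
  names(genes) <- ids
  for (g in genes) {
    if (!g$contig %in% names(genome))
      stop("gene '", g$gene_id, "' on unknown contig '", g$contig, "'")
    if (max(g$blocks) > length(genome[[g$contig]]) || min(g$blocks) < 1L)
      stop("block of gene '", g$gene_id, "' outside contig '", g$contig, "'")
  }
  genes <- lapply(genes, function(g) {
    g$spliced <- spliced_sequence(g, genome)
    g$down3 <- suppressWarnings(downstream_context(g, genome, 3L))
    g$introns <- gene_introns(g)
    g$span <- gene_span(g)
    g
  })
  gene_table <- data.frame(
    gene_id = ids,
    contig = vapply(genes, `[[`, character(1L), "contig"),
    strand = vapply(genes, `[[`, character(1L), "strand"),
    gene_class = vapply(genes, `[[`, character(1L), "gene_class"),
    family = vapply(genes, `[[`, character(1L), "family"),
    mature_length = vapply(genes, `[[`, integer(1L), "mature_length"),
    row.names = NULL)
  cyto <- ids[gene_table$gene_class == "tRNA"]
  identity_groups <- list()
  if (length(cyto)) {
    seqs <- vapply(genes[cyto], `[[`, character(1L), "spliced")
    identity_groups <- split(cyto, seqs)
    identity_groups <- lapply(identity_groups, sort)
    names(identity_groups) <-
      vapply(identity_groups, `[[`, character(1L), 1L)
    identity_groups <- identity_groups[order(names(identity_groups))]
  }
  group_of <- setNames(rep(names(identity_groups),
                           lengths(identity_groups)),
                       unlist(identity_groups, use.names = FALSE))
  family_index <- split(ids, gene_table$family)
  structure(
    list(genes = genes, gene_table = gene_table,
         identity_groups = identity_groups, group_of = group_of,
         family_index = family_index, genome = genome),
    class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  tab <- table(x$gene_table$gene_class)
  cat("AnnotationSet:", nrow(x$gene_table), "features on",
      length(x$genome), "contigs\n")
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  cat("  tRNA identity groups:", length(x$identity_groups), "\n")
  invisible(x)
}

#' Load annotation files
#'
#' Reads a reference FASTA, gene structures from GTF (exon rows with
#' attributes `gene_id`, `gene_class`, `family`), optional tRNA metadata
#' (TSV with columns `gene_id`, `amino_acid`, `anticodon`, `is_mito`) and
#' optional Y RNA repeat intervals (6-column BED whose name column is the
#' RepeatMasker HY family: HY1/HY3/HY4/HY5, mapped to RNY1/RNY3/RNY4/RNY5).
#' Gzipped files are accepted.
#'
#' @param genome_fa Path to reference FASTA.
#' @param genes_gtf Path to GTF with exon rows.
#' @param trna_meta Optional path to tRNA metadata TSV; when supplied it
#'   overrides tRNA family (`amino_acid`-`anticodon`) and mitochondrial
#'   class.
#' @param repeats_bed Optional path to BED of Y RNA repeat intervals.
#' @return An [annotation_set()].
#' @export
load_annotations <- function(genome_fa, genes_gtf, trna_meta = NULL,
                             repeats_bed = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gtf <- rtracklayer::import(genes_gtf, format = "gtf")
  gtf <- gtf[gtf$type == "exon"]
  md <- S4Vectors::mcols(gtf)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attribute")
  strands <- as.character(GenomicRanges::strand(gtf))
  if (any(strands == "*")) stop("malformed strand in GTF (found '*')")
  meta <- NULL
  if (!is.null(trna_meta)) {
    meta <- read.delim(trna_meta, stringsAsFactors = FALSE)
    need <- c("gene_id", "amino_acid", "anticodon", "is_mito")
    if (!all(need %in% names(meta)))
      stop("tRNA metadata must have columns: ", paste(need, collapse = ", "))
  }
  genes <- lapply(split(seq_along(gtf), md$gene_id), function(idx) {
    gi <- gtf[idx]
    gene_id <- md$gene_id[idx[1L]]
    strand <- as.character(GenomicRanges::strand(gi))[1L]
    contig <- as.character(GenomicRanges::seqnames(gi))[1L]
    cls <- md$gene_class[idx[1L]]
    fam <- md$family[idx[1L]]
    if (!is.null(meta) && gene_id %in% meta$gene_id) {
      m <- meta[match(gene_id, meta$gene_id), ]
      fam <- paste(m$amino_acid, m$anticodon, sep = "-")
      cls <- if (isTRUE(as.logical(m$is_mito))) "tRNA_mito" else "tRNA"
    }
    b <- cbind(GenomicRanges::start(gi), GenomicRanges::end(gi))
    b <- b[order(b[, 1L], decreasing = (strand == "-")), , drop = FALSE]
    gene_model(gene_id, contig, strand, b, cls, fam)
  })
  if (!is.null(repeats_bed)) {
    bed <- rtracklayer::import(repeats_bed, format = "bed")
    fams <- bed$name
    if (any(!fams %in% names(HY_FAMILY_MAP)))
      stop("repeat families restricted to ",
           paste(names(HY_FAMILY_MAP), collapse = "/"),
           "; found: ", paste(setdiff(fams, names(HY_FAMILY_MAP)),
                              collapse = ", "))
    reps <- lapply(seq_along(bed), function(i) {
      contig <- as.character(GenomicRanges::seqnames(bed))[i]
      strand <- as.character(GenomicRanges::strand(bed))[i]
      if (strand == "*") strand <- "+"
      gene_model(
        gene_id = sprintf("%s_%s_%d", fams[i], contig,
                          GenomicRanges::start(bed)[i]),
        contig = contig, strand = strand,
        blocks = cbind(GenomicRanges::start(bed)[i],
                       GenomicRanges::end(bed)[i]),
        gene_class = "yRNA_repeat",
        family = HY_FAMILY_MAP[[fams[i]]])
    })
    genes <- c(genes, reps)
  }
  annotation_set(unname(genes), genome)
}

#' Mature-transcript coordinates of an alignment
#'
#' Maps the aligned (CIGAR `M`) reference positions of one alignment record
#' into the 1-based mature-transcript coordinate system of a gene: position
#' 1 is the mature 5' end regardless of genomic strand, and intronic gaps
#' are excised.  Aligned bases lying beyond the mature annotation (flanks,
#' introns, genome-templated tail bases) do not contribute.
#'
#' @param aln A one-row data frame or list with fields `contig`, `strand`,
#'   `genomic_start`, `cigar` (see [alignment_records()]).
#' @param gene A [gene_model()].
#' @return Integer vector `c(tstart, tend)`, or `c(NA, NA)` when the
#'   alignment does not overlap the gene's blocks ("no-overlap" signal).
#' @export
transcript_coords <- function(aln, gene) {
  if (aln$contig != gene$contig || aln$strand != gene$strand)
    return(c(NA_integer_, NA_integer_))
  info <- align_info(aln, gene)
  c(info$tstart, info$tend)
}
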