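# Hand-built deterministic reference for unit tests: a few tRNA genes with
# controlled downstream contexts, an intron-containing gene, a minus-strand
# gene and a mitochondrial decoy.  `offset` shifts every c1 gene, for
# translation-invariance checks; `mutate_copy2` breaks the identical pair.
unit_ref <- function(offset = 0L, mutate_copy2 = FALSE) {
  set.seed(424242)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  c1 <- rnd(2800L + offset)
  c2 <- rnd(800L)
  plant <- function(x, pos, s) {
    substr(x, pos, pos + nchar(s) - 1L) <- s
    x
  }
  gly <- rnd(76L)
  gly2 <- gly
  if (mutate_copy2) {
    p <- 40L
    substr(gly2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(gly2, p, p))[1L]
  }
  asp <- rnd(76L)
  tyr <- rnd(76L)
  tyr_intron <- rnd(14L)
  phe <- rnd(69L)
  o <- offset
  c1 <- plant(c1, 1001L + o, gly)
  c1 <- plant(c1, 1077L + o, "CCAT")            # templated CCA context
  c1 <- plant(c1, 1301L + o, gly2)
  c1 <- plant(c1, 1377L + o, "TGCA")            # no templated context
  c1 <- plant(c1, 2001L + o, exofrag:::revcomp_chr(asp))  # minus strand
  c1 <- plant(c1, 1998L + o, "TGG")             # revcomp("CCA") upstream
  c1 <- plant(c1, 501L + o,
              paste0(substr(tyr, 1L, 37L), tyr_intron,
                     substr(tyr, 38L, 76L)))
  c1 <- plant(c1, 591L + o, "GTTT")
  c2 <- plant(c2, 301L, phe)
  genome <- Biostrings::DNAStringSet(c(c1 = c1, c2 = c2))
  genes <- list(
    gene_model("tGly1", "c1", "+", cbind(1001L + o, 1076L + o),
               "tRNA", "Gly-GCC"),
    gene_model("tGly2", "c1", "+", cbind(1301L + o, 1376L + o),
               "tRNA", "Gly-GCC"),
    gene_model("tAsp1", "c1", "-", cbind(2001L + o, 2076L + o),
               "tRNA", "Asp-GTC"),
    gene_model("tTyr1", "c1", "+",
               rbind(c(501L + o, 537L + o), c(552L + o, 590L + o)),
               "tRNA", "Tyr-GTA"),
    gene_model("tPheM", "c2", "+", cbind(301L, 369L),
               "tRNA_mito", "Phe-GAA"))
  annotation_set(genes, genome)
}

# One exact alignment record covering mature positions t1..t2 of a gene,
# with an optional nontemplated tail (genome-templated part becomes M).
mk_aln <- function(ann, gene_id, t1, t2, tail = "", read_id = "r1",
                   is_primary = TRUE, has_adapter = TRUE, nh = 1L) {
  g <- ann$genes[[gene_id]]
  p <- exofrag:::build_alignment(g, t1, t2, tail)
  alignment_records(read_id, p$seq, p$contig, p$strand, p$genomic_start,
                    p$cigar, is_primary, has_adapter, nh)
}

# Mirror a reference: reverse complement every contig and flip every
# annotation, preserving transcript order.
flip_reference <- function(ann) {
  clens <- setNames(Biostrings::width(ann$genome), names(ann$genome))
  genome2 <- Biostrings::reverseComplement(ann$genome)
  names(genome2) <- names(ann$genome)
  genes2 <- lapply(ann$genes, function(g) {
    L <- clens[[g$contig]]
    b <- cbind(L - g$blocks[, 2L] + 1L, L - g$blocks[, 1L] + 1L)
    gene_model(g$gene_id, g$contig,
               if (g$strand == "+") "-" else "+",
               b, g$gene_class, g$family)
  })
  annotation_set(unname(genes2), genome2)
}

# Mirror alignment records to match flip_reference(): reflected position,
# swapped strand, reversed CIGAR; seq stays in RNA orientation.
flip_alignments <- function(alns, ann) {
  clens <- setNames(Biostrings::width(ann$genome), names(ann$genome))
  ref_len <- vapply(alns$cigar, function(cg) {
    ops <- exofrag:::parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE)
  new_start <- clens[alns$contig] - (alns$genomic_start + ref_len - 1L) + 1L
  new_cigar <- vapply(alns$cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("\\d+[A-Z]", cg))[[1L]]
    paste(rev(toks), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  out <- alns
  out$genomic_start <- unname(new_start)
  out$strand <- ifelse(alns$strand == "+", "-", "+")
  out$cigar <- new_cigar
  out
}
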