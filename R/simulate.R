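## Synthetic data: a deterministic toy reference (tRNA + Y RNA annotation
## on a small genome) and a fragment-library simulator emulating
## extracellular RNase cleavage and library-preparation end-chemistry.

## Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Default per-family abundance weights and 5' shares for half molecules.
## Derived from the relative abundances of the most frequent isoacceptor
## halves in RNase-processed extracellular RNA; weights sum to 1.
DEFAULT_FAMILY_ABUNDANCES <- c(
  "Gly-GCC" = 0.254, "Asp-GTC" = 0.264, "Glu-CTC" = 0.240,
  "Glu-TTC" = 0.077, "Val-TAC" = 0.070, "Lys-CTT" = 0.031,
  "Val-CAC" = 0.027, "Gly-CCC" = 0.019, "Tyr-GTA" = 0.018)
DEFAULT_FAMILY_SPLIT5 <- c(
  "Gly-GCC" = 0.980, "Asp-GTC" = 0.023, "Glu-CTC" = 0.721,
  "Glu-TTC" = 0.052, "Val-TAC" = 0.214, "Lys-CTT" = 0.903,
  "Val-CAC" = 0.889, "Gly-CCC" = 0.842, "Tyr-GTA" = 0.500)

#' Simulation configuration
#'
#' Defines the generative conditions of a simulated extracellular small
#' RNA library.  `genotype = "WT"` emulates medium conditioned by cells
#' secreting an active extracellular ribonuclease: a large fraction of
#' mapped reads are anticodon-loop cleavage halves and tRNA 3' ends are
#' mostly trimmed to a single nontemplated C.  `genotype = "mutant"`
#' emulates a nuclease-null background: few halves, and 3' ends mostly
#' carrying the intact CCA tail.
#'
#' @param genotype `"WT"` or `"mutant"`; sets the defaults noted below.
#' @param n_reads Number of molecules to draw.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param half_fraction Target fraction of mapped reads that are tRNA
#'   halves (WT default 0.173, mutant 0.016).
#' @param split5 Generative 5' share of halves (WT default 0.53).
#' @param tail_probs Named probabilities over `CCA`, `CC`, `C`, `NONE` for
#'   molecules whose 3' end is the mature tRNA end (WT default
#'   `c(CCA=.05, CC=.05, C=.70, NONE=.20)`; mutant
#'   `c(CCA=.90, CC=.04, C=.03, NONE=.03)`).
#' @param cleavage_window Transcript positions of anticodon-loop cuts;
#'   a cut after position c yields a 5' half `1..c` and a 3' half
#'   `(c+1)..L`.  Default 31-38.
#' @param family_abundances Named weights over tRNA families for half
#'   molecules.
#' @param family_split5 Named per-family 5' shares; the global `split5` is
#'   drawn first, so the overall generative split is exactly `split5` and
#'   these shape only which family a 5' vs 3' half comes from.
#' @param yrna_frac,background_frac,mito_frac Fractions of molecules that
#'   are Y RNA reads, unannotated background decoys, and mitochondrial
#'   tRNA decoys; the remainder (after halves) are full-length tRNAs.
#' @param y_family_probs Named weights over `RNY1`/`RNY3`/`RNY4`/`RNY5`.
#' @param y_source_probs Weights over `gene`, `pseudogene`, `repeat`
#'   placement (families lacking pseudogenes/repeats fall back to the
#'   gene).
#' @param y_frag_probs Weights over `y5frag`, `y3frag`, `y_full` (WT
#'   default `c(.55, .25, .20)`; mutant `c(.05, .05, .90)`).
#' @param pnk_treated Was the RNA end-healed with polynucleotide kinase
#'   before ligation.  Cleavage leaves a 2'-3' cyclic phosphate and a 5'
#'   hydroxyl, which RNA ligases cannot join: without PNK each cleaved end
#'   is only spontaneously ligatable with probability `p_spont_heal`.  5'
#'   halves carry one cleaved end; 3' halves carry two (anticodon loop and
#'   CCA-tail trimming), so they are more PNK-sensitive.
#' @param p_spont_heal Per-end ligatability without PNK (default 0.2).
#' @param demethylated,deacylated Were AlkB demethylation / 3' deacylation
#'   pretreatments applied.
#' @param p_methyl_block Probability (scalar or named per-family) that a
#'   half carries an RT-blocking base methylation; such molecules are
#'   dropped unless `demethylated`.
#' @param p_aminoacyl Probability that a molecule ending in an intact CCA
#'   is aminoacylated; dropped unless `deacylated`.
#' @param adapter 3' adapter sequence appended to raw reads.
#' @param frac_no_adapter Fraction of long-insert reads (length >=
#'   `long_insert`) whose raw read ends before the adapter is readable;
#'   emitted with `has_adapter = FALSE`.
#' @param long_insert Insert length (nt) above which adapter drop-out can
#'   occur (short fragments always expose the adapter).
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(genotype = c("WT", "mutant"),
                       n_reads = 20000L, seed = 1L,
                       half_fraction = NULL, split5 = NULL,
                       tail_probs = NULL,
                       cleavage_window = c(31L, 38L),
                       family_abundances = DEFAULT_FAMILY_ABUNDANCES,
                       family_split5 = DEFAULT_FAMILY_SPLIT5,
                       yrna_frac = 0.25, background_frac = 0.40,
                       mito_frac = 0.005,
                       y_family_probs = c(RNY1 = 0.09, RNY3 = 0.13,
                                          RNY4 = 0.22, RNY5 = 0.56),
                       y_source_probs = c(gene = 0.55, pseudogene = 0.30,
                                          "repeat" = 0.15),
                       y_frag_probs = NULL,
                       pnk_treated = TRUE, p_spont_heal = 0.2,
                       demethylated = FALSE, deacylated = FALSE,
                       p_methyl_block = 0, p_aminoacyl = 0,
                       adapter = "TGGAATTCTC", frac_no_adapter = 0.3,
                       long_insert = 70L) {
  genotype <- match.arg(genotype)
  if (is.null(half_fraction))
    half_fraction <- if (genotype == "WT") 0.173 else 0.016
  if (is.null(split5)) split5 <- if (genotype == "WT") 0.53 else 0.50
  if (is.null(tail_probs))
    tail_probs <- if (genotype == "WT")
      c(CCA = 0.05, CC = 0.05, C = 0.70, NONE = 0.20)
    else c(CCA = 0.90, CC = 0.04, C = 0.03, NONE = 0.03)
  if (is.null(y_frag_probs))
    y_frag_probs <- if (genotype == "WT")
      c(y5frag = 0.55, y3frag = 0.25, y_full = 0.20)
    else c(y5frag = 0.05, y3frag = 0.05, y_full = 0.90)
  stopifnot(setequal(names(tail_probs), c("CCA", "CC", "C", "NONE")),
            abs(sum(tail_probs) - 1) < 1e-8,
            all(tail_probs >= 0),
            length(cleavage_window) == 2L,
            cleavage_window[1L] <= cleavage_window[2L],
            half_fraction >= 0, half_fraction <= 1,
            split5 >= 0, split5 <= 1,
            p_spont_heal >= 0, p_spont_heal <= 1,
            all(p_methyl_block >= 0), all(p_methyl_block <= 1),
            p_aminoacyl >= 0, p_aminoacyl <= 1,
            frac_no_adapter >= 0, frac_no_adapter <= 1,
            nzchar(adapter))
  full_frac <- 1 - half_fraction - yrna_frac - background_frac - mito_frac
  if (full_frac < 0)
    stop("infeasible configuration: category fractions exceed 1")
  structure(list(
    genotype = genotype, n_reads = as.integer(n_reads),
    seed = as.integer(seed),
    half_fraction = half_fraction, split5 = split5,
    tail_probs = tail_probs[c("CCA", "CC", "C", "NONE")],
    cleavage_window = as.integer(cleavage_window),
    family_abundances = family_abundances / sum(family_abundances),
    family_split5 = family_split5,
    yrna_frac = yrna_frac, background_frac = background_frac,
    mito_frac = mito_frac, full_frac = full_frac,
    y_family_probs = y_family_probs / sum(y_family_probs),
    y_source_probs = y_source_probs / sum(y_source_probs),
    y_frag_probs = y_frag_probs / sum(y_frag_probs),
    pnk_treated = pnk_treated, p_spont_heal = p_spont_heal,
    demethylated = demethylated, deacylated = deacylated,
    p_methyl_block = p_methyl_block, p_aminoacyl = p_aminoacyl,
    adapter = adapter, frac_no_adapter = frac_no_adapter,
    long_insert = as.integer(long_insert)),
    class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig [%s] n=%d seed=%d half_fraction=%.3f split5=%.2f\n",
              x$genotype, x$n_reads, x$seed, x$half_fraction, x$split5))
  cat("  tail_probs:", paste(sprintf("%s=%.2f", names(x$tail_probs),
                                     x$tail_probs), collapse = " "), "\n")
  cat(sprintf("  PNK=%s demethylated=%s deacylated=%s\n",
              x$pnk_treated, x$demethylated, x$deacylated))
  invisible(x)
}

## Plant a sequence into a character genome at 1-based position.
plant <- function(contig_seq, pos, seq) {
  substr(contig_seq, pos, pos + nchar(seq) - 1L) <- seq
  contig_seq
}

#' Build the toy reference genome and annotation
#'
#' Deterministically (for a fixed seed) constructs a small genome with 9
#' cytosolic tRNA genes across 9 isoacceptor families -- including two
#' Gly-GCC copies with character-identical mature sequences, one
#' intron-containing gene (Tyr-GTA) and genes on both strands -- one
#' mitochondrial tRNA decoy, the four Y RNA genes (RNY5 84 nt), two RNY5
#' pseudogenes and three HY repeat intervals.  Several tRNA genes are
#' deliberately followed in the genome by `CCA`, `CC` or `C` so that
#' genome-templated tails are exercised.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `genome.fa`, `genes.gtf`,
#'   `trna_meta.tsv` and `repeats.bed` are written there (byte-identical
#'   for identical seeds).
#' @return A list with `annotation` (an [annotation_set()], genome
#'   included), `genome` (the [Biostrings::DNAStringSet]) and `files`
#'   (named paths or `NULL`).
#' @export
build_toy_reference <- function(seed = 1L, dir = NULL) {
  spec <- with_seed(seed, {
    contigs <- list(chrT1 = random_dna(3200L), chrT2 = random_dna(2400L),
                    chrY = random_dna(6000L), chrM = random_dna(1000L))
    ## mature sequences
    mat <- list(
      "tRNA-Gly-GCC-1" = random_dna(76L),
      "tRNA-Glu-CTC-1" = random_dna(76L),
      "tRNA-Glu-TTC-1" = random_dna(74L),
      "tRNA-Lys-CTT-1" = random_dna(75L),
      "tRNA-Tyr-GTA-1" = random_dna(76L),
      "tRNA-Asp-GTC-1" = random_dna(76L),
      "tRNA-Gly-CCC-1" = random_dna(76L),
      "tRNA-Val-CAC-1" = random_dna(75L),
      "tRNA-Val-TAC-1" = random_dna(76L),
      "tRNA-Phe-GAA-M" = random_dna(69L),
      "RNY1" = random_dna(112L), "RNY3" = random_dna(101L),
      "RNY4" = random_dna(93L), "RNY5" = random_dna(84L))
    mat[["tRNA-Gly-GCC-2"]] <- mat[["tRNA-Gly-GCC-1"]]
    tyr_intron <- random_dna(13L)
    ## pseudogenes: RNY5 with a few substitutions
    mutate_at <- function(s, pos) {
      for (p in pos) {
        cur <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
      s
    }
    p1 <- mutate_at(mat[["RNY5"]], c(10L, 40L, 70L))
    p3 <- mutate_at(mat[["RNY5"]], c(5L, 33L, 61L))
    rep_hy5 <- mutate_at(substr(mat[["RNY5"]], 1L, 60L),
                         c(7L, 21L, 44L, 52L, 58L))
    rep_hy4 <- mutate_at(substr(mat[["RNY4"]], 1L, 60L),
                         c(3L, 18L, 35L, 49L))
    rep_hy1 <- mutate_at(substr(mat[["RNY1"]], 1L, 60L),
                         c(11L, 27L, 42L))
    list(contigs = contigs, mat = mat, tyr_intron = tyr_intron,
         p1 = p1, p3 = p3, rep_hy5 = rep_hy5, rep_hy4 = rep_hy4,
         rep_hy1 = rep_hy1)
  })
  contigs <- spec$contigs
  mat <- spec$mat

  place_plus <- function(contig, pos, mseq, ctx) {
    contigs[[contig]] <<- plant(contigs[[contig]], pos, mseq)
    if (!is.null(ctx))
      contigs[[contig]] <<- plant(contigs[[contig]], pos + nchar(mseq), ctx)
    cbind(pos, pos + nchar(mseq) - 1L)
  }
  place_minus <- function(contig, pos, mseq, ctx) {
    contigs[[contig]] <<- plant(contigs[[contig]], pos, revcomp_chr(mseq))
    if (!is.null(ctx))
      contigs[[contig]] <<- plant(contigs[[contig]], pos - nchar(ctx),
                                  revcomp_chr(ctx))
    cbind(pos, pos + nchar(mseq) - 1L)
  }

  genes <- list()
  add <- function(id, contig, strand, blocks, cls, fam)
    genes[[id]] <<- gene_model(id, contig, strand, blocks, cls, fam)

  add("tRNA-Gly-GCC-1", "chrT1", "+",
      place_plus("chrT1", 201L, mat[["tRNA-Gly-GCC-1"]], "CCAT"),
      "tRNA", "Gly-GCC")
  add("tRNA-Glu-CTC-1", "chrT1", "+",
      place_plus("chrT1", 601L, mat[["tRNA-Glu-CTC-1"]], "CTTG"),
      "tRNA", "Glu-CTC")
  add("tRNA-Glu-TTC-1", "chrT1", "+",
      place_plus("chrT1", 1001L, mat[["tRNA-Glu-TTC-1"]], "TGAC"),
      "tRNA", "Glu-TTC")
  add("tRNA-Lys-CTT-1", "chrT1", "+",
      place_plus("chrT1", 1401L, mat[["tRNA-Lys-CTT-1"]], "GATC"),
      "tRNA", "Lys-CTT")
  ## intron-containing gene: mature 76 nt, 13 nt intron after position 37
  tyr <- mat[["tRNA-Tyr-GTA-1"]]
  tyr_genomic <- paste0(substr(tyr, 1L, 37L), spec$tyr_intron,
                        substr(tyr, 38L, 76L))
  contigs[["chrT1"]] <- plant(contigs[["chrT1"]], 1801L, tyr_genomic)
  contigs[["chrT1"]] <- plant(contigs[["chrT1"]], 1801L + 89L, "ACGT")
  add("tRNA-Tyr-GTA-1", "chrT1", "+",
      rbind(c(1801L, 1837L), c(1851L, 1889L)), "tRNA", "Tyr-GTA")
  add("tRNA-Asp-GTC-1", "chrT1", "-",
      place_minus("chrT1", 2501L, mat[["tRNA-Asp-GTC-1"]], "CCG"),
      "tRNA", "Asp-GTC")
  add("tRNA-Gly-GCC-2", "chrT2", "+",
      place_plus("chrT2", 301L, mat[["tRNA-Gly-GCC-2"]], "TGCA"),
      "tRNA", "Gly-GCC")
  add("tRNA-Gly-CCC-1", "chrT2", "+",
      place_plus("chrT2", 701L, mat[["tRNA-Gly-CCC-1"]], "ATCG"),
      "tRNA", "Gly-CCC")
  add("tRNA-Val-CAC-1", "chrT2", "-",
      place_minus("chrT2", 1201L, mat[["tRNA-Val-CAC-1"]], "TAG"),
      "tRNA", "Val-CAC")
  add("tRNA-Val-TAC-1", "chrT2", "+",
      place_plus("chrT2", 1601L, mat[["tRNA-Val-TAC-1"]], "GGTA"),
      "tRNA", "Val-TAC")
  add("tRNA-Phe-GAA-M", "chrM", "+",
      place_plus("chrM", 301L, mat[["tRNA-Phe-GAA-M"]], NULL),
      "tRNA_mito", "Phe-GAA")
  add("RNY5", "chrY", "+", place_plus("chrY", 501L, mat[["RNY5"]], NULL),
      "yRNA_gene", "RNY5")
  add("RNY1", "chrY", "+", place_plus("chrY", 1001L, mat[["RNY1"]], NULL),
      "yRNA_gene", "RNY1")
  add("RNY3", "chrY", "-", place_minus("chrY", 1501L, mat[["RNY3"]], NULL),
      "yRNA_gene", "RNY3")
  add("RNY4", "chrY", "+", place_plus("chrY", 2001L, mat[["RNY4"]], NULL),
      "yRNA_gene", "RNY4")
  add("RNY5P1", "chrY", "+", place_plus("chrY", 3001L, spec$p1, NULL),
      "yRNA_pseudogene", "RNY5")
  add("RNY5P3", "chrY", "-", place_minus("chrY", 3501L, spec$p3, NULL),
      "yRNA_pseudogene", "RNY5")
  add("HY5_chrY_4001", "chrY", "+",
      place_plus("chrY", 4001L, spec$rep_hy5, NULL),
      "yRNA_repeat", "RNY5")
  add("HY4_chrY_4501", "chrY", "-",
      place_minus("chrY", 4501L, spec$rep_hy4, NULL),
      "yRNA_repeat", "RNY4")
  add("HY1_chrY_5001", "chrY", "+",
      place_plus("chrY", 5001L, spec$rep_hy1, NULL),
      "yRNA_repeat", "RNY1")

  genome <- Biostrings::DNAStringSet(unlist(contigs))
  ann <- annotation_set(unname(genes), genome)
  files <- NULL
  if (!is.null(dir)) files <- write_annotation_files(ann, dir)
  list(annotation = ann, genome = genome, files = files)
}

#' Write annotation files for an annotation set
#'
#' Writes `genome.fa`, `genes.gtf` (exon rows; tRNA and Y RNA genes and
#' pseudogenes), `trna_meta.tsv` and `repeats.bed` (HY-family intervals)
#' into `dir`, in the formats accepted by [load_annotations()].
#'
#' @param ann An [annotation_set()].
#' @param dir Output directory.
#' @return Named character vector of paths, invisibly.
#' @export
write_annotation_files <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gtf"),
             meta = file.path(dir, "trna_meta.tsv"),
             repeats = file.path(dir, "repeats.bed"))
  Biostrings::writeXStringSet(ann$genome, paths[["genome"]])
  is_rep <- ann$gene_table$gene_class == "yRNA_repeat"
  gtf_lines <- unlist(lapply(ann$genes[ann$gene_table$gene_id[!is_rep]],
                             function(g) {
    sprintf(paste0("%s\texofrag\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; gene_class \"%s\"; family \"%s\";"),
            g$contig, g$blocks[, 1L], g$blocks[, 2L], g$strand,
            g$gene_id, g$gene_class, g$family)
  }))
  writeLines(gtf_lines, paths[["genes"]])
  tr <- ann$gene_table[ann$gene_table$gene_class %in%
                         c("tRNA", "tRNA_mito"), ]
  fam_parts <- strsplit(tr$family, "-", fixed = TRUE)
  meta <- data.frame(gene_id = tr$gene_id,
                     amino_acid = vapply(fam_parts, `[[`, "", 1L),
                     anticodon = vapply(fam_parts, `[[`, "", 2L),
                     is_mito = tr$gene_class == "tRNA_mito")
  write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  reps <- ann$genes[ann$gene_table$gene_id[is_rep]]
  inv_map <- setNames(names(HY_FAMILY_MAP), HY_FAMILY_MAP)
  bed_lines <- vapply(reps, function(g)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", g$contig, g$blocks[1L, 1L] - 1L,
            g$blocks[1L, 2L], inv_map[[g$family]], g$strand),
    character(1L))
  writeLines(bed_lines, paths[["repeats"]])
  invisible(paths)
}

## Map a mature-transcript span to genomic intervals, in transcript order.
map_span <- function(gene, t1, t2) {
  b <- gene$blocks
  out <- list()
  off <- 0L
  for (i in seq_len(nrow(b))) {
    w <- b[i, 2L] - b[i, 1L] + 1L
    ta <- off + 1L; tb <- off + w
    o1 <- max(t1, ta); o2 <- min(t2, tb)
    if (o1 <= o2) {
      if (gene$strand == "+") {
        out[[length(out) + 1L]] <- c(b[i, 1L] + (o1 - ta),
                                     b[i, 1L] + (o2 - ta))
      } else {
        out[[length(out) + 1L]] <- c(b[i, 2L] - (o2 - ta),
                                     b[i, 2L] - (o1 - ta))
      }
    }
    off <- off + w
  }
  out
}

## Construct one exact alignment record for a molecule covering mature
## positions t1..t2 of `gene` with nontemplated tail `tail` (possibly
## genome-templated in part): correct CIGAR (N across introns, M extension
## for templated tail bases, soft clip for the rest).
build_alignment <- function(gene, t1, t2, tail = "") {
  iv <- map_span(gene, t1, t2)
  tl <- 0L
  if (nzchar(tail)) {
    ctx <- gene$down3
    k <- min(nchar(tail), nchar(ctx))
    while (tl < k &&
           substr(tail, tl + 1L, tl + 1L) == substr(ctx, tl + 1L, tl + 1L))
      tl <- tl + 1L
  }
  if (tl > 0L) {
    last <- length(iv)
    if (gene$strand == "+") iv[[last]][2L] <- iv[[last]][2L] + tl
    else iv[[last]][1L] <- iv[[last]][1L] - tl
  }
  clip <- substring(tail, tl + 1L)
  if (gene$strand == "+") {
    ref_iv <- iv
  } else {
    ref_iv <- rev(iv)
  }
  ops <- character(0L)
  for (i in seq_along(ref_iv)) {
    if (i > 1L) {
      gap <- ref_iv[[i]][1L] - ref_iv[[i - 1L]][2L] - 1L
      ops <- c(ops, sprintf("%dN", gap))
    }
    ops <- c(ops, sprintf("%dM", ref_iv[[i]][2L] - ref_iv[[i]][1L] + 1L))
  }
  if (nzchar(clip)) {
    if (gene$strand == "+") ops <- c(ops, sprintf("%dS", nchar(clip)))
    else ops <- c(sprintf("%dS", nchar(clip)), ops)
  }
  list(contig = gene$contig, strand = gene$strand,
       genomic_start = ref_iv[[1L]][1L],
       cigar = paste(ops, collapse = ""),
       seq = paste0(substr(gene$spliced, t1, t2), tail))
}

## index into a named probability vector from one uniform draw
pick1 <- function(u, probs) {
  names(probs)[findInterval(u, cumsum(probs) / sum(probs)) + 1L]
}

## Free (unannotated) windows for background decoys: per-contig gaps at
## least `min_w` wide, padded away from every feature.
free_windows <- function(ann, pad = 60L, min_w = 80L) {
  out <- list()
  for (ct in names(ann$genome)) {
    feats <- ann$gene_table$gene_id[
      vapply(ann$genes, function(g) g$contig == ct, logical(1L))]
    iv <- do.call(rbind, lapply(ann$genes[feats], function(g)
      c(max(1L, g$span[1L] - pad), g$span[2L] + pad)))
    clen <- length(ann$genome[[ct]])
    if (is.null(iv)) {
      out[[length(out) + 1L]] <- data.frame(contig = ct, start = 1L,
                                            end = clen)
      next
    }
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    cur <- 1L
    for (i in seq_len(nrow(iv))) {
      if (iv[i, 1L] - 1L - cur + 1L >= min_w)
        out[[length(out) + 1L]] <- data.frame(contig = ct, start = cur,
                                              end = iv[i, 1L] - 1L)
      cur <- max(cur, iv[i, 2L] + 1L)
    }
    if (clen - cur + 1L >= min_w)
      out[[length(out) + 1L]] <- data.frame(contig = ct, start = cur,
                                            end = clen)
  }
  do.call(rbind, out)
}

#' Simulate an extracellular small RNA fragment library
#'
#' Draws `cfg$n_reads` molecules (tRNA halves, full-length tRNAs, Y RNA
#' fragments, mitochondrial decoys, unannotated background), applies the
#' end-chemistry / methylation / aminoacylation cloning model, and emits
#' exact alignment records (correct CIGARs: N ops across annotated
#' introns, M extension for genome-templated tail bases, soft clips for
#' nontemplated tail bases), raw reads with 4-nt randomized adapter ends,
#' and a per-molecule ground-truth table.
#'
#' Identical configurations give identical outputs.  Configurations
#' differing only in the cloning model (`pnk_treated`, `demethylated`,
#' `deacylated`) share the identical molecule set, so cloning effects can
#' be measured as paired differences on the truth table.
#'
#' @param cfg A [sim_config()].
#' @param ann The [annotation_set()] from [build_toy_reference()].
#' @param dir Optional output directory for `alignments.sam`,
#'   `reads.fastq` and `truth.tsv`.
#' @return A list with `alignments` (alignment-record data frame; cloned
#'   reads only, one primary each plus one secondary per multi-copy tRNA
#'   read), `truth` (per-molecule table: `read_id`, `family`, `gene_id`,
#'   `true_class`, `true_tail`, `source_class`, `cloned`, `drop_reason`,
#'   `has_adapter`, `trimmed_length`), `reads` (raw reads for cloned
#'   molecules), and `files`.
#' @export
simulate_library <- function(cfg, ann, dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), inherits(ann, "AnnotationSet"))
  n <- cfg$n_reads
  gt <- ann$gene_table
  trna_ids <- gt$gene_id[gt$gene_class == "tRNA"]
  fam_genes <- lapply(split(trna_ids,
                            gt$family[match(trna_ids, gt$gene_id)]), sort)
  fams <- names(cfg$family_abundances)
  if (!all(fams %in% names(fam_genes)))
    stop("infeasible configuration: families missing from annotation: ",
         paste(setdiff(fams, names(fam_genes)), collapse = ", "))
  mito_ids <- gt$gene_id[gt$gene_class == "tRNA_mito"]
  y_genes <- split(gt$gene_id[gt$gene_class == "yRNA_gene"],
                   gt$family[gt$gene_class == "yRNA_gene"])
  y_pseudo <- split(gt$gene_id[gt$gene_class == "yRNA_pseudogene"],
                    gt$family[gt$gene_class == "yRNA_pseudogene"])
  y_reps <- split(gt$gene_id[gt$gene_class == "yRNA_repeat"],
                  gt$family[gt$gene_class == "yRNA_repeat"])
  y5_len <- c(RNY1 = 31L, RNY3 = 32L, RNY4 = 30L, RNY5 = 33L)
  y3_len <- 22L
  min_L <- min(gt$mature_length[gt$gene_class == "tRNA"])
  if (cfg$cleavage_window[2L] + 1L > min_L - 4L)
    stop("infeasible configuration: cleavage window too close to tRNA ends")
  pmb <- cfg$p_methyl_block
  if (is.null(names(pmb))) pmb <- setNames(rep(pmb[1L], length(fams)), fams)

  fw <- free_windows(ann)
  fw_contig <- fw$contig; fw_start <- fw$start; fw_end <- fw$end
  contig_chr <- as.list(as.character(ann$genome))
  res <- with_seed(cfg$seed, {
    cat_probs <- c(half = cfg$half_fraction, full = cfg$full_frac,
                   y = cfg$yrna_frac, bg = cfg$background_frac,
                   mito = cfg$mito_frac)
    category <- pick1(runif(n), cat_probs)
    ## fixed-order uniform draws so that cloning-model flags never shift
    ## the molecule stream
    u_is5 <- runif(n); u_fam <- runif(n); u_copy <- runif(n)
    u_cut <- runif(n); u_tail <- runif(n)
    u_heal1 <- runif(n); u_heal2 <- runif(n)
    u_methyl <- runif(n); u_amino <- runif(n); u_noad <- runif(n)
    u_yfam <- runif(n); u_ysrc <- runif(n); u_yfeat <- runif(n)
    u_yfrag <- runif(n)
    u_bgwin <- runif(n); u_bgpos <- runif(n); u_bglen <- runif(n)
    u_bgstr <- runif(n)

    w <- cfg$family_abundances
    s5 <- cfg$family_split5[fams]
    p_fam5 <- w * s5; p_fam3 <- w * (1 - s5)
    is5 <- u_is5 < cfg$split5
    cw <- cfg$cleavage_window

    read_id <- sprintf("r%06d", seq_len(n))
    family <- character(n); gene_id <- rep(NA_character_, n)
    true_class <- character(n); true_tail <- rep(NA_character_, n)
    source_class <- rep(NA_character_, n)
    ends_needed <- integer(n)
    placement <- vector("list", n)
    nh <- rep(1L, n)
    sec_gene <- rep(NA_character_, n)

    for (i in seq_len(n)) {
      cat_i <- category[i]
      if (cat_i == "half") {
        fam <- if (is5[i]) pick1(u_fam[i], p_fam5)
               else pick1(u_fam[i], p_fam3)
        copies <- fam_genes[[fam]]
        gid <- copies[1L + floor(u_copy[i] * length(copies))]
        g <- ann$genes[[gid]]
        cutpos <- cw[1L] + floor(u_cut[i] * (cw[2L] - cw[1L] + 1L))
        family[i] <- fam; gene_id[i] <- gid
        if (length(copies) > 1L) {
          nh[i] <- length(copies)
          others <- setdiff(copies, gid)
          sec_gene[i] <- others[1L]
        }
        if (is5[i]) {
          true_class[i] <- "5half"; true_tail[i] <- "NOT_TAILED"
          ends_needed[i] <- 1L
          placement[[i]] <- build_alignment(g, 1L, cutpos, "")
        } else {
          tail <- pick1(u_tail[i], cfg$tail_probs)
          true_class[i] <- "3half"; true_tail[i] <- tail
          ends_needed[i] <- 2L
          placement[[i]] <- build_alignment(
            g, cutpos + 1L, g$mature_length,
            if (tail == "NONE") "" else tail)
        }
      } else if (cat_i %in% c("full", "mito")) {
        if (cat_i == "full") {
          fam <- pick1(u_fam[i], w)
          copies <- fam_genes[[fam]]
          gid <- copies[1L + floor(u_copy[i] * length(copies))]
          if (length(copies) > 1L) {
            nh[i] <- length(copies)
            sec_gene[i] <- setdiff(copies, gid)[1L]
          }
        } else {
          gid <- mito_ids[1L + floor(u_copy[i] * length(mito_ids))]
          fam <- gt$family[match(gid, gt$gene_id)]
        }
        g <- ann$genes[[gid]]
        tail <- pick1(u_tail[i], cfg$tail_probs)
        family[i] <- fam; gene_id[i] <- gid
        true_class[i] <- "full_length"; true_tail[i] <- tail
        ends_needed[i] <- if (tail == "CCA") 0L else 1L
        placement[[i]] <- build_alignment(
          g, 1L, g$mature_length, if (tail == "NONE") "" else tail)
      } else if (cat_i == "y") {
        fam <- pick1(u_yfam[i], cfg$y_family_probs)
        src <- pick1(u_ysrc[i], cfg$y_source_probs)
        if (src == "pseudogene" && is.null(y_pseudo[[fam]])) src <- "gene"
        if (src == "repeat" && is.null(y_reps[[fam]])) src <- "gene"
        cand <- switch(src, gene = y_genes[[fam]],
                       pseudogene = y_pseudo[[fam]],
                       "repeat" = y_reps[[fam]])
        gid <- sort(cand)[1L + floor(u_yfeat[i] * length(cand))]
        g <- ann$genes[[gid]]
        frag <- pick1(u_yfrag[i], cfg$y_frag_probs)
        L <- g$mature_length
        tr <- switch(frag,
                     y5frag = c(1L, min(y5_len[[fam]], L)),
                     y3frag = c(max(1L, L - y3_len + 1L), L),
                     y_full = c(1L, L))
        family[i] <- fam; gene_id[i] <- gid
        true_class[i] <- if (frag == "y_full") "y_full" else frag
        source_class[i] <- src
        ends_needed[i] <- if (frag == "y_full") 0L else 1L
        placement[[i]] <- build_alignment(g, tr[1L], tr[2L], "")
      } else {  ## background decoy from an unannotated interval
        wi <- 1L + floor(u_bgwin[i] * nrow(fw))
        win <- list(contig = fw_contig[wi], start = fw_start[wi],
                    end = fw_end[wi])
        len <- 20L + floor(u_bglen[i] * 21L)
        start <- win$start + floor(u_bgpos[i] * (win$end - win$start + 1L -
                                                   len))
        strand <- if (u_bgstr[i] < 0.5) "+" else "-"
        gseq <- substr(contig_chr[[win$contig]], start, start + len - 1L)
        family[i] <- "background"
        true_class[i] <- "background"
        ends_needed[i] <- 0L
        placement[[i]] <- list(
          contig = win$contig, strand = strand, genomic_start = start,
          cigar = sprintf("%dM", len),
          seq = if (strand == "-") revcomp_chr(gseq) else gseq)
      }
    }

    ## cloning model: end chemistry, methylation, aminoacylation
    heal1_ok <- cfg$pnk_treated | (u_heal1 < cfg$p_spont_heal)
    heal2_ok <- cfg$pnk_treated | (u_heal2 < cfg$p_spont_heal)
    end_block <- (ends_needed >= 1L & !heal1_ok) |
      (ends_needed >= 2L & !heal2_ok)
    fam_pmb <- ifelse(family %in% names(pmb), pmb[family], 0)
    methyl_block <- category == "half" & !cfg$demethylated &
      u_methyl < fam_pmb
    amino_block <- !cfg$deacylated &
      !is.na(true_tail) & true_tail == "CCA" &
      u_amino < cfg$p_aminoacyl
    drop_reason <- rep("none", n)
    drop_reason[amino_block] <- "aminoacyl"
    drop_reason[methyl_block] <- "methyl_block"
    drop_reason[end_block] <- "end_chemistry"
    cloned <- drop_reason == "none"

    trimmed_length <- vapply(placement, function(p) nchar(p$seq),
                             integer(1L))
    has_adapter <- !(trimmed_length >= cfg$long_insert &
                       u_noad < cfg$frac_no_adapter)

    truth <- data.frame(
      read_id = read_id, family = family, gene_id = gene_id,
      true_class = true_class, true_tail = true_tail,
      source_class = source_class, cloned = cloned,
      drop_reason = drop_reason, has_adapter = has_adapter,
      trimmed_length = trimmed_length, row.names = NULL)

    idx <- which(cloned)
    prim <- alignment_records(
      read_id = read_id[idx],
      seq = vapply(placement[idx], `[[`, "", "seq"),
      contig = vapply(placement[idx], `[[`, "", "contig"),
      strand = vapply(placement[idx], `[[`, "", "strand"),
      genomic_start = vapply(placement[idx], function(p)
        as.integer(p$genomic_start), integer(1L)),
      cigar = vapply(placement[idx], `[[`, "", "cigar"),
      is_primary = TRUE,
      has_adapter = has_adapter[idx],
      nh = nh[idx])
    ## one secondary record on another identical-sequence copy
    sec_idx <- idx[!is.na(sec_gene[idx])]
    sec <- NULL
    if (length(sec_idx)) {
      sec_pl <- lapply(sec_idx, function(i) {
        g2 <- ann$genes[[sec_gene[i]]]
        p <- placement[[i]]
        core_len <- nchar(p$seq) -
          (if (!is.na(true_tail[i]) &&
               true_tail[i] %in% c("C", "CC", "CCA"))
             nchar(true_tail[i]) else 0L)
        t1 <- if (true_class[i] == "3half")
          g2$mature_length - core_len + 1L else 1L
        build_alignment(g2, t1, t1 + core_len - 1L,
                        substring(p$seq, core_len + 1L))
      })
      sec <- alignment_records(
        read_id = read_id[sec_idx],
        seq = vapply(sec_pl, `[[`, "", "seq"),
        contig = vapply(sec_pl, `[[`, "", "contig"),
        strand = vapply(sec_pl, `[[`, "", "strand"),
        genomic_start = vapply(sec_pl, function(p)
          as.integer(p$genomic_start), integer(1L)),
        cigar = vapply(sec_pl, `[[`, "", "cigar"),
        is_primary = FALSE,
        has_adapter = has_adapter[sec_idx],
        nh = nh[sec_idx])
    }
    alns <- if (is.null(sec)) prim else rbind(prim, sec)

    ## raw reads: 4 randomized bases flank the insert on both sides
    ## (adapter-end randomization), then the 3' adapter (or a stub too
    ## short to detect when the adapter was not reached)
    rand4 <- function(m) {
      b <- matrix(sample(c("A", "C", "G", "T"), 4L * m, replace = TRUE),
                  ncol = 4L)
      paste0(b[, 1L], b[, 2L], b[, 3L], b[, 4L])
    }
    n_cl <- length(idx)
    r5 <- rand4(n_cl); r3 <- rand4(n_cl)
    raw <- paste0(r5, prim$seq, r3,
                  ifelse(prim$has_adapter, cfg$adapter,
                         substr(cfg$adapter, 1L, 3L)))
    reads <- data.frame(read_id = prim$read_id, raw = raw,
                        row.names = NULL)
    list(alignments = alns, truth = truth, reads = reads)
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(alignments = file.path(dir, "alignments.sam"),
               reads = file.path(dir, "reads.fastq"),
               truth = file.path(dir, "truth.tsv"))
    write_sam(res$alignments, ann$genome, files[["alignments"]])
    write_fastq(res$reads, files[["reads"]])
    write.table(res$truth, files[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  c(res, list(config = cfg, files = files))
}
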