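## Y RNA assignment: gene > pseudogene > repeat fallback hierarchy,
## strand-specific, with per-family aggregation across pseudogenes and
## repeat-derived copies.

Y_FAMILIES <- c("RNY1", "RNY3", "RNY4", "RNY5")

#' Assign reads to Y RNA genes, pseudogenes and repeats
#'
#' Primary alignments are tested for strand-specific overlap (>= 1 nt)
#' with Y RNA genes first, then Y RNA pseudogenes.  Only reads assigned to
#' no annotated feature at all (of any class) are then tested against Y
#' RNA repeat intervals.  Reads mapping to any pseudogene or repeat of a
#' family are grouped under that family.  Y RNA reads are not passed
#' through the tRNA qualification cascade; only primariness and strand are
#' enforced.
#'
#' @param alns Alignment-record data frame; secondary records are dropped.
#' @param ann An [annotation_set()].
#' @return A data frame with one row per primary record: `read_id`,
#'   `family` (`RNY1`/`RNY3`/`RNY4`/`RNY5` or `"none"`), `source_class`
#'   (`"gene"`, `"pseudogene"`, `"repeat"` or `"none"`), `gene_id` of the
#'   matched feature (or `NA`) and `trimmed_length`.
#' @export
assign_yrna <- function(alns, ann) {
  alns <- alns[alns$is_primary, , drop = FALSE]
  n <- nrow(alns)
  fam <- rep("none", n); src <- rep("none", n)
  feat <- rep(NA_character_, n)
  g <- assign_gene_by_overlap(alns, ann, "yRNA_gene")
  p <- assign_gene_by_overlap(alns, ann, "yRNA_pseudogene")
  any_feat <- assign_gene_by_overlap(
    alns, ann, setdiff(GENE_CLASSES, "yRNA_repeat"))
  r <- assign_gene_by_overlap(alns, ann, "yRNA_repeat")
  fam_of <- setNames(ann$gene_table$family, ann$gene_table$gene_id)
  hit_g <- !is.na(g)
  fam[hit_g] <- fam_of[g[hit_g]]; src[hit_g] <- "gene"; feat[hit_g] <- g[hit_g]
  hit_p <- !hit_g & !is.na(p)
  fam[hit_p] <- fam_of[p[hit_p]]; src[hit_p] <- "pseudogene"
  feat[hit_p] <- p[hit_p]
  hit_r <- !hit_g & !hit_p & is.na(any_feat) & !is.na(r)
  fam[hit_r] <- fam_of[r[hit_r]]; src[hit_r] <- "repeat"; feat[hit_r] <- r[hit_r]
  data.frame(read_id = alns$read_id, family = fam, source_class = src,
             gene_id = feat, trimmed_length = nchar(alns$seq),
             row.names = NULL)
}

#' Summarize Y RNA assignments
#'
#' @param assignments Output of [assign_yrna()].
#' @return A list with `family_shares` (per-family share of Y-mapped
#'   reads; sums to 1 over assigned reads), `source_shares` (share per
#'   source class among assigned reads), and `length_hist` (per-family
#'   1-nt length histogram of adapter-trimmed read lengths).
#' @export
yrna_summary <- function(assignments) {
  asg <- assignments[assignments$family != "none", , drop = FALSE]
  if (!nrow(asg)) {
    return(list(
      family_shares = setNames(numeric(0L), character(0L)),
      source_shares = setNames(numeric(0L), character(0L)),
      length_hist = data.frame(family = character(0L),
                               length = integer(0L),
                               count = integer(0L))))
  }
  fam_counts <- table(factor(asg$family, levels = Y_FAMILIES))
  fam_counts <- fam_counts[fam_counts > 0L]
  src_counts <- table(asg$source_class)
  hist <- as.data.frame(table(family = asg$family,
                              length = asg$trimmed_length),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0L, ]
  hist <- data.frame(family = hist$family,
                     length = as.integer(hist$length),
                     count = as.integer(hist$Freq))
  hist <- hist[order(hist$family, hist$length), ]
  rownames(hist) <- NULL
  list(family_shares = setNames(as.numeric(fam_counts) / nrow(asg),
                                names(fam_counts)),
       source_shares = setNames(as.numeric(src_counts) / nrow(asg),
                                names(src_counts)),
       length_hist = hist)
}
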