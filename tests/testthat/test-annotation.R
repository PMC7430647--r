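test_that("identity groups follow exact spliced-sequence identity", {
  ann <- unit_ref()
  grp <- ann$identity_groups
  expect_true("tGly1" %in% names(grp))
  expect_setequal(grp[["tGly1"]], c("tGly1", "tGly2"))
  # one substitution separates the copies into singleton groups
  ann2 <- unit_ref(mutate_copy2 = TRUE)
  expect_setequal(names(ann2$identity_groups),
                  c("tAsp1", "tGly1", "tGly2", "tTyr1"))
  expect_true(all(lengths(ann2$identity_groups[c("tGly1", "tGly2")]) == 1L))
})

test_that("identity groups partition the cytosolic tRNA gene ids", {
  ann <- build_toy_reference(seed = 1)$annotation
  ids <- unlist(ann$identity_groups, use.names = FALSE)
  expect_false(anyDuplicated(ids) > 0L)
  cyto <- ann$gene_table$gene_id[ann$gene_table$gene_class == "tRNA"]
  expect_setequal(ids, cyto)
  # mitochondrial decoy carried but never grouped
  expect_true("tRNA-Phe-GAA-M" %in% ann$gene_table$gene_id)
  expect_false("tRNA-Phe-GAA-M" %in% ids)
})

test_that("transcript coordinates map plus, minus and intron-spanning alignments", {
  ann <- unit_ref()
  spl <- function(id) ann$genes[[id]]$spliced
  # plus-strand gene blocks 1001..1076, span 1001..1033 -> (1, 33)
  a <- alignment_records("p", substr(spl("tGly1"), 1, 33), "c1", "+",
                         1001L, "33M")
  expect_equal(transcript_coords(a[1, ], ann$genes[["tGly1"]]), c(1L, 33L))
  # minus-strand gene blocks 2001..2076, span 2044..2076 -> (1, 33)
  b <- alignment_records("m", substr(spl("tAsp1"), 1, 33), "c1", "-",
                         2044L, "33M")
  expect_equal(transcript_coords(b[1, ], ann$genes[["tAsp1"]]), c(1L, 33L))
  # intron-containing gene, 8M across the junction with an exact N gap:
  # frozen expectation (30, 46) from a brute-force spliced-coordinate walk
  d <- alignment_records("i", substr(spl("tTyr1"), 30, 46), "c1", "+",
                         530L, "8M14N9M")
  expect_equal(transcript_coords(d[1, ], ann$genes[["tTyr1"]]), c(30L, 46L))
  # no overlap -> NA signal
  e <- alignment_records("x", "ACGTACGTAC", "c1", "+", 10L, "10M")
  expect_equal(transcript_coords(e[1, ], ann$genes[["tGly1"]]),
               c(NA_integer_, NA_integer_))
})

test_that("transcript/genomic round trip is the identity on both strands", {
  ann <- unit_ref()
  for (id in c("tGly1", "tAsp1", "tTyr1")) {
    g <- ann$genes[[id]]
    for (p in seq_len(g$mature_length)) {
      gp <- exofrag:::transcript_to_genomic(g, p)
      expect_identical(exofrag:::genomic_to_transcript(g, gp), p)
    }
  }
})

test_that("downstream context is strand-aware and truncates at contig ends", {
  ann <- unit_ref()
  expect_identical(downstream_context(ann$genes[["tGly1"]], ann$genome, 3),
                   "CCA")
  # minus-strand gene with genomic 5' flank TGG reads as CCA
  expect_identical(downstream_context(ann$genes[["tAsp1"]], ann$genome, 3),
                   "CCA")
  expect_identical(downstream_context(ann$genes[["tGly2"]], ann$genome, 3),
                   "TGC")
  g_edge <- gene_model("edge", "cx", "+", cbind(2L, 11L), "yRNA_gene",
                       "RNY5")
  genome <- Biostrings::DNAStringSet(c(cx = "AACGTACGTACG"))
  expect_warning(ctx <- downstream_context(g_edge, genome, 3),
                 "truncated")
  expect_identical(ctx, "G")
})

test_that("annotation files round trip through write and load", {
  dir <- withr::local_tempdir()
  ref <- build_toy_reference(seed = 5, dir = dir)
  ann <- ref$annotation
  ann2 <- load_annotations(file.path(dir, "genome.fa"),
                           file.path(dir, "genes.gtf"),
                           file.path(dir, "trna_meta.tsv"),
                           file.path(dir, "repeats.bed"))
  t1 <- ann$gene_table[order(ann$gene_table$gene_id), ]
  t2 <- ann2$gene_table[order(ann2$gene_table$gene_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t2, t1)
  expect_equal(ann2$identity_groups, ann$identity_groups)
  for (id in ann$gene_table$gene_id)
    expect_identical(ann2$genes[[id]]$spliced, ann$genes[[id]]$spliced)
  # HY repeat records are associated with their Y RNA family
  reps <- ann2$gene_table[ann2$gene_table$gene_class == "yRNA_repeat", ]
  expect_setequal(reps$family, c("RNY1", "RNY4", "RNY5"))
  expect_true(all(grepl("^HY", reps$gene_id)))
})

test_that("malformed annotations fail loudly with the offending gene", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 50)))
  expect_error(
    annotation_set(list(gene_model("gX", "c9", "+", cbind(1L, 80L),
                                   "tRNA", "Gly-GCC")), genome),
    "gX.*unknown contig|unknown contig.*gX")
  expect_error(
    annotation_set(list(gene_model("gY", "c1", "+", cbind(150L, 230L),
                                   "tRNA", "Gly-GCC")), genome),
    "outside contig")
  expect_error(gene_model("gZ", "c1", "*", cbind(1L, 80L), "tRNA", "X-Y"),
               "strand")
  expect_error(gene_model("gW", "c1", "+", cbind(1L, 50L), "tRNA", "X-Y"),
               "mature length")
})

test_that("strand symmetry: mirrored reference gives identical coordinates", {
  ann <- unit_ref()
  flipped <- flip_reference(ann)
  for (id in c("tGly1", "tAsp1", "tTyr1")) {
    g <- ann$genes[[id]]
    spl <- g$spliced
    expect_identical(flipped$genes[[id]]$spliced, spl)
    for (span in list(c(1L, 33L), c(34L, g$mature_length), c(10L, 50L))) {
      a <- mk_aln(ann, id, span[1L], span[2L])
      af <- flip_alignments(a, ann)
      expect_equal(
        transcript_coords(af[1, ], flipped$genes[[id]]),
        transcript_coords(a[1, ], g))
    }
  }
})
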