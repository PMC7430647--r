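test_that("adapter detection requires an exact adapter prefix of min_match nt", {
  ad <- "TGGAATTCTC"
  r <- detect_adapter(paste0("ACGTACGT", ad), ad, 6)
  expect_identical(r$trimmed_seq, "ACGTACGT")
  expect_true(r$has_adapter)
  r2 <- detect_adapter("ACGTACGTACGT", ad, 6)
  expect_identical(r2$trimmed_seq, "ACGTACGTACGT")
  expect_false(r2$has_adapter)
  # a 5-nt adapter prefix is below min_match
  r3 <- detect_adapter("ACGTACGTTGGAA", ad, 6)
  expect_false(r3$has_adapter)
  expect_identical(r3$trimmed_seq, "ACGTACGTTGGAA")
})

test_that("tail calls distinguish NOT_TAILED, NONE, C/CC/CCA and OTHER", {
  ann <- unit_ref()
  gly2 <- ann$genes[["tGly2"]]   # downstream context TGC: nothing templated
  gly1 <- ann$genes[["tGly1"]]   # downstream context CCA: fully templated
  # alignment ends exactly at the mature end, no soft clip
  expect_identical(tail_call(mk_aln(ann, "tGly2", 1, 76)[1, ], gly2), "NONE")
  # soft-clipped CCA where the genome context is not CCA
  a <- mk_aln(ann, "tGly2", 34, 76, "CCA")
  expect_match(a$cigar, "3S")
  expect_identical(tail_call(a[1, ], gly2), "CCA")
  # genome context CCA: the tail aligns as M beyond the annotation end
  b <- mk_aln(ann, "tGly1", 34, 76, "CCA")
  expect_identical(b$cigar, "46M")
  expect_identical(tail_call(b[1, ], gly1), "CCA")
  # alignment stopping short of the mature end
  expect_identical(tail_call(mk_aln(ann, "tGly2", 1, 74)[1, ], gly2),
                   "NOT_TAILED")
  # a non-CCA-like addition
  g <- mk_aln(ann, "tGly2", 34, 76, "G")
  expect_identical(tail_call(g[1, ], gly2), "OTHER")
  # minus-strand gene with templated CCA context (upstream TGG)
  asp <- ann$genes[["tAsp1"]]
  d <- mk_aln(ann, "tAsp1", 34, 76, "CCA")
  expect_identical(d$cigar, "46M")
  expect_identical(d$genomic_start, 1998L)
  expect_identical(tail_call(d[1, ], asp), "CCA")
})

test_that("the qualification cascade assigns reasons in fixed order", {
  ann <- unit_ref()
  gly1 <- ann$genes[["tGly1"]]
  spl <- gly1$spliced
  q <- function(aln, gene) qualify_read(aln[1, ], gene)
  # deletion in the CIGAR
  del <- alignment_records("d", substr(spl, 1, 33), "c1", "+", 1001L,
                           "20M1D13M")
  expect_identical(q(del, gly1)$reason, "indel_or_intron")
  # insertion
  ins <- alignment_records("i", paste0(substr(spl, 1, 20), "A",
                                       substr(spl, 21, 33)),
                           "c1", "+", 1001L, "20M1I13M")
  expect_identical(q(ins, gly1)$reason, "indel_or_intron")
  # N gap not matching the annotated intron
  tyr <- ann$genes[["tTyr1"]]
  badn <- alignment_records("n", substr(tyr$spliced, 30, 46), "c1", "+",
                            530L, "8M13N9M")
  expect_identical(q(badn, tyr)$reason, "indel_or_intron")
  # N gap exactly matching the annotated intron passes
  goodn <- alignment_records("n2", substr(tyr$spliced, 30, 46), "c1", "+",
                             530L, "8M14N9M")
  expect_identical(q(goodn, tyr)$reason, "ok")
  # missing 3' adapter
  noad <- mk_aln(ann, "tGly1", 1, 33, has_adapter = FALSE)
  expect_identical(q(noad, gly1)$reason, "no_adapter")
  # mitochondrial tRNA excluded before anything else is checked
  mito <- mk_aln(ann, "tPheM", 1, 30)
  expect_identical(q(mito, ann$genes[["tPheM"]])$reason, "mito")
  # secondary alignment
  sec <- mk_aln(ann, "tGly1", 1, 33, is_primary = FALSE)
  expect_identical(q(sec, gly1)$reason, "not_primary")
  # 5' soft clip fails the end-to-end length rule
  clip5 <- alignment_records("c5", paste0("AA", substr(spl, 3, 33)),
                             "c1", "+", 1003L, "2S31M")
  expect_identical(q(clip5, gly1)$reason, "length_mismatch")
  # 3' soft clip on a read that never reaches the mature end
  mid <- alignment_records("mid", paste0(substr(spl, 1, 30), "CCA"),
                           "c1", "+", 1001L, "30M3S")
  expect_identical(q(mid, gly1)$reason, "length_mismatch")
  # one nucleotide upstream of the mature 5' end marks a pre-tRNA
  up <- alignment_records("u", paste0(
    substr(as.character(ann$genome[["c1"]]), 1000, 1000),
    substr(spl, 1, 33)), "c1", "+", 1000L, "34M")
  expect_identical(q(up, gly1)$reason, "pre_trna")
  # tailed read with a templated CCA is ok, not pre-tRNA
  tmpl <- mk_aln(ann, "tGly1", 34, 76, "CCA")
  res <- q(tmpl, gly1)
  expect_identical(res$reason, "ok")
  expect_identical(res$tail, "CCA")
  # soft-clipped CCA tail: length may exceed the CIGAR matches by the
  # non-genome-matching tail
  sc <- mk_aln(ann, "tGly2", 34, 76, "CCA")
  res2 <- q(sc, ann$genes[["tGly2"]])
  expect_identical(res2$reason, "ok")
  expect_identical(res2$tail, "CCA")
})

test_that("qualification is order-invariant and conserves read counts", {
  ann <- build_toy_reference(seed = 2)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 600, seed = 8), ann)
  alns <- sim$alignments
  q1 <- qualify_reads(alns, ann)
  set.seed(1)
  perm <- sample(nrow(alns))
  q2 <- qualify_reads(alns[perm, ], ann)
  key1 <- paste(q1$read_id, q1$gene_id, q1$reason, q1$tail)
  key2 <- paste(q2$read_id, q2$gene_id, q2$reason, q2$tail)
  expect_setequal(key2, key1)
  # every primary record lands in exactly one non-secondary reason bucket
  primary_reasons <- q1$reason[alns$is_primary]
  expect_identical(length(primary_reasons), sum(alns$is_primary))
  expect_false(any(primary_reasons == "not_primary"))
  expect_identical(sum(table(primary_reasons)), sum(alns$is_primary))
  expect_true(all(q1$reason[!alns$is_primary] == "not_primary"))
})

test_that("qualification agrees with the string-matching oracle", {
  ann <- build_toy_reference(seed = 3)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 800, seed = 13), ann)
  q <- qualify_reads(sim$alignments, ann)
  o <- oracle_table(sim$alignments, ann)
  expect_identical(q$reason, o$reason)
  ok <- q$reason == "ok"
  expect_identical(q$tail[ok], o$tail[ok])
})
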