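test_that("toy reference has the intended structure", {
  ann <- build_toy_reference(seed = 1)$annotation
  gt <- ann$gene_table
  cyto <- gt[gt$gene_class == "tRNA", ]
  expect_gte(nrow(cyto), 8L)
  expect_gte(length(unique(cyto$family)), 4L)
  expect_true(all(cyto$mature_length >= 74L & cyto$mature_length <= 76L))
  expect_true(any(gt$gene_class == "tRNA_mito"))
  expect_setequal(gt$family[gt$gene_class == "yRNA_gene"],
                  c("RNY1", "RNY3", "RNY4", "RNY5"))
  expect_identical(gt$mature_length[gt$gene_id == "RNY5"], 84L)
  expect_gte(sum(gt$gene_class == "yRNA_pseudogene"), 2L)
  expect_gte(sum(gt$gene_class == "yRNA_repeat"), 2L)
  expect_setequal(unique(cyto$strand), c("+", "-"))
  # an identical-sequence pair and an intron-containing gene exist
  expect_true(any(lengths(ann$identity_groups) == 2L))
  expect_true(any(vapply(ann$genes, function(g) nrow(g$blocks) > 1L,
                         logical(1L))))
  # several genes carry a templated C/CC/CCA downstream context
  ctx <- vapply(ann$genes[cyto$gene_id], `[[`, "", "down3")
  expect_true(any(ctx == "CCA"))
  expect_true(any(substr(ctx, 1, 2) == "CC" & ctx != "CCA"))
  expect_true(any(substr(ctx, 1, 1) == "C" & substr(ctx, 1, 2) != "CC"))
})

test_that("identical seeds give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- build_toy_reference(seed = 9, dir = d1)
  r2 <- build_toy_reference(seed = 9, dir = d2)
  for (f in names(r1$files))
    expect_identical(readLines(r1$files[[f]]), readLines(r2$files[[f]]))
  cfg <- sim_config("WT", n_reads = 400, seed = 17)
  s1 <- simulate_library(cfg, r1$annotation, dir = file.path(d1, "sim"))
  s2 <- simulate_library(cfg, r2$annotation, dir = file.path(d2, "sim"))
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
  for (f in names(s1$files))
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
})

test_that("truth table and emitted reads are mutually conserved", {
  ann <- build_toy_reference(seed = 2)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 900, seed = 19), ann)
  expect_identical(nrow(sim$truth), 900L)
  expect_false(anyDuplicated(sim$truth$read_id) > 0L)
  cloned <- sim$truth$read_id[sim$truth$cloned]
  # every raw read appears exactly once in the truth table, and every
  # cloned molecule exactly once among primary alignments
  expect_setequal(sim$reads$read_id, cloned)
  prim <- sim$alignments[sim$alignments$is_primary, ]
  expect_false(anyDuplicated(prim$read_id) > 0L)
  expect_setequal(prim$read_id, cloned)
  expect_true(all(sim$truth$cloned == (sim$truth$drop_reason == "none")))
})

test_that("every emitted alignment is self-consistent with the genome", {
  ann <- build_toy_reference(seed = 3)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 700, seed = 23), ann)
  alns <- sim$alignments
  genome <- as.character(ann$genome)
  for (i in seq_len(nrow(alns))) {
    ops <- exofrag:::parse_cigar(alns$cigar[i])
    seq_ref <- if (alns$strand[i] == "-")
      exofrag:::revcomp_chr(alns$seq[i]) else alns$seq[i]
    rpos <- alns$genomic_start[i]; qpos <- 1L
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op == "M") {
        expect_identical(substr(seq_ref, qpos, qpos + len - 1L),
                         substr(genome[[alns$contig[i]]], rpos,
                                rpos + len - 1L))
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op %in% c("D", "N")) rpos <- rpos + len
      else qpos <- qpos + len
    }
  }
  # raw reads embed the emitted sequence between randomized 4-mers
  m <- match(sim$reads$read_id, alns$read_id)
  expect_true(all(substr(sim$reads$raw, 5L, 4L + nchar(alns$seq[m])) ==
                    alns$seq[m]))
  ad <- detect_adapter(sim$reads$raw, sim$config$adapter, 6)
  expect_identical(ad$has_adapter, alns$has_adapter[m])
})

test_that("the pipeline recovers the simulated truth exactly", {
  ann <- build_toy_reference(seed = 4)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 1000, seed = 29), ann)
  tr <- sim$truth[sim$truth$cloned, ]
  calls <- fragment_calls(sim$alignments, ann)
  q <- attr(calls, "qualification")
  qp <- q[match(tr$read_id, q$read_id), ]
  exp_reason <- ifelse(
    tr$true_class %in% c("y_full", "y5frag", "y3frag", "background"),
    "no_gene",
    ifelse(tr$family == "Phe-GAA", "mito",
           ifelse(!tr$has_adapter, "no_adapter", "ok")))
  expect_identical(qp$reason, exp_reason)
  m <- match(calls$read_id, tr$read_id)
  exp_half <- c("5half" = "FIVE_PRIME", "3half" = "THREE_PRIME",
                "full_length" = "OTHER")[tr$true_class[m]]
  expect_identical(calls$half, unname(exp_half))
  expect_identical(calls$tail, tr$true_tail[m])
})

test_that("PNK-off libraries lose 3' halves faster than 5' halves", {
  ann <- build_toy_reference(seed = 5)$annotation
  on <- simulate_library(sim_config("WT", n_reads = 2500, seed = 37,
                                    pnk_treated = TRUE), ann)
  off <- simulate_library(sim_config("WT", n_reads = 2500, seed = 37,
                                     pnk_treated = FALSE), ann)
  keep <- c("read_id", "true_class", "true_tail", "gene_id", "family")
  expect_identical(on$truth[keep], off$truth[keep])  # same molecules
  cl <- function(s, cls) sum(s$truth$cloned & s$truth$true_class == cls)
  expect_lt(cl(off, "3half"), cl(on, "3half"))
  rate <- function(s, cls) mean(s$truth$cloned[s$truth$true_class == cls])
  drop5 <- rate(on, "5half") - rate(off, "5half")
  drop3 <- rate(on, "3half") - rate(off, "3half")
  expect_gt(drop3, drop5)
})

test_that("group counts are invariant to which identical copy is primary", {
  ann <- build_toy_reference(seed = 6)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 1200, seed = 43), ann)
  calls1 <- fragment_calls(sim$alignments, ann)
  # promote every secondary record to primary and vice versa
  alns2 <- sim$alignments
  multi <- alns2$read_id %in% alns2$read_id[!alns2$is_primary]
  alns2$is_primary[multi] <- !alns2$is_primary[multi]
  calls2 <- fragment_calls(alns2, ann)
  count_by_group <- function(calls) {
    halves <- calls[calls$half != "OTHER", ]
    table(halves$identity_group, halves$half)
  }
  expect_equal(count_by_group(calls2), count_by_group(calls1))
})

test_that("infeasible configurations fail with a message", {
  expect_error(sim_config("WT", half_fraction = 0.5, yrna_frac = 0.4,
                          background_frac = 0.2), "infeasible")
  ann <- build_toy_reference(seed = 1)$annotation
  expect_error(
    simulate_library(sim_config("WT", n_reads = 10,
                                cleavage_window = c(31L, 72L)), ann),
    "cleavage window")
  expect_error(sim_config("WT", tail_probs = c(CCA = 1, CC = 1, C = 0,
                                               NONE = 0)))
})

test_that("SAM round trip preserves alignment records", {
  ann <- build_toy_reference(seed = 7)$annotation
  sim <- simulate_library(sim_config("WT", n_reads = 300, seed = 47), ann)
  path <- file.path(withr::local_tempdir(), "lib.sam")
  write_sam(sim$alignments, ann$genome, path)
  back <- read_alignments(path)
  key <- function(df) paste(df$read_id, df$is_primary)
  back <- back[match(key(sim$alignments), key(back)), ]
  rownames(back) <- NULL
  expect_equal(back, sim$alignments)
})
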