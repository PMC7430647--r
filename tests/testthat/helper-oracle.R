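# Brute-force oracle: reconstructs what one read must be by exact string
# matching of its sequence against the spliced mature gene sequence (plus
# an optional C/CC/CCA tail ending at the mature 3' end), independently of
# any CIGAR arithmetic.  Returns reason, half class and tail.
oracle_read <- function(aln, gene, windows = half_windows()) {
  if (!isTRUE(aln$is_primary))
    return(list(reason = "not_primary", half = NA, tail = NA))
  if (is.null(gene))
    return(list(reason = "no_gene", half = NA, tail = NA))
  if (gene$gene_class == "tRNA_mito")
    return(list(reason = "mito", half = NA, tail = NA))
  S <- gene$spliced
  L <- nchar(S)
  seq <- aln$seq
  interp <- list()
  # internal placements (alignment fully within the mature annotation)
  hits <- gregexpr(seq, S, fixed = TRUE)[[1L]]
  if (hits[1L] != -1L) {
    for (h in hits) {
      interp[[length(interp) + 1L]] <-
        list(tstart = h, tend = h + nchar(seq) - 1L,
             tail = if (h + nchar(seq) - 1L == L) "NONE" else "NOT_TAILED",
             tailed = h + nchar(seq) - 1L == L)
    }
  }
  # tailed placements: core suffix at the mature end + C/CC/CCA
  for (t in c("CCA", "CC", "C")) {
    if (nchar(seq) > nchar(t) && endsWith(seq, t)) {
      core <- substr(seq, 1L, nchar(seq) - nchar(t))
      if (core == substr(S, L - nchar(core) + 1L, L)) {
        interp[[length(interp) + 1L]] <-
          list(tstart = L - nchar(core) + 1L, tend = L, tail = t,
               tailed = TRUE)
      }
    }
  }
  if (!length(interp))
    return(list(reason = "unmatched", half = NA, tail = NA))
  # ties resolve toward the tailed interpretation, then the longest core
  tailed <- vapply(interp, `[[`, logical(1L), "tailed")
  if (any(tailed)) interp <- interp[tailed]
  core_len <- vapply(interp, function(x) x$tend - x$tstart + 1L, integer(1L))
  pick <- interp[[which.max(core_len)]]
  if (!isTRUE(aln$has_adapter))
    return(list(reason = "no_adapter", half = NA, tail = NA))
  half <- local({
    ts <- pick$tstart; te <- pick$tend
    five <- ts <= windows$max_start5 &&
      te >= windows$loop_lo && te <= windows$loop_hi
    three <- ts >= windows$loop_lo && ts <= windows$loop_hi &&
      te >= L - windows$end3_margin + 1L
    if (five) "FIVE_PRIME" else if (three) "THREE_PRIME" else "OTHER"
  })
  list(reason = "ok", half = half, tail = pick$tail)
}

# Run the oracle over a whole alignment table, against the same gene the
# pipeline assigned (assignment itself is overlap-based, not string-based).
oracle_table <- function(alns, ann) {
  gene_id <- exofrag:::assign_gene_by_overlap(alns, ann,
                                              c("tRNA", "tRNA_mito"))
  res <- lapply(seq_len(nrow(alns)), function(i) {
    aln <- list(seq = alns$seq[i], is_primary = alns$is_primary[i],
                has_adapter = alns$has_adapter[i])
    g <- if (is.na(gene_id[i])) NULL else ann$genes[[gene_id[i]]]
    o <- oracle_read(aln, g)
    data.frame(read_id = alns$read_id[i],
               reason = o$reason,
               half = if (is.na(o$half[1L])) NA_character_ else o$half,
               tail = if (is.na(o$tail[1L])) NA_character_ else o$tail)
  })
  do.call(rbind, res)
}
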