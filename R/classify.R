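## Half classification: 5' halves start at the mature 5' end and end in
## the anticodon loop; 3' halves start in the loop and end at the mature
## 3' end.  Windows follow the transcript coordinates of the mature
## annotation; tail bases never extend tend.

#' Half-classification windows
#'
#' The transcript-coordinate windows defining tRNA halves.  Defaults: a 5'
#' half starts no farther than the fifth nucleotide and ends within
#' nucleotides 29-41; a 3' half starts within nucleotides 29-41 and ends
#' within the last five nucleotides of the mature annotation.  All bounds
#' are inclusive.
#'
#' @param max_start5 Latest allowed start (nt) of a 5' half.
#' @param loop_lo,loop_hi Anticodon-loop window (nt) in which 5' halves
#'   end and 3' halves start.
#' @param end3_margin A 3' half must end within the last `end3_margin` nt.
#' @return An object of class `HalfWindows`.
#' @export
half_windows <- function(max_start5 = 5L, loop_lo = 29L, loop_hi = 41L,
                         end3_margin = 5L) {
  w <- list(max_start5 = as.integer(max_start5),
            loop_lo = as.integer(loop_lo),
            loop_hi = as.integer(loop_hi),
            end3_margin = as.integer(end3_margin))
  if (!(1L <= w$max_start5 && w$max_start5 < w$loop_lo &&
        w$loop_lo <= w$loop_hi && w$end3_margin >= 1L))
    stop("invalid half windows: need 1 <= max_start5 < loop_lo <= loop_hi ",
         "and end3_margin >= 1")
  structure(w, class = "HalfWindows")
}

HALF_LEVELS <- c("FIVE_PRIME", "THREE_PRIME", "OTHER")

#' Classify an alignment span as a 5' half, 3' half or other
#'
#' Vectorized over `tstart`/`tend`/`L`.  `tend` must be the last
#' genome-annotated aligned base (nontemplated or genome-templated tail
#' bases excluded).
#'
#' @param tstart,tend 1-based mature-transcript span of the aligned bases.
#' @param L Mature length(s) of the gene(s).
#' @param w A [half_windows()].
#' @return Character vector over `"FIVE_PRIME"`, `"THREE_PRIME"`,
#'   `"OTHER"`.
#' @examples
#' classify_half(1, 33, 76)   # FIVE_PRIME
#' classify_half(34, 74, 76)  # THREE_PRIME
#' @export
classify_half <- function(tstart, tend, L, w = half_windows()) {
  stopifnot(inherits(w, "HalfWindows"))
  if (any(L < w$loop_hi + w$end3_margin, na.rm = TRUE))
    stop("mature length shorter than loop_hi + end3_margin: ",
         "5' and 3' windows would overlap")
  n <- max(length(tstart), length(tend), length(L))
  tstart <- rep_len(tstart, n); tend <- rep_len(tend, n)
  L <- rep_len(L, n)
  bad <- !is.na(tstart) & !is.na(tend) &
    (tstart < 1L | tstart > tend | tend > L)
  if (any(bad)) stop("invalid transcript span: need 1 <= tstart <= tend <= L")
  five <- tstart <= w$max_start5 & tend >= w$loop_lo & tend <= w$loop_hi
  three <- tstart >= w$loop_lo & tstart <= w$loop_hi &
    tend >= L - w$end3_margin + 1L
  out <- ifelse(five, "FIVE_PRIME", ifelse(three, "THREE_PRIME", "OTHER"))
  out[is.na(tstart) | is.na(tend)] <- NA_character_
  out
}

#' Qualify and classify all reads into fragment calls
#'
#' Runs the qualification cascade ([qualify_reads()]) and, for qualified
#' reads, classifies the mature-transcript span into 5' half / 3' half /
#' other and attaches the identity group and family of the assigned gene.
#'
#' @param alns Alignment-record data frame.
#' @param ann An [annotation_set()].
#' @param w A [half_windows()].
#' @return A data frame of fragment calls (qualified reads only) with
#'   columns `read_id`, `gene_id`, `identity_group`, `family`, `half`,
#'   `tail`, `tstart`, `tend`, `trimmed_length`.  Attributes:
#'   `n_mapped_primary` (number of primary records in `alns`) and
#'   `qualification` (the full per-record qualification table).
#' @export
fragment_calls <- function(alns, ann, w = half_windows()) {
  qual <- qualify_reads(alns, ann)
  ok <- qual[qual$passed, , drop = FALSE]
  L <- ann$gene_table$mature_length[match(ok$gene_id,
                                          ann$gene_table$gene_id)]
  calls <- data.frame(
    read_id = ok$read_id,
    gene_id = ok$gene_id,
    identity_group = unname(ann$group_of[ok$gene_id]),
    family = ann$gene_table$family[match(ok$gene_id,
                                         ann$gene_table$gene_id)],
    half = if (nrow(ok)) classify_half(ok$tstart, ok$tend, L, w)
           else character(0L),
    tail = ok$tail,
    tstart = ok$tstart,
    tend = ok$tend,
    trimmed_length = ok$trimmed_length,
    row.names = NULL)
  attr(calls, "n_mapped_primary") <- sum(alns$is_primary)
  attr(calls, "qualification") <- qual
  calls
}

#' Tail-status table over tailed reads
#'
#' Counts and fractions over the tail statuses `NONE`, `C`, `CC`, `CCA`
#' among reads whose alignments reached the annotated tRNA end.  Reads
#' with `NOT_TAILED` or `OTHER` tails are excluded from the denominator.
#'
#' @param calls A fragment-call data frame ([fragment_calls()]) or any
#'   data frame with a `tail` column.
#' @return Data frame with columns `tail`, `count`, `fraction`; fractions
#'   are `NA` (undefined) when there are no tailed reads.
#' @export
tail_status_table <- function(calls) {
  tl <- calls$tail[calls$tail %in% TAIL_STATUSES]
  counts <- table(factor(tl, levels = TAIL_STATUSES))
  denom <- sum(counts)
  data.frame(tail = TAIL_STATUSES,
             count = as.integer(counts),
             fraction = if (denom > 0L) as.numeric(counts) / denom
                        else rep(NA_real_, length(TAIL_STATUSES)),
             row.names = NULL)
}
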