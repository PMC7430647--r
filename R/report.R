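## Dataset-level summaries: half fraction of mapped primaries, 5'/3'
## split, tail-status table, per-family abundance table, 5'/3' imbalance
## of identity groups, and length histograms.

#' Run configuration for reporting
#'
#' @param windows A [half_windows()].
#' @param adapter 3' adapter sequence.
#' @param min_match Minimum adapter prefix match ([detect_adapter()]).
#' @param imbalance_threshold Max/min half-count ratio below which an
#'   identity group is called balanced (default 10, i.e. "less than 10:1").
#' @param min_group_halves Minimum total halves for a group to enter the
#'   imbalance denominator.
#' @param seed Optional integer recorded in output metadata.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(windows = half_windows(),
                       adapter = "TGGAATTCTC", min_match = 6L,
                       imbalance_threshold = 10, min_group_halves = 10L,
                       seed = NULL) {
  stopifnot(imbalance_threshold > 1, min_group_halves >= 1L)
  structure(list(windows = windows, adapter = adapter,
                 min_match = as.integer(min_match),
                 imbalance_threshold = imbalance_threshold,
                 min_group_halves = as.integer(min_group_halves),
                 seed = seed),
            class = "RunConfig")
}

## Per-identity-group 5'/3' half counts from a fragment-call table.
group_half_counts <- function(calls) {
  halves <- calls[calls$half %in% c("FIVE_PRIME", "THREE_PRIME"), ,
                  drop = FALSE]
  if (!nrow(halves))
    return(data.frame(group = character(0L), c5 = integer(0L),
                      c3 = integer(0L)))
  tab <- table(halves$identity_group, halves$half)
  groups <- rownames(tab)
  c5 <- if ("FIVE_PRIME" %in% colnames(tab)) tab[, "FIVE_PRIME"] else 0L
  c3 <- if ("THREE_PRIME" %in% colnames(tab)) tab[, "THREE_PRIME"] else 0L
  data.frame(group = groups, c5 = as.integer(c5), c3 = as.integer(c3),
             row.names = NULL)
}

#' 5'/3' imbalance statistics over identity groups
#'
#' For each identity group with counts `(c5, c3)` the imbalance ratio is
#' `max(c5, c3) / min(c5, c3)` (infinite when one half is absent).  The
#' headline statistic is the percentage of groups whose ratio is below the
#' threshold (default 10:1); groups with fewer than `min_total` halves are
#' excluded from the denominator.
#'
#' @param group_counts Data frame with columns `group`, `c5`, `c3`
#'   (see `group_half_counts`), or a fragment-call data frame.
#' @param threshold Ratio threshold (> 1).
#' @param min_total Minimum `c5 + c3` for inclusion.
#' @return A list with `table` (per-group ratios, eligibility, balance
#'   flag) and `pct_below` (percentage of eligible groups with ratio below
#'   `threshold`; `NA` when no group is eligible).
#' @export
imbalance_stats <- function(group_counts, threshold = 10, min_total = 10L) {
  stopifnot(threshold > 1)
  if (!is.null(group_counts$half)) group_counts <- group_half_counts(group_counts)
  gc <- group_counts
  ratio <- ifelse(pmin(gc$c5, gc$c3) == 0L, Inf,
                  pmax(gc$c5, gc$c3) / pmin(gc$c5, gc$c3))
  eligible <- (gc$c5 + gc$c3) >= min_total
  below <- ratio < threshold
  tab <- data.frame(group = gc$group, c5 = gc$c5, c3 = gc$c3,
                    ratio = ratio, eligible = eligible, below = below,
                    row.names = NULL)
  pct <- if (any(eligible)) 100 * mean(below[eligible]) else NA_real_
  list(table = tab, pct_below = pct)
}

## Per-(family, half type) percentage of all halves for one call set.
family_half_pcts <- function(calls) {
  halves <- calls[calls$half %in% c("FIVE_PRIME", "THREE_PRIME"), ,
                  drop = FALSE]
  if (!nrow(halves))
    return(data.frame(family = character(0L), half = character(0L),
                      pct = numeric(0L)))
  tab <- as.data.frame(table(family = halves$family, half = halves$half),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  data.frame(family = tab$family, half = tab$half,
             count = as.integer(tab$Freq),
             pct = 100 * tab$Freq / nrow(halves), row.names = NULL)
}

#' Table of most abundant tRNA halves
#'
#' Aggregates fragment calls by isoacceptor family and half type, reports
#' the percentage of all tRNA halves per row, and (for multiple
#' replicates) the across-replicate mean and SD.  Rows are sorted by mean
#' percentage descending, ties broken lexicographically.
#'
#' @param calls A fragment-call data frame, or a list of them (one per
#'   replicate).
#' @param k Number of rows to return.
#' @return Data frame with `fragment` (e.g. `"tRNA-Gly-GCC 5' half"`),
#'   `family`, `half`, `mean_pct`, `sd_pct` (`NA` for a single replicate).
#' @export
top_table <- function(calls, k = 10L) {
  stopifnot(k >= 1L)
  if (is.data.frame(calls)) calls <- list(calls)
  per <- lapply(calls, family_half_pcts)
  keys <- unique(do.call(rbind, lapply(per, function(p)
    p[c("family", "half")])))
  if (is.null(keys) || !nrow(keys))
    return(data.frame(fragment = character(0L), family = character(0L),
                      half = character(0L), mean_pct = numeric(0L),
                      sd_pct = numeric(0L)))
  mat <- sapply(per, function(p) {
    v <- p$pct[match(paste(keys$family, keys$half),
                     paste(p$family, p$half))]
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = nrow(keys))
  mean_pct <- rowMeans(mat)
  sd_pct <- if (ncol(mat) > 1L) apply(mat, 1L, sd) else rep(NA_real_,
                                                            nrow(keys))
  lab <- sprintf("tRNA-%s %s half", keys$family,
                 ifelse(keys$half == "FIVE_PRIME", "5'", "3'"))
  out <- data.frame(fragment = lab, family = keys$family, half = keys$half,
                    mean_pct = mean_pct, sd_pct = sd_pct, row.names = NULL)
  out <- out[order(-out$mean_pct, out$fragment), ]
  rownames(out) <- NULL
  head(out, k)
}

summarize_one <- function(calls, n_mapped_primary, cfg) {
  halves <- calls[calls$half %in% c("FIVE_PRIME", "THREE_PRIME"), ,
                  drop = FALSE]
  n_half <- nrow(halves)
  n5 <- sum(halves$half == "FIVE_PRIME")
  split5 <- if (n_half > 0L) n5 / n_half else NA_real_
  gt <- family_half_pcts(calls)
  gt <- gt[order(-gt$pct, gt$family, gt$half), ]
  rownames(gt) <- NULL
  lh <- list()
  for (cl in c("FIVE_PRIME", "THREE_PRIME")) {
    sub <- halves[halves$half == cl, , drop = FALSE]
    lh[[cl]] <- as.data.frame(table(length = sub$trimmed_length),
                              stringsAsFactors = FALSE)
  }
  all_tab <- as.data.frame(table(length = calls$trimmed_length),
                           stringsAsFactors = FALSE)
  length_hist <- do.call(rbind, c(
    list(if (nrow(all_tab)) data.frame(class = "ALL",
                                       length = as.integer(all_tab$length),
                                       count = as.integer(all_tab$Freq))
         else NULL),
    lapply(names(lh), function(cl)
      if (nrow(lh[[cl]])) data.frame(class = cl,
                                     length = as.integer(lh[[cl]]$length),
                                     count = as.integer(lh[[cl]]$Freq))
      else NULL)))
  imb <- imbalance_stats(group_half_counts(calls),
                         threshold = cfg$imbalance_threshold,
                         min_total = cfg$min_group_halves)
  structure(list(
    n_mapped_primary = n_mapped_primary,
    n_qualified = nrow(calls),
    n_halves = n_half,
    half_fraction = if (n_mapped_primary > 0L) n_half / n_mapped_primary
                    else NA_real_,
    split5 = split5,
    split3 = if (n_half > 0L) 1 - split5 else NA_real_,
    tail_table = tail_status_table(calls),
    group_table = gt,
    imbalance = imb,
    length_hist = length_hist,
    config = cfg), class = "SummaryReport")
}

#' Summarize fragment calls into a dataset report
#'
#' Single-replicate mode (a fragment-call data frame) returns a
#' `SummaryReport`; replicate mode (a list of call data frames) returns a
#' `SummaryReportSet` with per-replicate reports plus mean and SD of each
#' headline metric.
#'
#' @param calls A fragment-call data frame, or a list of them.
#' @param n_mapped_primary Number of primary alignments in the dataset
#'   (the denominator of the half fraction); a vector in replicate mode.
#'   Defaults to the `n_mapped_primary` attribute set by
#'   [fragment_calls()].
#' @param cfg A [run_config()].
#' @return A `SummaryReport` or `SummaryReportSet`.
#' @export
summarize_fragments <- function(calls,
                                n_mapped_primary = NULL,
                                cfg = run_config()) {
  if (is.data.frame(calls)) {
    if (is.null(n_mapped_primary))
      n_mapped_primary <- attr(calls, "n_mapped_primary")
    if (is.null(n_mapped_primary))
      stop("n_mapped_primary required")
    if (n_mapped_primary < nrow(calls))
      stop("n_mapped_primary smaller than the number of qualified reads")
    return(summarize_one(calls, n_mapped_primary, cfg))
  }
  if (is.null(n_mapped_primary))
    n_mapped_primary <- vapply(calls, function(x) {
      v <- attr(x, "n_mapped_primary")
      if (is.null(v)) stop("n_mapped_primary required") else as.integer(v)
    }, integer(1L))
  reps <- Map(summarize_one, calls, as.list(n_mapped_primary),
              MoreArgs = list(cfg = cfg))
  metric <- function(name) vapply(reps, `[[`, numeric(1L), name)
  agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) sd(x)
                                           else NA_real_)
  tailfrac <- sapply(reps, function(r) setNames(r$tail_table$fraction,
                                                r$tail_table$tail))
  tailfrac <- matrix(tailfrac, nrow = 4L,
                     dimnames = list(TAIL_STATUSES, NULL))
  structure(list(
    replicates = reps,
    half_fraction = agg(metric("half_fraction")),
    split5 = agg(metric("split5")),
    split3 = agg(metric("split3")),
    tail_fractions = data.frame(
      tail = TAIL_STATUSES,
      mean = rowMeans(tailfrac),
      sd = if (ncol(tailfrac) > 1L) apply(tailfrac, 1L, sd)
           else rep(NA_real_, 4L)),
    top_table = top_table(calls, k = 10L),
    config = cfg), class = "SummaryReportSet")
}

#' @export
print.SummaryReport <- function(x, ...) {
  cat(sprintf("SummaryReport: %d mapped primaries, %d qualified, %d halves\n",
              x$n_mapped_primary, x$n_qualified, x$n_halves))
  cat(sprintf("  half fraction: %.4f  (5' %.1f%% / 3' %.1f%%)\n",
              x$half_fraction, 100 * x$split5, 100 * x$split3))
  tl <- x$tail_table
  cat("  tail status:",
      paste(sprintf("%s %.1f%%", tl$tail, 100 * tl$fraction),
            collapse = "  "), "\n")
  if (!is.na(x$imbalance$pct_below))
    cat(sprintf("  groups < %g:1 imbalance: %.1f%%\n",
                x$config$imbalance_threshold, x$imbalance$pct_below))
  invisible(x)
}

#' Write a machine-readable summary
#'
#' Writes the headline metrics of a `SummaryReport` as JSON and the group
#' table, tail table and length histograms as TSV files.
#'
#' @param report A `SummaryReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "SummaryReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(n_mapped_primary = report$n_mapped_primary,
             n_qualified = report$n_qualified,
             n_halves = report$n_halves,
             half_fraction = report$half_fraction,
             split5 = report$split5, split3 = report$split3,
             imbalance_pct_below = report$imbalance$pct_below,
             imbalance_threshold = report$config$imbalance_threshold,
             min_group_halves = report$config$min_group_halves)
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(report$group_table, file.path(dir, "group_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$tail_table, file.path(dir, "tail_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$length_hist, file.path(dir, "length_hist.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
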