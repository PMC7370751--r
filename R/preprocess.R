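#' Library-size normalization and log2 transformation of count matrices
#'
#' Scales raw counts by total mapped library size, rescales to a common depth
#' (the mean library size, so values stay on the raw-count scale), adds a
#' pseudocount and log2-transforms:
#' \deqn{v_{gs} = \log_2(c_{gs} / N_s \cdot \bar N + p)}
#' where \eqn{c_{gs}} is the count of gene g in sample s, \eqn{N_s} the
#' library size, \eqn{\bar N} the mean library size and p the pseudocount.
#'
#' @param raw_counts non-negative gene x time-point count matrix.
#' @param times time points (hours) for the columns; defaults to numeric
#'   column names.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @param pseudocount count offset (default 8).
#'
#' @return An [expr_matrix()] of log2 values.
#' @export
normalize_log_transform <- function(raw_counts, times = NULL,
                                    library_sizes = NULL, pseudocount = 8) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  if (is.null(times)) times <- as.numeric(colnames(raw_counts))
  if (is.null(library_sizes)) library_sizes <- colSums(raw_counts)
  if (length(library_sizes) != ncol(raw_counts))
    stop("one library size per sample is required")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive and finite")
  scale <- mean(library_sizes)
  scaled <- sweep(raw_counts, 2, library_sizes / scale, "/")
  expr_matrix(log2(scaled + pseudocount), times, pseudocount, scale)
}

#' Exclude lowly expressed genes
#'
#' A gene is excluded when its gene-width-adjusted maximum expression,
#' `max_t value - (log2(width) - mean(log2(width)))`, does not exceed the
#' threshold (default 6, with the boundary itself excluded).
#'
#' @param mat an [expr_matrix()].
#' @param gene_lengths named vector of gene widths in bp, covering all genes
#'   in `mat`.
#' @param threshold exclusion cut-off on adjusted log2 expression (default 6).
#'
#' @return Logical mask (TRUE = retained) in the gene order of `mat`.
#' @export
filter_low_expressed <- function(mat, gene_lengths, threshold = 6) {
  genes <- rownames(mat)
  missing <- setdiff(genes, names(gene_lengths))
  if (length(missing))
    stop("missing gene length for: ", paste(missing, collapse = ", "))
  w <- gene_lengths[genes]
  if (any(w <= 0)) stop("gene lengths must be positive")
  offs <- log2(w) - mean(log2(w))
  adj <- apply(unclass(mat), 1, max) - offs
  mask <- adj > threshold
  names(mask) <- genes
  mask
}

#' Fuse two overlapping expression time courses at a seam
#'
#' Combines the columns of the early course up to and including
#' `switch_time` with the later columns of the late course, restricted to
#' the gene intersection. The sampling grid must be continuous across the
#' seam.
#'
#' @param early,late [expr_matrix()] objects with overlapping gene sets.
#' @param switch_time seam (h); the column exactly at `switch_time` comes
#'   from the early course (default 13).
#'
#' @return A list with the fused `expr_matrix` (`fused`), the genes kept
#'   (`genes`) and the Pearson correlation of matched shared-time columns
#'   between the courses (`seam_correlation`).
#' @export
fuse_time_courses <- function(early, late, switch_time = 13) {
  genes <- intersect(rownames(early), rownames(late))
  if (length(genes) == 0) stop("no genes shared between the two courses")
  te <- em_times(early); tl <- em_times(late)
  if (!any(te <= switch_time))
    stop("early course has no time points at or before `switch_time`")
  if (max(te) < switch_time)
    stop("`switch_time` is beyond the early course's last sample")
  if (!any(tl > switch_time))
    stop("late course has no time points after `switch_time`")
  keep_e <- te <= switch_time
  keep_l <- tl > switch_time
  t_fused <- c(te[keep_e], tl[keep_l])
  step <- stats::median(diff(sort(unique(c(te, tl)))))
  if (min(tl[keep_l]) - max(te[keep_e]) > 1.5 * step)
    stop("time gap at the fusion seam")
  vals <- cbind(unclass(early)[genes, keep_e, drop = FALSE],
                unclass(late)[genes, keep_l, drop = FALSE])
  shared <- intersect(te, tl)
  seam_cor <- if (length(shared) >= 1) {
    stats::cor(as.vector(unclass(early)[genes, as.character(shared)]),
               as.vector(unclass(late)[genes, as.character(shared)]))
  } else NA_real_
  list(fused = expr_matrix(vals, t_fused, attr(early, "pseudocount"),
                           attr(early, "scale")),
       genes = genes, seam_correlation = seam_cor)
}

#' Exclude genes whose mean expression deviates between L2 and L4
#'
#' Computes, per gene, the normalized absolute difference between mean
#' expression in the C2 (L2) and C4 (L4) cycle windows,
#' `abs((m2 - m4) / (0.5 * (m2 + m4)))`, and excludes genes whose statistic
#' exceeds the threshold (default 0.25).
#'
#' @param mat an [expr_matrix()].
#' @param meta a [timecourse_meta()] whose C2 and C4 windows lie inside the
#'   time range of `mat`.
#' @param threshold exclusion cut-off (default 0.25).
#'
#' @return Logical mask (TRUE = retained) with the deviation statistic as
#'   attribute `"statistic"`.
#' @export
exclude_l4_deviating <- function(mat, meta = timecourse_meta(),
                                 threshold = 0.25) {
  win <- cycle_windows(meta)
  tms <- em_times(mat)
  for (w in win[c("C2", "C4")])
    if (w[1] < min(tms) || w[2] > max(tms))
      stop("cycle window outside the matrix time range")
  m2 <- rowMeans(em_window(mat, win$C2[1], win$C2[2]))
  m4 <- rowMeans(em_window(mat, win$C4[1], win$C4[2]))
  stat <- abs((m2 - m4) / (0.5 * (m2 + m4)))
  mask <- stat <= threshold
  attr(mask, "statistic") <- stat
  mask
}

#' Read a tab-separated count or expression matrix
#'
#' First column gene identifiers, remaining column names the time points in
#' hours.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and time-point column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
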