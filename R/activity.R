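# Single-cell immediate-early-gene (IEG) activity scoring and per-cell
# terminal-exon PSI. Cells are scored by a five-gene IEG panel anchored on
# Fos, binned into activity groups, and splicing is compared across bins.

#' Default IEG panel
#'
#' Fos is the anchor gene; Ier2, Egr1, Junb and Dusp1 are the co-regulated
#' immediate-early genes combined into the activity score.
#' @export
ieg_panel <- function() c("Fos", "Ier2", "Egr1", "Junb", "Dusp1")

# log1p of depth-normalized expression (counts per `scale` per cell)
.log_normalize <- function(mat, scale = 1e4) {
  depth <- colSums(mat)
  depth[depth == 0] <- 1
  log1p(sweep(mat, 2L, depth / scale, "/"))
}

#' Rank genes by correlation to the anchor IEG
#'
#' Pearson correlation of each gene's log-normalized expression with the
#' anchor gene's, across cells, sorted in descending order. Genes with zero
#' variance are excluded and flagged; a constant anchor is an error.
#'
#' @param mat genes x cells count matrix with rownames.
#' @param anchor anchor gene (default \code{"Fos"}).
#' @return data.frame \code{gene}, \code{correlation}, \code{rank} plus an
#'   \code{excluded} attribute listing zero-variance genes.
#' @export
rank_ieg_candidates <- function(mat, anchor = "Fos") {
  stopifnot(anchor %in% rownames(mat))
  # constancy is judged on raw counts: a flat gene stays excluded even when
  # varying per-cell depth makes its normalized values wiggle
  v_raw <- apply(mat, 1L, stats::var)
  if (v_raw[anchor] == 0) stop("anchor gene '", anchor, "' is constant")
  ln <- .log_normalize(mat)
  v <- apply(ln, 1L, stats::var)
  ok <- v > 0 & v_raw > 0
  cc <- as.numeric(stats::cor(t(ln[ok, , drop = FALSE]), ln[anchor, ]))
  out <- data.frame(gene = rownames(ln)[ok], correlation = cc)
  out <- out[order(-out$correlation), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(ln)[!ok]
  out
}

#' Per-cell IEG activity score
#'
#' The score combines the panel genes as the mean of per-gene z-scores
#' (across cells) of log1p depth-normalized expression; a panel gene with
#' zero variance contributes 0. The score is invariant to jointly scaling a
#' cell's counts and its depth (depth-normalization property).
#'
#' @param mat genes x cells count matrix with rownames.
#' @param panel character vector of panel genes (default \code{ieg_panel()}).
#' @return numeric score per cell (named by column names of \code{mat}).
#' @export
ieg_score <- function(mat, panel = ieg_panel()) {
  missing <- setdiff(panel, rownames(mat))
  if (length(missing) > 0L)
    stop("panel genes absent: ", paste(missing, collapse = ", "))
  ln <- .log_normalize(mat)[panel, , drop = FALSE]
  z <- t(apply(ln, 1L, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  out <- colMeans(z)
  names(out) <- colnames(mat)
  out
}

#' Bin cells by activity score
#'
#' Cells at or below the \code{low_q} score quantile are IEG-low, at or above
#' the \code{high_q} quantile IEG-high, the rest IEG-medium. Quantiles use
#' linear interpolation (type 7). The default cut points (0.40, 0.92) mirror
#' the low/medium/high proportions of the reference single-cell analysis and
#' are configurable. If all scores are equal every cell is IEG-medium, with a
#' warning.
#'
#' @param scores numeric per-cell scores.
#' @param low_q,high_q quantile cut points, 0 <= low_q < high_q <= 1.
#' @return factor with levels \code{IEG-low}, \code{IEG-medium},
#'   \code{IEG-high}.
#' @export
bin_by_score <- function(scores, low_q = 0.40, high_q = 0.92) {
  if (!(low_q >= 0 && low_q < high_q && high_q <= 1))
    stop("need 0 <= low_q < high_q <= 1")
  lv <- c("IEG-low", "IEG-medium", "IEG-high")
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; assigning every cell to IEG-medium")
    return(factor(rep("IEG-medium", length(scores)), levels = lv))
  }
  q <- quantile(scores, c(low_q, high_q), type = 7, names = FALSE)
  bin <- ifelse(scores <= q[1L], "IEG-low",
                ifelse(scores >= q[2L], "IEG-high", "IEG-medium"))
  factor(bin, levels = lv)
}

#' Per-cell terminal-exon PSI
#'
#' A cell is eligible when it has at least one read for either terminal exon;
#' eligible cells get the length-normalized terminal PSI of their own counts
#' (bulk terminal rule applied per cell), ineligible cells get missing PSI.
#'
#' @param e31_counts,e32_counts integer read counts per cell.
#' @param e31_len,e32_len exon lengths in bases.
#' @return data.frame \code{eligible}, \code{psi_e31}, \code{psi_e32}.
#' @export
per_cell_psi <- function(e31_counts, e32_counts, e31_len, e32_len) {
  stopifnot(length(e31_counts) == length(e32_counts),
            e31_len > 0, e32_len > 0)
  eligible <- (e31_counts + e32_counts) >= 1L
  d31 <- e31_counts / e31_len
  d32 <- e32_counts / e32_len
  psi31 <- ifelse(eligible, 100 * d31 / (d31 + d32), NA_real_)
  data.frame(eligible = eligible, psi_e31 = psi31, psi_e32 = 100 - psi31)
}

#' Full per-cell activity/splicing table
#'
#' Convenience composition: IEG score, activity bin and per-cell PSI.
#'
#' @param mat genes x cells count matrix.
#' @param e31_counts,e32_counts per-cell terminal-exon read counts.
#' @param e31_len,e32_len terminal exon lengths in bases.
#' @inheritParams bin_by_score
#' @param panel IEG panel genes.
#' @return data.frame, one row per cell: \code{cell}, \code{ieg_score},
#'   \code{bin}, \code{eligible}, \code{psi_e31}, \code{psi_e32}.
#' @export
cell_activity_table <- function(mat, e31_counts, e32_counts,
                                e31_len, e32_len,
                                panel = ieg_panel(),
                                low_q = 0.40, high_q = 0.92) {
  score <- ieg_score(mat, panel)
  bin <- bin_by_score(score, low_q, high_q)
  psi <- per_cell_psi(e31_counts, e32_counts, e31_len, e32_len)
  cells <- colnames(mat)
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(mat)))
  cbind(data.frame(cell = cells, ieg_score = unname(score), bin = bin), psi)
}

# exact two-sided rank-sum p by enumeration of all group assignments,
# using midranks so ties are handled (p = 1 for identical groups)
.ranksum_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); N <- length(r)
  w_obs <- sum(r[seq_len(n1)])
  e <- n1 * (N + 1) / 2
  sets <- combn(N, n1)
  w_all <- colSums(matrix(r[sets], nrow = n1))
  mean(abs(w_all - e) >= abs(w_obs - e) - 1e-9)
}

#' Compare PSI between activity groups
#'
#' Two-sided Wilcoxon rank-sum test between two groups of per-cell PSI
#' values: exact enumeration of all rank assignments (midranks for ties) when
#' the combined n is at most 10, otherwise the tie-corrected normal
#' approximation with continuity correction. Also returns each group's
#' empirical cumulative distribution evaluated on the pooled values.
#'
#' @param x,y numeric PSI values of the two groups (no NAs).
#' @param labels character(2) group labels.
#' @return list with \code{labels}, \code{statistic} (rank sum of the first
#'   group), \code{p.value}, and \code{ecdf} (data.frame of pooled values
#'   with each group's ECDF).
#' @export
compare_groups <- function(x, y, labels = c("group1", "group2")) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  stopifnot(!anyNA(x), !anyNA(y))
  r <- rank(c(x, y))
  w <- sum(r[seq_along(x)])
  p <- if (length(x) + length(y) <= 10L) .ranksum_exact(x, y)
  else wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  pooled <- sort(unique(c(x, y)))
  ec <- data.frame(value = pooled,
                   ecdf1 = stats::ecdf(x)(pooled),
                   ecdf2 = stats::ecdf(y)(pooled))
  names(ec)[2:3] <- labels
  list(labels = labels, statistic = w, p.value = min(p, 1), ecdf = ec)
}

#' @importFrom stats wilcox.test
NULL

#' Read a gene x cell matrix in MatrixMarket format
#'
#' @param mtx path to the MTX file.
#' @param genes,cells paths to one-column TSVs of row and column names.
#' @return dense integer matrix with dimnames.
#' @export
read_cell_matrix <- function(mtx, genes, cells) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- read.delim(genes, header = FALSE)[[1L]]
  colnames(m) <- read.delim(cells, header = FALSE)[[1L]]
  storage.mode(m) <- "integer"
  m
}
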