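#' Quantify annotated loci per sample
#'
#' Sums track signal over each annotated locus and aggregates loci sharing a
#' `group_id` by addition, so that an annotation lifted onto every copy of a
#' tandem array contributes the total over all copies — signal at a repeated
#' gene is amplified by its copy number, and summing is what makes that
#' amplification visible in the quantification.
#'
#' @param tracks Named list of `coverage_track`s, one per sample (normally
#'   fraction-normalized).
#' @param annotations data.frame with columns `locus_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `group_id` (defaults to
#'   `locus_id`); see [read_annotations()].
#' @return A sample x group numeric matrix of class `locus_signal`
#'   (rownames = sample ids, colnames = group ids).
#' @export
quantify_loci <- function(tracks, annotations) {
  stopifnot(is.list(tracks), length(tracks) > 0, is.data.frame(annotations))
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("'tracks' must be a named list (sample ids)")
  if (is.null(annotations$group_id))
    annotations$group_id <- annotations$locus_id
  groups <- unique(annotations$group_id)

  missing <- lapply(tracks, function(tr)
    setdiff(unique(annotations$chrom), names(tr$values)))
  bad <- unique(unlist(missing))
  if (length(bad))
    stop(sprintf("annotation chromosome(s) absent from track(s): %s",
                 paste(bad, collapse = ", ")))

  sig <- matrix(0, nrow = length(tracks), ncol = length(groups),
                dimnames = list(names(tracks), groups))
  for (s in names(tracks)) {
    per_locus <- vapply(seq_len(nrow(annotations)), function(i)
      region_sum(tracks[[s]], annotations$chrom[i], annotations$start[i],
                 annotations$end[i]),
      numeric(1))
    sig[s, ] <- rowsum(per_locus, annotations$group_id)[groups, 1]
  }
  structure(sig, class = c("locus_signal", "matrix", "array"))
}

#' Rank loci by signal within each sample
#'
#' Assigns descending ranks per sample (rank 1 = highest signal, ties
#' averaged) and averages the ranks across samples, the standard way of
#' asking which loci are consistently the most occupied across a patient
#' cohort. Ranks are invariant to per-sample scaling, so raw and
#' fraction-normalized signal rank identically.
#'
#' @param table A `locus_signal` matrix from [quantify_loci()] (or any
#'   sample x feature numeric matrix).
#' @return An object of class `rank_table`: list with `ranks` (sample x
#'   group matrix) and `mean_rank` (named vector, sorted ascending).
#' @export
rank_loci <- function(table) {
  table <- as.matrix(table)
  if (!nrow(table) || !ncol(table)) stop("signal table is empty")
  ranks <- t(apply(table, 1, function(x) rank(-x, ties.method = "average")))
  if (ncol(table) == 1L) ranks <- matrix(1, nrow(table), 1,
                                         dimnames = dimnames(table))
  mean_rank <- sort(colMeans(ranks))
  structure(list(ranks = ranks, mean_rank = mean_rank),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, n = 10, ...) {
  cat(sprintf("<rank_table> %d sample(s) x %d group(s); top by mean rank:\n",
              nrow(x$ranks), ncol(x$ranks)))
  top <- utils::head(x$mean_rank, n)
  for (g in names(top))
    cat(sprintf("  %-20s %.2f\n", g, top[[g]]))
  invisible(x)
}

#' Modified Bland-Altman (MA) points for a matched sample pair
#'
#' For each feature with signal `T` in the tumor (or treated) sample and `N`
#' in the matched normal (control), computes the mean abundance
#' \eqn{A = \log_{10}((T + N)/2 + \epsilon)} and the difference
#' \eqn{M = \log_{10}(T + \epsilon) - \log_{10}(N + \epsilon)}. The
#' pseudocount \eqn{\epsilon > 0} keeps both coordinates finite for features
#' absent from one or both samples. Features superabundant in both samples
#' sit far right at M near 0; differential features move vertically.
#'
#' @param tumor,normal Named numeric vectors of per-feature signal (e.g. two
#'   rows of a `locus_signal` matrix) over the same features.
#' @param epsilon Pseudocount, default 0.5.
#' @return data.frame with columns `feature_id`, `A`, `M`.
#' @export
ma_points <- function(tumor, normal, epsilon = 0.5) {
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (is.null(names(tumor)) || is.null(names(normal)))
    stop("'tumor' and 'normal' must be named by feature")
  if (!identical(sort(names(tumor)), sort(names(normal))))
    stop("tumor and normal feature sets differ")
  normal <- normal[names(tumor)]
  data.frame(feature_id = names(tumor),
             A = log10((tumor + normal) / 2 + epsilon),
             M = log10(tumor + epsilon) - log10(normal + epsilon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' MA scatter plot for a matched pair
#'
#' @param ma data.frame from [ma_points()].
#' @param highlight Optional character vector of feature ids to emphasize.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `ma`.
#' @export
plot_ma <- function(ma, highlight = NULL, ...) {
  graphics::plot(ma$A, ma$M, pch = 16, cex = 0.5,
                 col = "grey40", xlab = expression(log[10] ~ "mean signal (A)"),
                 ylab = expression(log[10] ~ "fold difference (M)"), ...)
  graphics::abline(h = 0, lty = 2)
  if (!is.null(highlight)) {
    sel <- ma$feature_id %in% highlight
    graphics::points(ma$A[sel], ma$M[sel], pch = 16, col = "red")
    graphics::text(ma$A[sel], ma$M[sel], ma$feature_id[sel], pos = 3,
                   col = "red", cex = 0.8)
  }
  invisible(ma)
}
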