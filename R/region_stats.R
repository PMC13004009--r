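#' Sum normalized signal over named regions, per sample and strand
#'
#' For each sample the signal on each strand is summed over every region
#' (typically an entire mini-chromosome). Tracks should be fraction-
#' normalized with the sample-wide convention ([normalize_strand_pair()]) so
#' that sums are comparable across samples.
#'
#' @param tracks Named list of samples; each sample is either a single
#'   `coverage_track` (unstranded) or a list with elements `fwd` and `rev`.
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), or `NULL` to use whole chromosomes as regions.
#' @return data.frame with columns `sample_id`, `region_id`, `strand`, `S`.
#' @export
summarize_regions <- function(tracks, regions = NULL) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  out <- list()
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    strands <- if (inherits(tr, "coverage_track")) {
      stats::setNames(list(tr), tr$strand)
    } else list("+" = tr$fwd, "-" = tr$rev)
    for (st in names(strands)) {
      track <- strands[[st]]
      reg <- if (is.null(regions)) whole_chrom_regions(track) else regions
      S <- vapply(seq_len(nrow(reg)), function(i)
        region_sum(track, reg$chrom[i], reg$start[i], reg$end[i]),
        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, region_id = reg$region_id,
        strand = if (st %in% c("fwd", "+")) "+" else
          if (st %in% c("rev", "-")) "-" else "both",
        S = S, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

whole_chrom_regions <- function(track) {
  data.frame(region_id = names(track$values), chrom = names(track$values),
             start = 0,
             end = vapply(track$values, length, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Strand-averaged overall ratio of a perturbation
#'
#' The perturbation statistic for treated-vs-control comparisons over whole
#' regions: per-region summed signal is divided strand by strand
#' (`R_s = S_treated,s / S_control,s`) and the two strand fold changes are
#' averaged arithmetically into an overall ratio `R = (R_+ + R_-)/2`.
#' Under fraction normalization R is invariant to each sample's library
#' size, so unperturbed control regions sit near 1 while a knocked-down
#' region drops below it.
#'
#' If the control signal is zero on one strand, that strand's ratio is
#' undefined and R falls back to the defined strand with a warning; zero
#' control on both strands is an error.
#'
#' @param treated,control data.frames from [summarize_regions()], each for
#'   one sample (or pooled replicates), with strands `+` and `-`.
#' @return data.frame of class `overall_ratio` with columns `region_id`,
#'   `R_fwd`, `R_rev`, `R`.
#' @export
overall_ratio <- function(treated, control) {
  regions <- unique(control$region_id)
  if (!setequal(regions, unique(treated$region_id)))
    stop("treated and control cover different regions")
  get_S <- function(df, region, strand) {
    v <- df$S[df$region_id == region & df$strand == strand]
    if (length(v) == 0L) NA_real_ else sum(v)
  }
  res <- data.frame(region_id = regions, R_fwd = NA_real_, R_rev = NA_real_,
                    R = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    rg <- regions[i]
    r <- c(fwd = NA_real_, rev = NA_real_)
    for (st in c("+", "-")) {
      Sc <- get_S(control, rg, st)
      St <- get_S(treated, rg, st)
      key <- if (st == "+") "fwd" else "rev"
      if (is.na(Sc) || is.na(St)) next
      r[[key]] <- if (Sc > 0) St / Sc else NA_real_
    }
    if (all(is.na(r)))
      stop(sprintf("region '%s': control signal is zero on both strands", rg))
    if (any(is.na(r)))
      warning(sprintf(
        "region '%s': control signal zero on one strand; overall ratio uses the defined strand only",
        rg))
    res$R_fwd[i] <- r[["fwd"]]
    res$R_rev[i] <- r[["rev"]]
    res$R[i] <- mean(r, na.rm = TRUE)
  }
  class(res) <- c("overall_ratio", "data.frame")
  res
}

#' @export
print.overall_ratio <- function(x, ...) {
  cat("<overall_ratio> treated / control, strand-averaged\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compositional compartment fractions per sample
#'
#' For each sample, the (both-strand) signal in each compartment divided by
#' the sample's total signal. Fractions are invariant to library size and are
#' the per-sample profile rows that [correlation_matrix()] correlates across
#' a cohort. Note the compositional constraint: fractions of a sample sum to
#' 1 when the compartments tile the reference, so a compartment that swells
#' in some samples (e.g. a repeat array with higher copy number) necessarily
#' depresses all others — anticorrelation between a dominant compartment and
#' the rest is the expected signature of such variation.
#'
#' @param tracks Named list of samples; each a `coverage_track` or a
#'   `fwd`/`rev` list (strands are combined).
#' @param compartments data.frame with `region_id`, `chrom`, `start`, `end`,
#'   or `NULL` for whole chromosomes.
#' @return sample x compartment numeric matrix of fractions.
#' @export
compartment_fractions <- function(tracks, compartments = NULL) {
  tracks <- lapply(tracks, function(tr)
    if (inherits(tr, "coverage_track")) tr else combine_tracks(tr$fwd, tr$rev))
  summ <- summarize_regions(tracks, compartments)
  samples <- unique(summ$sample_id)
  regions <- unique(summ$region_id)
  frac <- matrix(NA_real_, length(samples), length(regions),
                 dimnames = list(samples, regions))
  for (s in samples) {
    tot <- sum(unlist(tracks[[s]]$values, use.names = FALSE))
    if (tot <= 0) stop(sprintf("sample '%s' has zero total signal", s))
    rows <- summ[summ$sample_id == s, , drop = FALSE]
    frac[s, rows$region_id] <- rows$S / tot
  }
  frac
}

#' Pairwise Pearson correlation of compartment profiles across samples
#'
#' Correlates every pair of compartments across the cohort's samples and
#' reports two-sided p-values from the t-statistic
#' \eqn{t = r \sqrt{n - 2} / \sqrt{1 - r^2}} on `n - 2` degrees of freedom
#' (unadjusted, as is conventional for these matrices). A compartment with
#' zero variance across samples yields `NA` correlations with a warning.
#'
#' @param fractions sample x compartment matrix from
#'   [compartment_fractions()] (any sample x feature matrix works).
#' @return Object of class `correlation_matrix`: list with `r` (symmetric,
#'   unit diagonal), `p` (NA on the diagonal; only computed for n >= 3) and
#'   `n` (number of samples).
#' @export
correlation_matrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  n <- nrow(fractions)
  if (n < 2L) stop("at least 2 samples are required for correlations")
  sds <- apply(fractions, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance compartment(s): %s; correlations set to NA",
                    paste(colnames(fractions)[sds == 0], collapse = ", ")))
  r <- suppressWarnings(stats::cor(fractions))
  diag(r) <- 1
  p <- matrix(NA_real_, ncol(r), ncol(r), dimnames = dimnames(r))
  if (n >= 3L) {
    rr <- pmin(pmax(r, -1), 1)
    t_stat <- rr * sqrt(n - 2) / sqrt(pmax(1 - rr^2, .Machine$double.eps))
    p[] <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    p <- pmin(p, 1)
    diag(p) <- NA_real_
  }
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d compartments, n = %d samples\nr:\n",
              ncol(x$r), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' Heatmap of a compartment correlation matrix
#'
#' @param x A `correlation_matrix`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.correlation_matrix <- function(x, ...) {
  k <- ncol(x$r)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(k), seq_len(k), t(x$r[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(x$r), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(x$r)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' Write ratio and correlation reports as TSV
#'
#' @param x An `overall_ratio` or `correlation_matrix`.
#' @param path Output path; for a `correlation_matrix` two files are written
#'   (`<path>.r.tsv` and `<path>.p.tsv`).
#' @return Invisibly, the path(s) written.
#' @export
write_region_stats <- function(x, path) {
  if (inherits(x, "overall_ratio")) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (inherits(x, "correlation_matrix")) {
    pr <- paste0(path, ".r.tsv")
    pp <- paste0(path, ".p.tsv")
    utils::write.table(x$r, pr, sep = "\t", quote = FALSE)
    utils::write.table(x$p, pp, sep = "\t", quote = FALSE)
    return(invisible(c(pr, pp)))
  }
  stop("unsupported object")
}
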