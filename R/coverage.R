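#' Per-base coverage track from mapped fragments
#'
#' Converts fragment records into per-base signal over a reference, in one of
#' three counting modes:
#' \describe{
#'   \item{`span`}{adds 1 to every base a fragment covers (run-on and
#'     chromatin profiling signal);}
#'   \item{`end3`}{adds 1 at the fragment's 3'-terminal base — `end - 1` for
#'     `+` fragments, `start` for `-` fragments — the convention for
#'     NET-seq/PRO-seq active-site profiles;}
#'   \item{`end5`}{adds 1 at the 5'-terminal base (PRO-cap style initiation
#'     profiles).}
#' }
#' Fragments are counted independently; duplicates are not collapsed.
#'
#' @param fragments data.frame of fragment records ([read_fragments()]).
#' @param ref_lengths Named numeric vector of chromosome lengths, or a
#'   `mini_genome`.
#' @param mode Counting mode, one of `"span"`, `"end3"`, `"end5"`.
#' @param strand Strand filter: `"both"`, `"+"` or `"-"` (`"fwd"`/`"rev"`
#'   accepted as aliases).
#' @return An object of class `coverage_track`: list with `values` (named
#'   list of per-base numeric vectors), `strand`, `mode`, `total_count` (sum
#'   of raw counts, C), `genome_length` (L), `normalized` flag.
#' @examples
#' frags <- data.frame(chrom = "chrT", start = 0, end = 5, name = ".",
#'                     score = 0, strand = "+")
#' compute_track(frags, c(chrT = 10), mode = "span")
#' @export
compute_track <- function(fragments, ref_lengths,
                          mode = c("span", "end3", "end5"),
                          strand = c("both", "+", "-", "fwd", "rev")) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  strand <- c(both = "both", "+" = "+", "-" = "-",
              fwd = "+", rev = "-")[[strand]]
  ref_lengths <- as_ref_lengths(ref_lengths)
  validate_fragments(fragments, ref_lengths)
  if (strand != "both")
    fragments <- fragments[fragments$strand == strand, , drop = FALSE]

  values <- lapply(ref_lengths, function(L) numeric(L))
  for (chrom in unique(fragments$chrom)) {
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    L <- ref_lengths[[chrom]]
    if (mode == "span") {
      cov <- IRanges::coverage(IRanges::IRanges(start = fr$start + 1,
                                                end = fr$end),
                               width = L)
      values[[chrom]] <- as.numeric(cov)
    } else {
      # 0-based position of the counted terminal base
      pos <- if (mode == "end3") {
        ifelse(fr$strand == "+", fr$end - 1, fr$start)
      } else {
        ifelse(fr$strand == "+", fr$start, fr$end - 1)
      }
      values[[chrom]] <- tabulate(pos + 1L, nbins = L)
    }
  }
  new_coverage_track(values, strand = strand, mode = mode)
}

new_coverage_track <- function(values, strand, mode, normalized = FALSE,
                               total_count = sum(unlist(values,
                                                        use.names = FALSE))) {
  structure(list(values = values, strand = strand, mode = mode,
                 total_count = total_count,
                 genome_length = sum(vapply(values, length, numeric(1))),
                 normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %d chromosome(s), %s bp; mode=%s strand=%s %s\n",
    length(x$values), format(x$genome_length, big.mark = ","), x$mode,
    x$strand,
    if (x$normalized) "(fraction-normalized)"
    else sprintf("(raw, C=%g)", x$total_count)))
  invisible(x)
}

#' Fraction-normalize a coverage track
#'
#' Rescales raw per-base counts \eqn{c_i} to \eqn{f_i = (c_i / C) \cdot L},
#' the fraction of mapped counts at each base scaled by the reference size,
#' so that uniformly distributed counts give exactly 1 at every base and
#' \eqn{\sum_i f_i = L}. The result is invariant to library size, which is
#' what makes per-region sums comparable across samples.
#'
#' For strand-separated tracks of one sample, pass the sample-wide count so
#' that both strands share one denominator (see [normalize_strand_pair()]);
#' by default `C` is the track's own total, in which case the normalized
#' track has genome-wide mean exactly 1.
#'
#' @param track A raw `coverage_track`.
#' @param total_count The denominator C; defaults to the track's own total.
#' @return A normalized `coverage_track`.
#' @export
fraction_normalize <- function(track, total_count = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) stop("track is already normalized")
  C <- if (is.null(total_count)) track$total_count else total_count
  if (C <= 0) stop("empty track cannot be normalized (C = 0)")
  L <- track$genome_length
  values <- lapply(track$values, function(v) v / C * L)
  new_coverage_track(values, strand = track$strand, mode = track$mode,
                     normalized = TRUE, total_count = track$total_count)
}

#' Normalize the two strand tracks of one sample with a shared denominator
#'
#' Both strands are divided by the sample-wide count `C = C_fwd + C_rev` and
#' scaled by the genome length, so that the *combined* signal has genome-wide
#' mean 1 while the per-strand split is preserved. This is the convention
#' under which per-region strand-ratio statistics are comparable between
#' samples.
#'
#' @param fwd,rev Raw `coverage_track`s for the `+` and `-` strand of one
#'   sample.
#' @return A list with normalized elements `fwd` and `rev`.
#' @export
normalize_strand_pair <- function(fwd, rev) {
  stopifnot(inherits(fwd, "coverage_track"), inherits(rev, "coverage_track"))
  C <- fwd$total_count + rev$total_count
  list(fwd = fraction_normalize(fwd, total_count = C),
       rev = fraction_normalize(rev, total_count = C))
}

#' Sum of track values over an interval
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Numeric sum of per-base values over `[start, end)`.
#' @export
region_sum <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$values[[chrom]]
  if (is.null(v))
    stop(sprintf("chromosome '%s' not in track", chrom))
  if (start < 0 || end > length(v) || end <= start)
    stop(sprintf("interval %s:%d-%d out of bounds (chromosome is %d bp)",
                 chrom, start, end, length(v)))
  sum(v[(start + 1):end])
}

#' Write a coverage track as bedGraph
#'
#' Per-base values are run-length encoded into 4-column bedGraph lines
#' (0-based half-open); zero-valued runs are omitted and restored as zero on
#' read, so the round trip through [read_bedgraph()] is exact on values.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    r <- rle(track$values[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    # %.17g round-trips IEEE doubles exactly
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts[keep], ends[keep],
                       r$values[keep]),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path Path to a 4-column bedGraph.
#' @param ref_lengths Named numeric vector of chromosome lengths (or a
#'   `mini_genome`); required so uncovered bases are restored as zeros.
#' @param strand,mode Metadata to record on the returned track.
#' @param normalized Whether the values are fraction-normalized.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, ref_lengths, strand = "both", mode = "span",
                          normalized = FALSE) {
  ref_lengths <- as_ref_lengths(ref_lengths)
  values <- lapply(ref_lengths, function(L) numeric(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) != 4L) stop("bedGraph must have exactly 4 columns")
    names(tab) <- c("chrom", "start", "end", "value")
    unknown <- setdiff(unique(tab$chrom), names(ref_lengths))
    if (length(unknown))
      stop(sprintf("bedGraph chromosome(s) not in reference: %s",
                   paste(unknown, collapse = ", ")))
    for (chrom in unique(tab$chrom)) {
      runs <- tab[tab$chrom == chrom, , drop = FALSE]
      runs <- runs[order(runs$start), , drop = FALSE]
      if (any(runs$end > ref_lengths[[chrom]]))
        stop(sprintf("bedGraph run past end of %s", chrom))
      if (nrow(runs) > 1L && any(runs$start[-1] < runs$end[-nrow(runs)]))
        stop(sprintf("overlapping bedGraph intervals on %s", chrom))
      for (i in seq_len(nrow(runs)))
        values[[chrom]][(runs$start[i] + 1):runs$end[i]] <- runs$value[i]
    }
  }
  if (normalized) {
    tr <- new_coverage_track(values, strand = strand, mode = mode,
                             normalized = TRUE)
    tr$total_count <- NA_real_
    tr
  } else {
    new_coverage_track(values, strand = strand, mode = mode)
  }
}

#' Add two coverage tracks elementwise
#'
#' Used to combine the two strand tracks of a sample; both tracks must be on
#' the same reference and normalization state.
#'
#' @param a,b `coverage_track`s.
#' @return A `coverage_track` with summed values, strand `"both"`.
#' @export
combine_tracks <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"),
            identical(names(a$values), names(b$values)),
            a$normalized == b$normalized)
  values <- Map(`+`, a$values, b$values)
  new_coverage_track(values, strand = "both", mode = a$mode,
                     normalized = a$normalized,
                     total_count = a$total_count + b$total_count)
}
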