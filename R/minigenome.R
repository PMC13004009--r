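#' Build a composite mini-genome from segment recipes
#'
#' Extracts the recipe segments from the source sequences, concatenates them
#' in order, repeats the concatenation `tandem_copies` times, and records a
#' segment map — one record per (segment, tandem copy) — that tiles every
#' mini-chromosome exactly and supports annotation liftover. Aligning reads to
#' a small composite reference like this is the standard trick for quantifying
#' signal over loci (rDNA arrays, histone clusters, control genes) that are
#' unwieldy or absent in full assemblies.
#'
#' @param source_sequences A [Biostrings::DNAStringSet], a named character
#'   vector of sequences, or the path to a FASTA file.
#' @param recipes A list of [segment_recipe()] objects (e.g. from
#'   [read_recipes()]), or a single recipe.
#' @return An object of class `mini_genome` with elements:
#'   \describe{
#'     \item{sequences}{`DNAStringSet` of mini-chromosomes.}
#'     \item{segment_map}{data.frame with columns `mini_name`, `mini_start`,
#'       `mini_end` (0-based half-open), `src_chrom`, `src_start`, `src_end`
#'       (1-based inclusive), `copy_index` (0-based tandem copy).}
#'   }
#' @examples
#' src <- c(chrT = "ACGTACGTACGTACGTACGT")
#' mini <- build_minigenome(src,
#'   segment_recipe("rep", region_spec("chrT", 1, 10), tandem_copies = 3))
#' mini_lengths(mini)
#' @export
build_minigenome <- function(source_sequences, recipes) {
  src <- as_dna_set(source_sequences)
  if (inherits(recipes, "segment_recipe")) recipes <- list(recipes)
  if (!length(recipes) || !all(vapply(recipes, inherits, TRUE, "segment_recipe")))
    stop("'recipes' must be one or more segment_recipe objects")
  src_len <- stats::setNames(Biostrings::width(src), names(src))

  seqs <- character(0)
  maps <- list()
  for (rec in recipes) {
    unit <- character(length(rec$segments))
    for (i in seq_along(rec$segments)) {
      sp <- rec$segments[[i]]
      if (!sp$chrom %in% names(src))
        stop(sprintf("recipe '%s': source chromosome '%s' not found",
                     rec$name, sp$chrom))
      if (sp$end > src_len[[sp$chrom]])
        stop(sprintf(
          "recipe '%s': segment %s:%s-%s extends past end of source (%d bp)",
          rec$name, sp$chrom, sp$start, sp$end, src_len[[sp$chrom]]))
      unit[i] <- as.character(Biostrings::subseq(src[[sp$chrom]],
                                                 sp$start, sp$end))
    }
    unit_seq <- paste0(unit, collapse = "")
    seqs[rec$name] <- strrep(unit_seq, rec$tandem_copies)

    seg_len <- vapply(rec$segments, region_length, numeric(1))
    unit_len <- sum(seg_len)
    for (copy in seq_len(rec$tandem_copies) - 1L) {
      off <- copy * unit_len + c(0, cumsum(seg_len)[-length(seg_len)])
      for (i in seq_along(rec$segments)) {
        sp <- rec$segments[[i]]
        maps[[length(maps) + 1L]] <- data.frame(
          mini_name = rec$name,
          mini_start = off[i],
          mini_end = off[i] + seg_len[i],
          src_chrom = sp$chrom,
          src_start = sp$start,
          src_end = sp$end,
          copy_index = copy,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- structure(
    list(sequences = Biostrings::DNAStringSet(seqs),
         segment_map = do.call(rbind, maps)),
    class = "mini_genome")
  stopifnot(all(mini_lengths(out) ==
                  vapply(recipes, recipe_length, numeric(1))))
  out
}

#' @export
print.mini_genome <- function(x, ...) {
  len <- mini_lengths(x)
  cat(sprintf("<mini_genome> %d mini-chromosome(s), %s bp total\n",
              length(len), format(sum(len), big.mark = ",")))
  for (nm in names(len)) {
    n_seg <- sum(x$segment_map$mini_name == nm)
    cat(sprintf("  %s: %s bp (%d segment record%s)\n", nm,
                format(len[[nm]], big.mark = ","), n_seg,
                if (n_seg == 1L) "" else "s"))
  }
  invisible(x)
}

#' Mini-chromosome lengths
#'
#' @param mini A `mini_genome`.
#' @return Named numeric vector of lengths in bp.
#' @export
mini_lengths <- function(mini) {
  stopifnot(inherits(mini, "mini_genome"))
  stats::setNames(as.numeric(Biostrings::width(mini$sequences)),
                  names(mini$sequences))
}

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x)))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("source sequences given as a character vector must be named")
    return(Biostrings::DNAStringSet(x))
  }
  stop("cannot interpret 'source_sequences' as sequences or a FASTA path")
}

#' Write a mini-genome to FASTA plus a segment-map table
#'
#' The segment map is written as BED6 plus a seventh `copy_index` column:
#' mini-chromosome coordinates in columns 1-3 (0-based half-open), the source
#' interval printed as `chrom:start-end` (1-based inclusive) in the name
#' column, score 0, strand `+`.
#'
#' @param mini A `mini_genome`.
#' @param out_prefix Output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.segments.bed`.
#' @return Invisibly, the two paths written.
#' @export
write_minigenome <- function(mini, out_prefix) {
  stopifnot(inherits(mini, "mini_genome"))
  fa <- paste0(out_prefix, ".fa")
  bed <- paste0(out_prefix, ".segments.bed")
  Biostrings::writeXStringSet(mini$sequences, fa)
  sm <- mini$segment_map
  lines <- sprintf("%s\t%d\t%d\t%s:%d-%d\t0\t+\t%d",
                   sm$mini_name, sm$mini_start, sm$mini_end,
                   sm$src_chrom, sm$src_start, sm$src_end, sm$copy_index)
  writeLines(lines, bed)
  invisible(c(fasta = fa, segments = bed))
}

#' Read a segment-map table written by [write_minigenome()]
#'
#' @param path Path to a `.segments.bed` file.
#' @return A segment-map data.frame as in [build_minigenome()].
#' @export
read_segment_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 7L)
    stop("segment map must have 7 columns (BED6 + copy_index)")
  src <- regmatches(tab[[4]], regexec("^(.+):([0-9]+)-([0-9]+)$", tab[[4]]))
  if (any(lengths(src) != 4L))
    stop("malformed source interval in segment map name column")
  data.frame(mini_name = tab[[1]], mini_start = tab[[2]], mini_end = tab[[3]],
             src_chrom = vapply(src, `[`, "", 2L),
             src_start = as.numeric(vapply(src, `[`, "", 3L)),
             src_end = as.numeric(vapply(src, `[`, "", 4L)),
             copy_index = tab[[7]], stringsAsFactors = FALSE)
}

#' Lift source-coordinate annotations onto a mini-genome
#'
#' Each feature that is fully contained in a mapped source segment is emitted
#' once per tandem copy of that segment, with the copy recorded in a
#' `copy_index` column, so that an annotation inside a repeat unit (a
#' microRNA, say) lands on every copy of the expanded array. Features that
#' straddle the junction between two concatenated segments are dropped with a
#' warning — junction-spanning intervals are artifacts of concatenation, not
#' biology. Features overlapping no segment at all are silently omitted and
#' counted in the `n_outside` attribute of the result.
#'
#' @param features A data.frame of BED intervals on source coordinates:
#'   columns `chrom`, `start`, `end` (0-based half-open), and optionally
#'   `name`, `score`, `strand`.
#' @param mini A `mini_genome`, or a segment-map data.frame (from
#'   [read_segment_map()] or the `segment_map` element).
#' @return A data.frame of lifted intervals on mini coordinates with the
#'   input's columns plus `copy_index`; attributes `n_outside` and
#'   `n_boundary` count omitted features.
#' @export
lift_annotation <- function(features, mini) {
  sm <- if (inherits(mini, "mini_genome")) mini$segment_map else mini
  stopifnot(is.data.frame(sm), is.data.frame(features))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(features)))
    stop("'features' must have columns chrom, start, end")
  if (any(features$end <= features$start))
    stop("features must satisfy start < end (0-based half-open)")

  out <- list()
  n_outside <- 0L
  boundary <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    f1 <- f$start + 1   # 1-based inclusive start
    same_chrom <- sm[sm$src_chrom == f$chrom, , drop = FALSE]
    contains <- same_chrom$src_start <= f1 & f$end <= same_chrom$src_end
    overlaps <- same_chrom$src_start <= f$end & f1 <= same_chrom$src_end
    if (!any(overlaps)) {
      n_outside <- n_outside + 1L
      next
    }
    if (!any(contains)) {
      boundary <- c(boundary,
                    sprintf("%s:%d-%d", f$chrom, f$start, f$end))
      next
    }
    hit <- same_chrom[contains, , drop = FALSE]
    lifted <- f[rep(1L, nrow(hit)), , drop = FALSE]
    lifted$chrom <- hit$mini_name
    lifted$start <- hit$mini_start + (f$start - (hit$src_start - 1))
    lifted$end <- lifted$start + (f$end - f$start)
    lifted$copy_index <- hit$copy_index
    out[[length(out) + 1L]] <- lifted
  }
  if (length(boundary))
    warning(sprintf("dropped %d feature(s) spanning segment junctions: %s",
                    length(boundary), paste(boundary, collapse = ", ")))
  res <- if (length(out)) do.call(rbind, out) else {
    empty <- features[0, , drop = FALSE]
    empty$copy_index <- integer(0)
    empty
  }
  rownames(res) <- NULL
  attr(res, "n_outside") <- n_outside
  attr(res, "n_boundary") <- length(boundary)
  res
}

#' Map mini-genome intervals back to source coordinates
#'
#' The inverse of [lift_annotation()] for intervals contained in a single
#' segment record: returns the source chromosome interval (0-based half-open)
#' together with the tandem `copy_index` the interval fell in.
#'
#' @param features data.frame with `chrom`, `start`, `end` on mini
#'   coordinates (0-based half-open).
#' @param mini A `mini_genome` or segment-map data.frame.
#' @return data.frame with columns `chrom`, `start`, `end`, `copy_index` on
#'   source coordinates; intervals spanning segment records raise an error.
#' @export
lift_back <- function(features, mini) {
  sm <- if (inherits(mini, "mini_genome")) mini$segment_map else mini
  out <- features
  out$copy_index <- NA_integer_
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    hit <- sm[sm$mini_name == f$chrom & sm$mini_start <= f$start &
                f$end <= sm$mini_end, , drop = FALSE]
    if (nrow(hit) != 1L)
      stop(sprintf("interval %s:%d-%d is not contained in a single segment",
                   f$chrom, f$start, f$end))
    out$chrom[i] <- hit$src_chrom
    out$start[i] <- (hit$src_start - 1) + (f$start - hit$mini_start)
    out$end[i] <- out$start[i] + (f$end - f$start)
    out$copy_index[i] <- hit$copy_index
  }
  out
}
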