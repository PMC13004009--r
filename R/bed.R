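# BED6 dialect used throughout: whitespace-delimited, >= 3 columns,
# 0-based half-open, strand in column 6 (defaulting to "+" with a warning
# when absent). Validation is against explicit reference lengths so that
# coordinate errors surface with line numbers at read time, not as silent
# truncation later.

#' Read mapped fragments from a BED file
#'
#' Reads a whitespace-delimited BED file of mapped fragments (>= 3 columns;
#' name, score and strand optional) and validates every record against the
#' reference chromosome lengths. Records missing a strand column default to
#' `+` with a single warning. This is the entry format for all coverage
#' computation: alignment pipelines end in "bamtobed"-style fragment BEDs,
#' and everything downstream here consumes those.
#'
#' @param path Path to a BED file.
#' @param ref_lengths Named numeric vector of chromosome lengths (or a
#'   `mini_genome`). If `NULL`, coordinate bounds are not checked.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_fragments <- function(path, ref_lengths = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (ncol(tab) < 3L)
    stop("BED file must have at least 3 columns")
  tab[is.na(tab)] <- ""
  for (v in paste0("V", 4:6)) if (is.null(tab[[v]])) tab[[v]] <- ""
  start <- suppressWarnings(as.numeric(tab$V2))
  end <- suppressWarnings(as.numeric(tab$V3))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("non-integer coordinates at line %d of %s", bad[1], path))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("end <= start at line %d of %s", bad[1], path))
  if (any(start < 0))
    stop(sprintf("negative start at line %d of %s", which(start < 0)[1], path))

  strand <- tab$V6
  no_strand <- !nzchar(strand) | is.na(strand)
  if (any(no_strand)) {
    warning(sprintf("%d record(s) without a strand column; defaulting to '+'",
                    sum(no_strand)))
    strand[no_strand] <- "+"
  }
  if (!all(strand %in% c("+", "-")))
    stop(sprintf("invalid strand at line %d of %s",
                 which(!strand %in% c("+", "-"))[1], path))

  frags <- data.frame(chrom = tab$V1, start = start, end = end,
                      name = ifelse(nzchar(tab$V4), tab$V4, "."),
                      score = suppressWarnings(
                        ifelse(nzchar(tab$V5), as.numeric(tab$V5), 0)),
                      strand = strand, stringsAsFactors = FALSE)
  validate_fragments(frags, ref_lengths, path)
  frags
}

validate_fragments <- function(frags, ref_lengths, what = "fragments") {
  if (is.null(ref_lengths)) return(invisible(frags))
  ref_lengths <- as_ref_lengths(ref_lengths)
  unknown <- setdiff(unique(frags$chrom), names(ref_lengths))
  if (length(unknown))
    stop(sprintf("%s: chromosome(s) not in reference: %s", what,
                 paste(unknown, collapse = ", ")))
  over <- which(frags$end > ref_lengths[frags$chrom])
  if (length(over))
    stop(sprintf("%s: line %d extends past end of %s (%d bp)", what, over[1],
                 frags$chrom[over[1]], ref_lengths[[frags$chrom[over[1]]]]))
  invisible(frags)
}

as_ref_lengths <- function(x) {
  if (inherits(x, "mini_genome")) return(mini_lengths(x))
  if (inherits(x, "coverage_track"))
    return(vapply(x$values, length, numeric(1)))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("reference lengths must be a named numeric vector or a mini_genome")
}

#' Write fragments or intervals as BED6
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (missing columns are filled with `.`, 0 and `+`).
#'   An extra `copy_index` column, if present, is written as a 7th column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep("+", nrow(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), name, format(score, trim = TRUE),
                   strand)
  if ("copy_index" %in% names(x))
    lines <- paste0(lines, "\t", x$copy_index)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of locus annotations
#'
#' Like [read_fragments()] but keeps a `locus_id` (column 4) and parses an
#' optional group tag: a name of the form `id|group` assigns the locus to
#' `group`, so that, e.g., the 16 lifted copies of one microRNA can share a
#' group and be aggregated by [quantify_loci()]. Without a tag the group
#' defaults to the locus id.
#'
#' @inheritParams read_fragments
#' @return data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `group_id`.
#' @export
read_annotations <- function(path, ref_lengths = NULL) {
  frags <- read_fragments(path, ref_lengths)
  ids <- frags$name
  has_group <- grepl("|", ids, fixed = TRUE)
  group <- ifelse(has_group, sub("^.*\\|", "", ids), ids)
  locus <- ifelse(has_group, sub("\\|[^|]*$", "", ids), ids)
  data.frame(locus_id = locus, chrom = frags$chrom, start = frags$start,
             end = frags$end, strand = frags$strand, group_id = group,
             stringsAsFactors = FALSE)
}
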