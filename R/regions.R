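#' Genomic region in 1-based inclusive coordinates
#'
#' A `region_spec` records a source-genome interval the way coordinates are
#' printed in genome browsers and assembly recipes: 1-based, both endpoints
#' included. All internal interval arithmetic and all BED input/output in this
#' package use 0-based half-open coordinates instead; `region_spec` is the
#' boundary type that keeps the two conventions from mixing.
#'
#' @param chrom Chromosome name.
#' @param start,end Integer positions, 1-based inclusive, `start >= 1`,
#'   `end >= start`.
#' @return An object of class `region_spec` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' region_spec("chr21", 31912598, 31959322)
#' @seealso [parse_region()], [region_length()]
#' @export
region_spec <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("'chrom' must be a single non-empty chromosome name")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("'start' and 'end' must be single numbers")
  if (start != floor(start) || end != floor(end))
    stop("'start' and 'end' must be integers")
  if (start < 1)
    stop("'start' must be >= 1 (coordinates are 1-based inclusive)")
  if (end < start)
    stop(sprintf("invalid region %s:%d-%d: end < start", chrom, start, end))
  structure(list(chrom = chrom, start = start, end = end),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(region_length(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Parse a printed region string
#'
#' Accepts the coordinate syntax used in assembly recipes and figure legends:
#' `chrom:start-end`, `chrom:start..end`, or `chrom:start to end`, with
#' optional thousands separators (commas) in the numbers. Coordinates are
#' interpreted as 1-based inclusive.
#'
#' @param text A single region string, e.g. `"chr21:31,912,598-31,959,322"`.
#' @return A [region_spec()].
#' @examples
#' parse_region("chr21:31,912,598-31,959,322")
#' parse_region("chr1:100 to 200")
#' @export
parse_region <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single character string")
  txt <- trimws(text)
  m <- regexec("^([^:[:space:]]+):([0-9,]+)\\s*(?:-|\\.\\.|to)\\s*([0-9,]+)$",
               txt)
  parts <- regmatches(txt, m)[[1]]
  if (length(parts) != 4L)
    stop(sprintf("cannot parse region string '%s': expected chrom:start-end",
                 text))
  start <- suppressWarnings(as.numeric(gsub(",", "", parts[3], fixed = TRUE)))
  end <- suppressWarnings(as.numeric(gsub(",", "", parts[4], fixed = TRUE)))
  if (is.na(start))
    stop(sprintf("cannot parse start coordinate '%s' in '%s'", parts[3], text))
  if (is.na(end))
    stop(sprintf("cannot parse end coordinate '%s' in '%s'", parts[4], text))
  region_spec(parts[2], start, end)
}

#' Length of a region in base pairs
#'
#' For 1-based inclusive coordinates the length is `end - start + 1`; the
#' printed sizes of composite reference "chromosomes" (e.g. 46,725 bp for a
#' housekeeping control region, 44,788 bp for one rDNA repeat unit) validate
#' this convention.
#'
#' @param spec A [region_spec()].
#' @return Integer width in bp.
#' @examples
#' region_length(parse_region("chr21:3,141,168-3,185,955"))  # 44788
#' @export
region_length <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  spec$end - spec$start + 1
}

#' Assembly recipe for one composite mini-chromosome
#'
#' A mini-chromosome is built by concatenating one or more source segments in
#' order and, optionally, repeating the result in tandem. Tandem expansion
#' (`tandem_copies > 1`) is restricted to single-segment recipes so that the
#' segment map stays unambiguous; the motivating use is writing one rDNA
#' repeat unit 16 times to emulate a repeat array.
#'
#' @param name Mini-chromosome name.
#' @param segments A list of [region_spec()] (or a single `region_spec`).
#' @param tandem_copies Positive integer number of tandem copies (default 1).
#' @return An object of class `segment_recipe`.
#' @examples
#' segment_recipe("rDNA", parse_region("chr21:3,141,168-3,185,955"),
#'                tandem_copies = 16)
#' @export
segment_recipe <- function(name, segments, tandem_copies = 1L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (inherits(segments, "region_spec")) segments <- list(segments)
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "region_spec")))
    stop("'segments' must be one or more region_spec objects")
  tandem_copies <- as.integer(tandem_copies)
  if (is.na(tandem_copies) || tandem_copies < 1L)
    stop("'tandem_copies' must be a positive integer")
  if (tandem_copies > 1L && length(segments) > 1L)
    stop(sprintf("recipe '%s': tandem expansion requires a single segment",
                 name))
  structure(list(name = name, segments = segments,
                 tandem_copies = tandem_copies),
            class = "segment_recipe")
}

#' @export
print.segment_recipe <- function(x, ...) {
  segs <- vapply(x$segments, function(s)
    sprintf("%s:%s-%s", s$chrom, s$start, s$end), "")
  cat(sprintf("<recipe> %s = %s%s (%s bp)\n", x$name,
              paste(segs, collapse = " + "),
              if (x$tandem_copies > 1L) sprintf(" x%d", x$tandem_copies) else "",
              format(recipe_length(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Total length of a recipe's mini-chromosome
#'
#' @param recipe A [segment_recipe()].
#' @return `tandem_copies` times the summed segment lengths, in bp.
#' @export
recipe_length <- function(recipe) {
  stopifnot(inherits(recipe, "segment_recipe"))
  recipe$tandem_copies *
    sum(vapply(recipe$segments, region_length, numeric(1)))
}

#' Read mini-chromosome recipes from a plain-text config
#'
#' One recipe per line, in the syntax the recipes are printed in:
#'
#' ```
#' GART-SON = chr21:31,912,598-31,959,322
#' rDNA = chr21:3,141,168-3,185,955 x16
#' Chr1q-remaining = chr1:124048268-148935898 + chr1:149012901-227744286
#' ```
#'
#' Blank lines and lines starting with `#` are ignored. The `to` and `..`
#' coordinate separators are accepted as well as `-`. A trailing `xN` (or
#' `*N`) requests N tandem copies and is only valid with a single segment.
#'
#' @param path Path to the config file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of config lines (overrides `path`).
#' @return A named list of [segment_recipe()] objects.
#' @export
read_recipes <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recipes <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.+)$", ln))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("cannot parse recipe line '%s': expected name = regions", ln))
    name <- trimws(kv[2])
    rhs <- trimws(kv[3])
    copies <- 1L
    mx <- regmatches(rhs, regexec("^(.*?)[x*]\\s*([0-9]+)$", rhs))[[1]]
    if (length(mx) == 3L && grepl("[0-9]$", trimws(mx[2]))) {
      rhs <- trimws(mx[2])
      copies <- as.integer(mx[3])
    }
    seg_txt <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1]])
    segs <- lapply(seg_txt, parse_region)
    if (!is.null(recipes[[name]]))
      stop(sprintf("duplicate recipe name '%s'", name))
    recipes[[name]] <- segment_recipe(name, segs, copies)
  }
  recipes
}
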