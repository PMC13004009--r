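# Synthetic mini-genome and fragment-set generator with planted truth.
# The generator emulates the statistical structure the pipeline measures:
# a toy composite reference with a tandem repeat array and planted
# stem-loop (hairpin) loci, multinomial region-weighted fragment sampling,
# per-sample repeat copy-number factors, knockdown ratios and paired
# tumor/normal effects. Everything is deterministic under the config seed.

#' Simulation configuration
#'
#' Bundles the genome recipe, fragment model and cohort structure with
#' their default study conditions. Defaults describe a desk-scale composite
#' reference: a repeat array of 16 tandem 2-kb units carrying two planted
#' stem-loop loci per unit (the dominant one GC-rich, as real rDNA promoter
#' hairpins are), a 20-kb euchromatin block, two histone-cluster analogs, a
#' housekeeping control block and a small 5S-like block. Fragment lengths
#' are truncated-normal (mean 75, sd 15, range 20-150), 50,000 fragments
#' per sample.
#'
#' @param seed Integer seed; the same seed gives byte-identical outputs.
#' @param chroms Named lengths of the non-repeat chromosomes.
#' @param gc Background GC fraction.
#' @param repeat_chrom Name of the tandem-repeat chromosome.
#' @param unit_length,n_copies Repeat unit length (bp) and tandem copy
#'   number.
#' @param repeat_gc GC fraction of the repeat unit background.
#' @param stem_gc GC fraction of planted hairpin stems.
#' @param hairpins data.frame with `name`, `unit_pos` (0-based offset of the
#'   stem-loop within the repeat unit), `stem`, `loop` (bp).
#' @param weights Named fragment weights per chromosome (lambda).
#' @param locus_weights Named fragment weights for planted hairpin loci
#'   (split evenly across tandem copies).
#' @param strand_bias Named per-chromosome probability that a fragment is on
#'   `+`; chromosomes not named get 0.5.
#' @param n_fragments Fragments per sample (F).
#' @param frag_len Named vector `mean`, `sd`, `min`, `max` of the fragment
#'   length distribution.
#' @param n_samples Cohort size for the copy-number design.
#' @param kappa_sdlog Lognormal sdlog of the per-sample repeat copy-number
#'   factor kappa.
#' @param rho Named knockdown ratios (per chromosome or locus group).
#' @param delta Named tumor/normal effect sizes (per chromosome or locus
#'   group).
#' @param n_pairs Number of matched tumor/normal pairs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chroms = c(euchr = 20000, hist1 = 6000, hist6 = 6000,
                                  gartson = 6000, rna5s = 2000),
                       gc = 0.5,
                       repeat_chrom = "rDNA",
                       unit_length = 2000,
                       n_copies = 16L,
                       repeat_gc = 0.6,
                       stem_gc = 0.85,
                       hairpins = data.frame(
                         name = c("hp1", "hp2"),
                         unit_pos = c(600L, 1200L),
                         stem = c(20L, 12L),
                         loop = c(10L, 8L),
                         stringsAsFactors = FALSE),
                       weights = c(rDNA = 0.5, euchr = 0.25, hist1 = 0.08,
                                   hist6 = 0.08, gartson = 0.07,
                                   rna5s = 0.02),
                       locus_weights = c(hp1 = 0.05, hp2 = 0.01),
                       strand_bias = c(rDNA = 0.9),
                       n_fragments = 50000L,
                       frag_len = c(mean = 75, sd = 15, min = 20, max = 150),
                       n_samples = 20L,
                       kappa_sdlog = 0.3,
                       rho = c(hp1 = 0.5),
                       delta = c(hp2 = 10),
                       n_pairs = 7L) {
  cfg <- list(seed = as.integer(seed), chroms = chroms, gc = gc,
              repeat_chrom = repeat_chrom, unit_length = unit_length,
              n_copies = as.integer(n_copies), repeat_gc = repeat_gc,
              stem_gc = stem_gc, hairpins = hairpins, weights = weights,
              locus_weights = locus_weights, strand_bias = strand_bias,
              n_fragments = as.integer(n_fragments), frag_len = frag_len,
              n_samples = as.integer(n_samples), kappa_sdlog = kappa_sdlog,
              rho = rho, delta = delta, n_pairs = as.integer(n_pairs))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$weights < 0) || sum(cfg$weights) <= 0)
    stop("'weights' must be non-negative with positive sum")
  if (cfg$n_fragments <= 0) stop("'n_fragments' must be positive")
  hp <- cfg$hairpins
  if (nrow(hp)) {
    span <- 2 * hp$stem + hp$loop
    if (any(hp$unit_pos < 0 | hp$unit_pos + span > cfg$unit_length))
      stop("planted hairpin extends outside the repeat unit")
    if (nrow(hp) > 1L) {
      o <- order(hp$unit_pos)
      s <- hp$unit_pos[o]; e <- s + span[o]
      if (any(s[-1] < e[-length(e)]))
        stop("planted hairpins overlap within the repeat unit")
    }
    if (!all(names(cfg$locus_weights) %in% hp$name))
      stop("'locus_weights' names must match planted hairpin names")
  }
  miss <- setdiff(names(cfg$weights),
                  c(names(cfg$chroms), cfg$repeat_chrom))
  if (length(miss))
    stop(sprintf("weights for unknown chromosome(s): %s",
                 paste(miss, collapse = ", ")))
  invisible(cfg)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a toy genome with a planted repeat array and hairpin loci
#'
#' Generates random background sequence at the configured GC content, writes
#' the repeat unit in tandem `n_copies` times, and plants each hairpin locus
#' as a perfect reverse-complement stem pair flanking a loop, so the folded
#' stability of every planted locus is known by construction. The truth
#' table records every planted feature — one record per tandem copy for
#' repeat-resident features.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_genome`: list with `genome`
#'   (`DNAStringSet`), `features` (data.frame: `name`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `type`, `copy_index`, `group_id`),
#'   `hairpin_seqs` (named character, the planted stem-loop sequences), and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- vapply(config$chroms, function(L) random_dna(L, config$gc), "")

  unit <- random_dna(config$unit_length, config$repeat_gc)
  hp <- config$hairpins
  feats <- list()
  hp_seqs <- character(0)
  if (nrow(hp)) {
    for (i in seq_len(nrow(hp))) {
      stem <- random_dna(hp$stem[i], config$stem_gc)
      loop <- random_dna(hp$loop[i], config$gc)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(stem)))
      hairpin <- paste0(stem, loop, rc)
      hp_seqs[hp$name[i]] <- hairpin
      substr(unit, hp$unit_pos[i] + 1,
             hp$unit_pos[i] + nchar(hairpin)) <- hairpin
    }
  }
  seqs[config$repeat_chrom] <- strrep(unit, config$n_copies)

  for (copy in seq_len(config$n_copies) - 1L) {
    off <- copy * config$unit_length
    feats[[length(feats) + 1L]] <- data.frame(
      name = sprintf("unit_%02d", copy), chrom = config$repeat_chrom,
      start = off, end = off + config$unit_length, strand = "+",
      type = "repeat_unit", copy_index = copy, group_id = "repeat_unit",
      stringsAsFactors = FALSE)
    if (nrow(hp)) {
      span <- 2 * hp$stem + hp$loop
      feats[[length(feats) + 1L]] <- data.frame(
        name = sprintf("%s_copy%02d", hp$name, copy),
        chrom = config$repeat_chrom,
        start = off + hp$unit_pos, end = off + hp$unit_pos + span,
        strand = "+", type = "hairpin", copy_index = copy,
        group_id = hp$name, stringsAsFactors = FALSE)
    }
  }
  structure(list(genome = Biostrings::DNAStringSet(seqs),
                 features = do.call(rbind, feats),
                 hairpin_seqs = hp_seqs,
                 config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  len <- Biostrings::width(x$genome)
  cat(sprintf(
    "<sim_genome> %d chromosome(s), %s bp; %d planted feature record(s)\n",
    length(len), format(sum(len), big.mark = ","), nrow(x$features)))
  invisible(x)
}

#' Fragment-sampling regions for a simulated genome
#'
#' Builds the region table the multinomial fragment model draws from:
#' each planted hairpin locus is its own region (its group weight split
#' evenly across tandem copies), and the remainder of every chromosome is
#' background carrying the chromosome weight distributed proportionally to
#' width. Planted loci are excluded from the background so a locus's
#' expected fragment share equals its weight exactly.
#'
#' @param sim A `sim_genome`.
#' @param weights,locus_weights,strand_bias Overrides of the config values.
#' @return data.frame with `region_id`, `chrom`, `start`, `end`, `weight`,
#'   `pstrand`.
#' @export
fragment_regions <- function(sim, weights = NULL, locus_weights = NULL,
                             strand_bias = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- sim$config
  if (is.null(weights)) weights <- cfg$weights
  if (is.null(locus_weights)) locus_weights <- cfg$locus_weights
  if (is.null(strand_bias)) strand_bias <- cfg$strand_bias
  chrom_len <- stats::setNames(as.numeric(Biostrings::width(sim$genome)),
                               names(sim$genome))
  pstrand <- function(chrom)
    if (chrom %in% names(strand_bias)) strand_bias[[chrom]] else 0.5

  out <- list()
  loci <- sim$features[sim$features$type == "hairpin" &
                         sim$features$group_id %in% names(locus_weights), ,
                       drop = FALSE]
  for (chrom in names(chrom_len)) {
    excl <- loci[loci$chrom == chrom, , drop = FALSE]
    # background = chromosome minus planted locus windows
    bounds <- sort(unique(c(0, chrom_len[[chrom]], excl$start, excl$end)))
    segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    in_locus <- vapply(seq_len(nrow(segs)), function(i)
      any(excl$start <= segs$start[i] & segs$end[i] <= excl$end),
      logical(1))
    bg <- segs[!in_locus, , drop = FALSE]
    w_chrom <- if (chrom %in% names(weights)) weights[[chrom]] else 0
    if (nrow(bg) && w_chrom > 0) {
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("%s_bg%02d", chrom, seq_len(nrow(bg))),
        chrom = chrom, start = bg$start, end = bg$end,
        weight = w_chrom * (bg$end - bg$start) / sum(bg$end - bg$start),
        pstrand = pstrand(chrom), stringsAsFactors = FALSE)
    }
  }
  for (g in names(locus_weights)) {
    win <- loci[loci$group_id == g, , drop = FALSE]
    if (!nrow(win)) next
    out[[length(out) + 1L]] <- data.frame(
      region_id = g, chrom = win$chrom, start = win$start, end = win$end,
      weight = locus_weights[[g]] / nrow(win),
      pstrand = vapply(win$chrom, pstrand, numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a strand-specific fragment set
#'
#' Draws `n_fragments` fragments by the multinomial region model: the
#' region of each fragment is drawn with probability proportional to its
#' weight, the start is uniform within the region, the length is
#' truncated-normal (further truncated to the region width, so fragments
#' never leave their region), and the strand is Bernoulli with the region's
#' `pstrand`.
#'
#' @param sim A `sim_genome` (or anything [fragment_regions()] accepts if
#'   `regions` is supplied).
#' @param n_fragments Number of fragments; default from the config.
#' @param regions Region table (see [fragment_regions()]); defaults to the
#'   config's regions.
#' @param frag_len Length distribution `c(mean, sd, min, max)`; default from
#'   the config.
#' @param seed Seed; default the config seed.
#' @return BED6-style data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`), sorted by chromosome and start.
#' @export
simulate_fragments <- function(sim, n_fragments = NULL, regions = NULL,
                               frag_len = NULL, seed = NULL) {
  cfg <- sim$config
  if (is.null(n_fragments)) n_fragments <- cfg$n_fragments
  if (is.null(regions)) regions <- fragment_regions(sim)
  if (is.null(frag_len)) frag_len <- cfg$frag_len
  if (is.null(seed)) seed <- cfg$seed
  if (sum(regions$weight) <= 0) stop("region weights must sum to > 0")
  width <- regions$end - regions$start
  if (any(width < frag_len[["min"]]))
    stop(sprintf(
      "region '%s' (%d bp) is shorter than the minimum fragment length (%d)",
      regions$region_id[which(width < frag_len[["min"]])[1]],
      width[which(width < frag_len[["min"]])[1]], frag_len[["min"]]))

  set.seed(seed)
  ridx <- sample.int(nrow(regions), n_fragments, replace = TRUE,
                     prob = regions$weight)
  len <- round(stats::rnorm(n_fragments, frag_len[["mean"]],
                            frag_len[["sd"]]))
  len <- pmax(frag_len[["min"]], pmin(len, frag_len[["max"]]))
  len <- pmin(len, width[ridx])
  start <- regions$start[ridx] +
    floor(stats::runif(n_fragments) * (width[ridx] - len + 1))
  strand <- c("-", "+")[(stats::runif(n_fragments) <
                           regions$pstrand[ridx]) + 1L]
  chrom <- regions$chrom[ridx]
  ord <- order(chrom, start, start + len, method = "radix")
  data.frame(chrom = chrom[ord], start = start[ord],
             end = (start + len)[ord],
             name = sprintf("frag%07d", seq_len(n_fragments)),
             score = 0, strand = strand[ord], stringsAsFactors = FALSE)
}

#' Simulate a multi-sample cohort with planted truth
#'
#' Three cohort designs over one simulated genome:
#' \describe{
#'   \item{`copy_number`}{`n_samples` samples whose repeat-array weight (and
#'     the weights of loci residing on it) is multiplied by a per-sample
#'     factor kappa ~ lognormal(0, `kappa_sdlog`^2), emulating repeat
#'     copy-number variation between individuals.}
#'   \item{`knockdown`}{a control/treated pair in which each region named in
#'     `rho` has its weight multiplied by the planted ratio in the treated
#'     sample — the ground truth for perturbation overall ratios.}
#'   \item{`paired`}{`n_pairs` matched tumor/normal pairs in which each
#'     feature named in `delta` has its weight multiplied by the planted
#'     effect in the tumor samples — the ground truth for MA points.}
#' }
#' Truth tables record the planted parameter per sample/feature for
#' downstream recovery tests.
#'
#' @param config A [sim_config()].
#' @param design One of `"copy_number"`, `"knockdown"`, `"paired"`.
#' @param sim Optionally a pre-built `sim_genome` (defaults to
#'   `simulate_genome(config)`).
#' @return list of class `sim_cohort`: `genome` (`sim_genome`), `fragments`
#'   (named list of BED6 data.frames), `truth` (data.frame), `design`.
#' @export
simulate_cohort <- function(config,
                            design = c("copy_number", "knockdown", "paired"),
                            sim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  if (is.null(sim)) sim <- simulate_genome(config)

  scale_weights <- function(factors) {
    w <- config$weights
    lw <- config$locus_weights
    for (nm in names(factors)) {
      if (nm %in% names(w)) w[[nm]] <- w[[nm]] * factors[[nm]]
      else if (nm %in% names(lw)) lw[[nm]] <- lw[[nm]] * factors[[nm]]
      else stop(sprintf("effect on unknown region/feature '%s'", nm))
    }
    fragment_regions(sim, weights = w, locus_weights = lw)
  }

  fragments <- list()
  if (design == "copy_number") {
    set.seed(config$seed)
    kappa <- stats::rlnorm(config$n_samples, 0, config$kappa_sdlog)
    ids <- sprintf("s%02d", seq_len(config$n_samples))
    truth <- data.frame(sample_id = ids, kappa = kappa,
                        stringsAsFactors = FALSE)
    on_rep <- intersect(
      names(config$locus_weights),
      sim$features$group_id[sim$features$chrom == config$repeat_chrom])
    rdna_factors <- function(k)
      stats::setNames(rep(k, 1 + length(on_rep)),
                      c(config$repeat_chrom, on_rep))
    for (i in seq_along(ids)) {
      fragments[[ids[i]]] <- simulate_fragments(
        sim, regions = scale_weights(rdna_factors(kappa[i])),
        seed = config$seed + i)
    }
  } else if (design == "knockdown") {
    truth <- data.frame(region = names(config$rho), rho = config$rho,
                        row.names = NULL, stringsAsFactors = FALSE)
    fragments$control <- simulate_fragments(
      sim, regions = fragment_regions(sim), seed = config$seed + 1L)
    fragments$treated <- simulate_fragments(
      sim, regions = scale_weights(config$rho), seed = config$seed + 2L)
  } else {
    truth <- data.frame(feature = names(config$delta),
                        delta = config$delta,
                        row.names = NULL, stringsAsFactors = FALSE)
    for (i in seq_len(config$n_pairs)) {
      fragments[[sprintf("normal_%d", i)]] <- simulate_fragments(
        sim, regions = fragment_regions(sim), seed = config$seed + 2L * i)
      fragments[[sprintf("tumor_%d", i)]] <- simulate_fragments(
        sim, regions = scale_weights(config$delta),
        seed = config$seed + 2L * i + 1L)
    }
  }
  structure(list(genome = sim, fragments = fragments, truth = truth,
                 design = design),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes the genome FASTA, the truth feature BED (with `copy_index`), one
#' BED6 fragment file per sample, and the design truth table as TSV.
#'
#' @param cohort A `sim_cohort`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(cohort$genome$genome, fa)
  paths <- c(paths, fa)
  bed <- file.path(out_dir, "features.bed")
  feats <- cohort$genome$features
  feats$score <- 0
  write_bed(feats[, c("chrom", "start", "end", "name", "score", "strand",
                      "copy_index")], bed)
  paths <- c(paths, bed)
  for (s in names(cohort$fragments)) {
    p <- file.path(out_dir, paste0(s, ".bed"))
    write_bed(cohort$fragments[[s]], p)
    paths <- c(paths, p)
  }
  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(cohort$truth, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, tt)
  invisible(paths)
}
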