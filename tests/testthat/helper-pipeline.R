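# Shared pipeline shortcuts for tests that run fragments -> tracks -> stats.

genome_lengths <- function(sim) {
  stats::setNames(as.numeric(Biostrings::width(sim$genome)),
                  names(sim$genome))
}

# normalized fwd/rev pair for one sample
stranded_tracks <- function(frags, lens) {
  normalize_strand_pair(compute_track(frags, lens, "span", "+"),
                        compute_track(frags, lens, "span", "-"))
}

both_strand_track <- function(frags, lens, normalized = FALSE) {
  tr <- compute_track(frags, lens, "span", "both")
  if (normalized) fraction_normalize(tr) else tr
}

hairpin_regions <- function(sim, group) {
  hp <- sim$features[sim$features$group_id == group, , drop = FALSE]
  data.frame(region_id = group, chrom = hp$chrom, start = hp$start,
             end = hp$end, stringsAsFactors = FALSE)
}

hairpin_annotations <- function(sim) {
  hp <- sim$features[sim$features$type == "hairpin", , drop = FALSE]
  data.frame(locus_id = hp$name, chrom = hp$chrom, start = hp$start,
             end = hp$end, strand = hp$strand, group_id = hp$group_id,
             stringsAsFactors = FALSE)
}
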