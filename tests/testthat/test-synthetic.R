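small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chroms = c(euchr = 5000, gartson = 2000, rna5s = 1000),
             unit_length = 1000, n_copies = 5L,
             hairpins = data.frame(name = "hp1", unit_pos = 300L,
                                   stem = 20L, loop = 10L,
                                   stringsAsFactors = FALSE),
             weights = c(rDNA = 0.5, euchr = 0.3, gartson = 0.15,
                         rna5s = 0.05),
             locus_weights = c(hp1 = 0.05),
             n_fragments = 5000L, ...)
}

test_that("simulated genomes have the configured repeat structure", {
  cfg <- small_config()
  sim <- simulate_genome(cfg)
  lens <- Biostrings::width(sim$genome)
  names(lens) <- names(sim$genome)
  expect_equal(unname(lens["rDNA"]), 1000 * 5)
  expect_equal(unname(lens["euchr"]), 5000)

  units <- sim$features[sim$features$type == "repeat_unit", ]
  expect_equal(nrow(units), 5)
  expect_equal(units$start, (0:4) * 1000)

  # tandem copies are byte-identical
  chr <- as.character(sim$genome[["rDNA"]])
  unit1 <- substr(chr, 1, 1000)
  for (k in 1:4)
    expect_equal(substr(chr, k * 1000 + 1, (k + 1) * 1000), unit1)

  # hairpin records exist once per copy and match the planted sequence
  hps <- sim$features[sim$features$group_id == "hp1", ]
  expect_equal(nrow(hps), 5)
  expect_equal(hps$end - hps$start, rep(50, 5))
  for (i in seq_len(nrow(hps)))
    expect_equal(
      as.character(Biostrings::subseq(sim$genome[["rDNA"]],
                                      hps$start[i] + 1, hps$end[i])),
      sim$hairpin_seqs[["hp1"]])
})

test_that("planted hairpins fold to at least the stem pair count", {
  sim <- simulate_genome(small_config(seed = 5))
  call <- fold_hairpin(sim$hairpin_seqs[["hp1"]])
  expect_gte(call$n_pairs, 20)
  expect_gte(call$score, 2 * 20)  # every stem pair scores at least 2
})

test_that("overlapping planted hairpins are rejected", {
  expect_error(
    sim_config(hairpins = data.frame(name = c("a", "b"),
                                     unit_pos = c(100L, 120L),
                                     stem = c(20L, 20L),
                                     loop = c(10L, 10L))),
    "overlap")
  expect_error(
    sim_config(unit_length = 100,
               hairpins = data.frame(name = "a", unit_pos = 80L,
                                     stem = 20L, loop = 10L)),
    "outside")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 99)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$features, s2$features)

  f1 <- simulate_fragments(s1)
  f2 <- simulate_fragments(s2)
  expect_identical(f1, f2)

  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, "knockdown", sim = s1), d1)
  write_cohort(simulate_cohort(cfg, "knockdown", sim = s2), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # a different seed changes the fragments
  f3 <- simulate_fragments(s1, seed = 100)
  expect_false(identical(f1$start, f3$start))
})

test_that("fragment shares follow the region weights (binomial oracle)", {
  sim <- simulate_genome(small_config(seed = 7))
  regions <- data.frame(region_id = c("r1", "r2"),
                        chrom = c("euchr", "gartson"),
                        start = c(0, 0), end = c(5000, 2000),
                        weight = c(0.8, 0.2), pstrand = c(0.5, 0.5))
  F <- 10000
  frags <- simulate_fragments(sim, n_fragments = F, regions = regions,
                              seed = 11)
  share <- mean(frags$chrom == "euchr")
  se <- sqrt(0.8 * 0.2 / F)
  expect_lte(abs(share - 0.8), 3 * se)

  # all weight on one region
  solo <- regions
  solo$weight <- c(1, 0)
  frags2 <- simulate_fragments(sim, n_fragments = 1000, regions = solo,
                               seed = 12)
  expect_true(all(frags2$chrom == "euchr"))

  # fragments never leave their region
  expect_true(all(frags$end <= c(euchr = 5000, gartson = 2000)[frags$chrom]))

  # region shorter than the minimum fragment length errors
  tiny <- data.frame(region_id = "t", chrom = "euchr", start = 0, end = 10,
                     weight = 1, pstrand = 0.5)
  expect_error(simulate_fragments(sim, regions = tiny), "shorter than")
})

test_that("strand bias is honoured per region", {
  sim <- simulate_genome(small_config(seed = 13))
  regions <- data.frame(region_id = "r", chrom = "euchr", start = 0,
                        end = 5000, weight = 1, pstrand = 0.9)
  frags <- simulate_fragments(sim, n_fragments = 5000, regions = regions,
                              seed = 14)
  p <- mean(frags$strand == "+")
  expect_lte(abs(p - 0.9), 3 * sqrt(0.9 * 0.1 / 5000))
})

test_that("cohort designs record their planted truth", {
  cfg <- small_config(seed = 17)
  kd <- simulate_cohort(cfg, "knockdown")
  expect_named(kd$fragments, c("control", "treated"))
  expect_equal(kd$truth$region, "hp1")
  expect_equal(kd$truth$rho, 0.5)

  cn <- simulate_cohort(sim_config(
    seed = 18, chroms = c(euchr = 5000), unit_length = 1000, n_copies = 5L,
    hairpins = data.frame(name = "hp1", unit_pos = 300L, stem = 20L,
                          loop = 10L),
    weights = c(rDNA = 0.5, euchr = 0.5), locus_weights = c(hp1 = 0.02),
    n_fragments = 2000L, n_samples = 6L), "copy_number")
  expect_length(cn$fragments, 6)
  expect_equal(nrow(cn$truth), 6)
  expect_true(all(cn$truth$kappa > 0))

  pr <- simulate_cohort(small_config(seed = 19, n_pairs = 2L,
                                     delta = c(hp1 = 10)), "paired")
  expect_named(pr$fragments,
               c("normal_1", "tumor_1", "normal_2", "tumor_2"))
  expect_equal(pr$truth$delta, 10)
})

test_that("a planted tumor effect is recovered as an MA shift", {
  # one pair, delta = 10 on the low-abundance hairpin locus; under
  # compositional closure the expected M is log10(delta / (1 + (delta-1) *
  # lambda_f)), within binomial sampling error
  cfg <- sim_config(seed = 23, n_pairs = 1L, n_fragments = 20000L)
  sim <- simulate_genome(cfg)
  pr <- simulate_cohort(cfg, "paired", sim = sim)
  lens <- genome_lengths(sim)
  tracks <- lapply(pr$fragments, both_strand_track, lens = lens,
                   normalized = TRUE)
  sig <- quantify_loci(tracks, hairpin_annotations(sim))
  ma <- ma_points(sig["tumor_1", ], sig["normal_1", ], epsilon = 0.5)

  lam <- 0.01   # hp2 locus weight
  delta <- 10
  expected_m <- log10(delta / (1 + (delta - 1) * lam))
  n_norm <- cfg$n_fragments * lam
  n_tum <- cfg$n_fragments * lam * delta / (1 + (delta - 1) * lam)
  se_m <- sqrt(1 / n_norm + 1 / n_tum) / log(10)
  m_hp2 <- ma$M[ma$feature_id == "hp2"]
  expect_lte(abs(m_hp2 - expected_m), 3 * se_m)
  # the unperturbed locus stays near M = 0
  expect_lte(abs(ma$M[ma$feature_id == "hp1"]), 0.1)
})
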