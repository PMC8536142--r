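# Synthetic genomes are the test bed for the whole pipeline; these tests
# use deliberately small genomes (0.2-0.8 Mbp) with planting rates scaled
# up accordingly, so signal-to-noise matches a much larger genome at
# field-realistic tract densities.

test_that("zero gene density yields a purely intergenic genome", {
  cfg <- synthetic_genome_config(chromosomes = c(c1 = 50000L),
                                 gene_density = 0, seed = 1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation$features), 0)
  comp <- region_composition(derive_regions(g), 50000)
  expect_equal(comp$percent[comp$region == "intergenic"], 100)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_genome_config(
    chromosomes = c(c1 = 60000L, c2 = 40000L), gene_density = 120,
    str_planting = list(list(region = "intergenic", unit = "AT",
                             rate_per_mbp = 80)),
    seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  generate_genome(cfg, dir = d1)
  generate_genome(cfg, dir = d2)
  for (f in c("genome.fasta", "genome.gff3", "tracts.bed", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  ## different seed changes the sequence
  cfg2 <- synthetic_genome_config(
    chromosomes = c(c1 = 60000L, c2 = 40000L), gene_density = 120, seed = 6)
  g2 <- generate_genome(cfg2)
  g1 <- generate_genome(cfg)
  expect_false(identical(as.character(g1$sequences[[1]]),
                         as.character(g2$sequences[[1]])))
})

test_that("realized tract counts follow the configured Poisson rate", {
  cfg <- synthetic_genome_config(
    chromosomes = c(c1 = 500000L), gc = 0.4, gene_density = 150,
    mean_intron_length = 600,
    str_planting = list(list(region = "intronic", unit = "AT",
                             rate_per_mbp = 50, min_len = 14,
                             mean_extension = 16)),
    seed = 8)
  g <- generate_genome(cfg)
  comp <- region_composition(derive_regions(g), 500000)
  intron_bp <- comp$bp[comp$region == "intronic"]
  lambda <- 50 * intron_bp / 1e6
  realized <- nrow(g$truth)
  expect_lt(abs(realized - lambda), 3 * sqrt(lambda) + 1)
  ## all tracts lie inside intronic intervals and are recorded in truth
  masks <- region_set_to_mask(derive_regions(g)$intronic,
                              g$annotation$chromosomes)
  for (i in seq_len(nrow(g$truth)))
    expect_true(all(masks[[g$truth$chrom[i]]][(g$truth$start[i] + 1):
                                                g$truth$end[i]]))
  ## mean tract length near min_len + mean_extension
  lens <- g$truth$end - g$truth$start
  expect_lt(abs(mean(lens) - 30), 3 * stats::sd(lens) / sqrt(length(lens)))
})

test_that("infeasible planting configurations are rejected", {
  cfg <- synthetic_genome_config(
    chromosomes = c(c1 = 20000L), gene_density = 0,
    str_planting = list(list(region = "intergenic", unit = "A",
                             rate_per_mbp = 60000, min_len = 20)),
    seed = 3)
  expect_error(generate_genome(cfg), "infeasible")
})

test_that("null genomes show reference-level STR contributions", {
  mk <- function(seed) synthetic_genome_config(
    chromosomes = c(c1 = 400000L), gc = 0.4, gene_density = 0, seed = seed)
  g1 <- generate_genome(mk(41))
  g2 <- generate_genome(mk(42))
  k <- 7
  x <- compute_spectrum(as.character(g1$sequences), k)
  y <- compute_spectrum(as.character(g2$sequences), k)
  b12 <- c(set_words(enumerate_str_words(k, 1)),
           set_words(enumerate_str_words(k, 2)))
  c_null <- contribution(x, y, b12)
  ## within the <=2% reference band for k = 7 ensembles at matched G+C
  expect_lt(abs(c_null), 0.03)
})

test_that("mismatch preference vectors are recovered from ground truth", {
  ## forward-strand planting: in symmetric mode half the tracts are
  ## reverse-complemented and their substitutions are drawn from pi
  ## renormalized against the complementary repeat base, which biases the
  ## pooled base mixture away from pi
  pi <- c(A = 0, C = 0.1, G = 0.6, T = 0.3)
  cfg <- synthetic_genome_config(
    chromosomes = c(c1 = 400000L), gc = 0.4, gene_density = 0,
    str_planting = list(list(region = "intergenic", unit = "A",
                             rate_per_mbp = 800, min_len = 12,
                             mean_extension = 6, mismatch_rate = 0.15,
                             strand_mode = "forward", pi = pi)),
    seed = 12)
  g <- generate_genome(cfg)
  rep <- emulation_report(g, k = 7)
  ## planted-word excess over the Markov expectation
  expect_gt(rep$planting$excess[1], 5)
  mm <- rep$mismatches[[1]]
  n <- sum(g$truth$n_mismatches)
  expect_gt(n, 50)
  ## recovered substitution ranking matches pi exactly: G > T > C > A
  nonzero <- mm[mm$pi > 0 | mm$observed > 0, ]
  expect_identical(order(mm$observed, decreasing = TRUE)[1:3],
                   order(mm$pi, decreasing = TRUE)[1:3])
  ## magnitudes within 3 sigma (binomial) of pi
  for (i in seq_len(nrow(mm))) {
    se <- sqrt(max(mm$pi[i] * (1 - mm$pi[i]), 0.01) / n)
    expect_lt(abs(mm$observed[i] - mm$pi[i]), 3 * se + 0.02)
  }
})

test_that("the deviation profiler recovers planted substitution rankings", {
  ## parameter-recovery property: profiles of planted families reproduce
  ## the ordering of the preference vector pi (scaled-down genome)
  pis <- list(polyA = c(A = 0, C = 0.1, G = 0.6, T = 0.3),
              AG = c(A = 0.15, C = 0.55, G = 0, T = 0.3))
  cfg <- synthetic_genome_config(
    chromosomes = c(c1 = 600000L), gc = 0.4, gene_density = 80,
    str_planting = list(
      list(region = "intergenic", unit = "A", rate_per_mbp = 800,
           min_len = 12, mean_extension = 6, mismatch_rate = 0.15,
           strand_mode = "forward", pi = pis$polyA),
      list(region = "intergenic", unit = "AG", rate_per_mbp = 800,
           min_len = 12, mean_extension = 6, mismatch_rate = 0.15,
           strand_mode = "forward", pi = pis$AG)),
    seed = 14)
  g <- generate_genome(cfg)
  regs <- derive_regions(g)
  sp <- compute_spectrum(extract_sequences(regs$intergenic, g$sequences), 7)
  ## polyA profile: expect G > T > C among substituted bases
  pA <- deviation_profile(sp, "AAAAAAA")
  expect_identical(names(pA$percent), c("G", "T", "C"))
  ## (AG)n profile: expect C > T > A (G cannot be a substitution where
  ## it already is the repeat base; pi(G) = 0 elsewhere)
  pAG <- deviation_profile(sp, "AGAGAGA")
  expect_identical(names(pAG$percent)[1:2], c("C", "T"))
})

test_that("strand planting modes drive the expected pattern calls", {
  mk <- function(mode, seed) synthetic_genome_config(
    chromosomes = c(chr1 = 800000L), gc = 0.4, gene_density = 100,
    str_planting = list(
      list(region = "intergenic", unit = "GT", rate_per_mbp = 1200,
           min_len = 7, mean_extension = 1, strand_mode = mode),
      list(region = "intronic", unit = "GT", rate_per_mbp = 1200,
           min_len = 7, mean_extension = 1, strand_mode = mode)),
    seed = seed)
  calls <- list()
  for (mode in c("forward", "symmetric")) {
    g1 <- generate_genome(mk(mode, 21))
    g2 <- generate_genome(mk(mode, 121))
    r1 <- derive_regions(g1)
    r2 <- derive_regions(g2)
    x <- compute_spectrum(extract_sequences(r1$intronic, g1$sequences), 7)
    y <- compute_spectrum(extract_sequences(r2$intergenic, g2$sequences), 7)
    words <- c("GTGTGTG", "TGTGTGT", "ACACACA", "CACACAC")
    v <- vapply(words, function(w) contribution(x, y, w), numeric(1))
    calls[[mode]] <- classify_strand_pattern(v, "GTGTGTG", b = 2)$call
    if (mode == "symmetric") {
      ## symmetric planting: word and inverse complement agree within noise
      expect_lt(abs(v["GTGTGTG"] - v["CACACAC"]),
                0.5 * max(v["GTGTGTG"], v["CACACAC"]))
    }
  }
  expect_equal(calls$forward, "shift")
  expect_equal(calls$symmetric, "inv_compl")
})

test_that("planted IIR cohort reproduces the STR contribution signature", {
  ## two genomes with matched intronic+intergenic (AT)n/polyA planting:
  ## b<=2 contribution to the intron-intergenic correlation far exceeds
  ## the Markov reference, while CDS-CDS stays at reference level
  mk <- function(seed) synthetic_genome_config(
    chromosomes = c(c1 = 600000L), gc = 0.4, gene_density = 150,
    mean_intron_length = 500,
    str_planting = list(
      list(region = "intronic", unit = "AT", rate_per_mbp = 250,
           min_len = 12, mean_extension = 8),
      list(region = "intronic", unit = "A", rate_per_mbp = 250,
           min_len = 12, mean_extension = 8),
      list(region = "intergenic", unit = "AT", rate_per_mbp = 250,
           min_len = 12, mean_extension = 8),
      list(region = "intergenic", unit = "A", rate_per_mbp = 250,
           min_len = 12, mean_extension = 8)),
    seed = seed)
  g1 <- generate_genome(mk(51))
  g2 <- generate_genome(mk(52))
  r1 <- derive_regions(g1)
  r2 <- derive_regions(g2)
  k <- 7
  b12 <- word_set("b12", k, indices = union(
    enumerate_str_words(k, 1)$indices, enumerate_str_words(k, 2)$indices))
  sx <- compute_spectrum(extract_sequences(r1$intronic, g1$sequences), k)
  sy <- compute_spectrum(extract_sequences(r2$intergenic, g2$sequences), k)
  c_iir <- contribution(sx, sy, b12)
  cx <- compute_spectrum(extract_sequences(r1$CDS, g1$sequences), k)
  cy <- compute_spectrum(extract_sequences(r2$CDS, g2$sequences), k)
  c_cds <- contribution(cx, cy, b12)
  ## reference level: first-order Markov ensemble bound at matched G+C
  ref <- str_reference_bound(ks = k, gc_levels = 0.4, length = 5e5,
                             n_replicates = 3, seed = 99)
  expect_gt(c_iir, 5 * max(ref$max_contribution, 0.005))
  expect_lt(abs(c_cds), 0.02)
})
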