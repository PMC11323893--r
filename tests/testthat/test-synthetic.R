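test_that("genome generation honours counts, lengths, GC and seed", {
  g <- gen_phage_genomes(3, 10000, 10000, 0.5, seed = 1)
  expect_length(g, 3)
  expect_equal(unname(Biostrings::width(g)), rep(10000L, 3))
  g2 <- gen_phage_genomes(3, 10000, 10000, 0.5, seed = 1)
  expect_identical(as.character(g), as.character(g2))
  expect_error(gen_phage_genomes(0), "positive")
  # GC concentration: 1 Mb at gc = 0.6 stays within a binomial band
  big <- gen_phage_genomes(10, 100000, 100000, 0.6, seed = 2)
  freq <- Biostrings::alphabetFrequency(big, as.prob = FALSE)
  gc_obs <- sum(freq[, c("C", "G")]) / sum(freq[, c("A", "C", "G", "T")])
  expect_gt(gc_obs, 0.59)
  expect_lt(gc_obs, 0.61)
})

test_that("SV implantation does exact length bookkeeping per type", {
  g <- gen_phage_genomes(1, 10000, 10000, 0.5, seed = 3)
  one <- function(type) {
    cnt <- stats::setNames(1L, type)
    implant_svs(g, cnt, len_range = c(100L, 100L), seed = 4)
  }
  expect_equal(unname(Biostrings::width(one("DEL")$genomes)), 9900L)
  expect_equal(unname(Biostrings::width(one("INS")$genomes)), 10100L)
  expect_equal(unname(Biostrings::width(one("DUP")$genomes)), 10100L)
  expect_equal(unname(Biostrings::width(one("INV")$genomes)), 10000L)
})

test_that("implanted truth has the requested per-type counts and margins", {
  g <- gen_phage_genomes(5, 20000, 30000, 0.45, seed = 5)
  counts <- c(INS = 30L, DEL = 30L, DUP = 10L, INV = 10L)
  imp <- implant_svs(g, counts, c(100L, 500L), seed = 6)
  expect_equal(as.vector(table(imp$truth$svtype)[names(counts)]),
               unname(counts))
  glen <- stats::setNames(Biostrings::width(g), names(g))
  expect_true(all(imp$truth$start >= 100))
  expect_true(all(sv_end(imp$truth) <= glen[imp$truth$contig] - 100))
  # determinism
  imp2 <- implant_svs(g, counts, c(100L, 500L), seed = 6)
  expect_identical(imp$truth, imp2$truth)
  expect_error(implant_svs(gen_phage_genomes(1, 500, 500, .5, 1),
                           c(DEL = 5L), c(200L, 200L)), "too small")
})

test_that("a degenerate caller profile reproduces the truth exactly", {
  g <- gen_phage_genomes(5, 20000, 20000, 0.45, seed = 7)
  imp <- implant_svs(g, c(INS = 10L, DEL = 10L), c(100L, 400L), seed = 8)
  clen <- stats::setNames(Biostrings::width(g), names(g))
  perfect <- list(caller_profile("perfect", 0, 0, 0, 0, 5))
  cs <- simulate_caller_vcfs(imp$truth, perfect, clen, seed = 9)
  out <- cs[["perfect"]]
  expect_equal(nrow(out), nrow(imp$truth))
  expect_equal(out$start, imp$truth$start)
  expect_equal(out$length, imp$truth$length)
  expect_equal(out$truth_id, imp$truth$record_id)
  # fn_rate = 1 silences the caller entirely
  mute <- list(caller_profile("mute", 0, 0, 1, 0, 5))
  expect_equal(nrow(simulate_caller_vcfs(imp$truth, mute, clen,
                                         seed = 9)[["mute"]]), 0L)
})

test_that("caller-private false positive totals follow the Poisson rate", {
  g <- gen_phage_genomes(50, 20000, 20000, 0.45, seed = 10)
  imp <- implant_svs(g, c(DEL = 50L), c(100L, 400L), seed = 11)
  clen <- stats::setNames(Biostrings::width(g), names(g))
  profs <- lapply(sprintf("c%d", 1:4), caller_profile,
                  fn_rate = 0, fp_rate_per_genome = 2)
  cs <- simulate_caller_vcfs(imp$truth, profs, clen, seed = 12)
  n_fp <- sum(vapply(cs, function(df) sum(is.na(df$truth_id)), integer(1)))
  # 4 callers x 2/genome x 50 genomes = 400 expected; +-3 sd Poisson
  expect_gt(n_fp, 400 - 3 * sqrt(400))
  expect_lt(n_fp, 400 + 3 * sqrt(400))
})

test_that("exchange segments report ground-truth-exact identities", {
  set.seed(1)
  ph <- gen_phage_genomes(3, 10000, 10000, 0.5, seed = 13)
  ba <- gen_phage_genomes(2, 20000, 20000, 0.5, seed = 14, prefix = "bact")
  ex0 <- implant_exchange_segments(ph, ba, 5, c(300, 600), 0, seed = 15)
  expect_true(all(ex0$hits$pct_identity == 100))
  ex <- implant_exchange_segments(ph, ba, 10, c(1000, 1000), 0.10, seed = 16)
  # binomial sd of the realised identity at p = 0.9, n = 1000 is ~0.95%
  expect_true(all(abs(ex$hits$pct_identity - 90) < 3))
  none <- implant_exchange_segments(ph, ba, 0, c(300, 600), 0.05, seed = 17)
  expect_identical(as.character(none$phages), as.character(ph))
  expect_equal(nrow(none$hits), 0L)
})

test_that("codon gene generation follows the transition matrix", {
  expect_error(gen_codon_genes(uniform_codon_matrix() * 2,
                               uniform_codon_matrix(), 1, 1, 50),
               "row-stochastic")
  g <- gen_codon_genes(uniform_codon_matrix(), uniform_codon_matrix(),
                       5, 0, 50, seed = 18)
  expect_length(g$sequences, 5)
  expect_true(all(g$labels == "native"))
  expect_true(all(nchar(g$sequences) == 150))
  # no in-frame stop codons anywhere
  for (s in g$sequences) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
  # uniform matrix: each sense codon near 1/61 (multinomial 3-sigma band)
  big <- gen_codon_genes(uniform_codon_matrix(), uniform_codon_matrix(),
                         40, 0, 100, seed = 19)
  cods <- unlist(lapply(big$sequences, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  fr <- table(cods) / length(cods)
  p <- 1 / 61
  sd3 <- 3 * sqrt(p * (1 - p) / length(cods))
  expect_true(all(abs(fr - p) < sd3 + 2e-3))
})

test_that("planted HGT trees are labelled, deterministic and truthful", {
  pure <- gen_hgt_trees(3, 10, 0, seed = 20)
  expect_true(all(!grepl("V_", pure$newick)))
  expect_equal(nrow(pure$truth), 0L)
  one <- gen_hgt_trees(5, 12, 1, seed = 21)
  expect_equal(nrow(one$truth), 5L)
  expect_true(all(one$truth$direction == "B_to_P"))
  again <- gen_hgt_trees(5, 12, 1, seed = 21)
  expect_identical(one$newick, again$newick)
  expect_error(gen_hgt_trees(1, 6, 5, seed = 22), "too large")
})

test_that("spacer libraries have known hosts and verified decoys", {
  ph <- gen_phage_genomes(4, 5000, 5000, 0.5, seed = 23)
  lib0 <- gen_spacer_library(ph, 10, 32, 0, 5, seed = 24)
  expect_length(lib0$spacers, 15)
  expect_equal(nrow(lib0$truth), 10L)
  for (i in seq_len(10)) {
    host <- lib0$truth$host_phage_id[i]
    expect_true(grepl(lib0$spacers[[lib0$truth$spacer_id[i]]],
                      as.character(ph[[host]]), fixed = TRUE))
  }
  lib2 <- gen_spacer_library(ph, 5, 32, 2, 5, seed = 25)
  decoys <- lib2$spacers[grepl("decoy", names(lib2$spacers))]
  for (d in decoys) {
    for (g in as.character(ph)) {
      expect_equal(nrow(brute_spacer_scan(d, g, 2)), 0L)
    }
  }
})

test_that("abundance coupling attains the latent correlation", {
  pairs <- data.frame(phage_id = sprintf("p%02d", 1:100),
                      taxon_id = sprintf("g%02d", 1:100))
  m1 <- gen_abundance_matrix(91, pairs[1, ], coupling_rho = 1,
                             sigma = 1, seed = 26)
  expect_equal(cor(m1["p01", ], m1["g01", ]), 1, tolerance = 1e-12)
  expect_true(all(m1 > 0))
  # rho = 0.8, sigma = 0.5: lognormal Pearson r concentrates near 0.78
  m <- gen_abundance_matrix(91, pairs, coupling_rho = 0.8, sigma = 0.5,
                            seed = 27)
  rs <- vapply(1:100, function(i)
    cor(m[pairs$phage_id[i], ], m[pairs$taxon_id[i], ]), numeric(1))
  expect_gt(mean(rs), 0.73)
  expect_lt(mean(rs), 0.87)
  # rho = 0: null correlations stay small on average
  m0 <- gen_abundance_matrix(91, pairs, coupling_rho = 0, sigma = 0.5,
                             seed = 28)
  rs0 <- vapply(1:100, function(i)
    cor(m0[pairs$phage_id[i], ], m0[pairs$taxon_id[i], ]), numeric(1))
  expect_lt(mean(abs(rs0)), 0.12)
  expect_error(gen_abundance_matrix(2, pairs), "3 samples")
})
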