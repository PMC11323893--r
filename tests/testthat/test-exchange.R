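mk_hit <- function(query, subject = "bactA", id = 90, alnlen = 900) {
  data.frame(query_id = query, subject_id = subject, pct_identity = id,
             aln_length = as.integer(alnlen), mismatches = 0L,
             gap_opens = 0L, qstart = 1L, qend = as.integer(alnlen),
             sstart = 1L, send = as.integer(alnlen), evalue = 0,
             bitscore = 2 * alnlen, stringsAsFactors = FALSE)
}

test_that("GE classification applies the length/identity/coverage rule", {
  svs <- data.frame(sv_id = c("sv1", "sv2", "sv3"),
                    length = c(1000L, 150L, 1000L),
                    stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("sv1", id = 85, alnlen = 850),
                mk_hit("sv2", id = 100, alnlen = 150),
                mk_hit("sv3", id = 79, alnlen = 1000))
  ge <- classify_ge_svs(svs, hits)
  expect_equal(ge$label, c("GE_like", "too_short", "noGE_like"))
  expect_equal(ge$best_subject[1], "bactA")
  expect_equal(ge$best_coverage[1], 0.85)
  # boundary cases are exclusive: exactly 80 identity or 0.8 coverage fail
  b <- classify_ge_svs(data.frame(sv_id = "b", length = 1000L),
                       rbind(mk_hit("b", id = 80, alnlen = 1000),
                             mk_hit("b", id = 100, alnlen = 800)))
  expect_equal(b$label, "noGE_like")
  expect_warning(classify_ge_svs(svs, mk_hit("unknown_sv")), "unknown SV")
})

test_that("raising thresholds never adds GE-like labels (monotonicity)", {
  set.seed(11)
  svs <- data.frame(sv_id = sprintf("s%d", 1:40),
                    length = sample(150:2000, 40, TRUE))
  hits <- do.call(rbind, lapply(1:40, function(i)
    mk_hit(sprintf("s%d", i), id = runif(1, 60, 100),
           alnlen = sample(100:2000, 1))))
  base <- classify_ge_svs(svs, hits, min_id = 80, min_cov = 0.8)
  for (mi in c(85, 90)) {
    for (mc in c(0.85, 0.9)) {
      strict <- classify_ge_svs(svs, hits, min_id = mi, min_cov = mc)
      expect_true(all(which(strict$label == "GE_like") %in%
                        which(base$label == "GE_like")))
    }
  }
})

empty_hits_df <- function() phagesv:::empty_hits()

test_that("prophage flagging uses the 80%/50% rule", {
  ge <- classify_ge_svs(data.frame(sv_id = c("s1", "s2"),
                                   length = c(1000L, 1000L)),
                        rbind(mk_hit("s1"), mk_hit("s2")))
  flagged <- flag_prophage_overlap(ge, mk_hit("s1", subject = "proph1",
                                              id = 90, alnlen = 600))
  expect_true(flagged$prophage_flag[1])
  expect_false(flagged$prophage_flag[2])
  low <- flag_prophage_overlap(ge, mk_hit("s1", subject = "proph1",
                                          id = 90, alnlen = 400))
  expect_false(any(low$prophage_flag))
  expect_equal(flag_prophage_overlap(ge, empty_hits_df())$prophage_flag,
               c(FALSE, FALSE))
})

test_that("LCA interaction range is the deepest shared rank", {
  lin <- data.frame(
    genome_id = c("g1", "g2", "g3", "g4"),
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = c("F1", "F1", "F1", "F2"),
    genus = c("G1", "G1", "G2", "G3"),
    species = c("sp1", "sp1", "sp2", "sp3"),
    stringsAsFactors = FALSE)
  expect_equal(lca_range(c("g1", "g2"), lin), "species")
  expect_equal(lca_range(c("g1", "g3"), lin), "family")
  expect_equal(lca_range(c("g1", "g4"), lin), "order")
  expect_equal(lca_range("g1", lin), "species")
  lin2 <- lin
  lin2[2, phagesv:::LINEAGE_RANKS] <-
    c("Archaea", "P2", "C2", "O2", "F9", "G9", "sp9")
  expect_equal(lca_range(c("g1", "g2"), lin2), "none")
  expect_error(lca_range("missing", lin), "missing")
})

test_that("codon model training matches the Laplace closed form", {
  # one transition AAA->AAA; smoothed P = (1+1)/(1+64)
  m <- train_codon_model(c(g1 = "AAAAAA"), pseudocount = 1)
  expect_equal(m$transition["AAA", "AAA"], 2 / 65, tolerance = 1e-12)
  expect_equal(m$transition["AAA", "AAC"], 1 / 65, tolerance = 1e-12)
  # empty corpus: uniform rows
  m0 <- train_codon_model(character(0))
  expect_true(all(abs(m0$transition - 1 / 64) < 1e-12))
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-9))
  expect_error(train_codon_model(c(bad = "AAAA")), "bad")
})

test_that("HT index equals its closed forms and is order-invariant", {
  uni <- list(transition = uniform_codon_matrix(), initial = rep(1 / 64, 64),
              pseudocount = 1)
  class(uni) <- "codon_model"
  expect_equal(ht_index("ACGACGACG", uni), -6)
  expect_equal(ht_index(strrep("TTT", 100), uni), -6)
  half <- uniform_codon_matrix()
  half["AAA", ] <- (1 - 0.5) / 63
  half["AAA", "AAA"] <- 0.5
  m <- list(transition = half, initial = rep(1 / 64, 64), pseudocount = 1)
  class(m) <- "codon_model"
  expect_equal(ht_index(strrep("AAA", 50), m), -1)
  # training-corpus permutation invariance
  g <- gen_codon_genes(random_codon_matrix(5, 0.5), uniform_codon_matrix(),
                       10, 0, 60, seed = 6)$sequences
  m1 <- train_codon_model(g)
  m2 <- train_codon_model(rev(g))
  expect_equal(vapply(g, ht_index, numeric(1), model = m1),
               vapply(g, ht_index, numeric(1), model = m2))
})

test_that("HGT detection reads nested cross-kingdom clades", {
  none <- detect_hgt_events(read_kingdom_trees(
    text = "((V_1,V_2),(B_1,B_2));")[[1]])
  expect_equal(nrow(none), 0L)
  one <- detect_hgt_events(read_kingdom_trees(
    text = "(B_1,(V_1,(B_2,B_3)));")[[1]])
  expect_equal(nrow(one), 1L)
  expect_equal(one$direction, "B_to_P")
  expect_equal(one$recipients, "V_1")
  expect_setequal(strsplit(one$context, ",")[[1]], c("B_1", "B_2", "B_3"))
  pure <- detect_hgt_events(read_kingdom_trees(
    text = "((V_1,V_2),(V_3,V_4));")[[1]])
  expect_equal(nrow(pure), 0L)
  # support filtering on the parent node
  tr <- read_kingdom_trees(text = "(B_1,(V_1,(B_2,B_3))40);")[[1]]
  expect_equal(nrow(detect_hgt_events(tr, min_support = 50)), 0L)
  expect_equal(nrow(detect_hgt_events(tr, min_support = 30)), 1L)
  # per-leaf counting mode expands a two-leaf clade into two rows
  two <- detect_hgt_events(read_kingdom_trees(
    text = "(B_1,((V_1,V_2),(B_2,B_3)));")[[1]], per_leaf = TRUE)
  expect_equal(nrow(two), 2L)
  expect_setequal(two$recipients, c("V_1", "V_2"))
})

test_that("spacer matching equals a brute-force Hamming scan", {
  set.seed(13)
  genome <- c(gA = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""))
  sp_exact <- substr(genome[[1]], 501, 532)
  ch <- strsplit(sp_exact, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  sp_mm2 <- paste(ch, collapse = "")
  ch[25] <- setdiff(c("A", "C", "G", "T"), ch[25])[1]
  sp_mm3 <- paste(ch, collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sp_exact), "")[[1]]),
              collapse = "")
  spacers <- c(s_exact = sp_exact, s_mm2 = sp_mm2, s_mm3 = sp_mm3,
               s_rc = rc)
  hits <- match_spacers(spacers, genome)
  h_exact <- hits[hits$spacer_id == "s_exact" & hits$strand == "+", ]
  expect_true(any(h_exact$position == 500 & h_exact$mismatches == 0))
  expect_true(any(hits$spacer_id == "s_mm2" & hits$mismatches == 2))
  expect_false(any(hits$spacer_id == "s_mm3"))
  expect_true(any(hits$spacer_id == "s_rc" & hits$strand == "-" &
                    hits$position == 500))
  # full equivalence against the oracle on random spacer/genome pairs
  for (i in 1:20) {
    g <- c(g1 = paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                      collapse = ""))
    sp <- if (i %% 2 == 0) {
      p <- sample(700, 1)
      w <- substr(g[[1]], p, p + 27)
      cw <- strsplit(w, "")[[1]]
      for (j in sample(28, sample(0:2, 1)))
        cw[j] <- sample(setdiff(c("A", "C", "G", "T"), cw[j]), 1)
      paste(cw, collapse = "")
    } else paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    got <- match_spacers(c(sp1 = sp), g)
    want <- brute_spacer_scan(sp, g[[1]])
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("spacer hits aggregate into a phage host table", {
  hits <- data.frame(spacer_id = c("sp1", "sp2", "sp3"),
                     genome_id = c("p1", "p1", "p2"),
                     position = c(0L, 5L, 9L), strand = "+",
                     mismatches = 0L, matched_len = 30L,
                     stringsAsFactors = FALSE)
  hosts <- spacer_host_table(hits, c(sp1 = "genus_A", sp2 = "genus_B",
                                     sp3 = "genus_A"))
  expect_equal(hosts$host_taxa[hosts$genome_id == "p1"], "genus_A,genus_B")
  expect_equal(hosts$host_taxa[hosts$genome_id == "p2"], "genus_A")
})
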