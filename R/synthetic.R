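#' Generate random phage (or bacterial) genome sequences
#'
#' Bases are i.i.d. at the requested GC content; lengths are uniform on
#' `[len_min, len_max]`. Output is reproducible for a given seed.
#'
#' @param n Number of genomes (> 0).
#' @param len_min,len_max Length bounds in bp.
#' @param gc GC content in (0, 1).
#' @param seed Integer seed.
#' @param prefix Identifier prefix (default `"phage"`).
#' @return Named [Biostrings::DNAStringSet].
#' @export
gen_phage_genomes <- function(n, len_min = 30000L, len_max = 60000L,
                              gc = 0.45, seed = 1L, prefix = "phage") {
  if (n <= 0) stop("n must be positive")
  stopifnot(len_min <= len_max, gc > 0, gc < 1)
  set.seed(seed)
  lens <- if (len_min == len_max) rep(len_min, n) else
    sample(len_min:len_max, n, replace = TRUE)
  seqs <- vapply(lens, random_seq, character(1), gc = gc)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_%03d", prefix, seq_len(n))
  out
}

# uniform integer draw(s) on [lo, hi]; immune to R's sample(scalar) rule
int_between <- function(lo, hi, n = 1L) {
  if (hi < lo) stop("empty integer range")
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_seq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# substitute each position independently at `rate`; returns sequence and
# realised substitution count
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L))
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

#' Implant truth SVs into reference genomes
#'
#' Places the requested number of INS/DEL/DUP/INV events at random,
#' non-overlapping positions at least `margin` bp from genome ends and
#' from each other, then builds the mutated (sample) version of every
#' genome. Truth coordinates are expressed on the reference. Mutated
#' lengths are checked exactly: each INS and DUP adds its length, each
#' DEL removes it, and INV preserves it.
#'
#' @param genomes Named `DNAStringSet` of reference genomes.
#' @param counts_by_type Named integer vector over
#'   `c("INS","DEL","DUP","INV")`.
#' @param len_range Min/max SV length (bp).
#' @param seed Integer seed.
#' @param margin Exclusion margin (bp) from ends and between implants.
#' @param genome_weights Optional per-genome sampling weights (e.g. to
#'   give temperate phages a higher SV load).
#' @return List with `genomes` (mutated `DNAStringSet`) and `truth` (SV
#'   record `data.frame`, caller and sample set to `"truth"`).
#' @export
implant_svs <- function(genomes, counts_by_type = c(INS = 150L, DEL = 150L,
                                                    DUP = 50L, INV = 50L),
                        len_range = c(100L, 1000L), seed = 1L,
                        margin = 100L, genome_weights = NULL) {
  stopifnot(all(names(counts_by_type) %in% SV_TYPES))
  set.seed(seed)
  ids <- names(genomes)
  glen <- stats::setNames(Biostrings::width(genomes), ids)
  if (is.null(genome_weights)) genome_weights <- rep(1, length(ids))
  types <- rep(names(counts_by_type), counts_by_type)
  host <- sample(ids, length(types), replace = TRUE, prob = genome_weights)
  placed <- lapply(ids, function(g) integer(0))  # used interval endpoints
  names(placed) <- ids
  occ <- lapply(ids, function(g) NULL)
  names(occ) <- ids
  rows <- vector("list", length(types))
  for (i in seq_along(types)) {
    g <- host[i]
    len <- int_between(len_range[1], len_range[2])
    lo <- margin
    hi <- glen[g] - len - margin
    if (hi < lo) stop("genome too small to host requested SVs: ", g)
    ok <- FALSE
    for (try in 1:1000) {
      st <- int_between(lo, hi)
      iv <- occ[[g]]
      if (is.null(iv) ||
          all(st + len + margin <= iv[, 1] | st >= iv[, 2] + margin)) {
        occ[[g]] <- rbind(iv, c(st, st + len))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("genome too small to host requested SVs: ", g)
    alt <- if (types[i] == "INS") random_seq(len) else NA_character_
    rows[[i]] <- data.frame(contig = g, start = st, length = len,
                            svtype = types[i], alt_seq = alt,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
  truth <- sv_records(truth$contig, truth$start, truth$length, truth$svtype,
                      alt_seq = truth$alt_seq, read_support = 0L,
                      caller = "truth", sample = "truth",
                      record_id = sprintf("truth_%04d", seq_len(nrow(truth))))
  list(genomes = apply_truth_svs(genomes, truth), truth = truth)
}

# build mutated genomes from reference + truth records (exact bookkeeping)
apply_truth_svs <- function(genomes, truth) {
  out <- as.character(genomes)
  for (g in names(out)) {
    tv <- truth[truth$contig == g, , drop = FALSE]
    if (nrow(tv) == 0) next
    tv <- tv[order(-tv$start), , drop = FALSE]  # edit right-to-left
    seq <- out[[g]]
    for (i in seq_len(nrow(tv))) {
      s <- tv$start[i]; L <- tv$length[i]
      seq <- switch(tv$svtype[i],
        DEL = paste0(substr(seq, 1, s), substring(seq, s + L + 1)),
        INS = paste0(substr(seq, 1, s), tv$alt_seq[i], substring(seq, s + 1)),
        DUP = paste0(substr(seq, 1, s + L), substr(seq, s + 1, s + L),
                     substring(seq, s + L + 1)),
        INV = paste0(substr(seq, 1, s), revcomp(substr(seq, s + 1, s + L)),
                     substring(seq, s + L + 1)))
    }
    delta <- sum(tv$length[tv$svtype %in% c("INS", "DUP")]) -
      sum(tv$length[tv$svtype == "DEL"])
    stopifnot(nchar(seq) == nchar(out[[g]]) + delta)
    out[[g]] <- seq
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(genomes)
  res
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Noise profile of a simulated SV caller
#'
#' @param caller_id Caller name.
#' @param pos_jitter_sd SD (bp) of Gaussian start jitter.
#' @param len_jitter_frac SD of the multiplicative length jitter.
#' @param fn_rate Probability of missing a truth SV.
#' @param fp_rate_per_genome Expected caller-private false positives per
#'   genome (Poisson).
#' @param read_support_mean Mean reported read support (shifted Poisson,
#'   minimum 1).
#' @return List of class `caller_profile`.
#' @export
caller_profile <- function(caller_id, pos_jitter_sd = 10, len_jitter_frac = 0.05,
                           fn_rate = 0.10, fp_rate_per_genome = 2,
                           read_support_mean = 8) {
  stopifnot(pos_jitter_sd >= 0, len_jitter_frac >= 0,
            fn_rate >= 0, fn_rate <= 1, fp_rate_per_genome >= 0,
            read_support_mean > 0)
  structure(list(caller_id = caller_id, pos_jitter_sd = pos_jitter_sd,
                 len_jitter_frac = len_jitter_frac, fn_rate = fn_rate,
                 fp_rate_per_genome = fp_rate_per_genome,
                 read_support_mean = read_support_mean),
            class = "caller_profile")
}

#' Default four-caller ensemble profile set
#' @return Named list of [caller_profile()] objects for the four
#'   long-read callers the merger prioritises.
#' @export
default_caller_profiles <- function() {
  ids <- c("Sniffles", "cuteSV", "pbsv", "SVIM")
  stats::setNames(lapply(ids, caller_profile), ids)
}

#' Simulate noisy per-caller callsets from a truth set
#'
#' Each caller emits each truth SV with probability `1 - fn_rate`, its
#' start shifted by rounded Gaussian jitter and its length scaled by
#' `1 + N(0, len_jitter_frac)` (floored at 1 bp), plus caller-private
#' false positives placed uniformly (Poisson count per genome). Read
#' support is a shifted Poisson with the profile's mean, minimum 1.
#'
#' @param truth Truth SV record `data.frame` from [implant_svs()].
#' @param profiles Named list of [caller_profile()] objects.
#' @param contig_lengths Named vector of reference contig lengths.
#' @param sample Sample identifier stamped on all emitted records.
#' @param seed Integer seed.
#' @return Named list (per caller) of SV record data.frames with an
#'   extra `truth_id` column (`NA` for false positives).
#' @export
simulate_caller_vcfs <- function(truth, profiles, contig_lengths,
                                 sample = "S1", seed = 1L) {
  if (length(profiles) < 1) stop("at least one caller profile required")
  set.seed(seed)
  len_rng <- if (nrow(truth) > 0) range(truth$length) else c(100L, 1000L)
  out <- list()
  for (pf in profiles) {
    keep <- runif(nrow(truth)) >= pf$fn_rate
    tv <- truth[keep, , drop = FALSE]
    n <- nrow(tv)
    st <- tv$start + round(rnorm(n, 0, pf$pos_jitter_sd))
    ln <- pmax(1L, round(tv$length * (1 + rnorm(n, 0, pf$len_jitter_frac))))
    clen <- contig_lengths[tv$contig]
    st <- pmin(pmax(st, 0L), clen - 1L)
    ln <- ifelse(tv$svtype == "INS", ln, pmin(ln, clen - st))
    # caller-private false positives
    fp_n <- rpois(length(contig_lengths), pf$fp_rate_per_genome)
    fp_contig <- rep(names(contig_lengths), fp_n)
    fp_len <- int_between(len_rng[1], len_rng[2], length(fp_contig))
    fp_max <- contig_lengths[fp_contig] - fp_len
    fp_st <- floor(runif(length(fp_contig)) * pmax(fp_max, 1))
    all_n <- n + length(fp_contig)
    support <- 1L + rpois(all_n, pf$read_support_mean - 1)
    rec <- sv_records(
      contig = c(tv$contig, fp_contig),
      start = c(st, fp_st),
      length = c(ln, fp_len),
      svtype = c(tv$svtype, sample(SV_TYPES, length(fp_contig),
                                   replace = TRUE)),
      alt_seq = c(tv$alt_seq, rep(NA_character_, length(fp_contig))),
      read_support = support,
      caller = pf$caller_id, sample = sample,
      record_id = sprintf("%s_%s_%05d", sample, pf$caller_id,
                          seq_len(all_n)))
    rec$truth_id <- c(tv$record_id, rep(NA_character_, length(fp_contig)))
    out[[pf$caller_id]] <- rec
  }
  out
}

#' Implant bacteria-derived segments into phage genomes
#'
#' Copies a random segment from a bacterial genome, applies i.i.d.
#' substitutions at `subst_rate`, and inserts it at a random position of
#' a random phage. The emitted hit table is ground-truth exact: identity
#' is 100 times one minus the realised substitution fraction, with
#' full-coverage coordinates.
#'
#' @param phages,bacteria Named `DNAStringSet`s.
#' @param n_events Number of transfer events.
#' @param seg_len Min/max segment length (bp); the minimum must exceed
#'   200 bp so the events remain detectable by the GE classification
#'   rule.
#' @param subst_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `phages` (modified), `events` and `hits`
#'   data.frames.
#' @export
implant_exchange_segments <- function(phages, bacteria, n_events,
                                      seg_len = c(300L, 1000L),
                                      subst_rate = 0.05, seed = 1L) {
  stopifnot(seg_len[1] > 200, subst_rate >= 0, subst_rate < 1)
  if (any(Biostrings::width(bacteria) < seg_len[2]))
    stop("bacterial genome(s) shorter than the maximum segment length")
  set.seed(seed)
  pseq <- as.character(phages)
  events <- vector("list", n_events)
  hits <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    donor <- sample(names(bacteria), 1)
    len <- int_between(seg_len[1], seg_len[2])
    dstart <- int_between(0L, Biostrings::width(bacteria)[match(donor, names(bacteria))] - len)
    seg <- substr(as.character(bacteria[[donor]]), dstart + 1, dstart + len)
    mut <- mutate_seq(seg, subst_rate)
    recip <- sample(names(pseq), 1)
    pos <- sample(0:nchar(pseq[[recip]]), 1)
    pseq[[recip]] <- paste0(substr(pseq[[recip]], 1, pos), mut$seq,
                            substring(pseq[[recip]], pos + 1))
    eid <- sprintf("xfer_%03d", i)
    events[[i]] <- data.frame(
      event_id = eid, donor_genome_id = donor, recipient_phage_id = recip,
      donor_start = dstart, donor_len = len, insert_pos = pos,
      subst_rate = subst_rate, n_sub = mut$n_sub, stringsAsFactors = FALSE)
    hits[[i]] <- exchange_hit_row(eid, donor, len, mut$n_sub, dstart)
  }
  out <- Biostrings::DNAStringSet(pseq)
  names(out) <- names(phages)
  list(phages = out,
       events = if (n_events > 0) do.call(rbind, events) else
         data.frame(event_id = character(0)),
       hits = if (n_events > 0) do.call(rbind, hits) else empty_hits())
}

exchange_hit_row <- function(query, subject, len, n_sub, sstart) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = 100 * (1 - n_sub / len),
             aln_length = as.integer(len), mismatches = as.integer(n_sub),
             gap_opens = 0L, qstart = 1L, qend = as.integer(len),
             sstart = as.integer(sstart + 1), send = as.integer(sstart + len),
             evalue = 0, bitscore = 2 * len, stringsAsFactors = FALSE)
}

# ---- codon genes -----------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Uniform codon-transition matrix (1/64 everywhere)
#' @export
uniform_codon_matrix <- function() {
  matrix(1 / 64, 64, 64, dimnames = list(CODONS, CODONS))
}

#' Random row-stochastic codon-transition matrix
#'
#' Rows are independent Dirichlet draws; smaller `concentration` gives
#' more skewed (more genome-specific) codon-neighbour preferences.
#'
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration per cell (default 1).
#' @return 64 x 64 row-stochastic matrix.
#' @export
random_codon_matrix <- function(seed = 1L, concentration = 1) {
  set.seed(seed)
  g <- matrix(stats::rgamma(64 * 64, shape = concentration), 64, 64,
              dimnames = list(CODONS, CODONS))
  g / rowSums(g)
}

#' Mean row-wise total-variation distance of two codon matrices
#' @param a,b Row-stochastic 64 x 64 matrices.
#' @return Mean over rows of half the L1 row difference.
#' @export
codon_matrix_tv <- function(a, b) mean(rowSums(abs(a - b)) / 2)

#' Generate genes from codon-transition Markov chains
#'
#' Native genes follow `native_T`, foreign genes `foreign_T`; each gene
#' is a first-order Markov chain over codons started uniformly on the 61
#' sense codons, with in-frame stop codons resampled.
#'
#' @param native_T,foreign_T Row-stochastic 64 x 64 matrices.
#' @param n_native,n_foreign Gene counts.
#' @param gene_len_codons Gene length in codons (>= 10).
#' @param seed Integer seed.
#' @return List with `sequences` (named character) and `labels` (named,
#'   `"native"`/`"foreign"`).
#' @export
gen_codon_genes <- function(native_T, foreign_T, n_native = 50L,
                            n_foreign = 50L, gene_len_codons = 300L,
                            seed = 1L) {
  stopifnot(gene_len_codons >= 10)
  for (nm in c("native_T", "foreign_T")) {
    m <- get(nm)
    bad <- which(abs(rowSums(m) - 1) > 1e-9)
    if (length(bad) > 0)
      stop(nm, " is not row-stochastic at row(s): ",
           paste(head(bad, 5), collapse = ", "))
  }
  set.seed(seed)
  sense <- setdiff(CODONS, STOP_CODONS)
  draw_gene <- function(T) {
    cod <- character(gene_len_codons)
    cod[1] <- sample(sense, 1)
    for (i in 2:gene_len_codons) {
      repeat {
        nxt <- sample(CODONS, 1, prob = T[cod[i - 1], ])
        if (!(nxt %in% STOP_CODONS)) break
      }
      cod[i] <- nxt
    }
    paste(cod, collapse = "")
  }
  n <- n_native + n_foreign
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- draw_gene(if (i <= n_native) native_T else foreign_T)
  }
  ids <- sprintf("gene_%03d", seq_len(n))
  labels <- c(rep("native", n_native), rep("foreign", n_foreign))
  list(sequences = stats::setNames(seqs, ids),
       labels = stats::setNames(labels, ids))
}

# ---- HGT trees -------------------------------------------------------------

# random rooted binary topology over the given labels, as a Newick string
random_binary_newick <- function(labels) {
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    i <- sample(length(nodes), 2)
    nodes[[i[1]]] <- paste0("(", nodes[[i[1]]], ",", nodes[[i[2]]], ")")
    nodes[[i[2]]] <- NULL
  }
  paste0(nodes[[1]], ";")
}

#' Generate gene trees with planted cross-kingdom transfer events
#'
#' Builds random rooted binary trees of one kingdom and grafts
#' `events_per_tree` small opposite-kingdom clades inside, each as the
#' new sibling of a background leaf, so that the grafted clade's sibling
#' and aunt leaf sets are purely donor-kingdom. At most one graft is
#' placed under any one parent node, keeping planted events mutually
#' non-interfering.
#'
#' @param n_trees Number of trees.
#' @param leaves_per_tree Background leaves per tree (>= 6).
#' @param events_per_tree Planted events per tree.
#' @param background `"bacterial"` or `"viral"` background kingdom.
#' @param clade_size_max Max leaves per grafted clade (default 2).
#' @param seed Integer seed.
#' @return List with `newick` (character vector, one tree per element)
#'   and `truth` data.frame (`tree_id`, `direction`, `recipients`).
#' @export
gen_hgt_trees <- function(n_trees, leaves_per_tree = 12L,
                          events_per_tree = 1L, background = "bacterial",
                          clade_size_max = 2L, seed = 1L) {
  stopifnot(leaves_per_tree >= 6)
  if (events_per_tree > floor(leaves_per_tree / 3))
    stop("events_per_tree too large for tree size")
  set.seed(seed)
  bg_pre <- if (background == "bacterial") "B" else "V"
  op_pre <- if (background == "bacterial") "V" else "B"
  direction <- if (background == "bacterial") "B_to_P" else "P_to_B"
  newicks <- character(n_trees)
  truth <- list()
  for (t in seq_len(n_trees)) {
    labs <- sprintf("%s_t%02d", bg_pre, seq_len(leaves_per_tree))
    nwk <- random_binary_newick(labs)
    tr <- ape::read.tree(text = nwk)
    parent <- rep(NA_integer_, leaves_per_tree + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    eligible <- seq_len(leaves_per_tree)
    for (e in seq_len(events_per_tree)) {
      if (length(eligible) == 0)
        stop("events_per_tree too large for tree size")
      tip <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      # protect the sibling/aunt context: drop every tip under this
      # tip's parent from further grafting
      p <- parent[tip]
      under_p <- which(vapply(seq_len(leaves_per_tree), function(x) {
        a <- x
        while (!is.na(a)) { if (a == p) return(TRUE); a <- parent[a] }
        FALSE
      }, logical(1)))
      eligible <- setdiff(eligible, under_p)
      m <- sample(clade_size_max, 1)
      glabs <- sprintf("%s_t%02de%d_%d", op_pre, t, e, seq_len(m))
      graft <- if (m == 1) glabs else random_binary_newick(glabs)
      graft <- sub(";$", "", graft)
      lab <- labs[tip]
      nwk <- sub(paste0("([(,])", lab, "([,)])"),
                 paste0("\\1(", graft, ",", lab, ")\\2"), nwk)
      truth[[length(truth) + 1L]] <- data.frame(
        tree_id = sprintf("tree_%03d", t), direction = direction,
        recipients = paste(sort(glabs), collapse = ","),
        stringsAsFactors = FALSE)
    }
    newicks[t] <- nwk
  }
  truth_df <- if (length(truth) == 0) {
    data.frame(tree_id = character(0), direction = character(0),
               recipients = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, truth)
  list(newick = stats::setNames(newicks, sprintf("tree_%03d", seq_len(n_trees))),
       truth = truth_df)
}

# ---- spacer library --------------------------------------------------------

#' Generate a CRISPR spacer library with known hosts
#'
#' True spacers are copied from random phage windows and mutated with
#' exactly `mismatches` substitutions, so each has a known host and a
#' known best Hamming distance. Decoy spacers are random sequences
#' verified (by an exhaustive two-strand scan) to have no window within
#' 2 mismatches in any phage.
#'
#' @param phages Named `DNAStringSet`.
#' @param n_true,n_decoys Spacer counts.
#' @param spacer_len Spacer length (<= shortest phage).
#' @param mismatches Substitutions implanted in each true spacer (0-2).
#' @param seed Integer seed.
#' @param max_retry Decoy verification retries before erroring.
#' @return List with `spacers` (named character) and `truth`
#'   (`spacer_id`, `host_phage_id`, `position`, `mismatches`).
#' @export
gen_spacer_library <- function(phages, n_true = 30L, spacer_len = 32L,
                               mismatches = 1L, n_decoys = 10L, seed = 1L,
                               max_retry = 50L) {
  stopifnot(mismatches >= 0, mismatches <= 2,
            spacer_len <= min(Biostrings::width(phages)))
  set.seed(seed)
  pseq <- as.character(phages)
  spacers <- character(0)
  rows <- vector("list", n_true)
  for (i in seq_len(n_true)) {
    host <- sample(names(pseq), 1)
    pos <- int_between(0L, nchar(pseq[[host]]) - spacer_len)
    sp <- substr(pseq[[host]], pos + 1, pos + spacer_len)
    if (mismatches > 0) {
      ch <- strsplit(sp, "")[[1]]
      at <- sample(spacer_len, mismatches)
      for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      sp <- paste(ch, collapse = "")
    }
    id <- sprintf("spacer_true_%03d", i)
    spacers[id] <- sp
    rows[[i]] <- data.frame(spacer_id = id, host_phage_id = host,
                            position = pos, mismatches = mismatches,
                            stringsAsFactors = FALSE)
  }
  gset <- Biostrings::DNAStringSet(pseq)
  for (i in seq_len(n_decoys)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cand <- random_seq(spacer_len)
      pat <- Biostrings::DNAString(cand)
      n_hit <- sum(Biostrings::vcountPattern(pat, gset, max.mismatch = 2)) +
        sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                      gset, max.mismatch = 2))
      if (n_hit == 0) { ok <- TRUE; break }
    }
    if (!ok) stop("could not generate a verified decoy spacer after ",
                  max_retry, " attempts")
    spacers[sprintf("spacer_decoy_%03d", i)] <- cand
  }
  list(spacers = spacers,
       truth = if (n_true > 0) do.call(rbind, rows) else
         data.frame(spacer_id = character(0), host_phage_id = character(0),
                    position = integer(0), mismatches = integer(0)))
}

# ---- abundance -------------------------------------------------------------

#' Generate a lognormal abundance matrix with coupled pairs
#'
#' Rows named in `coupled_pairs` are generated pairwise from a shared
#' latent Gaussian with correlation `coupling_rho`, then
#' exponentiated; all other rows are i.i.d. lognormal(mu, sigma). Note
#' the exponentiation attenuates the Pearson correlation on the
#' abundance scale below `coupling_rho` for large `sigma`.
#'
#' @param n_samples Number of samples (>= 3).
#' @param coupled_pairs `data.frame` with `phage_id`, `taxon_id`.
#' @param uncoupled_ids Extra feature ids with independent rows.
#' @param mu,sigma Lognormal parameters on the log scale.
#' @param coupling_rho Latent Gaussian correlation in `[0, 1]`.
#' @param seed Integer seed.
#' @return Numeric matrix (features x samples), all entries positive.
#' @export
gen_abundance_matrix <- function(n_samples = 91L, coupled_pairs = NULL,
                                 uncoupled_ids = character(0), mu = 0,
                                 sigma = 0.5, coupling_rho = 0.8,
                                 seed = 1L) {
  if (n_samples < 3) stop("need at least 3 samples")
  stopifnot(coupling_rho >= 0, coupling_rho <= 1)
  set.seed(seed)
  rows <- list()
  if (!is.null(coupled_pairs) && nrow(coupled_pairs) > 0) {
    # one latent per taxon; every phage coupled to that taxon shares it,
    # so each listed pair attains the requested latent correlation even
    # when a taxon hosts several phages (first listed taxon wins when a
    # phage appears more than once)
    cp <- coupled_pairs[!duplicated(coupled_pairs$phage_id), , drop = FALSE]
    latent <- list()
    for (b in unique(cp$taxon_id)) latent[[b]] <- rnorm(n_samples)
    for (b in unique(cp$taxon_id)) rows[[b]] <- exp(mu + sigma * latent[[b]])
    for (i in seq_len(nrow(cp))) {
      z <- coupling_rho * latent[[cp$taxon_id[i]]] +
        sqrt(1 - coupling_rho^2) * rnorm(n_samples)
      rows[[cp$phage_id[i]]] <- exp(mu + sigma * z)
    }
  }
  for (id in uncoupled_ids) {
    if (is.null(rows[[id]])) rows[[id]] <- rlnorm(n_samples, mu, sigma)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("sample_%02d", seq_len(n_samples))
  m
}
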