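#' Classify SVs as genetic-exchange-like
#'
#' An SV longer than `min_len` bp whose sequence aligns to a bacterial
#' genome with more than `min_id` percent identity over more than
#' `min_cov` of the SV length is labelled `GE_like` (evidence of
#' phage-bacteria genetic exchange); qualifying SVs without such a hit
#' are `noGE_like`; SVs of at most `min_len` bp are `too_short` and not
#' assessed. Coverage is computed on the SV sequence length
#' (`aln_length / sv_length`). The best hit maximises identity times
#' coverage.
#'
#' @param svs `data.frame` with at least `sv_id` and `length` (bp);
#'   a `contig` column (the carrying phage) is passed through if present.
#' @param hits Alignment hit table ([read_hits()]) with SV ids as
#'   queries and bacterial genome ids as subjects.
#' @param min_len Length below-or-equal which SVs are `too_short`
#'   (default 200 bp).
#' @param min_id Exclusive identity threshold in percent (default 80).
#' @param min_cov Exclusive coverage threshold as a fraction (default
#'   0.8).
#' @return `data.frame` with `sv_id`, `sv_length`, `label`,
#'   `best_subject`, `best_identity`, `best_coverage` and
#'   `matched_genomes` (comma-joined qualifying subjects), plus a
#'   `prophage_flag` column initialised to FALSE.
#' @export
classify_ge_svs <- function(svs, hits, min_len = 200L, min_id = 80,
                            min_cov = 0.8) {
  stopifnot(all(c("sv_id", "length") %in% names(svs)))
  unknown <- !(hits$query_id %in% svs$sv_id)
  if (any(unknown)) {
    warning(sprintf("%d hit(s) reference unknown SV ids; skipped",
                    sum(unknown)))
    hits <- hits[!unknown, , drop = FALSE]
  }
  n <- nrow(svs)
  out <- data.frame(sv_id = svs$sv_id, sv_length = svs$length,
                    label = rep_len("noGE_like", n),
                    best_subject = rep_len(NA_character_, n),
                    best_identity = rep_len(NA_real_, n),
                    best_coverage = rep_len(NA_real_, n),
                    matched_genomes = rep_len("", n),
                    prophage_flag = rep_len(FALSE, n),
                    stringsAsFactors = FALSE)
  if ("contig" %in% names(svs)) out$contig <- svs$contig
  out$label[out$sv_length <= min_len] <- "too_short"
  if (nrow(hits) > 0) {
    hl <- split(hits, hits$query_id)
    for (i in which(out$label != "too_short")) {
      h <- hl[[out$sv_id[i]]]
      if (is.null(h)) next
      cov <- h$aln_length / out$sv_length[i]
      qual <- h$pct_identity > min_id & cov > min_cov
      if (!any(qual)) next
      hq <- h[qual, , drop = FALSE]; covq <- cov[qual]
      best <- which.max(hq$pct_identity * covq)
      out$label[i] <- "GE_like"
      out$best_subject[i] <- hq$subject_id[best]
      out$best_identity[i] <- hq$pct_identity[best]
      out$best_coverage[i] <- covq[best]
      out$matched_genomes[i] <- paste(sort(unique(hq$subject_id)),
                                      collapse = ",")
    }
  }
  out
}

#' Flag GE-like SVs overlapping predicted prophage regions
#'
#' Homology between a phage SV and a bacterial genome may reflect an
#' integrated prophage rather than exchanged bacterial sequence. SVs with
#' an alignment to a prophage region at more than `min_id` percent
#' identity covering more than `min_cov` of the SV are flagged.
#'
#' @param ge Classification table from [classify_ge_svs()].
#' @param prophage_hits Hit table of SV sequences against prophage
#'   regions (queries = SV ids).
#' @param min_id,min_cov Thresholds (default 80 percent, 0.5).
#' @return `ge` with `prophage_flag` updated.
#' @export
flag_prophage_overlap <- function(ge, prophage_hits, min_id = 80,
                                  min_cov = 0.5) {
  if (nrow(prophage_hits) == 0) return(ge)
  idx <- match(prophage_hits$query_id, ge$sv_id)
  cov <- prophage_hits$aln_length / ge$sv_length[idx]
  qual <- !is.na(idx) & prophage_hits$pct_identity > min_id & cov > min_cov
  ge$prophage_flag[unique(idx[qual])] <- TRUE
  ge
}

#' Taxonomic rank of the last common ancestor of matched genomes
#'
#' Given the bacterial genomes matched by one SV, returns the deepest
#' rank (species > genus > ... > domain) at which all of them carry the
#' same, non-missing taxon. A single genome reports its deepest present
#' rank. Genomes disagreeing already at domain level return `"none"`.
#'
#' @param matched_genomes Character vector of genome ids.
#' @param lineages Lineage table ([read_lineages()]).
#' @return One rank label, or `"none"`.
#' @export
lca_range <- function(matched_genomes, lineages) {
  miss <- setdiff(matched_genomes, lineages$genome_id)
  if (length(miss) > 0)
    stop("no lineage for genome(s): ", paste(miss, collapse = ", "))
  rk <- lineages[match(matched_genomes, lineages$genome_id), LINEAGE_RANKS,
                 drop = FALSE]
  for (r in rev(LINEAGE_RANKS)) {
    v <- rk[[r]]
    if (!anyNA(v) && length(unique(v)) == 1) return(r)
  }
  "none"
}

# ---- codon-bias (HT index) -------------------------------------------------

#' All 64 codons in fixed lexicographic order
#' @export
CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                function(a, b) paste0(a, b)),
                          c("A", "C", "G", "T"), paste0))

split_codons <- function(seq, gene = "gene") {
  n <- nchar(seq)
  if (n %% 3 != 0 || n < 6)
    stop("gene length not a positive multiple of 3 (>= 2 codons): ", gene)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Train a codon-transition Markov model
#'
#' Pools adjacent in-frame codon pairs across all protein-coding genes of
#' a genome into a 64 x 64 transition-count matrix, adds a Laplace
#' pseudocount to every cell, and row-normalises. The resulting
#' first-order Markov chain captures the genome's neighbouring-codon
#' frequency bias and is the reference model for the HT index.
#'
#' @param genes Named character vector of gene nucleotide sequences
#'   (each a multiple of 3 long, at least 2 codons).
#' @param pseudocount Laplace smoothing constant (default 1).
#' @return List of class `codon_model` with `transition` (row-stochastic
#'   64 x 64), `initial` (length-64) and `pseudocount`.
#' @export
train_codon_model <- function(genes, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  counts <- matrix(0, 64, 64, dimnames = list(CODONS, CODONS))
  init <- stats::setNames(numeric(64), CODONS)
  nm <- names(genes)
  if (is.null(nm)) nm <- sprintf("gene%d", seq_along(genes))
  for (i in seq_along(genes)) {
    cod <- split_codons(toupper(genes[[i]]), nm[i])
    bad <- !(cod %in% CODONS)
    if (any(bad)) stop("non-ACGT codon in gene ", nm[i])
    init[cod[1]] <- init[cod[1]] + 1
    L <- length(cod)
    tr <- table(factor(cod[-L], CODONS), factor(cod[-1], CODONS))
    counts <- counts + as.matrix(tr)
  }
  trans <- (counts + pseudocount) / (rowSums(counts) + 64 * pseudocount)
  structure(list(transition = trans,
                 initial = (init + pseudocount) / (sum(init) + 64 * pseudocount),
                 pseudocount = pseudocount),
            class = "codon_model")
}

#' HT index of a gene under a codon model
#'
#' The mean log2 transition probability of the gene's in-frame codon
#' sequence under the genome's codon-transition Markov model:
#' \deqn{HT = \frac{1}{L-1} \sum_{i=1}^{L-1} \log_2 P(c_{i+1} \mid c_i)}
#' for a gene of L codons. Genes whose neighbouring-codon usage is
#' typical of the genome score high; compositionally alien (horizontally
#' acquired) genes score low. Under a uniform model every gene scores
#' exactly -6 (log2 of 1/64).
#'
#' @param gene Nucleotide sequence (multiple of 3, at least 2 codons).
#' @param model A `codon_model` from [train_codon_model()].
#' @return The HT index (a real number, typically negative).
#' @export
ht_index <- function(gene, model) {
  cod <- split_codons(toupper(gene))
  L <- length(cod)
  p <- model$transition[cbind(cod[-L], cod[-1])]
  mean(log2(p))
}

# ---- HGT directionality from tree topology ---------------------------------

#' Detect directed HGT events from cross-kingdom clade nesting
#'
#' Scans a rooted, kingdom-labelled gene tree for horizontal-transfer
#' signatures: a maximal clade of one kingdom nested inside the other
#' kingdom. For each maximal kingdom-pure clade C, let the sibling set S
#' be the leaves under the other children of C's parent and the aunt set
#' A the leaves under the other children of C's grandparent. An event
#' with recipients = leaves(C) and direction donor -> recipient kingdom
#' is reported when S is non-empty, every leaf of S and A belongs to the
#' opposite kingdom, and the parent node's support is at least
#' `min_support`. A clade whose parent is the root is one side of the
#' basal split and never counts as nested (so a clean kingdom
#' bipartition yields no events). Bacterial leaves nested in a viral
#' context give a P_to_B event; viral leaves nested in a bacterial
#' context give B_to_P.
#'
#' @param tree Rooted `phylo` object with kingdom-prefixed leaf labels.
#' @param prefixes Kingdom prefix map (see [read_kingdom_trees()]).
#' @param min_support Minimum support of the parent node (default 0; node
#'   labels must be numeric for this to have effect).
#' @param per_leaf If TRUE, report one event per recipient leaf instead
#'   of one per nested clade.
#' @return `data.frame` with `direction` (`B_to_P` / `P_to_B`),
#'   `recipients` (comma-joined leaf labels), `context` (comma-joined
#'   sibling+aunt leaves) and `support`.
#' @export
detect_hgt_events <- function(tree, prefixes = c(bacterial = "B_",
                                                 viral = "V_"),
                              min_support = 0, per_leaf = FALSE) {
  king <- leaf_kingdoms(tree, prefixes)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # leaves under each node
  leaves_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], leaves_under))
  }
  node_leaves <- lapply(seq_len(ntip + nnode), leaves_under)
  node_king <- vapply(node_leaves, function(lv) {
    kg <- unique(king[tree$tip.label[lv]])
    if (length(kg) == 1) kg else NA_character_
  }, character(1))
  support <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$node.label)) {
    support[ntip + seq_len(nnode)] <-
      suppressWarnings(as.numeric(tree$node.label))
  }
  events <- list()
  for (node in seq_len(ntip + nnode)) {
    kg <- node_king[node]
    if (is.na(kg)) next
    p <- parent[node]
    if (is.na(p)) next                       # the root: whole tree pure
    if (!is.na(node_king[p]) && node_king[p] == kg) next  # not maximal
    sibs <- setdiff(kids[[as.character(p)]], node)
    S <- tree$tip.label[unlist(node_leaves[sibs])]
    if (length(S) == 0) next
    gp <- parent[p]
    # a clade whose parent is the root is one side of the basal split,
    # not a nested clade
    if (is.na(gp)) next
    A <- tree$tip.label[unlist(node_leaves[setdiff(kids[[as.character(gp)]], p)])]
    other <- setdiff(c("bacterial", "viral"), kg)
    if (!all(king[c(S, A)] == other)) next
    sup <- support[p]
    if (!is.na(sup) && sup < min_support) next
    if (is.na(sup) && min_support > 0) next
    dir <- if (kg == "viral") "B_to_P" else "P_to_B"
    rec <- sort(tree$tip.label[node_leaves[[node]]])
    events[[length(events) + 1L]] <- data.frame(
      direction = dir, recipients = paste(rec, collapse = ","),
      context = paste(sort(c(S, A)), collapse = ","),
      support = if (is.na(sup)) NA_real_ else sup,
      stringsAsFactors = FALSE)
  }
  out <- if (length(events) == 0) {
    data.frame(direction = character(0), recipients = character(0),
               context = character(0), support = numeric(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, events)
  if (per_leaf && nrow(out) > 0) {
    reps <- strsplit(out$recipients, ",")
    out <- out[rep(seq_len(nrow(out)), lengths(reps)), , drop = FALSE]
    out$recipients <- unlist(reps)
    rownames(out) <- NULL
  }
  out
}

# ---- CRISPR spacer matching ------------------------------------------------

#' Match CRISPR spacers against phage genomes
#'
#' Finds every full-length, gap-free occurrence of each spacer in each
#' genome (both strands) with at most `max_mismatch` substitutions. `N`
#' in a spacer or genome window always counts as a mismatch. The
#' full-length no-indel rule enforces the conventional >95%-identity
#' requirement for spacers of 41 bp and longer; for shorter spacers the
#' per-hit mismatch count is reported so callers can tighten it.
#'
#' @param spacers Named character vector or `DNAStringSet` of spacers.
#' @param genomes Named character vector or `DNAStringSet` of phage
#'   genomes.
#' @param max_mismatch Maximum substitutions (default 2).
#' @return `data.frame` with `spacer_id`, `genome_id`, `position`
#'   (0-based on the forward strand), `strand`, `mismatches`,
#'   `matched_len`.
#' @export
match_spacers <- function(spacers, genomes, max_mismatch = 2L) {
  if (inherits(spacers, "XStringSet")) spacers <- as.character(spacers)
  if (inherits(genomes, "XStringSet")) genomes <- as.character(genomes)
  stopifnot(!is.null(names(spacers)), !is.null(names(genomes)))
  res <- list()
  gset <- Biostrings::DNAStringSet(genomes)
  for (si in seq_along(spacers)) {
    sp <- Biostrings::DNAString(spacers[[si]])
    splen <- length(sp)
    for (gi in seq_along(genomes)) {
      glen <- nchar(genomes[[gi]])
      if (glen < splen) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else Biostrings::reverseComplement(sp)
        m <- Biostrings::matchPattern(pat, gset[[gi]],
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) == 0) next
        starts <- Biostrings::start(m)
        win <- substring(genomes[[gi]], starts, starts + splen - 1L)
        mm <- hamming_with_n(as.character(pat), win)
        ok <- mm <= max_mismatch
        if (!any(ok)) next
        res[[length(res) + 1L]] <- data.frame(
          spacer_id = names(spacers)[si], genome_id = names(genomes)[gi],
          position = starts[ok] - 1L, strand = strand,
          mismatches = mm[ok], matched_len = splen,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(spacer_id = character(0), genome_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), matched_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$spacer_id, out$genome_id, out$position, out$strand), ,
      drop = FALSE]
}

# Hamming distance of `pat` against each window string; N never matches.
hamming_with_n <- function(pat, windows) {
  pc <- strsplit(pat, "")[[1]]
  vapply(strsplit(windows, ""), function(w) {
    sum(w != pc | w == "N" | pc == "N")
  }, integer(1))
}

#' Phage -> host taxon table from spacer hits
#'
#' @param hits Output of [match_spacers()].
#' @param spacer_sources Named character vector mapping spacer id to its
#'   source bacterial taxon.
#' @return `data.frame` with `genome_id` (phage) and comma-joined
#'   `host_taxa`.
#' @export
spacer_host_table <- function(hits, spacer_sources) {
  if (nrow(hits) == 0)
    return(data.frame(genome_id = character(0), host_taxa = character(0),
                      stringsAsFactors = FALSE))
  taxa <- spacer_sources[hits$spacer_id]
  agg <- tapply(taxa, hits$genome_id, function(x)
    paste(sort(unique(x)), collapse = ","))
  data.frame(genome_id = names(agg), host_taxa = unname(agg),
             stringsAsFactors = FALSE)
}
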