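#' Simulate a complete synthetic phage-SV cohort
#'
#' Produces every input the pipeline consumes, with ground truth for
#' every downstream stage: reference phage genomes with implanted truth
#' SVs (a subset of the insertions carrying bacteria-derived segments),
#' per-sample noisy callsets from four simulated callers, bacterial
#' genomes with lineages, gene annotations, codon-model gene sets,
#' kingdom-labelled gene trees with planted transfer events, a CRISPR
#' spacer library, lifestyle labels, and a phage/genus abundance matrix
#' whose exchange pairs are coupled.
#'
#' @param n_genomes Reference phage genomes.
#' @param genome_len Length range (bp).
#' @param gc GC content.
#' @param n_samples Number of sequenced samples.
#' @param sv_counts Truth SV counts by type.
#' @param sv_len Truth SV length range (bp).
#' @param n_bacteria Bacterial genomes.
#' @param bact_len Bacterial genome length range (bp).
#' @param n_exchange Number of truth insertions rewritten as
#'   bacteria-derived transfer events.
#' @param exchange_subst Substitution rate applied to transferred
#'   segments.
#' @param profiles Caller noise profiles.
#' @param n_trees,leaves_per_tree,events_per_tree Gene-tree simulation.
#' @param n_spacers,spacer_len,spacer_mismatch,n_decoys Spacer library.
#' @param n_abund_samples Abundance matrix columns.
#' @param coupling_rho Latent abundance coupling of exchange pairs.
#' @param abund_sigma Lognormal sigma (log scale).
#' @param temperate_frac Fraction of phages labelled temperate.
#' @param temperate_weight Relative SV load of temperate phages.
#' @param genes_per_genome Annotated genes per phage genome.
#' @param seed Master seed; all internal seeds derive from it.
#' @return A list of class `phage_cohort`.
#' @export
simulate_cohort <- function(n_genomes = 50L, genome_len = c(30000L, 60000L),
                            gc = 0.45, n_samples = 5L,
                            sv_counts = c(INS = 150L, DEL = 150L,
                                          DUP = 50L, INV = 50L),
                            sv_len = c(100L, 1000L),
                            n_bacteria = 20L, bact_len = c(50000L, 80000L),
                            n_exchange = 40L, exchange_subst = 0.05,
                            profiles = default_caller_profiles(),
                            n_trees = 100L, leaves_per_tree = 12L,
                            events_per_tree = 1L,
                            n_spacers = 30L, spacer_len = 32L,
                            spacer_mismatch = 1L, n_decoys = 10L,
                            n_abund_samples = 91L, coupling_rho = 0.8,
                            abund_sigma = 0.5,
                            temperate_frac = 0.5, temperate_weight = 2,
                            genes_per_genome = 15L, seed = 1L) {
  set.seed(seed)
  sd_ <- sample.int(.Machine$integer.max - 1L, 30)

  phages <- gen_phage_genomes(n_genomes, genome_len[1], genome_len[2], gc,
                              seed = sd_[1])
  bacteria <- gen_phage_genomes(n_bacteria, bact_len[1], bact_len[2], gc,
                                seed = sd_[2], prefix = "bact")
  lineages <- synth_lineages(names(bacteria), seed = sd_[3])

  set.seed(sd_[4])
  lifestyle <- stats::setNames(
    ifelse(runif(n_genomes) < temperate_frac, "temperate", "virulent"),
    names(phages))
  weights <- ifelse(lifestyle == "temperate", temperate_weight, 1)

  imp <- implant_svs(phages, sv_counts, sv_len, seed = sd_[5],
                     genome_weights = weights)
  truth <- imp$truth

  ex <- assign_exchange_to_ins(truth, bacteria, n_exchange,
                               exchange_subst, seed = sd_[6])
  truth <- ex$truth
  sample_genomes <- apply_truth_svs(phages, truth)

  contig_lengths <- stats::setNames(Biostrings::width(phages), names(phages))
  sample_ids <- sprintf("S%d", seq_len(n_samples))
  callsets <- lapply(seq_len(n_samples), function(s)
    simulate_caller_vcfs(truth, profiles, contig_lengths,
                         sample = sample_ids[s], seed = sd_[6 + s]))
  names(callsets) <- sample_ids

  genes <- synth_gene_annotations(contig_lengths, truth,
                                  genes_per_genome = genes_per_genome,
                                  seed = sd_[15])

  native_T <- random_codon_matrix(seed = sd_[16], concentration = 0.3)
  foreign_T <- random_codon_matrix(seed = sd_[17], concentration = 0.3)
  ht_genes <- gen_codon_genes(native_T, foreign_T, 50L, 50L, 300L,
                              seed = sd_[18])

  trees <- gen_hgt_trees(n_trees, leaves_per_tree, events_per_tree,
                         seed = sd_[19])
  spacer_lib <- gen_spacer_library(phages, n_spacers, spacer_len,
                                   spacer_mismatch, n_decoys, seed = sd_[20])
  set.seed(sd_[21])
  spacer_sources <- stats::setNames(
    sample(unique(lineages$genus), length(spacer_lib$spacers), replace = TRUE),
    names(spacer_lib$spacers))

  donor_genus <- lineages$genus[match(ex$events$donor_genome_id,
                                      lineages$genome_id)]
  coupled <- data.frame(phage_id = ex$events$recipient_phage_id,
                        taxon_id = donor_genus, stringsAsFactors = FALSE)
  # one coupled genus per phage: the first donor wins, matching the
  # abundance generator's coupling semantics
  coupled <- coupled[!duplicated(coupled$phage_id), , drop = FALSE]
  abundance <- gen_abundance_matrix(
    n_abund_samples, coupled,
    uncoupled_ids = c(setdiff(names(phages), coupled$phage_id),
                      setdiff(unique(lineages$genus), coupled$taxon_id)),
    sigma = abund_sigma, coupling_rho = coupling_rho, seed = sd_[22])

  structure(list(
    phages = phages, bacteria = bacteria, lineages = lineages,
    lifestyle = lifestyle, contig_lengths = contig_lengths,
    truth = truth, sample_genomes = sample_genomes,
    exchange_events = ex$events, exchange_hits = ex$hits,
    callsets = callsets, genes = genes,
    codon_models = list(native = native_T, foreign = foreign_T),
    ht_genes = ht_genes, trees = trees,
    spacers = spacer_lib$spacers, spacer_truth = spacer_lib$truth,
    spacer_sources = spacer_sources,
    coupled_pairs = coupled, abundance = abundance,
    params = list(seed = seed, n_samples = n_samples,
                  coupling_rho = coupling_rho)),
    class = "phage_cohort")
}

# Rewrite a subset of truth INS alt sequences as mutated bacterial
# segments; emits the transfer events and a ground-truth-exact hit table
# keyed by truth record id.
assign_exchange_to_ins <- function(truth, bacteria, n_events, subst_rate,
                                   seed = 1L, min_len = 250L) {
  set.seed(seed)
  elig <- which(truth$svtype == "INS" & truth$length > min_len)
  if (length(elig) < n_events) {
    warning("only ", length(elig), " insertions eligible for exchange; ",
            "using all of them")
    n_events <- length(elig)
  }
  pick <- sort(sample(elig, n_events))
  bseq <- as.character(bacteria)
  blen <- nchar(bseq)
  events <- vector("list", n_events)
  hits <- vector("list", n_events)
  for (j in seq_along(pick)) {
    i <- pick[j]
    len <- truth$length[i]
    donor <- sample(names(bseq)[blen >= len], 1)
    dstart <- sample(0:(blen[[donor]] - len), 1)
    seg <- substr(bseq[[donor]], dstart + 1, dstart + len)
    mut <- mutate_seq(seg, subst_rate)
    truth$alt_seq[i] <- mut$seq
    events[[j]] <- data.frame(
      event_id = truth$record_id[i], donor_genome_id = donor,
      recipient_phage_id = truth$contig[i], donor_start = dstart,
      donor_len = len, insert_pos = truth$start[i],
      subst_rate = subst_rate, n_sub = mut$n_sub, stringsAsFactors = FALSE)
    hits[[j]] <- exchange_hit_row(truth$record_id[i], donor, len,
                                  mut$n_sub, dstart)
  }
  list(truth = truth,
       events = if (n_events > 0) do.call(rbind, events) else
         data.frame(event_id = character(0), donor_genome_id = character(0),
                    recipient_phage_id = character(0)),
       hits = if (n_events > 0) do.call(rbind, hits) else empty_hits())
}

# simple bacterial taxonomy: two species per genus, shared upper ranks
synth_lineages <- function(genome_ids, seed = 1L, species_per_genus = 2L) {
  set.seed(seed)
  n <- length(genome_ids)
  genus <- sprintf("genus_%02d", ceiling(seq_len(n) / species_per_genus))
  family <- sprintf("family_%02d", ceiling(seq_len(n) / (2 * species_per_genus)))
  data.frame(genome_id = genome_ids, domain = "Bacteria",
             phylum = "Bacillota", class = "Clostridia",
             order = "Eubacteriales", family = family, genus = genus,
             species = sprintf("%s sp%02d", genus, seq_len(n)),
             stringsAsFactors = FALSE)
}

# tile genes along each genome with random functional categories; genes
# hitting a bacteria-derived insertion breakpoint are labelled bacterial
synth_gene_annotations <- function(contig_lengths, truth,
                                   genes_per_genome = 15L, seed = 1L) {
  set.seed(seed)
  lvl2 <- c("DNA replication", "integration/excision", "transposition",
            "defense systems", "capsid assembly", "tail fiber",
            "lysis", "regulation", "unknown function")
  lvl1 <- stats::setNames(
    c("replication", "mobile element", "mobile element", "defense",
      "structure", "structure", "lysis", "regulation", "unknown"),
    lvl2)
  rows <- list()
  for (g in names(contig_lengths)) {
    L <- contig_lengths[[g]]
    glen <- pmax(300L, round(rnorm(genes_per_genome, 900, 150)))
    gap <- floor(L / genes_per_genome)
    starts <- (seq_len(genes_per_genome) - 1L) * gap +
      sample(0:max(1, gap - max(glen) - 1), genes_per_genome, replace = TRUE)
    ends <- pmin(starts + glen, L)
    keep <- ends > starts
    cat2 <- sample(lvl2, genes_per_genome, replace = TRUE)
    rows[[g]] <- data.frame(
      genome_id = g, start = starts[keep], end = ends[keep],
      strand = sample(c("+", "-"), sum(keep), replace = TRUE),
      gene_id = sprintf("%s_g%02d", g, seq_len(sum(keep))),
      level1_category = unname(lvl1[cat2[keep]]),
      level2_category = cat2[keep],
      source = "viral", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  genes
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Exercises every stage end-to-end: Mash-distance reference
#' prefiltering, per-sample multi-caller CAST merging, cohort-level
#' nonredundant SV construction, benchmarking against the implanted
#' truth, genetic-exchange classification with interaction ranges,
#' HT-index scoring, tree-based HGT direction calls, CRISPR-spacer host
#' prediction, and cohort statistics (SV density, gene overlap,
#' functional enrichment, lifestyle comparison, sharing network with
#' abundance correlations).
#'
#' @param cohort A `phage_cohort` from [simulate_cohort()].
#' @param params [merge_params()].
#' @param mparams [match_params()] for truth matching.
#' @param sketch_k,sketch_s Sketch parameters for the prefilter stage.
#' @return List of class `pipeline_result`; see the vignette for the
#'   component tables.
#' @export
run_pipeline <- function(cohort, params = merge_params(),
                         mparams = match_params(),
                         sketch_k = 21L, sketch_s = 1000L) {
  stopifnot(inherits(cohort, "phage_cohort"))

  # reference prefilter: each sample-assembly constituent against the
  # reference catalog; a reference is retained when close to any
  # constituent
  ref_sketches <- lapply(seq_along(cohort$phages), function(i)
    sketch_sequence(as.character(cohort$phages[i]), sketch_k, sketch_s))
  names(ref_sketches) <- names(cohort$phages)
  sel <- lapply(seq_along(cohort$sample_genomes), function(i)
    select_references(ref_sketches,
                      sketch_sequence(as.character(cohort$sample_genomes[i]),
                                      sketch_k, sketch_s)))
  sel <- do.call(rbind, sel)
  prefilter <- stats::aggregate(list(distance = sel$distance),
                                list(genome_id = sel$genome_id), min)
  prefilter <- prefilter[order(prefilter$genome_id), , drop = FALSE]

  # per-sample merge, then cohort-level nonredundant set
  retained <- prefilter$genome_id
  per_sample <- lapply(cohort$callsets, function(cs) {
    cs <- lapply(cs, function(df) df[df$contig %in% retained, , drop = FALSE])
    merge_sample(cs, cohort$contig_lengths, params)
  })
  nonredundant <- merge_cohort(per_sample, params)

  # benchmark against truth
  matching <- match_callsets(cohort$truth, nonredundant, mparams)
  metrics <- benchmark_metrics(matching, cohort$truth, nonredundant)
  seen2 <- truth_seen_by_two(cohort)
  eligible_recall <- if (length(seen2) == 0) NA_real_ else
    mean(seen2 %in% matching$truth_id)
  supported <- calls_with_truth_support(cohort$truth, nonredundant, mparams)
  precision_any <- if (nrow(nonredundant) == 0) NA_real_ else mean(supported)

  # genetic-exchange classification on the nonredundant set
  hits <- cohort$exchange_hits
  id_map <- stats::setNames(matching$call_id, matching$truth_id)
  hits$query_id <- unname(id_map[hits$query_id])
  hits <- hits[!is.na(hits$query_id), , drop = FALSE]
  svs <- data.frame(sv_id = nonredundant$record_id,
                    length = nonredundant$length,
                    contig = nonredundant$contig, stringsAsFactors = FALSE)
  ge <- classify_ge_svs(svs, hits)
  ge_ranges <- vapply(which(ge$label == "GE_like"), function(i)
    lca_range(strsplit(ge$matched_genomes[i], ",")[[1]], cohort$lineages),
    character(1))

  # HT index: genome model from native genes, scored on all genes
  model <- train_codon_model(
    cohort$ht_genes$sequences[cohort$ht_genes$labels == "native"])
  ht <- vapply(cohort$ht_genes$sequences, ht_index, numeric(1),
               model = model)
  ht_tab <- data.frame(gene_id = names(ht), label = cohort$ht_genes$labels,
                       ht_index = unname(ht), stringsAsFactors = FALSE)

  # HGT direction calls on all gene trees
  hgt <- do.call(rbind, lapply(names(cohort$trees$newick), function(tid) {
    tr <- read_kingdom_trees(text = cohort$trees$newick[[tid]])[[1]]
    ev <- detect_hgt_events(tr)
    if (nrow(ev) > 0) ev$tree_id <- tid
    ev
  }))
  if (is.null(hgt)) hgt <- data.frame(direction = character(0),
                                      recipients = character(0),
                                      tree_id = character(0))
  hgt_recovery <- score_hgt_recovery(hgt, cohort$trees$truth)

  # spacer host prediction
  spacer_hits <- match_spacers(cohort$spacers, cohort$phages)
  hosts <- spacer_host_table(spacer_hits, cohort$spacer_sources)

  # cohort statistics
  counts <- table(factor(nonredundant$contig, levels = names(cohort$phages)))
  density <- sv_density(stats::setNames(as.integer(counts), names(counts)),
                        cohort$contig_lengths)
  genes <- gene_sv_overlap(cohort$genes, nonredundant)
  enrichment <- functional_enrichment(genes)
  lifestyle_cmp <- compare_lifestyles(density, cohort$lifestyle)
  network <- build_sharing_network(ge, cohort$lineages)
  net_cor <- abundance_correlations(cohort$abundance, network)

  structure(list(
    prefilter = prefilter, per_sample = per_sample,
    nonredundant = nonredundant, matching = matching, metrics = metrics,
    eligible_recall = eligible_recall, precision_any = precision_any,
    ge = ge, ge_ranges = ge_ranges,
    ht = ht_tab, hgt = hgt, hgt_recovery = hgt_recovery,
    spacer_hits = spacer_hits, hosts = hosts, density = density,
    genes = genes, enrichment = enrichment, lifestyle = lifestyle_cmp,
    network = network, abundance_r = net_cor),
    class = "pipeline_result")
}

# truth ids emitted by >= 2 distinct callers in at least one sample
truth_seen_by_two <- function(cohort) {
  ids <- character(0)
  for (cs in cohort$callsets) {
    emitted <- do.call(rbind, lapply(cs, function(df)
      df[!is.na(df$truth_id), c("truth_id", "caller")]))
    tab <- tapply(emitted$caller, emitted$truth_id,
                  function(x) length(unique(x)))
    ids <- union(ids, names(tab)[tab >= 2])
  }
  ids
}

# fraction of planted transfer events recovered with matching recipients
# and direction
score_hgt_recovery <- function(calls, truth) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(calls$tree_id == truth$tree_id[i] &
          calls$direction == truth$direction[i] &
          calls$recipients == truth$recipients[i])
  }, logical(1))
  mean(hit)
}

#' Write a synthetic cohort to a directory of standard-format files
#'
#' Emits reference and sample FASTA, truth and per-caller VCFs, the
#' exchange hit table (BLAST tabular), Newick trees, spacer FASTA,
#' lineage and abundance TSV — the on-disk shape the pipeline's readers
#' consume.
#'
#' @param cohort A `phage_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genomes(cohort$phages, file.path(dir, "phages.fasta"))
  write_genomes(cohort$bacteria, file.path(dir, "bacteria.fasta"))
  write_genomes(cohort$sample_genomes, file.path(dir, "sample_genomes.fasta"))
  write_sv_vcf(cohort$truth, file.path(dir, "truth.vcf"),
               cohort$contig_lengths)
  for (s in names(cohort$callsets)) {
    for (cl in names(cohort$callsets[[s]])) {
      write_sv_vcf(cohort$callsets[[s]][[cl]],
                   file.path(dir, sprintf("%s_%s.vcf", s, cl)),
                   cohort$contig_lengths)
    }
  }
  write_hits(cohort$exchange_hits, file.path(dir, "exchange_hits.tsv"))
  writeLines(unname(cohort$trees$newick), file.path(dir, "gene_trees.nwk"))
  write_genomes(Biostrings::DNAStringSet(cohort$spacers),
                file.path(dir, "spacers.fasta"))
  write.table(cohort$lineages, file.path(dir, "lineages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  write.table(cohort$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
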