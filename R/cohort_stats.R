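#' SV density per genome
#'
#' Number of SVs per 1 Mb of genome: `count * 1e6 / length`.
#'
#' @param sv_counts Named integer vector of SV counts per genome.
#' @param genome_lengths Named integer vector of genome lengths (bp).
#' @return Named numeric vector of densities, one per entry of
#'   `sv_counts`.
#' @export
sv_density <- function(sv_counts, genome_lengths) {
  miss <- setdiff(names(sv_counts), names(genome_lengths))
  if (length(miss) > 0)
    stop("genome length missing for: ", paste(miss, collapse = ", "))
  len <- genome_lengths[names(sv_counts)]
  if (any(len <= 0)) stop("genome lengths must be positive")
  sv_counts * 1e6 / len
}

#' Label genes as lying in SV or conserved regions
#'
#' A gene is in an SV region when its half-open interval intersects a
#' DEL/DUP/INV interval by at least 1 bp, or contains the breakpoint
#' (start position) of an INS; otherwise it is conserved.
#'
#' @param genes `data.frame` with `genome_id`, `start`, `end` (0-based
#'   half-open) and `gene_id`.
#' @param svs SV record `data.frame` (contigs named like `genome_id`).
#' @return `genes` with a `region` column (`"SV"` or `"conserved"`).
#' @export
gene_sv_overlap <- function(genes, svs) {
  genes$region <- "conserved"
  if (nrow(svs) > 0 && nrow(genes) > 0) {
    sv_start <- svs$start
    sv_end <- ifelse(svs$svtype == "INS", svs$start + 1L,
                     svs$start + svs$length)
    for (g in unique(genes$genome_id)) {
      gi <- which(genes$genome_id == g)
      si <- which(svs$contig == g)
      if (length(si) == 0) next
      gr <- IRanges::IRanges(start = genes$start[gi] + 1L,
                             end = genes$end[gi])
      sr <- IRanges::IRanges(start = sv_start[si] + 1L, end = sv_end[si])
      hit <- IRanges::overlapsAny(gr, sr, minoverlap = 1L)
      genes$region[gi[hit]] <- "SV"
    }
  }
  genes
}

#' Functional-category enrichment in SV regions
#'
#' For every level-2 functional category, tests whether genes of that
#' category are over-represented among SV-region genes relative to
#' conserved-region genes, using a one-sided Fisher's exact test on the
#' 2x2 table (category/other x SV/conserved). P values are adjusted
#' across all tested categories with the Benjamini-Hochberg FDR.
#'
#' @param genes `data.frame` with `region` (from [gene_sv_overlap()]) and
#'   `level2_category` columns.
#' @param categories Categories to test (default: all present).
#' @return `data.frame` sorted by `q` with columns `category`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `q`. `a` counts category genes in SV
#'   regions; `d` other genes in conserved regions.
#' @export
functional_enrichment <- function(genes, categories = NULL) {
  stopifnot(all(genes$region %in% c("SV", "conserved")))
  if (is.null(categories)) categories <- sort(unique(genes$level2_category))
  in_sv <- genes$region == "SV"
  rows <- lapply(categories, function(cat) {
    inc <- genes$level2_category == cat
    a <- sum(inc & in_sv); b <- sum(!inc & in_sv)
    cc <- sum(inc & !in_sv); d <- sum(!inc & !in_sv)
    p <- if (a + cc == 0) 1 else
      stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.frame(category = cat, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$category), , drop = FALSE]
}

#' Compare SV density between phage lifestyles
#'
#' Two-sided Mann-Whitney U test of per-genome SV density between
#' temperate and virulent phages. The exact null distribution is used
#' when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param density Named numeric vector of per-genome SV densities.
#' @param lifestyle Named character vector (`"temperate"` /
#'   `"virulent"`), aligned by genome name.
#' @return List with `U` (first group), `p`, `median_temperate`,
#'   `median_virulent`, `method`.
#' @export
compare_lifestyles <- function(density, lifestyle) {
  lifestyle <- lifestyle[names(density)]
  x <- density[lifestyle == "temperate"]
  y <- density[lifestyle == "virulent"]
  if (length(x) == 0 || length(y) == 0)
    stop("both lifestyle groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       median_temperate = stats::median(x),
       median_virulent = stats::median(y),
       method = if (exact) "exact" else "normal approximation")
}

#' Phage-bacteria SV-sharing network
#'
#' One edge per (phage, bacterial genus) pair, weighted by the number of
#' that phage's GE-like SVs with at least one qualifying hit to any
#' genome of the genus. Genomes lacking a genus assignment are
#' attributed to their deepest available rank with a warning.
#'
#' @param ge Classification table from [classify_ge_svs()]; must carry a
#'   `contig` column naming the phage of each SV.
#' @param lineages Lineage table for the matched bacterial genomes.
#' @return `data.frame` with `phage_id`, `bacterial_taxon`,
#'   `shared_sv_count`.
#' @export
build_sharing_network <- function(ge, lineages) {
  stopifnot("contig" %in% names(ge))
  gel <- ge[ge$label == "GE_like", , drop = FALSE]
  if (nrow(gel) == 0)
    return(data.frame(phage_id = character(0), bacterial_taxon = character(0),
                      shared_sv_count = integer(0), stringsAsFactors = FALSE))
  genus_of <- function(gid) {
    row <- lineages[match(gid, lineages$genome_id), ]
    if (!is.na(row$genus)) return(row$genus)
    pres <- rev(LINEAGE_RANKS)[!is.na(rev(unlist(row[LINEAGE_RANKS])))]
    warning("genome ", gid, " lacks genus; using deepest available rank")
    if (length(pres) == 0) return(NA_character_)
    as.character(row[[pres[1]]])
  }
  pairs <- list()
  for (i in seq_len(nrow(gel))) {
    gids <- strsplit(gel$matched_genomes[i], ",")[[1]]
    taxa <- unique(vapply(gids, genus_of, character(1)))
    taxa <- taxa[!is.na(taxa)]
    if (length(taxa) > 0)
      pairs[[length(pairs) + 1L]] <- data.frame(
        phage_id = gel$contig[i], bacterial_taxon = taxa,
        stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0)
    return(data.frame(phage_id = character(0), bacterial_taxon = character(0),
                      shared_sv_count = integer(0), stringsAsFactors = FALSE))
  pp <- do.call(rbind, pairs)
  agg <- stats::aggregate(list(shared_sv_count = rep(1L, nrow(pp))),
                          pp[, c("phage_id", "bacterial_taxon")], sum)
  agg[order(agg$phage_id, agg$bacterial_taxon), , drop = FALSE]
}

#' Abundance correlations along network edges
#'
#' Computes, for every network edge, the Pearson correlation across
#' samples between the phage's and the bacterial taxon's abundance rows,
#' and summarises the relationship between edge weight (shared SV count)
#' and pairwise abundance correlation as one overall Pearson r.
#'
#' @param mat Abundance matrix (features x samples).
#' @param edges Network table from [build_sharing_network()].
#' @return List with `edges` (input plus `abundance_r`, NA when either
#'   row has zero variance or is absent) and `summary_r`.
#' @export
abundance_correlations <- function(mat, edges) {
  if (ncol(mat) < 3) stop("need at least 3 samples for correlations")
  r <- rep(NA_real_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    p <- edges$phage_id[i]; b <- edges$bacterial_taxon[i]
    if (!(p %in% rownames(mat)) || !(b %in% rownames(mat))) next
    x <- mat[p, ]; y <- mat[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i] <- stats::cor(x, y)
  }
  edges$abundance_r <- r
  ok <- !is.na(r)
  summary_r <- if (sum(ok) >= 3 && stats::sd(edges$shared_sv_count[ok]) > 0 &&
                   stats::sd(r[ok]) > 0)
    stats::cor(edges$shared_sv_count[ok], r[ok]) else NA_real_
  list(edges = edges, summary_r = summary_r)
}
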