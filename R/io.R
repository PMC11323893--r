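#' Read genome sequences from FASTA
#'
#' Sequences are uppercased and identifiers truncated at the first
#' whitespace. Letters outside `{A,C,G,T,N}` are replaced by `N` with a
#' warning, so downstream k-mer and matching code sees a clean
#' nucleotide alphabet.
#'
#' @param path FASTA file, plain or gzipped.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genomes <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  if (any(cleaned != seqs)) {
    warning(sprintf("%d sequence(s) contained non-ACGTN letters; replaced with N",
                    sum(cleaned != seqs)))
  }
  out <- Biostrings::DNAStringSet(cleaned)
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

HITS_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatches", "gap_opens", "qstart", "qend", "sstart",
               "send", "evalue", "bitscore")

#' Read a 12-column tabular alignment hit table
#'
#' The column layout is the standard BLAST tabular (outfmt 6) dialect:
#' query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, E-value, bit score. Rows with the
#' wrong column count or a non-integer alignment length are rejected with
#' a summary warning. Reverse-orientation subject coordinates
#' (sstart > send) are preserved as-is.
#'
#' @param path Tab-separated file without header.
#' @return A `data.frame` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 12
  alnlen <- suppressWarnings(as.numeric(vapply(
    parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")))
  ok <- ok & !is.na(alnlen) & alnlen == floor(alnlen)
  if (any(!ok)) {
    warning(sprintf("rejected %d malformed hit row(s)", sum(!ok)))
    parts <- parts[ok]
  }
  if (length(parts) == 0) return(empty_hits())
  m <- do.call(rbind, parts)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  df
}

empty_hits <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   pct_identity = numeric(0), aln_length = integer(0),
                   mismatches = integer(0), gap_opens = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Write an alignment hit table
#' @param hits Hit `data.frame` as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits[, HITS_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read rooted, kingdom-labelled gene trees from Newick
#'
#' Each leaf must carry a kingdom prefix in its label (default `B_` for
#' bacterial and `V_` for viral taxa); a leaf matching neither prefix is
#' an error naming the leaf. Internal node labels, when numeric, are
#' interpreted as support values.
#'
#' @param path Newick file with one or more trees (or a character vector
#'   of Newick strings via `text`).
#' @param text Optional Newick text, used instead of `path`.
#' @param prefixes Named character vector mapping kingdom to label
#'   prefix.
#' @return A list of [ape::read.tree] `phylo` objects.
#' @export
read_kingdom_trees <- function(path = NULL, text = NULL,
                               prefixes = c(bacterial = "B_", viral = "V_")) {
  trees <- if (is.null(text)) ape::read.tree(path) else
    ape::read.tree(text = paste(text, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  for (tr in trees) leaf_kingdoms(tr, prefixes)  # validate labels
  trees
}

#' Kingdom of each leaf of a labelled tree
#' @param tree A `phylo` object.
#' @param prefixes Named prefix map as in [read_kingdom_trees()].
#' @return Named character vector (leaf label -> kingdom).
#' @export
leaf_kingdoms <- function(tree, prefixes = c(bacterial = "B_", viral = "V_")) {
  labs <- tree$tip.label
  king <- rep(NA_character_, length(labs))
  for (kg in names(prefixes)) {
    king[startsWith(labs, prefixes[[kg]])] <- kg
  }
  if (anyNA(king)) {
    stop("unlabeled kingdom: ", paste(labs[is.na(king)], collapse = ", "))
  }
  stats::setNames(king, labs)
}

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Read a taxonomy lineage table
#'
#' Tab-separated with header: `genome_id` plus the seven ranks domain
#' through species. Missing ranks below some depth are empty or NA;
#' present ranks must be contiguous from domain downward.
#'
#' @param path TSV file.
#' @return `data.frame` with `genome_id` and one column per rank.
#' @export
read_lineages <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", LINEAGE_RANKS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("lineage table lacks columns: ",
                             paste(miss, collapse = ", "))
  for (r in LINEAGE_RANKS) df[[r]][!is.na(df[[r]]) & df[[r]] == ""] <- NA
  rk <- as.matrix(df[, LINEAGE_RANKS])
  gap <- apply(rk, 1, function(x) {
    pres <- !is.na(x)
    if (all(pres)) return(FALSE)
    any(pres[which(!pres)[1]:length(pres)])
  })
  if (any(gap)) stop("non-contiguous lineage for: ",
                     paste(df$genome_id[gap], collapse = ", "))
  df
}

#' Read / write an abundance matrix
#'
#' Rows are features (phage contigs or bacterial genera), columns are
#' samples; the first TSV column holds row identifiers. All entries must
#' be non-negative.
#'
#' @param path TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("abundance matrix contains negative entries")
  m
}

#' @rdname read_abundance
#' @param mat Numeric abundance matrix.
#' @export
write_abundance <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
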