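#' MinHash sketch of a sequence set
#'
#' Builds a bottom-s MinHash sketch over the canonical k-mers (the
#' lexicographically smaller of a k-mer and its reverse complement, via a
#' 2-bit encoding) of one or more sequences. The hash function is fixed
#' and versioned, so sketches are portable across runs and machines.
#' Sketches drive the Mash-distance reference prefilter that restricts
#' each sample to catalog genomes within a chosen genomic distance.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet]. k-mers
#'   containing non-ACGT letters are skipped.
#' @param k Odd k-mer size (default 21, the usual genomic sketch size;
#'   odd so a k-mer can never equal its own reverse complement).
#' @param s Sketch capacity: number of smallest distinct hashes retained
#'   (default 1000).
#' @return An object of class `minhash_sketch`: list with `k`, `s` and
#'   the sorted `hashes`.
#' @export
sketch_sequence <- function(seqs, k = 21, s = 1000) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- as.character(seqs)
  if (k %% 2 == 0) stop("k must be odd so canonical k-mers are unambiguous")
  if (length(seqs) == 0 || all(nchar(seqs) < k))
    stop("no sequence of length >= k = ", k)
  hashes <- .sketch_cpp(seqs, as.integer(k), as.integer(s))
  structure(list(k = as.integer(k), s = as.integer(s), hashes = hashes,
                 version = 1L),
            class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index j of the two canonical k-mer sets from the
#' merged bottom-s sketch (the s' smallest distinct hashes of the union,
#' s' = min(s, distinct hashes available)), then converts it to a
#' genomic distance with the Mash formula
#' \deqn{d = -\frac{1}{k}\,\ln\frac{2j}{1+j}.}
#' A zero Jaccard estimate (and any distance beyond it) is capped at 1.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  sprime <- min(s, length(merged))
  if (sprime == 0) return(1.0)
  bottom <- merged[seq_len(sprime)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / sprime
  jaccard_to_mash(j, a$k)
}

#' Convert a Jaccard index to a Mash distance
#' @param j Jaccard index in `[0, 1]`.
#' @param k k-mer size used.
#' @return Distance in `[0, 1]` (capped).
#' @export
jaccard_to_mash <- function(j, k) {
  d <- ifelse(j <= 0, 1.0, -(1 / k) * log(2 * j / (1 + j)))
  pmin(d, 1.0)
}

#' Select reference genomes close to a sample
#'
#' Retains catalog genomes whose Mash distance to the sample sketch is at
#' most `max_distance`. The default 0.10 corresponds to a minimum
#' genomic identity of about 0.90, since the Mash distance approximates
#' one minus the average nucleotide identity.
#'
#' @param genome_sketches Named list of `minhash_sketch` objects, one per
#'   catalog genome.
#' @param sample_sketch `minhash_sketch` of the sample.
#' @param max_distance Retention threshold (default 0.10).
#' @return `data.frame` with `genome_id` and `distance` for retained
#'   genomes, in catalog order.
#' @export
select_references <- function(genome_sketches, sample_sketch,
                              max_distance = 0.10) {
  if (length(genome_sketches) == 0) {
    warning("empty genome catalog; no references selected")
    return(data.frame(genome_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  d <- vapply(genome_sketches, mash_distance, numeric(1), b = sample_sketch)
  keep <- d <= max_distance
  data.frame(genome_id = names(genome_sketches)[keep],
             distance = unname(d[keep]), stringsAsFactors = FALSE)
}
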