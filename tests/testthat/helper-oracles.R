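# Independent reference implementations used as test oracles. These are
# deliberately written from the algorithm definitions, separately from the
# package code paths they check.

# --- reference CAST on an adjacency matrix ---------------------------------
# pr: tie-break priority per node (smaller wins). Mirrors the published
# add/remove loop: seed with the max-degree unassigned node; add the
# qualifying unassigned node of max affinity; remove the member of min
# affinity below threshold; close when stable.
reference_cast <- function(adj, pr, t = 0.5) {
  n <- nrow(adj)
  assigned <- rep(FALSE, n)
  out <- list()
  pick_first <- function(nodes, key1) {
    # smallest key1, then smallest pr
    nodes[which(key1 == min(key1) & pr[nodes] ==
                  min(pr[nodes][key1 == min(key1)]))[1]]
  }
  while (!all(assigned)) {
    open <- which(!assigned)
    degs <- sapply(open, function(v) sum(adj[v, open]))
    seed <- pick_first(open, -degs)
    cl <- seed
    assigned[seed] <- TRUE
    states <- character(0)
    repeat {
      moved <- FALSE
      repeat {
        open <- which(!assigned)
        if (length(open) == 0) break
        aff <- sapply(open, function(v) sum(adj[v, cl]))
        cand <- open[aff >= t * length(cl)]
        if (length(cand) == 0) break
        caff <- sapply(cand, function(v) sum(adj[v, cl]))
        add <- pick_first(cand, -caff)
        cl <- c(cl, add)
        assigned[add] <- TRUE
        moved <- TRUE
      }
      repeat {
        if (length(cl) <= 1) break
        aff <- sapply(cl, function(v) sum(adj[v, setdiff(cl, v)]))
        low <- cl[aff < t * length(cl)]
        if (length(low) == 0) break
        laff <- sapply(low, function(v) sum(adj[v, setdiff(cl, v)]))
        rem <- pick_first(low, laff)
        cl <- setdiff(cl, rem)
        assigned[rem] <- FALSE
        moved <- TRUE
      }
      if (!moved) break
      # close at the first recurrence of a membership state (oscillation)
      key <- paste(sort(cl), collapse = ",")
      if (key %in% states) break
      states <- c(states, key)
    }
    out[[length(out) + 1]] <- sort(cl)
  }
  out
}

canonical_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(sapply(p, `[`, 1))]
}

# --- maximum bipartite matching (Kuhn's augmenting paths) -------------------
# elig: logical matrix truth x calls
max_bipartite_matching_size <- function(elig) {
  nt <- nrow(elig); nc <- ncol(elig)
  match_c <- rep(0L, nc)
  seen <- rep(FALSE, nc)
  try_kuhn <- function(t) {
    for (c in which(elig[t, ])) {
      if (!seen[c]) {
        seen[c] <<- TRUE
        if (match_c[c] == 0L || try_kuhn(match_c[c])) {
          match_c[c] <<- t
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (t in seq_len(nt)) {
    seen <- rep(FALSE, nc)
    if (try_kuhn(t)) size <- size + 1L
  }
  size
}

# --- exact canonical k-mer Jaccard (string based) ---------------------------
canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  fwd <- substring(seq, 1:(n - k + 1), k:n)
  rc <- chartr("ACGT", "TGCA", seq)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  rck <- rev(substring(rc, 1:(n - k + 1), k:n))
  unique(pmin(fwd, rck))
}

exact_mash_distance <- function(a, b, k) {
  A <- canonical_kmer_set(a, k)
  B <- canonical_kmer_set(b, k)
  j <- length(intersect(A, B)) / length(union(A, B))
  jaccard_to_mash(j, k)
}

# --- brute-force spacer scan ------------------------------------------------
# shift-comparison Hamming scan over every window, both strands; N never
# matches anything
brute_spacer_scan <- function(spacer, genome, max_mm = 2L) {
  revcomp_str <- function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  L <- nchar(genome); m <- nchar(spacer)
  gch <- strsplit(genome, "")[[1]]
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else revcomp_str(spacer)
    pch <- strsplit(pat, "")[[1]]
    if (L < m) next
    nw <- L - m + 1L
    mm <- integer(nw)
    for (j in seq_len(m)) {
      gj <- gch[j:(j + nw - 1L)]
      mm <- mm + as.integer(gj != pch[j] | gj == "N" | pch[j] == "N")
    }
    hit <- which(mm <= max_mm)
    if (length(hit) > 0) {
      out <- rbind(out, data.frame(position = hit - 1L, strand = strand,
                                   mismatches = mm[hit],
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(position = integer(0), strand = character(0),
                               mismatches = integer(0)) else
    out[order(out$position, out$strand), , drop = FALSE]
}

# --- exact statistics oracles ----------------------------------------------
# one-sided (over-representation) Fisher p for table (a,b,c,d) by direct
# hypergeometric tail sum
fisher_greater_oracle <- function(a, b, c, d) {
  m1 <- a + b          # SV-region genes
  k1 <- a + c          # category genes
  n <- a + b + c + d
  xs <- a:min(m1, k1)
  sum(choose(k1, xs) * choose(n - k1, m1 - xs)) / choose(n, m1)
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# exact two-sided Mann-Whitney p by enumeration over group assignments
mwu_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(nx))
  combs <- combn(nx + ny, nx)
  us <- apply(combs, 2, u_stat)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# --- per-base gene/SV overlap oracle ---------------------------------------
gene_in_sv_oracle <- function(gene_start, gene_end, svs) {
  if (gene_end <= gene_start) return(FALSE)
  bases <- gene_start:(gene_end - 1L)
  for (i in seq_len(nrow(svs))) {
    if (svs$svtype[i] == "INS") {
      if (svs$start[i] %in% bases) return(TRUE)
    } else {
      lo <- svs$start[i]; hi <- svs$start[i] + svs$length[i] - 1L
      if (any(bases >= lo & bases <= hi)) return(TRUE)
    }
  }
  FALSE
}

# --- shared big-cohort fixture (built once per test run) --------------------
.fixture_env <- new.env(parent = emptyenv())

cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(seed = 20260930)
  }
  .fixture_env$cohort
}

pipeline_fixture <- function() {
  if (is.null(.fixture_env$result)) {
    .fixture_env$result <- run_pipeline(cohort_fixture())
  }
  .fixture_env$result
}

# small deterministic record-table builder for merge tests
rec <- function(start, length, svtype = "DEL", caller = "Sniffles",
                contig = "c1", sample = "S1", id = NULL,
                read_support = 5L) {
  sv_records(contig, start, length, svtype, read_support = read_support,
             caller = caller, sample = sample, record_id = id)
}
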