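#' Parameters for ensemble SV merging
#'
#' Defaults implement the consensus-merging rules used throughout the
#' pipeline: SV pairs are connected when their mutual (reciprocal)
#' overlap is at least 80% of the longer SV; clusters are built by the
#' Cluster Affinity Search Technique (CAST) with affinity threshold 0.5;
#' a merged SV is reported only when discovered by at least two callers,
#' supported by at least two reads, longer than 50 bp, and at least
#' 100 bp away from both contig ends. Representatives follow the caller
#' priority order (best benchmark performance first).
#'
#' @param min_mutual_overlap Minimum reciprocal overlap for a graph edge.
#' @param cast_t CAST affinity threshold (fraction of cluster size).
#' @param min_callers Minimum distinct callers per reported cluster.
#' @param min_reads Minimum representative read support.
#' @param min_len_exclusive Representative length must exceed this (bp).
#' @param edge_margin Minimum distance of the representative interval
#'   from either contig end (bp).
#' @param caller_priority Character vector, most trusted caller first.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_mutual_overlap = 0.8, cast_t = 0.5,
                         min_callers = 2L, min_reads = 2L,
                         min_len_exclusive = 50L, edge_margin = 100L,
                         caller_priority = c("Sniffles", "cuteSV", "pbsv",
                                             "SVIM")) {
  stopifnot(min_mutual_overlap > 0, min_mutual_overlap <= 1,
            cast_t > 0, cast_t <= 1)
  structure(list(min_mutual_overlap = min_mutual_overlap, cast_t = cast_t,
                 min_callers = as.integer(min_callers),
                 min_reads = as.integer(min_reads),
                 min_len_exclusive = as.integer(min_len_exclusive),
                 edge_margin = as.integer(edge_margin),
                 caller_priority = caller_priority),
            class = "merge_params")
}

#' Reciprocal (mutual) overlap of two SV records
#'
#' Intersection length of the two half-open intervals
#' `[start, start + length)` divided by the longer SV's length.
#' Insertions use the same interval convention (end = start + length).
#' Records on different contigs or of different SV types have overlap 0
#' by definition.
#'
#' @param a,b Single-row SV record data.frames (or lists with `contig`,
#'   `start`, `length`, `svtype`).
#' @return Fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$contig != b$contig || a$svtype != b$svtype) return(0)
  ov <- min(a$start + a$length, b$start + b$length) -
    max(a$start, b$start)
  if (ov <= 0) return(0)
  ov / max(a$length, b$length)
}

# Pairwise reciprocal-overlap matrix for records sharing contig+svtype.
ro_matrix <- function(start, len) {
  end <- start + len
  inter <- outer(end, end, pmin) - outer(start, start, pmax)
  inter[inter < 0] <- 0
  inter / outer(len, len, pmax)
}

#' Partition SV records into non-overlapping positional groups
#'
#' Connected components of the "overlaps by at least 1 bp" relation on
#' the records' half-open intervals, computed per contig and SV type by
#' a sweep over sorted starts. Components have pairwise-disjoint
#' coordinate spans, so each can be clustered independently.
#'
#' @param records SV record `data.frame` sharing one contig and svtype
#'   (the sample merger partitions by both first).
#' @return List of integer vectors: row indices of `records` per group,
#'   in coordinate order.
#' @export
overlap_groups <- function(records) {
  n <- nrow(records)
  if (n == 0) return(list())
  ord <- order(records$start, records$start + records$length)
  st <- records$start[ord]
  en <- st + records$length[ord]
  run_max <- cummax(en)
  # a new component starts where an interval begins at/after everything seen
  brk <- c(TRUE, st[-1] >= run_max[-n])
  grp <- cumsum(brk)
  split(ord, grp)
}

#' CAST clustering of one overlap group
#'
#' Builds the "corrupted clique" graph on the group (edge iff reciprocal
#' overlap >= `min_mutual_overlap`) and partitions it with the classic
#' Cluster Affinity Search Technique: open a cluster with the
#' maximum-degree unassigned node; repeatedly add the unassigned node of
#' highest affinity (edge count into the cluster) while its affinity is
#' at least `cast_t` times the cluster size, then remove any member whose
#' affinity falls below that bound; close the cluster when stable and
#' repeat. All ties break deterministically by smaller start, then
#' shorter length, then caller-priority rank, then record id, so the
#' partition is independent of input order.
#'
#' @param group SV record `data.frame` (one group from
#'   [overlap_groups()]).
#' @param min_mutual_overlap Edge threshold.
#' @param cast_t Affinity threshold.
#' @param caller_priority Caller order used in tie-breaks.
#' @return List of integer vectors: row indices of `group` per cluster.
#' @export
cast_cluster <- function(group, min_mutual_overlap = 0.8, cast_t = 0.5,
                         caller_priority = c("Sniffles", "cuteSV", "pbsv",
                                             "SVIM")) {
  n <- nrow(group)
  if (n == 0) return(list())
  adj <- ro_matrix(group$start, group$length) >= min_mutual_overlap
  diag(adj) <- FALSE
  rank <- match(group$caller, caller_priority)
  rank[is.na(rank)] <- length(caller_priority) + 1L
  ord <- order(group$start, group$length, rank, group$record_id)
  pr <- integer(n); pr[ord] <- seq_len(n)  # pr[i] = tie-break priority of node i
  cast_partition(adj, pr, cast_t)
}

# CAST on a logical adjacency matrix; pr = tie-break priority (smaller wins).
cast_partition <- function(adj, pr, cast_t) {
  n <- nrow(adj)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    u <- which(unassigned)
    deg <- colSums(adj[u, u, drop = FALSE])
    seed <- u[order(-deg, pr[u])][1]
    memb <- seed
    unassigned[seed] <- FALSE
    seen_states <- character(0)
    repeat {
      changed <- FALSE
      # add phase: highest-affinity unassigned node meeting the bound
      repeat {
        u <- which(unassigned)
        if (length(u) == 0) break
        aff <- colSums(adj[memb, u, drop = FALSE])
        qual <- aff >= cast_t * length(memb)
        if (!any(qual)) break
        pick <- u[qual][order(-aff[qual], pr[u[qual]])][1]
        memb <- c(memb, pick)
        unassigned[pick] <- FALSE
        changed <- TRUE
      }
      # remove phase: lowest-affinity member below the bound
      repeat {
        if (length(memb) <= 1) break
        aff <- colSums(adj[memb, memb, drop = FALSE])
        bad <- aff < cast_t * length(memb)
        if (!any(bad)) break
        drop <- memb[bad][order(aff[bad], pr[memb[bad]])][1]
        memb <- setdiff(memb, drop)
        unassigned[drop] <- TRUE
        changed <- TRUE
      }
      if (!changed) break
      # an add/remove oscillation revisits a membership state; close the
      # cluster deterministically at the first recurrence
      sig <- paste(sort(memb), collapse = ",")
      if (sig %in% seen_states) break
      seen_states <- c(seen_states, sig)
    }
    clusters[[length(clusters) + 1L]] <- sort(memb)
  }
  clusters
}

#' Merge one sample's multi-caller callsets
#'
#' Implements the per-sample consensus step: records are partitioned by
#' contig and SV type, split into positional overlap groups, clustered
#' with CAST on the reciprocal-overlap graph, and each cluster reduced to
#' the record from the highest-priority caller present. Clusters are
#' reported only when (i) at least `min_callers` distinct callers
#' contributed, (ii) the representative is supported by at least
#' `min_reads` reads, (iii) its length exceeds `min_len_exclusive` bp and
#' (iv) its interval lies at least `edge_margin` bp from both contig
#' ends.
#'
#' @param callsets Either a single SV record `data.frame` (with a
#'   `caller` column) or a list of per-caller record data.frames.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param params [merge_params()].
#' @return SV record `data.frame` of cluster representatives with extra
#'   columns `callers` (comma-joined), `n_callers`, `n_members`,
#'   `read_support_max` and `member_ids` (comma-joined record ids).
#' @export
merge_sample <- function(callsets, contig_lengths, params = merge_params()) {
  records <- if (is.data.frame(callsets)) callsets else
    do.call(rbind, unname(callsets))
  if (nrow(records) == 0) return(annotate_clusters(records, list()))
  validate_sv_records(records)
  if (length(unique(records$sample)) > 1)
    stop("merge_sample expects records from a single sample")
  unknown <- setdiff(unique(records$caller), params$caller_priority)
  if (length(unknown) > 0)
    warning("unknown caller id(s) treated as lowest priority: ",
            paste(unknown, collapse = ", "))
  clusters <- cluster_records(records, params)
  out <- annotate_clusters(records, clusters, params)
  # quality filters on the representative
  miss <- setdiff(unique(out$contig), names(contig_lengths))
  if (length(miss) > 0)
    stop("contig length unknown for: ", paste(miss, collapse = ", "))
  clen <- contig_lengths[out$contig]
  keep <- out$n_callers >= params$min_callers &
    out$read_support >= params$min_reads &
    out$length > params$min_len_exclusive &
    out$start >= params$edge_margin &
    (out$start + out$length) <= (clen - params$edge_margin)
  out[keep, , drop = FALSE]
}

# partition by (contig, svtype) -> overlap groups -> CAST; returns list of
# global row-index vectors
cluster_records <- function(records, params) {
  key <- paste(records$contig, records$svtype, sep = "\r")
  clusters <- list()
  for (idx in split(seq_len(nrow(records)), key)) {
    sub <- records[idx, , drop = FALSE]
    for (g in overlap_groups(sub)) {
      cl <- cast_cluster(sub[g, , drop = FALSE], params$min_mutual_overlap,
                         params$cast_t, params$caller_priority)
      clusters <- c(clusters, lapply(cl, function(ii) idx[g][ii]))
    }
  }
  clusters
}

# elect representatives and annotate support columns
annotate_clusters <- function(records, clusters, params = merge_params()) {
  if (length(clusters) == 0) {
    out <- empty_sv_records()
    out$callers <- character(0); out$n_callers <- integer(0)
    out$n_members <- integer(0); out$read_support_max <- integer(0)
    out$member_ids <- character(0)
    return(out)
  }
  rows <- lapply(clusters, function(ii) {
    m <- records[ii, , drop = FALSE]
    rank <- match(m$caller, params$caller_priority)
    rank[is.na(rank)] <- length(params$caller_priority) + 1L
    rep_i <- order(rank, m$start, m$record_id)[1]
    rep <- m[rep_i, , drop = FALSE]
    rep$callers <- paste(sort(unique(m$caller)), collapse = ",")
    rep$n_callers <- length(unique(m$caller))
    rep$n_members <- nrow(m)
    rep$read_support_max <- max(m$read_support)
    rep$member_ids <- paste(sort(m$record_id), collapse = ",")
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$contig, out$svtype, out$start, out$record_id), , drop = FALSE]
}

#' Build the cohort-level nonredundant SV set
#'
#' Pools the per-sample merged representatives from all samples and
#' re-applies the positional grouping + CAST machinery across samples.
#' Each cross-sample cluster is reduced to its most prevalent member:
#' the record whose interval recurs (reciprocal overlap at least
#' `min_mutual_overlap`) in the largest number of distinct samples, with
#' ties broken by smaller start, then shorter length, then sample id.
#'
#' @param per_sample List of [merge_sample()] outputs (one per sample).
#' @param params [merge_params()].
#' @return SV record `data.frame` of nonredundant representatives with
#'   columns `samples` (comma-joined), `n_samples`, `n_members` and
#'   `member_ids`; the per-sample presence matrix is attached as
#'   attribute `"presence"` and per-type counts as attribute
#'   `"type_counts"`.
#' @export
merge_cohort <- function(per_sample, params = merge_params()) {
  pooled <- do.call(rbind, lapply(per_sample, function(df)
    df[, c("contig", "start", "length", "svtype", "alt_seq", "read_support",
           "caller", "sample", "record_id")]))
  rownames(pooled) <- NULL
  all_samples <- unique(pooled$sample)
  if (nrow(pooled) == 0) {
    out <- empty_sv_records()
    out$samples <- character(0); out$n_samples <- integer(0)
    out$n_members <- integer(0); out$member_ids <- character(0)
    attr(out, "presence") <- matrix(FALSE, 0, length(all_samples),
                                    dimnames = list(NULL, all_samples))
    attr(out, "type_counts") <- table(factor(character(0), levels = SV_TYPES))
    return(out)
  }
  clusters <- cluster_records(pooled, params)
  rows <- lapply(clusters, function(ii) {
    m <- pooled[ii, , drop = FALSE]
    # prevalence: distinct samples whose member overlaps this member >= 0.8
    ro <- ro_matrix(m$start, m$length)
    prev <- vapply(seq_len(nrow(m)), function(i) {
      length(unique(m$sample[ro[i, ] >= params$min_mutual_overlap]))
    }, integer(1))
    rep_i <- order(-prev, m$start, m$length, m$sample)[1]
    rep <- m[rep_i, , drop = FALSE]
    rep$samples <- paste(sort(unique(m$sample)), collapse = ",")
    rep$n_samples <- length(unique(m$sample))
    rep$n_members <- nrow(m)
    rep$member_ids <- paste(sort(m$record_id), collapse = ",")
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$contig, out$svtype, out$start, out$record_id), ,
             drop = FALSE]
  pres <- vapply(all_samples, function(s)
    vapply(strsplit(out$samples, ","), function(x) s %in% x, logical(1)),
    logical(nrow(out)))
  pres <- matrix(pres, nrow = nrow(out),
                 dimnames = list(out$record_id, all_samples))
  attr(out, "presence") <- pres
  attr(out, "type_counts") <- table(factor(out$svtype, levels = SV_TYPES))
  out
}
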