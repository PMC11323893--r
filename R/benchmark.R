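#' Parameters for truth-vs-callset matching
#'
#' @param refdist Maximum breakpoint (start) distance in bp for a truth
#'   record and a call to be considered the same event (default 500).
#' @param pctsize Minimum size ratio `min(len)/max(len)` (default 0.7).
#' @param require_type_match Must the SV types agree (default TRUE)?
#' @return List of class `match_params`.
#' @export
match_params <- function(refdist = 500L, pctsize = 0.7,
                         require_type_match = TRUE) {
  stopifnot(refdist >= 0, pctsize > 0, pctsize <= 1)
  structure(list(refdist = as.integer(refdist), pctsize = pctsize,
                 require_type_match = isTRUE(require_type_match)),
            class = "match_params")
}

#' Match a callset against a truth set
#'
#' A truth record and a call are eligible partners when they share a
#' contig (and SV type, unless disabled), their starts differ by at most
#' `refdist` bp and their size ratio is at least `pctsize`. Eligible
#' pairs are matched greedily by ascending start distance, with ties
#' broken by ascending length difference, then truth id, then call id;
#' each record is used at most once.
#'
#' @param truth,calls SV record data.frames.
#' @param params [match_params()].
#' @return `data.frame` with columns `truth_id`, `call_id`,
#'   `start_dist`, `len_diff`.
#' @export
match_callsets <- function(truth, calls, params = match_params()) {
  empty <- data.frame(truth_id = character(0), call_id = character(0),
                      start_dist = integer(0), len_diff = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(truth) == 0 || nrow(calls) == 0) return(empty)
  pairs <- NULL
  keyt <- if (params$require_type_match)
    paste(truth$contig, truth$svtype) else truth$contig
  keyc <- if (params$require_type_match)
    paste(calls$contig, calls$svtype) else calls$contig
  for (k in intersect(unique(keyt), unique(keyc))) {
    ti <- which(keyt == k); ci <- which(keyc == k)
    dd <- abs(outer(truth$start[ti], calls$start[ci], "-"))
    lmin <- outer(truth$length[ti], calls$length[ci], pmin)
    lmax <- outer(truth$length[ti], calls$length[ci], pmax)
    ok <- dd <= params$refdist & (lmin / lmax) >= params$pctsize
    if (!any(ok)) next
    w <- which(ok, arr.ind = TRUE)
    pairs <- rbind(pairs, data.frame(
      t = ti[w[, 1]], c = ci[w[, 2]],
      start_dist = dd[ok], len_diff = (lmax - lmin)[ok],
      stringsAsFactors = FALSE))
  }
  if (is.null(pairs)) return(empty)
  ord <- order(pairs$start_dist, pairs$len_diff,
               truth$record_id[pairs$t], calls$record_id[pairs$c])
  pairs <- pairs[ord, , drop = FALSE]
  used_t <- logical(nrow(truth)); used_c <- logical(nrow(calls))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$t[i]; ci <- pairs$c[i]
    if (!used_t[ti] && !used_c[ci]) {
      keep[i] <- TRUE; used_t[ti] <- TRUE; used_c[ci] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  data.frame(truth_id = truth$record_id[m$t], call_id = calls$record_id[m$c],
             start_dist = m$start_dist, len_diff = m$len_diff,
             stringsAsFactors = FALSE)
}

#' Which calls have at least one eligible truth partner
#'
#' Many-to-one companion to [match_callsets()]: flags every call with at
#' least one eligible truth record under the same eligibility rule,
#' without consuming truth records. Useful to separate genuine false
#' positives (no truth anywhere near) from duplicate calls of one event,
#' which the one-to-one matching counts as FP.
#'
#' @param truth,calls SV record data.frames.
#' @param params [match_params()].
#' @return Logical vector along `calls` rows.
#' @export
calls_with_truth_support <- function(truth, calls, params = match_params()) {
  if (nrow(calls) == 0) return(logical(0))
  if (nrow(truth) == 0) return(rep(FALSE, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    cand <- truth$contig == calls$contig[i] &
      abs(truth$start - calls$start[i]) <= params$refdist &
      pmin(truth$length, calls$length[i]) /
        pmax(truth$length, calls$length[i]) >= params$pctsize
    if (params$require_type_match) cand <- cand & truth$svtype == calls$svtype[i]
    any(cand)
  }, logical(1))
}

#' Precision / recall / F1 from a matching
#'
#' @param matching Output of [match_callsets()].
#' @param truth,calls The matched SV record data.frames.
#' @return List of class `benchmark_result` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
benchmark_metrics <- function(matching, truth, calls) {
  tp <- nrow(matching)
  fp <- nrow(calls) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("SV benchmark: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}
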