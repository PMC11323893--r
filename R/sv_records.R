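#' Structural-variant record tables
#'
#' An SV record is one structural-variant call: a contig, a 0-based start,
#' a length in bp, one of the four SV types (INS, DEL, DUP, INV), the
#' caller and sample that produced it, and its read support. Records are
#' kept in a plain `data.frame` with one row per call; every pipeline
#' stage consumes and produces this shape.
#'
#' Coordinates are 0-based and half-open internally: an SV occupies
#' `[start, start + length)`. For insertions the interval is the same
#' convention applied to the inserted length, so the effective end of an
#' INS is its start plus its length. VCF POS (1-based) is converted at the
#' I/O boundary only.
#'
#' @param contig Character vector of contig/genome identifiers.
#' @param start Integer vector of 0-based start positions.
#' @param length Integer vector of SV lengths in bp (always positive,
#'   including deletions).
#' @param svtype Character vector, each one of `"INS"`, `"DEL"`, `"DUP"`,
#'   `"INV"`.
#' @param alt_seq Optional inserted sequence for INS records (NA
#'   otherwise).
#' @param read_support Integer vector of supporting read counts.
#' @param caller,sample Identifiers of the producing caller and sample.
#' @param record_id Unique record identifiers; autogenerated when NULL.
#' @return A `data.frame` with columns `contig`, `start`, `length`,
#'   `svtype`, `alt_seq`, `read_support`, `caller`, `sample`, `record_id`.
#' @export
sv_records <- function(contig, start, length, svtype, alt_seq = NA_character_,
                       read_support = 0L, caller = "", sample = "",
                       record_id = NULL) {
  n <- base::length(contig)
  if (is.null(record_id)) record_id <- sprintf("sv%d", seq_len(n))
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    length = as.integer(length),
    svtype = as.character(svtype),
    alt_seq = rep_len(as.character(alt_seq), n),
    read_support = rep_len(as.integer(read_support), n),
    caller = rep_len(as.character(caller), n),
    sample = rep_len(as.character(sample), n),
    record_id = as.character(record_id),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
  df
}

#' @rdname sv_records
#' @param records An SV record `data.frame` to validate.
#' @export
validate_sv_records <- function(records) {
  need <- c("contig", "start", "length", "svtype", "read_support",
            "caller", "sample", "record_id")
  miss <- setdiff(need, names(records))
  if (base::length(miss) > 0)
    stop("SV record table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!records$svtype %in% SV_TYPES))
    stop("svtype must be one of ", paste(SV_TYPES, collapse = ", "))
  if (any(records$start < 0)) stop("start positions must be >= 0")
  if (any(records$length < 1)) stop("SV lengths must be >= 1")
  if (any(records$read_support < 0)) stop("read_support must be >= 0")
  if (anyDuplicated(records$record_id))
    stop("record_id values must be unique")
  invisible(records)
}

#' The four recognised SV types
#' @export
SV_TYPES <- c("INS", "DEL", "DUP", "INV")

#' Effective end coordinate of SV records
#'
#' Always `start + length`, half-open, for all four SV types (insertions
#' included, so that positional merging can treat INS like the interval
#' types).
#'
#' @param records SV record `data.frame`.
#' @return Integer vector of exclusive end coordinates.
#' @export
sv_end <- function(records) records$start + records$length

empty_sv_records <- function() {
  sv_records(character(0), integer(0), integer(0), character(0),
             record_id = character(0))
}
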