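#' Read SV calls from a VCF file
#'
#' Parses a VCF 4.2 file carrying structural variants described by the
#' INFO keys `SVTYPE`, `SVLEN` and `END` into an SV record table. VCF POS
#' is 1-based; internal starts are 0-based. A negative `SVLEN` (the usual
#' deletion convention) is normalised to its absolute value.
#'
#' Read support is taken from the first of INFO `RE`, INFO `SUPPORT`, or
#' the FORMAT field `DV` that is present; records carrying none get
#' support 0. Records lacking `SVTYPE` or `SVLEN`, with `SVLEN` 0, or with
#' an SVTYPE other than INS/DEL/DUP/INV are rejected with one summary
#' warning rather than aborting the parse.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param default_caller,default_sample Values used when the record
#'   carries no `CALLER`/`SAMPLE` INFO annotation.
#' @return An SV record `data.frame` (see [sv_records()]).
#' @export
read_sv_vcf <- function(path, default_caller = "", default_sample = "") {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_sv_records())

  svtype <- info_field(fix[, "INFO"], "SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_field(fix[, "INFO"], "SVLEN")))
  bad <- is.na(svtype) | is.na(svlen) | svlen == 0 | !(svtype %in% SV_TYPES)
  if (any(bad)) {
    warning(sprintf("rejected %d VCF record(s) with missing/invalid SVTYPE or SVLEN",
                    sum(bad)))
  }

  support <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "RE")))
  sup2 <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "SUPPORT")))
  support[is.na(support)] <- sup2[is.na(support)]
  if (any(is.na(support)) && !is.null(vcf@gt) && ncol(vcf@gt) >= 2) {
    dv <- tryCatch(
      suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DV")[, 1])),
      error = function(e) rep(NA_integer_, nrow(fix)))
    support[is.na(support)] <- dv[is.na(support)]
  }
  support[is.na(support)] <- 0L

  caller <- info_field(fix[, "INFO"], "CALLER")
  caller[is.na(caller)] <- default_caller
  sample <- info_field(fix[, "INFO"], "SAMPLE")
  sample[is.na(sample)] <- default_sample
  alt <- fix[, "ALT"]
  alt_seq <- ifelse(svtype == "INS" & !is.na(alt) & !grepl("^<", alt),
                    alt, NA_character_)
  id <- fix[, "ID"]
  if (any(is.na(id) | id == ".")) {
    fill <- sprintf("rec%d", seq_len(nrow(fix)))
    id[is.na(id) | id == "."] <- fill[is.na(id) | id == "."]
  }

  keep <- !bad
  sv_records(
    contig = fix[keep, "CHROM"],
    start = as.integer(fix[keep, "POS"]) - 1L,
    length = as.integer(abs(svlen[keep])),
    svtype = svtype[keep],
    alt_seq = alt_seq[keep],
    read_support = support[keep],
    caller = caller[keep],
    sample = sample[keep],
    record_id = id[keep]
  )
}

# Extract a single key from semicolon-delimited INFO strings.
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Write SV records to a VCF file
#'
#' Inverse of [read_sv_vcf()]: all SV record fields round-trip losslessly
#' through INFO keys `SVTYPE`, `SVLEN` (negative for DEL), `END`, `RE`,
#' `CALLER` and `SAMPLE`. INS records with a known inserted sequence
#' carry it in ALT; all other records use symbolic ALT alleles.
#'
#' @param records SV record `data.frame`.
#' @param path Output path.
#' @param contig_lengths Optional named vector adding `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, contig_lengths = NULL) {
  validate_sv_records(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=phagesv",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length (negative for DEL)\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (start+length)\">",
    "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Supporting read count\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Producing SV caller\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample of origin\">"
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  svlen <- ifelse(records$svtype == "DEL", -records$length, records$length)
  alt <- ifelse(records$svtype == "INS" & !is.na(records$alt_seq),
                records$alt_seq, paste0("<", records$svtype, ">"))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;RE=%d;CALLER=%s;SAMPLE=%s",
                  records$svtype, svlen, sv_end(records),
                  records$read_support, records$caller, records$sample)
  body <- paste(records$contig, records$start + 1L, records$record_id, "N",
                alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
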