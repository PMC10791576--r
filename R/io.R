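# Shared format readers/writers: FASTQ (phred+33), SAM/BAM alignment
# records, kinetic trace tables, and the intensity container
# (long-format TSV + JSON sidecar).

#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records, phred+33).
#' @return data.frame `(id, seq, qual)`; `qual` is the phred+33 string.
#' @export
read_fastq <- function(path) {
  # structural validation first: the backend parser is lenient about
  # truncated quality lines, which must instead be a positioned error
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(ln)))
  }
  n_rec <- length(ln) %/% 4
  i1 <- seq(1L, by = 4L, length.out = n_rec)
  if (any(substr(ln[i1], 1, 1) != "@") || any(substr(ln[i1 + 2L], 1, 1) != "+")) {
    stop(sprintf("malformed FASTQ '%s': record separators misplaced", path))
  }
  bad <- which(nchar(ln[i1 + 1L]) != nchar(ln[i1 + 3L]))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': sequence/quality length mismatch at record %d",
                 path, bad[1]))
  }
  out <- tryCatch({
    recs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    data.frame(id = names(recs),
               seq = as.character(recs),
               qual = as.character(S4Vectors::mcols(recs)$qualities),
               row.names = NULL, stringsAsFactors = FALSE)
  }, error = function(e) {
    stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  })
  out
}

#' Write a FASTQ file
#'
#' @param ids Record identifiers.
#' @param seqs Base strings.
#' @param quals Phred+33 quality strings (same lengths as `seqs`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch at record %d", bad[1]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Read alignment records from SAM or BAM
#'
#' SAM text is converted to BAM on the fly (htslib via Rsamtools); region
#' queries require (and will create) an index. Coordinates are reported as
#' stored in SAM (1-based `pos`); downstream analyses convert to 0-based
#' half-open internally.
#'
#' @param path SAM or BAM file.
#' @param region Optional data.frame `(contig, start, end)` (0-based
#'   half-open) restricting iteration to overlapping records.
#' @return data.frame `(qname, flag, rname, pos, mapq, cigar, seq)`.
#' @export
read_alignments <- function(path, region = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what)
  } else {
    region <- as.data.frame(region)
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      ok <- tryCatch({ Rsamtools::indexBam(bam); TRUE }, error = function(e) FALSE)
      if (!ok) stop(sprintf("region query needs an index for '%s'; indexing failed (is the file coordinate-sorted?)", bam))
    }
    gr <- GenomicRanges::GRanges(region[[1]],
                                 IRanges::IRanges(region[[2]] + 1L, region[[3]]))
    param <- Rsamtools::ScanBamParam(what = what, which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  dfs <- lapply(res, function(x) {
    data.frame(qname = x$qname, flag = x$flag, rname = as.character(x$rname),
               pos = x$pos, mapq = x$mapq, cigar = x$cigar,
               seq = as.character(x$seq), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  if (!is.null(region) && nrow(out)) {
    out <- out[!duplicated(paste(out$qname, out$flag, out$pos)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write / read a kinetic trace table
#'
#' Plain TSV with a `time` and `signal` column; condition metadata
#' (concentration, substrate kind) is carried in `#`-prefixed header lines
#' and restored on read.
#'
#' @param trace A `kinetic_trace` (data.frame time/signal).
#' @param path File path.
#' @return `write_trace()` returns the path; `read_trace()` a
#'   `kinetic_trace`.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", attr(trace, "kind") %||% "unknown"),
               sprintf("# conc: %s", format(attr(trace, "conc") %||% NA)),
               "time\tsignal"), con)
  utils::write.table(data.frame(time = trace$time, signal = trace$signal),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  kind <- sub("^# kind: ", "", grep("^# kind:", hdr, value = TRUE)[1])
  conc <- suppressWarnings(as.numeric(sub("^# conc: ", "", grep("^# conc:", hdr, value = TRUE)[1])))
  body <- utils::read.table(text = ln[!startsWith(ln, "#")], header = TRUE, sep = "\t")
  kinetic_trace(body$time, body$signal, kind = kind, conc = conc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load an intensity container
#'
#' The tensor is stored as a long-format TSV (`polony`, `cycle`, `channel`,
#' `value`) next to a JSON sidecar holding the simulator config, seed and
#' truth calls, so a run is reproducible byte-for-byte from its container.
#'
#' @param x List with `intensities` (polony x cycle x channel) and
#'   optionally `truth`, as returned by [render_intensities()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param config Optional [sim_config()] recorded in the sidecar.
#' @return `save_intensities()` returns the prefix; `load_intensities()` the
#'   list (`intensities`, `truth`, `config`).
#' @name intensity_io
NULL

#' @rdname intensity_io
#' @export
save_intensities <- function(x, prefix, config = NULL) {
  dm <- dim(x$intensities)
  long <- data.frame(polony = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
                     cycle = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
                     channel = rep(BASES[seq_len(dm[3])], each = dm[1] * dm[2]),
                     value = as.vector(x$intensities))
  utils::write.table(long, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(dim = dm, channel_order = BASES,
               truth = if (!is.null(x$truth)) apply(x$truth, 1, paste0, collapse = ""),
               config = if (!is.null(config)) {
                 cfg <- unclass(config)
                 cfg$crosstalk <- as.vector(cfg$crosstalk)
                 cfg
               })
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname intensity_io
#' @export
load_intensities <- function(prefix) {
  long <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dm <- as.integer(side$dim)
  arr <- array(0, dim = dm, dimnames = list(NULL, NULL, channel = side$channel_order))
  ch_i <- match(long$channel, side$channel_order)
  arr[cbind(long$polony, long$cycle, ch_i)] <- long$value
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- do.call(rbind, strsplit(side$truth, ""))
  }
  list(intensities = arr, truth = truth, config = side$config)
}
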