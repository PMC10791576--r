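# Ground-truthed alignment fixtures: a synthetic reference carrying known
# homopolymer runs, a slop-padded BED of those runs, and coordinate-sorted
# SAM reads with substitution errors injected at different rates before and
# after each homopolymer (in read 5'->3' orientation).

#' Generate a homopolymer error-profiling fixture
#'
#' Writes a synthetic FASTA reference containing the requested homopolymer
#' runs, a BED file of the runs padded by `slop` bases per side, and a
#' coordinate-sorted SAM of reads tiled across the runs. Substitution errors
#' are drawn independently per base: positions preceding the homopolymer in
#' read orientation at rate `pre_error`, positions following it at rate
#' `post_error` (bases over the run itself use `pre_error`). Optionally
#' injects SNP-carrying positions and records that downstream filters must
#' discard (secondary / supplementary / unmapped / MAPQ 0).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ref_length Reference length in bases.
#' @param homopolymers data.frame with columns `base`, `length`, `position`
#'   (0-based start); runs must not overlap or touch.
#' @param pre_error,post_error Per-base substitution probabilities in `[0, 1)`.
#' @param n_reads Number of kept (primary, MAPQ 60) reads.
#' @param read_length Read length in bases.
#' @param slop Padding encoded into the BED coordinates (default 5).
#' @param snp_positions Optional 0-based reference positions at which every
#'   covering read carries the alternate base (for mask testing).
#' @param n_filtered Number of extra records carrying filterable flags/MAPQ.
#' @param contig Reference sequence name.
#' @return List with file paths (`fasta`, `bed`, `sam`), the reference
#'   string, the trimmed interval table, and a per-read truth table with
#'   injected pre/post error counts (in read orientation).
#' @export
generate_profiling_fixture <- function(dir, seed, ref_length, homopolymers,
                                       pre_error, post_error, n_reads,
                                       read_length, slop = 5L,
                                       snp_positions = integer(),
                                       n_filtered = 0L, contig = "synthref") {
  stopifnot(pre_error >= 0, pre_error < 1, post_error >= 0, post_error < 1,
            n_reads >= 1, read_length >= 1)
  hp <- as.data.frame(homopolymers)
  stopifnot(all(c("base", "length", "position") %in% names(hp)))
  hp <- hp[order(hp$position), , drop = FALSE]
  hp$end <- hp$position + hp$length
  if (any(hp$end > ref_length)) stop("homopolymer extends past the reference")
  if (nrow(hp) > 1 && any(hp$position[-1] <= hp$end[-nrow(hp)])) {
    stop("homopolymer specs overlap")
  }
  local_rng(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ref <- sample(BASES, ref_length, replace = TRUE)
  for (i in seq_len(nrow(hp))) {
    idx <- (hp$position[i] + 1L):hp$end[i]
    ref[idx] <- hp$base[i]
    # keep the run exact: flanks must differ from the run base
    for (fl in c(hp$position[i], hp$end[i] + 1L)) {
      if (fl >= 1 && fl <= ref_length && ref[fl] == hp$base[i]) {
        ref[fl] <- sample(setdiff(BASES, hp$base[i]), 1L)
      }
    }
  }
  snp_positions <- as.integer(snp_positions)
  if (any(snp_positions < 0 | snp_positions >= ref_length)) {
    stop("snp_positions out of reference bounds")
  }
  snp_alt <- vapply(snp_positions, function(p) {
    sample(setdiff(BASES, ref[p + 1L]), 1L)
  }, "")
  ref_str <- paste0(ref, collapse = "")

  fasta <- file.path(dir, "reference.fa")
  seqs <- Biostrings::DNAStringSet(ref_str)
  names(seqs) <- contig
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)

  bed <- file.path(dir, "homopolymers.bed")
  bed_df <- data.frame(contig = contig,
                       start = pmax(0L, hp$position - slop),
                       end = pmin(ref_length, hp$end + slop))
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # --- reads tiled across the homopolymers ----------------------------------
  which_hp <- rep_len(seq_len(nrow(hp)), n_reads)
  lo <- pmax(0L, hp$end[which_hp] - read_length)        # still overlaps run
  hi <- pmin(ref_length - read_length, hp$position[which_hp] + hp$length[which_hp] - 1L)
  hi <- pmax(hi, lo)
  start <- lo + floor(stats::runif(n_reads) * (hi - lo + 1L))  # 0-based
  strand_rev <- (seq_len(n_reads) %% 2L) == 0L

  seq_chars <- matrix("", nrow = n_reads, ncol = read_length)
  for (j in seq_len(read_length)) seq_chars[, j] <- ref[start + j]

  # planted SNPs: every covering read carries the alternate allele
  for (si in seq_along(snp_positions)) {
    p <- snp_positions[si]
    cov <- which(start <= p & start + read_length > p)
    if (length(cov)) seq_chars[cbind(cov, p - start[cov] + 1L)] <- snp_alt[si]
  }

  # per-stored-index error rate, honoring read orientation
  h0 <- hp$position[which_hp]; h1 <- hp$end[which_hp]
  n_pre_err <- n_post_err <- integer(n_reads)
  col_idx <- seq_len(read_length)
  for (i in seq_len(n_reads)) {
    refpos <- start[i] + col_idx - 1L
    # "pre"/"post" are read-orientation sides: a reverse-strand read enters
    # the locus from the high-coordinate end, so the sides swap.
    pre_side <- if (strand_rev[i]) refpos >= h1[i] else refpos < h0[i]
    post_side <- if (strand_rev[i]) refpos < h0[i] else refpos >= h1[i]
    rate <- rep(pre_error, read_length)    # run itself scored at pre_error
    rate[post_side] <- post_error
    hit <- stats::runif(read_length) < rate
    if (any(hit)) {
      cur <- seq_chars[i, hit]
      seq_chars[i, hit] <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), "")
      n_pre_err[i] <- sum(hit & pre_side)
      n_post_err[i] <- sum(hit & post_side)
    }
  }
  read_seq <- apply(seq_chars, 1, paste0, collapse = "")

  reads <- data.frame(
    qname = sprintf("read%06d", seq_len(n_reads)),
    flag = ifelse(strand_rev, 16L, 0L),
    pos = start + 1L,                      # SAM is 1-based
    mapq = 60L,
    cigar = paste0(read_length, "M"),
    seq = read_seq,
    n_pre_err = n_pre_err, n_post_err = n_post_err,
    hp_index = which_hp,
    stringsAsFactors = FALSE)

  if (n_filtered > 0) {
    fstart <- rep_len(hp$position[1], n_filtered)
    fseq <- substr(ref_str, fstart + 1L, fstart + read_length)
    fflags <- rep_len(c(256L, 2048L, 4L, 0L), n_filtered)   # the 0L gets MAPQ 0
    fmapq <- ifelse(fflags == 0L, 0L, 60L)
    filt <- data.frame(qname = sprintf("filtered%03d", seq_len(n_filtered)),
                       flag = fflags, pos = fstart + 1L, mapq = fmapq,
                       cigar = paste0(read_length, "M"), seq = fseq,
                       n_pre_err = 0L, n_post_err = 0L, hp_index = NA_integer_,
                       stringsAsFactors = FALSE)
    reads_all <- rbind(reads, filt)
  } else reads_all <- reads

  sam <- file.path(dir, "alignments.sam")
  write_sam(reads_all, sam, contig = contig, ref_length = ref_length)

  intervals <- data.frame(contig = contig, start = hp$position, end = hp$end,
                          base = hp$base, length = hp$length,
                          stringsAsFactors = FALSE)
  list(fasta = fasta, bed = bed, sam = sam, reference = ref_str,
       intervals = intervals, reads = reads,
       snp = data.frame(position = snp_positions, alt = snp_alt))
}

# Minimal SAM v1.6 writer for fixture records (coordinate-sorted, M-only or
# caller-supplied CIGARs). Quality string is uniform Q40.
write_sam <- function(records, path, contig, ref_length) {
  records <- records[order(records$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, as.integer(ref_length))), con)
  qual <- vapply(nchar(records$seq), function(n) strrep("I", n), "")
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     records$qname, records$flag, contig, records$pos,
                     records$mapq, records$cigar, records$seq, qual), con)
  invisible(path)
}
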