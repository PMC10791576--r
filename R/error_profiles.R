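# Alignment-based error characterization: homopolymer three-segment
# analysis with a per-offset error matrix, and k-mer context mismatch
# tables against a variant-masked reference.

#' Load homopolymer intervals from a slop-padded BED file
#'
#' Trims `slop` bases from each end of every interval to recover the exact
#' homopolymer run (the NIST stratification encodes 5-base slop in its
#' coordinates). When a reference is supplied, each trimmed interval is
#' verified to be a single-base run; failures are rejected with a message.
#'
#' @param path BED file (0-based, half-open, no header).
#' @param slop Padding to trim from each side (default 5).
#' @param reference Optional reference (FASTA path, `DNAStringSet`, named
#'   character vector, or [mask_known_sites()] result) for run validation.
#' @param min_length Minimum run length retained (default 12).
#' @return data.frame `(contig, start, end, base, length)`, 0-based
#'   half-open, slop-trimmed.
#' @export
load_homopolymer_bed <- function(path, slop = 5L, reference = NULL,
                                 min_length = 12L) {
  stopifnot(slop >= 0)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("contig", "start", "end")
  start <- bed$start + slop
  end <- bed$end - slop
  keep <- end > start
  if (any(!keep)) {
    message(sprintf("load_homopolymer_bed: %d rows empty after slop trim; rejected", sum(!keep)))
  }
  out <- data.frame(contig = bed$contig[keep], start = start[keep], end = end[keep],
                    base = NA_character_, length = end[keep] - start[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    ref <- as_reference(reference)
    ok <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      chars <- ref$chars[[out$contig[i]]][(out$start[i] + 1L):out$end[i]]
      ok[i] <- length(unique(chars)) == 1L
      if (ok[i]) out$base[i] <- chars[1]
    }
    if (any(!ok)) {
      message(sprintf("load_homopolymer_bed: %d trimmed intervals are not single-base runs; rejected", sum(!ok)))
      out <- out[ok, , drop = FALSE]
    }
  }
  short <- out$length < min_length
  if (any(short)) {
    message(sprintf("load_homopolymer_bed: %d runs below min_length %d; dropped", sum(short), min_length))
    out <- out[!short, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Filter alignment records for profiling
#'
#' Discards secondary, supplementary and unmapped records and reads with
#' mapping quality 0; removal counts by reason are attached as an attribute.
#'
#' @param aln Alignment data.frame from [read_alignments()].
#' @return Filtered data.frame with attribute `removed` (named counts).
#' @export
filter_reads <- function(aln) {
  fl <- aln$flag
  unmapped <- bitwAnd(fl, 4L) != 0L
  secondary <- bitwAnd(fl, 256L) != 0L
  suppl <- bitwAnd(fl, 2048L) != 0L
  mapq0 <- aln$mapq == 0L
  drop <- unmapped | secondary | suppl | mapq0
  out <- aln[!drop, , drop = FALSE]
  attr(out, "removed") <- c(unmapped = sum(unmapped), secondary = sum(secondary),
                            supplementary = sum(suppl), mapq0 = sum(mapq0 & !(unmapped | secondary | suppl)))
  out
}

# Expand one alignment into per-column vectors. Returns ref_pos (0-based),
# read_idx (1-based index into the stored SEQ), read/ref bases. S and I
# consume read only; D and N consume reference only; none emit columns.
expand_alignment <- function(pos, cigar, seq, ref_chars) {
  L <- nchar(seq)
  if (grepl("^[0-9]+M$", cigar)) {            # fast path: gapless alignment
    read_idx <- seq_len(L)
    ref_pos <- (pos - 1L) + read_idx - 1L
  } else {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    n_op <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    c_op <- substr(ops, nchar(ops), nchar(ops))
    read_idx <- integer(0); ref_pos <- integer(0)
    rc <- 1L; fc <- pos - 1L                  # read cursor (1-based), ref (0-based)
    for (i in seq_along(c_op)) {
      n <- n_op[i]
      switch(c_op[i],
        M = , `=` = , X = {
          read_idx <- c(read_idx, rc:(rc + n - 1L))
          ref_pos <- c(ref_pos, fc:(fc + n - 1L))
          rc <- rc + n; fc <- fc + n
        },
        I = , S = { rc <- rc + n },
        D = , N = { fc <- fc + n },
        H = , P = NULL)
    }
  }
  read_base <- substring(seq, read_idx, read_idx)
  list(ref_pos = ref_pos, read_idx = read_idx, read_base = read_base,
       ref_base = ref_chars[ref_pos + 1L])
}

#' Segment an aligned read around a homopolymer
#'
#' Orients the read 5'->3' and splits its aligned columns into the segment
#' preceding the homopolymer, the one overlapping it, and the one following
#' it (reference projection defines the overlap). Mismatches are counted per
#' segment excluding N-calls, soft-clipped bases, indel columns and masked
#' positions. Reads whose pre or post segment holds fewer than `min_flank`
#' aligned bases are discarded, as are reads lying entirely inside the run.
#'
#' @param read One alignment record (list/row with `pos`, `cigar`, `seq`,
#'   `flag`).
#' @param interval One homopolymer interval (`start`, `end`, 0-based
#'   half-open, slop already trimmed).
#' @param ref_chars Reference sequence of the read's contig as a character
#'   vector.
#' @param mask Optional logical vector (TRUE = masked position) along the
#'   contig.
#' @param min_flank Minimum aligned bases required in each flank (default 5).
#' @return List with per-segment aligned-base and mismatch counts
#'   (`pre_n`, `pre_mm`, `overlap_n`, `overlap_mm`, `post_n`, `post_mm`),
#'   `strand`, and `offsets`/`offset_mm` (positional offsets in read
#'   orientation: 0 = first base after the run's 3' end, negative = before
#'   the run); or `NULL` with attribute `reason` when discarded.
#' @export
segment_read <- function(read, interval, ref_chars, mask = NULL, min_flank = 5L) {
  col <- expand_alignment(read$pos, read$cigar, read$seq, ref_chars)
  if (!length(col$ref_pos)) return(discard("no_aligned_bases"))
  rev_strand <- bitwAnd(read$flag, 16L) != 0L

  usable <- col$read_base != "N" & col$ref_base != "N"
  mm <- usable & (col$read_base != col$ref_base)
  if (!is.null(mask)) {
    masked <- mask[col$ref_pos + 1L]
    usable <- usable & !masked
    mm <- mm & !masked
  }

  h0 <- interval$start; h1 <- interval$end      # 0-based half-open
  in_run <- col$ref_pos >= h0 & col$ref_pos < h1
  before <- col$ref_pos < h0
  after <- col$ref_pos >= h1
  # read orientation: for a reverse-strand read the 5' end is the
  # high-coordinate side, so "pre" and "post" swap
  pre <- if (rev_strand) after else before
  post <- if (rev_strand) before else after

  pre_n <- sum(usable & pre); post_n <- sum(usable & post)
  if (pre_n == 0 && post_n == 0) return(discard("inside_interval"))
  if (pre_n < min_flank || post_n < min_flank) return(discard("short_flank"))

  # positional offset in read orientation; 0 = first base after the 3' end
  offset <- integer(length(col$ref_pos))
  if (rev_strand) {
    offset[post] <- h0 - 1L - col$ref_pos[post]
    offset[pre] <- col$ref_pos[pre] - h1
    offset[in_run] <- NA_integer_
    offset[pre] <- -(offset[pre] + 1L)
  } else {
    offset[post] <- col$ref_pos[post] - h1
    offset[pre] <- -(h0 - col$ref_pos[pre])
    offset[in_run] <- NA_integer_
  }

  list(pre_n = pre_n, pre_mm = sum(mm & pre),
       overlap_n = sum(usable & in_run), overlap_mm = sum(mm & in_run),
       post_n = post_n, post_mm = sum(mm & post),
       strand = if (rev_strand) "-" else "+",
       offsets = offset[usable], offset_mm = mm[usable])
}

discard <- function(reason) structure(list(), reason = reason, class = "discarded_read")

#' Homopolymer error summary over an alignment set
#'
#' Aggregates [segment_read()] over every read x overlapping-interval pair:
#' mean pre/overlap/post mismatch percentages, the per-offset error matrix,
#' and per-interval pre/post rates with their pairwise difference.
#'
#' @param alignments Alignment data.frame (will be passed through
#'   [filter_reads()]).
#' @param intervals Interval data.frame from [load_homopolymer_bed()] (or
#'   the fixture generator's `intervals`).
#' @param reference Reference (FASTA path, `DNAStringSet`, named character
#'   vector, or masked reference).
#' @param min_flank Minimum flank length (default 5).
#' @return List: `per_segment` data.frame (segment, bases, mismatches,
#'   rate_pct), `offset_matrix` data.frame (offset, bases, mismatches,
#'   rate_pct), `per_interval` data.frame, `n_reads_used`, `discarded`
#'   (named counts).
#' @export
homopolymer_error_summary <- function(alignments, intervals, reference,
                                      min_flank = 5L) {
  ref <- as_reference(reference)
  aln <- filter_reads(alignments)
  if (nrow(aln) == 0 || nrow(intervals) == 0) {
    warning("no qualifying reads or intervals; empty result")
    return(list(per_segment = empty_segments(), offset_matrix = NULL,
                per_interval = NULL, n_reads_used = 0L,
                discarded = attr(aln, "removed")))
  }
  ref_width <- cigar_ref_width(aln$cigar)
  aln_end <- aln$pos - 1L + ref_width           # 0-based exclusive

  seg_tot <- c(pre = 0, overlap = 0, post = 0)
  seg_mm <- c(pre = 0, overlap = 0, post = 0)
  max_off <- max(nchar(aln$seq))
  off_n <- numeric(2L * max_off + 1L)           # offsets -max_off..max_off
  off_mm <- numeric(2L * max_off + 1L)
  iv_rows <- vector("list", nrow(intervals))
  n_used <- 0L
  disc <- c(no_aligned_bases = 0L, inside_interval = 0L, short_flank = 0L)

  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    chars <- ref$chars[[iv$contig]]
    msk <- ref$mask[[iv$contig]]
    hit <- which(aln$rname == iv$contig & aln$pos - 1L < iv$end & aln_end > iv$start)
    acc <- c(pre_n = 0, pre_mm = 0, post_n = 0, post_mm = 0)
    for (j in hit) {
      sr <- segment_read(aln[j, ], iv, chars, mask = msk, min_flank = min_flank)
      if (inherits(sr, "discarded_read")) {
        r <- attr(sr, "reason"); disc[r] <- disc[r] + 1L
        next
      }
      n_used <- n_used + 1L
      seg_tot <- seg_tot + c(sr$pre_n, sr$overlap_n, sr$post_n)
      seg_mm <- seg_mm + c(sr$pre_mm, sr$overlap_mm, sr$post_mm)
      acc <- acc + c(sr$pre_n, sr$pre_mm, sr$post_n, sr$post_mm)
      ok <- !is.na(sr$offsets) & abs(sr$offsets) <= max_off
      idx <- sr$offsets[ok] + max_off + 1L
      off_n <- off_n + tabulate(idx, length(off_n))
      if (any(sr$offset_mm[ok])) {
        off_mm <- off_mm + tabulate(idx[sr$offset_mm[ok]], length(off_mm))
      }
    }
    iv_rows[[i]] <- data.frame(
      contig = iv$contig, start = iv$start, end = iv$end,
      length = iv$end - iv$start,
      pre_rate_pct = 100 * acc[["pre_mm"]] / max(acc[["pre_n"]], 1),
      post_rate_pct = 100 * acc[["post_mm"]] / max(acc[["post_n"]], 1),
      pre_n = acc[["pre_n"]], post_n = acc[["post_n"]],
      stringsAsFactors = FALSE)
  }
  per_interval <- do.call(rbind, iv_rows)
  per_interval$diff_pct <- per_interval$post_rate_pct - per_interval$pre_rate_pct

  keep <- off_n > 0
  offsets <- seq(-max_off, max_off)[keep]
  per_segment <- data.frame(
    segment = c("pre", "overlap", "post"),
    bases = unname(seg_tot), mismatches = unname(seg_mm),
    rate_pct = unname(100 * seg_mm / pmax(seg_tot, 1)))
  if (n_used == 0L) warning("zero qualifying reads after segmentation filters")
  list(per_segment = per_segment,
       offset_matrix = data.frame(offset = offsets, bases = off_n[keep],
                                  mismatches = off_mm[keep],
                                  rate_pct = 100 * off_mm[keep] / off_n[keep]),
       per_interval = per_interval,
       n_reads_used = n_used,
       discarded = c(attr(aln, "removed"), disc))
}

empty_segments <- function() {
  data.frame(segment = c("pre", "overlap", "post"), bases = 0, mismatches = 0,
             rate_pct = NA_real_)
}

# reference-consumed width per CIGAR (M/=/X/D/N)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (grepl("^[0-9]+M$", cg)) return(as.integer(sub("M$", "", cg)))
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "=", "X", "D", "N")])
  }, 1L, USE.NAMES = FALSE)
}

#' Mask known variant sites in a reference
#'
#' Masked positions are excluded from every mismatch count and contribute
#' to no k-mer instance, so true polymorphisms are not scored as sequencing
#' errors.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param sites Either a BED-style data.frame/file (`contig`, `start`,
#'   `end`; 0-based half-open) or a VCF file path (positions of all records
#'   are masked).
#' @return Object of class `masked_reference` usable wherever a reference is
#'   accepted.
#' @export
mask_known_sites <- function(reference, sites) {
  ref <- as_reference(reference)
  if (is.character(sites) && length(sites) == 1) {
    sites <- if (grepl("\\.vcf(\\.gz)?$", sites)) read_vcf_sites(sites)
             else {
               b <- utils::read.table(sites, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
               names(b) <- c("contig", "start", "end"); b
             }
  }
  sites <- as.data.frame(sites)
  stopifnot(all(c("contig", "start", "end") %in% names(sites)))
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig[i]
    if (!ctg %in% names(ref$chars)) stop(sprintf("mask contig '%s' not in reference", ctg))
    len <- length(ref$chars[[ctg]])
    if (sites$start[i] < 0 || sites$end[i] > len || sites$end[i] <= sites$start[i]) {
      stop(sprintf("mask interval %s:%d-%d out of reference bounds (length %d)",
                   ctg, sites$start[i], sites$end[i], len))
    }
    ref$mask[[ctg]][(sites$start[i] + 1L):sites$end[i]] <- TRUE
  }
  ref
}

read_vcf_sites <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) return(data.frame(contig = character(), start = integer(), end = integer()))
  f <- strsplit(ln, "\t")
  data.frame(contig = vapply(f, `[[`, "", 1),
             start = as.integer(vapply(f, `[[`, "", 2)) - 1L,  # VCF is 1-based
             end = as.integer(vapply(f, `[[`, "", 2)) - 1L +
               nchar(vapply(f, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

# Normalize any accepted reference form to list(chars = per-contig character
# vectors, mask = per-contig logical vectors).
as_reference <- function(reference) {
  if (inherits(reference, "masked_reference")) return(reference)
  if (is.character(reference) && length(reference) == 1 && file.exists(reference) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    seqs <- as.character(reference)
    names(seqs) <- nm
    reference <- seqs
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  chars <- lapply(reference, function(s) strsplit(toupper(s), "")[[1]])
  mask <- lapply(chars, function(ch) rep(FALSE, length(ch)))
  structure(list(chars = chars, mask = mask), class = "masked_reference")
}

#' k-mer context mismatch table
#'
#' For k in 1..3, counts every instance of each reference k-mer — a window
#' of k consecutive reference positions fully covered by aligned,
#' non-clipped, non-indel, non-N, non-masked read bases — and the fraction
#' of instances containing at least one mismatch. Contexts are keyed in
#' read (sequencing) orientation by default: the reference context of a
#' reverse-strand read is reverse-complemented.
#'
#' @param alignments Alignment data.frame (passed through [filter_reads()]).
#' @param reference Reference or masked reference.
#' @param k Context size, 1, 2 or 3.
#' @param read_oriented Key contexts in read orientation (default TRUE) or
#'   reference orientation.
#' @param sample_fraction Fraction of reads used (seeded subsampling; 1 =
#'   all).
#' @param seed Seed for subsampling.
#' @return data.frame with `4^k` rows: `kmer`, `instances`, `mismatching`,
#'   `pct_mismatch`.
#' @export
kmer_mismatch_table <- function(alignments, reference, k, read_oriented = TRUE,
                                sample_fraction = 1, seed = 1L) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  ref <- as_reference(reference)
  aln <- filter_reads(alignments)
  if (sample_fraction < 1) {
    local_rng(seed)
    aln <- aln[sort(sample.int(nrow(aln), ceiling(nrow(aln) * sample_fraction))), ,
               drop = FALSE]
  }
  nk <- 4L^k
  inst <- numeric(nk); mism <- numeric(nk)
  pow <- 4L^((k - 1L):0L)
  for (j in seq_len(nrow(aln))) {
    ctg <- aln$rname[j]
    col <- expand_alignment(aln$pos[j], aln$cigar[j], aln$seq[j], ref$chars[[ctg]])
    if (length(col$ref_pos) < k) next
    rev_strand <- bitwAnd(aln$flag[j], 16L) != 0L
    rb <- col$read_base; fb <- col$ref_base
    rp <- col$ref_pos; ri <- col$read_idx
    msk <- ref$mask[[ctg]][rp + 1L]
    if (read_oriented && rev_strand) {
      ord <- rev(seq_along(rp))
      rb <- comp_base(rb[ord]); fb <- comp_base(fb[ord])
      msk <- msk[ord]
      rp <- -rp[ord]; ri <- -ri[ord]            # keep "consecutive" = diff 1
    }
    code <- match(fb, BASES) - 1L
    ok <- rb != "N" & fb != "N" & !is.na(code) & !msk
    mmv <- as.integer(ok & (rb != fb))
    n <- length(rp)
    if (n < k) next
    nw <- n - k + 1L
    valid <- ok[seq_len(nw)]
    kcode <- code[seq_len(nw)] * pow[1]
    msum <- mmv[seq_len(nw)]
    if (k > 1) {
      contig_ref <- diff(rp) == 1L
      contig_read <- diff(ri) == 1L
      for (d in 1:(k - 1L)) {
        sl <- seq_len(nw) + d
        valid <- valid & ok[sl] & contig_ref[sl - 1L] & contig_read[sl - 1L]
        kcode <- kcode + code[sl] * pow[d + 1L]
        msum <- msum + mmv[sl]
      }
    }
    vi <- which(valid)
    if (!length(vi)) next
    inst <- inst + tabulate(kcode[vi] + 1L, nk)
    hit <- vi[msum[vi] > 0]
    if (length(hit)) mism <- mism + tabulate(kcode[hit] + 1L, nk)
  }
  # codes enumerate base-4 with the first base most significant
  kmers <- vapply(0:(nk - 1L), function(i) {
    paste0(BASES[(i %/% pow) %% 4L + 1L], collapse = "")
  }, "")
  data.frame(kmer = kmers, instances = inst, mismatching = mism,
             pct_mismatch = 100 * mism / pmax(inst, 1),
             stringsAsFactors = FALSE)
}

comp_base <- function(b) {
  out <- b
  out[b == "A"] <- "T"; out[b == "T"] <- "A"
  out[b == "C"] <- "G"; out[b == "G"] <- "C"
  out
}

#' Cross-platform k-mer win counts
#'
#' Given k-mer mismatch tables over the identical context set (first = the
#' platform of interest), counts the contexts where the first table's
#' mismatch percentage is strictly lowest; ties for lowest are reported
#' separately.
#'
#' @param tables List of [kmer_mismatch_table()] results (>= 2).
#' @return List: `wins`, `ties`, `losses`, and the per-context comparison
#'   data.frame.
#' @export
compare_platforms <- function(tables) {
  stopifnot(length(tables) >= 2)
  km <- tables[[1]]$kmer
  for (tb in tables[-1]) {
    if (!identical(tb$kmer, km)) stop("k-mer row sets differ between tables")
  }
  first <- tables[[1]]$pct_mismatch
  others <- do.call(cbind, lapply(tables[-1], `[[`, "pct_mismatch"))
  best_other <- apply(others, 1, min)
  wins <- first < best_other
  ties <- first == best_other
  list(wins = sum(wins), ties = sum(ties), losses = sum(!wins & !ties),
       detail = data.frame(kmer = km, first = first, best_other = best_other,
                           outcome = ifelse(wins, "win", ifelse(ties, "tie", "loss"))))
}
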