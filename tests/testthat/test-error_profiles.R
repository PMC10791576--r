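# Error profiling: BED slop handling, read filters, segmentation, the
# per-offset matrix, masking, k-mer tables, platform comparison. Counting
# correctness is checked against the naive per-base walker in the helpers.

test_that("BED loading trims slop and validates runs against the reference", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t95\t125", bed)
  iv <- load_homopolymer_bed(bed, slop = 5, min_length = 12)
  expect_equal(c(iv$start, iv$end, iv$length), c(100, 120, 20))
  iv0 <- load_homopolymer_bed(bed, slop = 0, min_length = 12)
  expect_equal(c(iv0$start, iv0$end), c(95, 125))

  # fixture BED: every trimmed interval verified homopolymeric
  fx <- small_fixture(n_reads = 10)
  ivf <- load_homopolymer_bed(fx$bed, slop = 5, reference = fx$fasta)
  expect_equal(ivf$base, "A")
  expect_equal(ivf$length, 15)

  # a non-homopolymeric trimmed interval is rejected when reference given
  bad <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d", "synthref", 5, 40), bad)
  expect_message(ivb <- load_homopolymer_bed(bad, slop = 5, reference = fx$fasta),
                 "not single-base")
  expect_equal(nrow(ivb), 0)
})

test_that("read filtering removes exactly the flagged and MAPQ-0 records", {
  fx <- small_fixture(n_reads = 25, n_filtered = 8)
  aln <- read_alignments(fx$sam)
  expect_equal(nrow(aln), 33)
  kept <- filter_reads(aln)
  expect_equal(nrow(kept), 25)
  expect_true(all(startsWith(kept$qname, "read")))
  rem <- attr(kept, "removed")
  expect_equal(sum(rem), 8)
  expect_true(all(rem[c("unmapped", "secondary", "supplementary", "mapq0")] == 2))
})

test_that("segmentation reproduces the 150-bp worked example and strand flip", {
  ref <- paste0(c(rep("C", 99), rep("A", 21), rep("G", 200)), collapse = "")
  iv <- list(start = 99, end = 120)          # run at read positions 100-120 (1-based)
  read <- list(pos = 1L, cigar = "150M", seq = substr(ref, 1, 150), flag = 0L)
  chars <- strsplit(ref, "")[[1]]
  sr <- segment_read(read, iv, chars)
  expect_equal(sr$pre_n, 99)
  expect_equal(sr$post_n, 30)
  expect_equal(sr$overlap_n, 21)

  # same geometry on the reverse strand swaps the flanks
  read_rev <- modifyList(read, list(flag = 16L))
  srr <- segment_read(read_rev, iv, chars)
  expect_equal(srr$pre_n, 30)
  expect_equal(srr$post_n, 99)

  # offset convention: 0 = first base after the run's 3' end, read oriented
  expect_equal(min(sr$offsets[sr$offsets >= 0], na.rm = TRUE), 0)
  expect_equal(range(sr$offsets[!is.na(sr$offsets) & sr$offsets < 0]), c(-99, -1))
  expect_equal(sum(!is.na(srr$offsets) & srr$offsets >= 0), 99)

  # a 4-base flank fails the minimum-flank rule
  short <- list(pos = 96L, cigar = "40M", seq = substr(ref, 96, 135), flag = 0L)
  expect_s3_class(segment_read(short, iv, chars), "discarded_read")
  expect_equal(attr(segment_read(short, iv, chars), "reason"), "short_flank")

  # read entirely inside the run is discarded
  inside <- list(pos = 101L, cigar = "18M", seq = substr(ref, 101, 118), flag = 0L)
  expect_equal(attr(segment_read(inside, iv, chars), "reason"), "inside_interval")
})

test_that("segment counts equal the brute-force walker, CIGARs included", {
  fx <- small_fixture(n_reads = 40, pre_error = 0.05, post_error = 0.15)
  aln <- read_alignments(fx$sam)
  iv <- fx$intervals
  chars <- strsplit(fx$reference, "")[[1]]

  # add gapped and clipped records around the run
  extra <- data.frame(
    qname = c("gap1", "gap2", "clip1"),
    flag = c(0L, 16L, 0L),
    pos = c(151L, 156L, 161L),
    mapq = 60L,
    cigar = c("30M2D30M", "25M3I22M", "8S40M"),
    seq = NA, stringsAsFactors = FALSE)
  mkseq <- function(pos, cigar) {
    w <- walk_alignment(pos, cigar, strrep("N", 200), fx$reference)
    # fill aligned columns from the reference, then mutate two of them
    qlen <- sum(as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]][
      regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]] %in% c("M", "I", "S")]))
    s <- rep("A", qlen)
    s[w$read_idx] <- w$ref_base
    s[w$read_idx[c(3, 10)]] <- vapply(w$ref_base[c(3, 10)], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste0(s, collapse = "")
  }
  for (i in 1:3) extra$seq[i] <- mkseq(extra$pos[i], extra$cigar[i])
  all_reads <- rbind(aln[, names(extra)], extra)

  for (j in seq_len(nrow(all_reads))) {
    r <- all_reads[j, ]
    got <- segment_read(list(pos = r$pos, cigar = r$cigar, seq = r$seq,
                             flag = r$flag),
                        list(start = iv$start, end = iv$end), chars)
    want <- brute_segments(r$pos, r$cigar, r$seq, r$flag, fx$reference,
                           iv$start, iv$end)
    if (inherits(got, "discarded_read")) {
      expect_true(want$pre_n < 5 || want$post_n < 5)
    } else {
      expect_equal(got[c("pre_n", "pre_mm", "overlap_n", "overlap_mm",
                         "post_n", "post_mm")], want)
      # segment additivity over usable aligned columns
      cols <- walk_alignment(r$pos, r$cigar, r$seq, fx$reference)
      usable <- sum(cols$read_base != "N" & cols$ref_base != "N")
      expect_equal(got$pre_n + got$overlap_n + got$post_n, usable)
    }
  }
})

test_that("summary aggregates recover injected rates and the offset matrix is conserved", {
  fx <- small_fixture(n_reads = 3000, pre_error = 0.004, post_error = 0.02,
                      seed = 77)
  aln <- read_alignments(fx$sam)
  res <- homopolymer_error_summary(aln, fx$intervals, fx$fasta)
  seg <- res$per_segment
  pre_hat <- seg$rate_pct[seg$segment == "pre"] / 100
  post_hat <- seg$rate_pct[seg$segment == "post"] / 100
  # 3-sigma binomial bands around the injected rates (single-draw check)
  ci <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(pre_hat - 0.004), ci(0.004, seg$bases[seg$segment == "pre"]) + 1e-4)
  expect_lt(abs(post_hat - 0.02), ci(0.02, seg$bases[seg$segment == "post"]) + 1e-4)

  # offset matrix totals equal the segment totals they partition
  om <- res$offset_matrix
  expect_equal(sum(om$bases[om$offset >= 0]), seg$bases[seg$segment == "post"])
  expect_equal(sum(om$bases[om$offset < 0]), seg$bases[seg$segment == "pre"])
  expect_equal(sum(om$mismatches), sum(seg$mismatches[seg$segment != "overlap"]))

  # equal-rate fixture: pre/post difference compatible with zero
  fx0 <- small_fixture(n_reads = 2000, pre_error = 0.01, post_error = 0.01,
                       seed = 78)
  res0 <- homopolymer_error_summary(read_alignments(fx0$sam), fx0$intervals,
                                    fx0$fasta)
  seg0 <- res0$per_segment
  d <- abs(seg0$rate_pct[3] - seg0$rate_pct[1]) / 100
  expect_lt(d, 1.96 * sqrt(2 * 0.01 * 0.99 / min(seg0$bases[c(1, 3)])) + 5e-4)
})

test_that("profiling is invariant under reverse-complementing the fixture", {
  fx <- small_fixture(n_reads = 60, pre_error = 0.02, post_error = 0.08, seed = 13)
  aln <- read_alignments(fx$sam)
  res <- homopolymer_error_summary(aln, fx$intervals, fx$fasta)

  # mirror: revcomp reference, flip reads
  L <- nchar(fx$reference)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste0(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  ref_rc <- setNames(rc(fx$reference), "synthref")
  rl <- nchar(aln$seq[1])
  aln_rc <- aln
  aln_rc$pos <- L - (aln$pos - 1L + rl) + 1L
  aln_rc$seq <- vapply(aln$seq, rc, "")
  aln_rc$flag <- bitwXor(aln$flag, 16L)
  iv_rc <- fx$intervals
  iv_rc$start <- L - fx$intervals$end
  iv_rc$end <- L - fx$intervals$start
  res_rc <- homopolymer_error_summary(aln_rc, iv_rc, ref_rc)
  expect_equal(res_rc$per_segment, res$per_segment)
})

test_that("masking excludes planted SNPs from mismatch and k-mer counts", {
  fx <- generate_profiling_fixture(tempfile(), seed = 21, ref_length = 400,
    homopolymers = data.frame(base = "A", length = 15, position = 180),
    pre_error = 0, post_error = 0, n_reads = 60, read_length = 60,
    snp_positions = c(150, 230))
  aln <- read_alignments(fx$sam)

  unmasked <- homopolymer_error_summary(aln, fx$intervals, fx$fasta)
  expect_gt(sum(unmasked$per_segment$mismatches), 0)

  mask <- data.frame(contig = "synthref", start = c(150, 230), end = c(151, 231))
  masked_ref <- mask_known_sites(fx$fasta, mask)
  masked <- homopolymer_error_summary(aln, fx$intervals, masked_ref)
  expect_equal(sum(masked$per_segment$mismatches), 0)

  # the drop equals exactly the SNP base count; the segment summary only
  # sees reads passing the 5-base flank rule (run at [180, 195), 60-bp reads)
  kept <- (180 - (aln$pos - 1L)) >= 5 & ((aln$pos - 1L) + 60 - 195) >= 5
  snp_cov_kept <- sum(vapply(c(150, 230), function(p)
    sum(kept & aln$pos - 1L <= p & aln$pos - 1L + 60 > p), 0))
  expect_equal(sum(unmasked$per_segment$bases) - sum(masked$per_segment$bases),
               snp_cov_kept)
  snp_cov <- sum(vapply(c(150, 230), function(p)
    sum(aln$pos - 1L <= p & aln$pos - 1L + 60 > p), 0))

  # k-mer: masked positions contribute to no instance
  t1u <- kmer_mismatch_table(aln, fx$fasta, 1)
  t1m <- kmer_mismatch_table(aln, masked_ref, 1)
  expect_equal(sum(t1u$instances) - sum(t1m$instances), snp_cov)
  expect_equal(sum(t1m$mismatching), 0)

  expect_error(mask_known_sites(fx$fasta,
    data.frame(contig = "synthref", start = 399, end = 450)), "bounds")
})

test_that("k-mer tables enumerate contexts and match the closed form and walker", {
  fx <- small_fixture(n_reads = 400, pre_error = 0.01, post_error = 0.01, seed = 31)
  aln <- read_alignments(fx$sam)
  for (k in 1:3) {
    tb <- kmer_mismatch_table(aln, fx$fasta, k)
    expect_equal(nrow(tb), 4^k)
    expect_true(all(tb$pct_mismatch >= 0 & tb$pct_mismatch <= 100))
  }
  expect_error(kmer_mismatch_table(aln, fx$fasta, 4), "k must be")

  # uniform error e: expected instance mismatch fraction 1 - (1-e)^k
  tb2 <- kmer_mismatch_table(aln, fx$fasta, 2)
  e <- 0.01
  frac <- sum(tb2$mismatching) / sum(tb2$instances)
  expval <- 1 - (1 - e)^2
  n_inst <- sum(tb2$instances)
  expect_lt(abs(frac - expval), 1.96 * sqrt(expval * (1 - expval) / n_inst) + 2e-3)

  # brute-force agreement on a small mixed-strand subset
  sub <- read_alignments(fx$sam)
  sub <- sub[1:30, ]
  for (k in 1:3) {
    tb <- kmer_mismatch_table(sub, fx$fasta, k)
    naive <- do.call(rbind, lapply(seq_len(nrow(sub)), function(j)
      brute_kmers(sub$pos[j], sub$cigar[j], sub$seq[j], sub$flag[j],
                  fx$reference, k)))
    want_inst <- table(factor(naive$kmer, levels = tb$kmer))
    want_mm <- table(factor(naive$kmer[naive$mismatch], levels = tb$kmer))
    expect_equal(unname(tb$instances), as.vector(want_inst))
    expect_equal(unname(tb$mismatching), as.vector(want_mm))
  }

  # reference-orientation mode differs from read orientation on '-' reads
  rev_only <- aln[bitwAnd(aln$flag, 16L) != 0L, ][1:20, ]
  t_read <- kmer_mismatch_table(rev_only, fx$fasta, 1)
  t_ref <- kmer_mismatch_table(rev_only, fx$fasta, 1, read_oriented = FALSE)
  comp_order <- match(c("T", "G", "C", "A"), c("A", "C", "G", "T"))
  expect_equal(t_read$instances, t_ref$instances[comp_order])
})

test_that("platform comparison counts strict wins and ties", {
  fx <- small_fixture(n_reads = 100, seed = 41)
  aln <- read_alignments(fx$sam)
  tb <- kmer_mismatch_table(aln, fx$fasta, 2)
  expect_equal(compare_platforms(list(tb, tb))$ties, 16)
  expect_equal(compare_platforms(list(tb, tb))$wins, 0)

  better <- tb; better$pct_mismatch <- tb$pct_mismatch + 1
  worse <- tb; worse$pct_mismatch <- tb$pct_mismatch + 2
  expect_equal(compare_platforms(list(tb, better, worse))$wins, 16)

  # planted ordering: first best on a known subset only
  a <- tb; b <- tb
  a$pct_mismatch <- rep(1, 16); b$pct_mismatch <- rep(2, 16)
  a$pct_mismatch[1:5] <- 3
  cmp <- compare_platforms(list(a, b))
  expect_equal(cmp$wins, 11)
  expect_equal(cmp$losses, 5)

  bad <- tb[rev(seq_len(nrow(tb))), ]
  expect_error(compare_platforms(list(tb, bad)), "differ")
})
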