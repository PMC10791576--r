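# Shared fixtures and independent oracles. The oracles deliberately share no
# code with the package: the walker re-parses CIGARs one operation at a time
# and counts per base; the strand simulator realizes phasing by sampling.

default_crosstalk <- function() {
  matrix(c(1, .08, .02, .01,
           .06, 1, .05, .02,
           .03, .04, 1, .07,
           .01, .02, .06, 1), 4, 4)
}

# Monte-Carlo oracle for the phasing state distribution: simulate strand
# positions explicitly and tabulate.
mc_state_distribution <- function(p_lag, p_lead, cycles, n_strands, seed) {
  set.seed(seed)
  pos <- rep(0L, n_strands)
  out <- matrix(0, cycles, 2L * cycles - 1L)
  out[1, ] <- tabulate(pos + 1L, 2L * cycles - 1L) / n_strands
  for (t in seq_len(cycles - 1L)) {
    u <- runif(n_strands)
    step <- ifelse(u < p_lag, 0L, ifelse(u < p_lag + p_lead, 2L, 1L))
    pos <- pos + step
    out[t + 1L, ] <- tabulate(pos + 1L, 2L * cycles - 1L) / n_strands
  }
  out
}

# Naive per-base alignment walker: returns one row per aligned column with
# 0-based ref position, 1-based stored-seq index, read base and ref base.
walk_alignment <- function(pos, cigar, seq, ref_str) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  rows <- list()
  rp <- pos - 1L   # 0-based ref
  qi <- 1L         # 1-based read
  for (i in seq_along(ops)) {
    for (rep in seq_len(nums[i])) {
      if (ops[i] %in% c("M", "=", "X")) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_pos = rp, read_idx = qi,
          read_base = substr(seq, qi, qi),
          ref_base = substr(ref_str, rp + 1L, rp + 1L))
        rp <- rp + 1L; qi <- qi + 1L
      } else if (ops[i] %in% c("I", "S")) {
        qi <- qi + 1L
      } else if (ops[i] %in% c("D", "N")) {
        rp <- rp + 1L
      }
    }
  }
  do.call(rbind, rows)
}

# Brute-force three-segment counts for one read (read 5'->3' orientation),
# mirroring the filtering rules but computed per base from walk_alignment.
brute_segments <- function(pos, cigar, seq, flag, ref_str, h0, h1,
                           mask = integer()) {
  cols <- walk_alignment(pos, cigar, seq, ref_str)
  rev_strand <- bitwAnd(flag, 16L) != 0L
  res <- list(pre_n = 0L, pre_mm = 0L, overlap_n = 0L, overlap_mm = 0L,
              post_n = 0L, post_mm = 0L)
  for (i in seq_len(nrow(cols))) {
    rb <- cols$read_base[i]; fb <- cols$ref_base[i]
    if (rb == "N" || fb == "N") next
    if (cols$ref_pos[i] %in% mask) next
    seg <- if (cols$ref_pos[i] < h0) {
      if (rev_strand) "post" else "pre"
    } else if (cols$ref_pos[i] >= h1) {
      if (rev_strand) "pre" else "post"
    } else "overlap"
    res[[paste0(seg, "_n")]] <- res[[paste0(seg, "_n")]] + 1L
    if (rb != fb) res[[paste0(seg, "_mm")]] <- res[[paste0(seg, "_mm")]] + 1L
  }
  res
}

# Brute-force k-mer instance/mismatch counts for one read, in read
# orientation for reverse-strand records.
brute_kmers <- function(pos, cigar, seq, flag, ref_str, k, mask = integer()) {
  cols <- walk_alignment(pos, cigar, seq, ref_str)
  rev_strand <- bitwAnd(flag, 16L) != 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  inst <- character(); mm <- logical()
  if (rev_strand) cols <- cols[rev(seq_len(nrow(cols))), , drop = FALSE]
  n <- nrow(cols)
  for (i in seq_len(max(0L, n - k + 1L))) {
    w <- cols[i:(i + k - 1L), , drop = FALSE]
    step <- if (rev_strand) -1L else 1L
    if (k > 1 && (any(diff(w$ref_pos) != step) || any(diff(w$read_idx) != step))) next
    if (any(w$read_base == "N" | w$ref_base == "N")) next
    if (any(w$ref_pos %in% mask)) next
    km <- w$ref_base
    if (rev_strand) km <- unname(comp[km])
    inst <- c(inst, paste0(km, collapse = ""))
    mm <- c(mm, any(w$read_base != w$ref_base))
  }
  data.frame(kmer = inst, mismatch = mm, stringsAsFactors = FALSE)
}

# Small standard fixture used by several tests.
small_fixture <- function(dir = tempfile("fx"), seed = 42, n_reads = 40,
                          pre_error = 0.02, post_error = 0.1,
                          read_length = 60, n_filtered = 0) {
  generate_profiling_fixture(dir, seed = seed, ref_length = 400,
                             homopolymers = data.frame(base = "A", length = 15,
                                                       position = 180),
                             pre_error = pre_error, post_error = post_error,
                             n_reads = n_reads, read_length = read_length,
                             n_filtered = n_filtered)
}
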