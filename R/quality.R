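# Empirical phred quality tables: four intensity-derived predictors,
# equal-frequency binning with pseudocount smoothing, phred+33 assignment,
# and predicted-vs-observed calibration assessment.

#' Phred score / error probability / ASCII conversions
#'
#' `phred_encode()` maps integer Q to the phred+33 ASCII character,
#' `phred_decode()` inverts it, and `q_to_error_prob()` /
#' `error_prob_to_q()` implement `Q = -10 * log10(p)`.
#'
#' @param q Integer quality scores.
#' @param chars Character vector of phred+33 symbols (single characters or
#'   one string per read).
#' @param p Error probabilities in `(0, 1]`.
#' @return See individual functions.
#' @name phred
NULL

#' @rdname phred
#' @export
phred_encode <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  vapply(as.integer(q), function(x) rawToChar(as.raw(x + 33L)), "")
}

#' @rdname phred
#' @export
phred_decode <- function(chars) {
  ints <- utf8ToInt(paste0(chars, collapse = "")) - 33L
  if (any(ints < 0)) stop("character below phred+33 range")
  ints
}

#' @rdname phred
#' @export
q_to_error_prob <- function(q) 10^(-q / 10)

#' @rdname phred
#' @export
error_prob_to_q <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  -10 * log10(p)
}

#' Compute the four quality predictors
#'
#' Per base call: (1) maximum normalized intensity across channels; (2)
#' clarity `(A + 1)/(B + 1)` where A and B are the highest and second
#' highest normalized channel intensities; (3) the run-level sum of phasing
#' and prephasing estimates; (4) cohort clarity, the per-cycle median
#' clarity of the 10% lowest-maximum-intensity polonies.
#'
#' @param ci Polony x cycle x channel array of normalized intensities.
#' @param p_lag,p_lead Run phasing estimates (scalars).
#' @return data.frame with one row per (polony, cycle) in polony-major
#'   order: `polony`, `cycle` (0-based), `max_intensity`, `clarity`,
#'   `phasing_sum`, `cohort_clarity`.
#' @export
compute_predictors <- function(ci, p_lag, p_lead) {
  stopifnot(length(dim(ci)) == 3, dim(ci)[3] == 4)
  dm <- dim(ci)
  flat <- matrix(ci, ncol = 4L)
  tt <- top_two(flat)
  clarity <- (tt$first + 1) / (tt$second + 1)
  maxint <- tt$first
  max_m <- matrix(maxint, dm[1], dm[2])
  cla_m <- matrix(clarity, dm[1], dm[2])
  k <- max(1L, floor(dm[1] * 0.10))
  cohort <- vapply(seq_len(dm[2]), function(t) {
    low <- order(max_m[, t])[seq_len(k)]
    stats::median(cla_m[low, t])
  }, 0)
  data.frame(polony = rep(seq_len(dm[1]), times = dm[2]),
             cycle = rep(seq_len(dm[2]) - 1L, each = dm[1]),
             max_intensity = maxint,
             clarity = clarity,
             phasing_sum = p_lag + p_lead,
             cohort_clarity = rep(cohort, each = dm[1]))
}

#' Train an empirical quality table
#'
#' Discretizes the predictor space into equal-frequency (quantile) bins,
#' tabulates error and total counts per bin against truth labels, applies
#' `(errors + 1)/(total + 2)` pseudocount smoothing, and converts to phred
#' `Q = round(-10 * log10(p))` clamped to `[2, q_cap]`. Bins with fewer than
#' `min_bin_count` observations are merged with their nearest neighbor along
#' the clarity axis.
#'
#' @param predictors data.frame from [compute_predictors()].
#' @param truth_errors Logical vector, TRUE where the call is an error,
#'   aligned 1:1 with `predictors` rows.
#' @param bins Named integer vector of bins per predictor.
#' @param min_bin_count Minimum observations per retained bin.
#' @param q_cap Maximum reported Q (default 45).
#' @return Object of class `quality_table`: bin `edges` per predictor, a
#'   `table` data.frame (bin indices, errors, total, q), and the smoothing /
#'   cap parameters.
#' @export
train_quality_table <- function(predictors, truth_errors,
                                bins = c(max_intensity = 8L, clarity = 12L,
                                         phasing_sum = 4L, cohort_clarity = 4L),
                                min_bin_count = 30L, q_cap = 45L) {
  if (nrow(predictors) == 0) stop("no training observations")
  stopifnot(length(truth_errors) == nrow(predictors))
  preds <- c("max_intensity", "clarity", "phasing_sum", "cohort_clarity")
  edges <- lapply(preds, function(p) {
    nb <- bins[[p]]
    e <- unique(stats::quantile(predictors[[p]], probs = seq(0, 1, length.out = nb + 1),
                                names = FALSE))
    if (length(e) < 2) e <- c(e, e + 1)          # constant predictor -> one bin
    e
  })
  names(edges) <- preds
  idx <- lapply(preds, function(p) bin_index(predictors[[p]], edges[[p]]))
  names(idx) <- preds

  key <- interaction(idx$max_intensity, idx$clarity, idx$phasing_sum,
                     idx$cohort_clarity, drop = TRUE)
  errors <- tapply(as.integer(truth_errors), key, sum)
  total <- tapply(rep(1L, length(key)), key, sum)
  parts <- do.call(rbind, strsplit(names(errors), ".", fixed = TRUE))
  tab <- data.frame(i_max = as.integer(parts[, 1]),
                    i_clarity = as.integer(parts[, 2]),
                    i_phasing = as.integer(parts[, 3]),
                    i_cohort = as.integer(parts[, 4]),
                    errors = as.integer(errors), total = as.integer(total))

  # merge sparse bins into the nearest clarity neighbor within the same
  # (max, phasing, cohort) slice
  slice <- interaction(tab$i_max, tab$i_phasing, tab$i_cohort, drop = TRUE)
  merged <- do.call(rbind, lapply(split(tab, slice), function(s) {
    s <- s[order(s$i_clarity), , drop = FALSE]
    repeat {
      small <- which(s$total < min_bin_count)
      if (!length(small) || nrow(s) == 1) break
      i <- small[1]
      j <- if (i == 1) 2L else if (i == nrow(s)) i - 1L else {
        if (s$total[i - 1] <= s$total[i + 1]) i - 1L else i + 1L
      }
      keep <- min(i, j); drop <- max(i, j)
      s$errors[keep] <- s$errors[keep] + s$errors[drop]
      s$total[keep] <- s$total[keep] + s$total[drop]
      # the surviving row absorbs the dropped clarity bin's index range
      s <- s[-drop, , drop = FALSE]
    }
    s
  }))
  rownames(merged) <- NULL
  p_hat <- (merged$errors + 1) / (merged$total + 2)
  merged$q <- pmin(q_cap, pmax(2L, as.integer(round(-10 * log10(p_hat)))))

  structure(list(edges = edges, table = merged, bins = bins,
                 min_bin_count = min_bin_count, q_cap = q_cap,
                 smoothing = c(a = 1, b = 2)),
            class = "quality_table")
}

# quantile-bin index with edge clamping (values outside range -> edge bins)
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Assign quality scores from a trained table
#'
#' Looks up each call's predictor bin; out-of-range values clamp to the edge
#' bins. Bin tuples absent from the table (removed by merging) fall back to
#' the populated bin with the nearest clarity index in the same slice, then
#' to the globally nearest bin.
#'
#' @param predictors data.frame from [compute_predictors()].
#' @param table A [train_quality_table()] result.
#' @return List: `q` integer vector per call and `p_error` the table's
#'   smoothed error estimate per call.
#' @export
assign_quality <- function(predictors, table) {
  stopifnot(inherits(table, "quality_table"))
  e <- table$edges
  i_max <- bin_index(predictors$max_intensity, e$max_intensity)
  i_cla <- bin_index(predictors$clarity, e$clarity)
  i_pha <- bin_index(predictors$phasing_sum, e$phasing_sum)
  i_coh <- bin_index(predictors$cohort_clarity, e$cohort_clarity)
  tb <- table$table
  key_tab <- paste(tb$i_max, tb$i_phasing, tb$i_cohort, sep = "\r")
  key_q <- paste(i_max, i_pha, i_coh, sep = "\r")
  q <- integer(length(key_q))
  p_err <- numeric(length(key_q))
  n_fallback <- 0L
  for (kk in unique(key_q)) {
    sel <- key_q == kk
    rows <- which(key_tab == kk)
    if (!length(rows)) {                       # slice missing: nearest overall
      n_fallback <- n_fallback + sum(sel)
      rows <- seq_len(nrow(tb))
    }
    # nearest clarity bin among candidate rows (precomputed per clarity index)
    cand_cla <- tb$i_clarity[rows]
    nb <- length(e$clarity) - 1L
    lookup <- vapply(seq_len(nb), function(ic) rows[which.min(abs(cand_cla - ic))], 1L)
    pick <- lookup[i_cla[sel]]
    q[sel] <- tb$q[pick]
    p_err[sel] <- (tb$errors[pick] + 1) / (tb$total[pick] + 2)
  }
  if (n_fallback > 0) {
    message(sprintf("assign_quality: %d calls fell back to nearest populated slice", n_fallback))
  }
  list(q = q, p_error = p_err)
}

#' Serialize / restore a quality table as versioned JSON
#'
#' @param table A `quality_table`.
#' @param path JSON file path.
#' @return `save_quality_table()` returns the path; `load_quality_table()`
#'   the restored `quality_table`.
#' @name qtable_io
NULL

#' @rdname qtable_io
#' @export
save_quality_table <- function(table, path) {
  stopifnot(inherits(table, "quality_table"))
  payload <- list(format = "aviseq-quality-table", version = 1L,
                  edges = table$edges, table = table$table,
                  bins = as.list(table$bins), min_bin_count = table$min_bin_count,
                  q_cap = table$q_cap, smoothing = as.list(table$smoothing))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname qtable_io
#' @export
load_quality_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "aviseq-quality-table")) {
    stop(sprintf("'%s' is not a quality-table JSON file", path))
  }
  structure(list(edges = lapply(p$edges, as.numeric),
                 table = as.data.frame(p$table),
                 bins = unlist(p$bins), min_bin_count = p$min_bin_count,
                 q_cap = p$q_cap, smoothing = unlist(p$smoothing)),
            class = "quality_table")
}

#' Assess quality-score calibration
#'
#' Groups calls by predicted Q and reports the observed mismatch-derived Q,
#' `-10 * log10(observed error fraction)`, per group. Groups with zero
#' errors report the resolution-limited lower bound
#' `-10 * log10(1 / (n + 1))`.
#'
#' @param q Integer predicted quality per call.
#' @param truth_errors Logical, TRUE where the call is wrong.
#' @param min_count Groups below this size are dropped.
#' @return data.frame `(predicted_q, observed_q, n, errors)` sorted by
#'   predicted Q.
#' @export
assess_calibration <- function(q, truth_errors, min_count = 1L) {
  stopifnot(length(q) == length(truth_errors))
  sp <- split(as.logical(truth_errors), q)
  rows <- lapply(names(sp), function(qs) {
    v <- sp[[qs]]
    n <- length(v); e <- sum(v)
    if (n < min_count) return(NULL)
    obs <- if (e == 0) -10 * log10(1 / (n + 1)) else -10 * log10(e / n)
    data.frame(predicted_q = as.integer(qs), observed_q = obs, n = n, errors = e)
  })
  out <- do.call(rbind, rows)
  out[order(out$predicted_q), , drop = FALSE]
}

#' Fractions of calls above quality thresholds
#'
#' @param q Integer quality scores.
#' @param thresholds Q thresholds (strict `>`).
#' @return Named numeric vector of percentages, e.g. `pct_gt_q30`.
#' @export
summarize_q_fractions <- function(q, thresholds = c(30, 40)) {
  out <- vapply(thresholds, function(th) 100 * mean(q > th), 0)
  names(out) <- paste0("pct_gt_q", thresholds)
  out
}
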