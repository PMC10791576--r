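# Primary analysis: invert spectral cross-talk, deconvolve phasing,
# normalize per channel/cycle, and call the base with the highest
# normalized intensity.

#' Invert spectral cross-talk
#'
#' Solves `m %*% x = y` for every (polony, cycle) observed channel vector
#' `y`, recovering pure dye signals. Negative components (possible in the
#' presence of noise) are clamped to zero after the solve so the linear
#' algebra stays exact; the clamp count is recorded as an attribute.
#'
#' @param raw Polony x cycle x channel intensity array.
#' @param m 4x4 cross-talk matrix (rows = observed channels).
#' @param cond_warn Condition-number threshold above which a warning is
#'   emitted.
#' @return Corrected array with attribute `n_clamped`.
#' @export
correct_crosstalk <- function(raw, m, cond_warn = 1e6) {
  m <- as.matrix(m)
  stopifnot(length(dim(raw)) == 3, dim(raw)[3] == 4, identical(dim(m), c(4L, 4L)))
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf("cross-talk matrix is numerically singular (condition number %.3g)", kap))
  }
  if (kap > cond_warn) {
    warning(sprintf("ill-conditioned cross-talk matrix (condition number %.3g)", kap))
  }
  dm <- dim(raw)
  flat <- matrix(raw, ncol = 4L)                 # rows are (polony, cycle)
  solved <- t(solve(m, t(flat)))
  n_clamped <- sum(solved < 0)
  solved[solved < 0] <- 0
  out <- array(solved, dim = dm, dimnames = dimnames(raw))
  attr(out, "n_clamped") <- n_clamped
  attr(out, "condition_number") <- kap
  out
}

#' Deconvolve phasing from an intensity tensor
#'
#' Builds the cycles x cycles truncation of the phasing state matrix and
#' solves the per-polony, per-channel linear system over cycles, recovering
#' pure per-cycle signals. This is the exact inverse of the simulator's
#' forward model when templates do not extend past the read (otherwise the
#' final ~`2 * p_lead * cycles` cycles carry truncation error). If the
#' truncated system is ill-conditioned the solve falls back to ridge
#' regularization and warns.
#'
#' @param tensor Polony x cycle x channel array (typically cross-talk
#'   corrected).
#' @param p_lag,p_lead Phasing probabilities (e.g. from
#'   [estimate_phasing()]).
#' @param cond_limit Condition number above which the ridge fallback is used.
#' @param ridge Ridge penalty used by the fallback.
#' @return Corrected array with attribute `phasing = c(p_lag, p_lead)`.
#' @export
correct_phasing <- function(tensor, p_lag, p_lead, cond_limit = 1e10,
                            ridge = 1e-8) {
  stopifnot(length(dim(tensor)) == 3)
  dm <- dim(tensor)
  Tc <- dm[2]
  if (p_lag == 0 && p_lead == 0) {
    out <- tensor
    attr(out, "phasing") <- c(p_lag = 0, p_lead = 0)
    return(out)
  }
  P <- phasing_state_matrix(p_lag, p_lead, Tc)[, seq_len(Tc), drop = FALSE]
  # columns of Y are signal-over-cycles vectors, one per (polony, channel)
  Y <- matrix(aperm(tensor, c(2, 1, 3)), nrow = Tc)
  kap <- kappa(P, exact = FALSE)
  if (is.finite(kap) && kap <= cond_limit) {
    X <- solve(P, Y)
  } else {
    warning(sprintf(
      "truncated phasing system ill-conditioned (condition number %.3g); ridge solve with lambda = %g",
      kap, ridge))
    X <- solve(crossprod(P) + diag(ridge, Tc), crossprod(P, Y))
  }
  out <- aperm(array(X, dim = c(Tc, dm[1], dm[3])), c(2, 1, 3))
  dimnames(out) <- dimnames(tensor)
  attr(out, "phasing") <- c(p_lag = p_lag, p_lead = p_lead)
  out
}

#' Estimate phasing probabilities by clarity-maximizing grid search
#'
#' Applies trial phasing corrections over a `(p_lag, p_lead)` grid to a
#' deterministic polony subsample and returns the grid point maximizing mean
#' clarity `(A + 1) / (B + 1)` of the corrected intensities, with A and B
#' the top two of the absolute corrected values — so overcorrection, which
#' drives off channels negative, is penalized just like residual leakage.
#'
#' @param tensor Polony x cycle x channel array (cross-talk corrected).
#' @param grid_lag,grid_lead Candidate probability grids; pairs with
#'   `p_lag + p_lead >= 1` are skipped.
#' @param n_subsample Number of polonies scored (evenly spaced; deterministic).
#' @return List of class `phasing_estimate`: `p_lag`, `p_lead`, `objective`.
#' @export
estimate_phasing <- function(tensor, grid_lag = seq(0, 0.02, by = 5e-4),
                             grid_lead = seq(0, 0.02, by = 5e-4),
                             n_subsample = 100L) {
  stopifnot(length(dim(tensor)) == 3, dim(tensor)[2] >= 2)
  if (all(tensor == 0)) stop("degenerate tensor: all intensities are zero")
  n <- dim(tensor)[1]
  idx <- unique(round(seq(1, n, length.out = min(n, n_subsample))))
  sub <- tensor[idx, , , drop = FALSE]
  best <- list(p_lag = NA_real_, p_lead = NA_real_, objective = -Inf)
  for (pl in grid_lag) {
    for (pp in grid_lead) {
      if (pl + pp >= 1) next
      corr <- correct_phasing(sub, pl, pp)
      obj <- phasing_objective(corr)
      if (obj > best$objective + 1e-12) {
        best <- list(p_lag = pl, p_lead = pp, objective = obj)
      }
    }
  }
  structure(best, class = "phasing_estimate")
}

# Vectorized top-two of a 4-column matrix (tournament reduction).
top_two <- function(flat) {
  a <- pmax(flat[, 1], flat[, 2]); b <- pmin(flat[, 1], flat[, 2])
  c_ <- pmax(flat[, 3], flat[, 4]); d <- pmin(flat[, 3], flat[, 4])
  list(first = pmax(a, c_), second = pmax(pmin(a, c_), pmax(b, d)))
}

# Grid-search objective: clarity computed on absolute corrected values,
# (A+1)/(B+1) with A, B the top two of |x|. Undercorrection leaves positive
# leakage in B; overcorrection drives channels negative, which |.| also
# routes into B — so the objective peaks at the true (p_lag, p_lead)
# instead of rewarding ever-larger corrections.
phasing_objective <- function(tensor) {
  flat <- abs(matrix(tensor, ncol = dim(tensor)[3]))
  tt <- top_two(flat)
  mean((tt$first + 1) / (tt$second + 1))
}

# Mean clarity (A+1)/(B+1) over all polony/cycles, negatives clamped.
mean_clarity <- function(tensor) {
  flat <- matrix(pmax(tensor, 0), ncol = dim(tensor)[3])
  tt <- top_two(flat)
  mean((tt$first + 1) / (tt$second + 1))
}

#' Normalize intensities per channel and cycle
#'
#' Affine map per (channel, cycle): the `lower_pct` percentile of all values
#' in that channel/cycle is sent to 0 and the `upper_pct` percentile of the
#' channel's on-state values (values where the channel is the per-polony
#' maximum) is sent to 1, making cross-channel comparisons meaningful.
#'
#' @param tensor Polony x cycle x channel array.
#' @param lower_pct,upper_pct Percentiles (defaults 5 and 95).
#' @return Normalized array of class-compatible shape, with attribute
#'   `normalized = TRUE`.
#' @export
normalize_intensities <- function(tensor, lower_pct = 5, upper_pct = 95) {
  stopifnot(length(dim(tensor)) == 3)
  dm <- dim(tensor)
  out <- tensor
  maxch <- matrix(max.col(matrix(tensor, ncol = dm[3]), ties.method = "first"),
                  dm[1], dm[2])                  # polony x cycle
  for (t in seq_len(dm[2])) {
    for (ch in seq_len(dm[3])) {
      v <- tensor[, t, ch]
      if (length(unique(v)) < 2) {
        stop(sprintf("cannot normalize: channel %d, cycle %d has < 2 distinct values", ch, t))
      }
      lo <- stats::quantile(v, lower_pct / 100, names = FALSE)
      on_v <- v[maxch[, t] == ch]
      if (!length(on_v)) on_v <- v
      hi <- stats::quantile(on_v, upper_pct / 100, names = FALSE)
      if (hi <= lo) {
        stop(sprintf("cannot normalize: degenerate percentile range in channel %d, cycle %d", ch, t))
      }
      out[, t, ch] <- (v - lo) / (hi - lo)
    }
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Call bases by maximum normalized intensity
#'
#' The highest normalized intensity in each (polony, cycle) determines the
#' call; ties within `tie_tol` are broken toward the lowest channel index
#' (A < C < G < T) and flagged.
#'
#' @param ci Polony x cycle x channel array of normalized intensities.
#' @param tie_tol Absolute tolerance for declaring a tie.
#' @return List of class `basecall_result`: `calls` (character matrix) and
#'   `tie_flags` (logical matrix).
#' @export
call_bases <- function(ci, tie_tol = 1e-9) {
  stopifnot(length(dim(ci)) == 3, dim(ci)[3] == 4, all(is.finite(ci)))
  dm <- dim(ci)
  flat <- matrix(ci, ncol = 4L)
  top <- max.col(flat, ties.method = "first")
  top_val <- flat[cbind(seq_len(nrow(flat)), top)]
  flat2 <- flat
  flat2[cbind(seq_len(nrow(flat)), top)] <- -Inf
  second <- pmax(flat2[, 1], flat2[, 2], flat2[, 3], flat2[, 4])
  ties <- (top_val - second) <= tie_tol
  calls <- matrix(BASES[top], dm[1], dm[2])
  structure(list(calls = calls,
                 tie_flags = matrix(ties, dm[1], dm[2])),
            class = "basecall_result")
}

#' Run the full primary-analysis pipeline
#'
#' Stage order: cross-talk inversion, phasing estimation (or a supplied
#' estimate), phasing deconvolution, per channel/cycle normalization, and
#' max-intensity base calling.
#'
#' @param raw Polony x cycle x channel raw intensity array.
#' @param crosstalk 4x4 cross-talk matrix.
#' @param phasing Either `"auto"` (grid-search estimation) or a numeric
#'   length-2 vector `c(p_lag, p_lead)`.
#' @param grid_lag,grid_lead Grids for `"auto"` estimation.
#' @param truth Optional polony x cycle matrix of true bases; when supplied,
#'   per-cycle error rates are reported in the summary.
#' @return List: `calls` ([call_bases()] result), `ci` (normalized
#'   intensities), `phasing` (estimate), `summary` (per-cycle data.frame with
#'   mean clarity and, if truth given, error rate).
#' @export
run_basecall_pipeline <- function(raw, crosstalk, phasing = "auto",
                                  grid_lag = seq(0, 0.02, by = 5e-4),
                                  grid_lead = seq(0, 0.02, by = 5e-4),
                                  truth = NULL) {
  xt <- correct_crosstalk(raw, crosstalk)
  est <- if (identical(phasing, "auto")) {
    estimate_phasing(xt, grid_lag = grid_lag, grid_lead = grid_lead)
  } else {
    stopifnot(is.numeric(phasing), length(phasing) == 2)
    structure(list(p_lag = phasing[1], p_lead = phasing[2], objective = NA_real_),
              class = "phasing_estimate")
  }
  ph <- correct_phasing(xt, est$p_lag, est$p_lead)
  ci <- normalize_intensities(ph)
  bc <- call_bases(ci)
  Tc <- dim(raw)[2]
  summ <- data.frame(cycle = seq_len(Tc) - 1L,
                     mean_clarity = vapply(seq_len(Tc), function(t) {
                       mean_clarity(ci[, t, , drop = FALSE])
                     }, 0))
  if (!is.null(truth)) {
    summ$error_rate <- vapply(seq_len(Tc), function(t) {
      mean(bc$calls[, t] != truth[, t])
    }, 0)
  }
  list(calls = bc, ci = ci, phasing = est, summary = summ)
}
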