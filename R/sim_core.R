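# Forward simulator: polony intensity tensors, binding-kinetics traces, and
# alignment fixtures with homopolymer-conditional error rates.

BASES <- c("A", "C", "G", "T")

#' Simulator configuration
#'
#' Bundles and validates the knobs of the polony intensity forward model:
#' phasing (lag = failure to advance, lead = double advance), a 4x4 spectral
#' cross-talk matrix, per-polony brightness variation, additive Gaussian
#' noise, and a multiplicative per-cycle signal decay.
#'
#' @param n_polonies Number of polonies (>= 1).
#' @param read_length Number of sequencing cycles (>= 1).
#' @param p_lag Per-cycle probability a strand fails to advance, in `[0, 1)`.
#' @param p_lead Per-cycle probability a strand advances two positions, in `[0, 1)`.
#' @param crosstalk 4x4 invertible channel-mixing matrix (rows = observed
#'   channels, columns = pure dye channels, order A, C, G, T).
#' @param brightness_cv Coefficient of variation of per-polony brightness
#'   (log-normal, mean 1); 0 disables variation.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param signal_decay_per_cycle Multiplicative signal retention per cycle,
#'   in `(0, 1]`.
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_polonies, read_length, p_lag = 0, p_lead = 0,
                       crosstalk = diag(4), brightness_cv = 0, noise_sd = 0,
                       signal_decay_per_cycle = 1, seed = 1L) {
  stopifnot(length(n_polonies) == 1, n_polonies >= 1,
            length(read_length) == 1, read_length >= 1)
  if (p_lag < 0 || p_lag >= 1 || p_lead < 0 || p_lead >= 1 ||
      p_lag + p_lead >= 1) {
    stop("invalid phasing probabilities: need p_lag, p_lead in [0,1) and p_lag + p_lead < 1")
  }
  crosstalk <- as.matrix(crosstalk)
  if (!identical(dim(crosstalk), c(4L, 4L))) stop("crosstalk must be a 4x4 matrix")
  if (abs(det(crosstalk)) < .Machine$double.eps * 16) {
    stop("crosstalk matrix is singular (determinant ~ 0)")
  }
  stopifnot(brightness_cv >= 0, noise_sd >= 0,
            signal_decay_per_cycle > 0, signal_decay_per_cycle <= 1)
  structure(list(n_polonies = as.integer(n_polonies),
                 read_length = as.integer(read_length),
                 p_lag = p_lag, p_lead = p_lead, crosstalk = crosstalk,
                 brightness_cv = brightness_cv, noise_sd = noise_sd,
                 signal_decay_per_cycle = signal_decay_per_cycle,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate polony template sequences
#'
#' Templates stand in for the clonal concatemer identity of each polony.
#' Without a reference, bases are i.i.d. uniform over A/C/G/T; with a
#' reference, templates are random substrings of it.
#'
#' @param n Number of templates.
#' @param length Template length in bases (>= the intended read length).
#' @param seed Integer seed.
#' @param reference Optional character vector of reference sequences to
#'   sample substrings from.
#' @return Character vector of `n` sequences with attribute `origin`.
#' @export
generate_templates <- function(n, length, seed = 1L, reference = NULL) {
  stopifnot(n >= 1, length >= 1)
  rng <- local_rng(seed)
  if (is.null(reference)) {
    mat <- matrix(sample(BASES, n * length, replace = TRUE), nrow = n)
    out <- apply(mat, 1, paste0, collapse = "")
    attr(out, "origin") <- "random"
  } else {
    reference <- as.character(reference)
    widths <- nchar(reference)
    if (all(widths < length)) {
      stop("all reference sequences are shorter than the requested template length")
    }
    ok <- which(widths >= length)
    src <- ok[sample.int(length(ok), n, replace = TRUE)]
    start <- vapply(widths[src], function(w) sample.int(w - length + 1L, 1L), 1L)
    out <- substr(reference[src], start, start + length - 1L)
    attr(out, "origin") <- "reference"
  }
  out
}

#' Phasing state-distribution matrix
#'
#' Forward recursion of the trinomial stepping model: at each cycle a strand
#' advances 0 positions with probability `p_lag`, 2 with probability
#' `p_lead`, and 1 otherwise. Row `t` (0-based cycle) gives the distribution
#' of the next templating position across strands of a polony; row 0 is unit
#' mass at position 0 and row `t` is supported on positions `0..2t`.
#'
#' @param p_lag,p_lead Per-cycle lag / lead probabilities, `p_lag + p_lead < 1`.
#' @param cycles Number of cycles (rows).
#' @return A `cycles` x `(2*cycles - 1)` matrix whose rows sum to 1; columns
#'   are template positions `0..2*(cycles-1)`.
#' @export
phasing_state_matrix <- function(p_lag, p_lead, cycles) {
  if (p_lag < 0 || p_lead < 0 || p_lag + p_lead >= 1) {
    stop("invalid phasing probabilities: need p_lag, p_lead >= 0 and p_lag + p_lead < 1")
  }
  stopifnot(cycles >= 1)
  npos <- 2L * cycles - 1L
  P <- matrix(0, nrow = cycles, ncol = npos)
  P[1, 1] <- 1
  p1 <- 1 - p_lag - p_lead
  if (cycles > 1) {
    for (t in 2:cycles) {
      prev <- P[t - 1, ]
      row <- p_lag * prev
      row[-1] <- row[-1] + p1 * prev[-npos]
      row[-(1:2)] <- row[-(1:2)] + p_lead * prev[-((npos - 1):npos)]
      P[t, ] <- row
    }
  }
  dimnames(P) <- list(cycle = paste0("c", seq_len(cycles) - 1L),
                      position = paste0("p", seq_len(npos) - 1L))
  P
}

#' Render a polony intensity tensor from templates
#'
#' Forward model: the pure signal of channel `b` at cycle `t` is
#' `brightness * decay^t * sum_j P[t, j] * [template[j] == b]`; the observed
#' vector is `crosstalk %*% pure` plus Gaussian noise, clipped at zero.
#'
#' @param templates Character vector of template sequences (length
#'   `config$n_polonies`, each at least `read_length` bases; positions past a
#'   template's end emit no signal).
#' @param config A [sim_config()].
#' @return List with `intensities` (polony x cycle x channel array, channels
#'   A/C/G/T), `truth` (polony x cycle character matrix of templated bases),
#'   and `brightness` (per-polony scalars).
#' @export
render_intensities <- function(templates, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_polonies
  Tc <- config$read_length
  if (length(templates) != n) stop("need one template per polony")
  if (any(nchar(templates) < Tc)) stop("templates shorter than read_length")
  rng <- local_rng(config$seed)

  P <- phasing_state_matrix(config$p_lag, config$p_lead, Tc)
  npos <- ncol(P)
  decay <- config$signal_decay_per_cycle ^ (seq_len(Tc) - 1L)

  brightness <- if (config$brightness_cv > 0) {
    sdlog <- sqrt(log(1 + config$brightness_cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, n)

  # template one-hot over positions actually reachable (0 .. npos-1)
  tmpl_mat <- matrix("", nrow = n, ncol = npos)
  maxw <- min(npos, max(nchar(templates)))
  for (j in seq_len(maxw)) tmpl_mat[, j] <- substr(templates, j, j)

  vals <- array(0, dim = c(n, Tc, 4L),
                dimnames = list(NULL, NULL, channel = BASES))
  for (ch in 1:4) {
    onehot <- tmpl_mat == BASES[ch]          # n x npos
    pure <- onehot %*% t(P)                  # n x cycles: sum_j 1[..] P[t,j]
    vals[, , ch] <- pure * rep(decay, each = n) * brightness
  }
  # spectral mixing: observed = M %*% pure per (polony, cycle)
  flat <- matrix(vals, ncol = 4L)            # (n*Tc) x 4, pure channel vectors
  flat <- flat %*% t(config$crosstalk)
  if (config$noise_sd > 0) {
    flat <- flat + stats::rnorm(length(flat), sd = config$noise_sd)
  }
  flat[flat < 0] <- 0
  vals <- array(flat, dim = c(n, Tc, 4L),
                dimnames = list(NULL, NULL, channel = BASES))

  truth <- matrix("", n, Tc)
  for (t in seq_len(Tc)) truth[, t] <- substr(templates, t, t)
  list(intensities = vals, truth = truth, brightness = brightness)
}

#' Simulate a real-time association trace
#'
#' Pseudo-first-order binding: `S(t) = s_max * (1 - exp(-k_on * conc * t))`
#' plus additive Gaussian noise. Models avidite (or monovalent nucleotide)
#' signal generation during the binding step.
#'
#' @param k_on Association rate constant (per concentration unit per second).
#' @param conc Substrate concentration (same unit as `k_on`'s denominator).
#' @param t_grid Strictly increasing time grid in seconds; default spans five
#'   observed-rate lifetimes.
#' @param s_max Plateau signal.
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param seed Optional integer seed.
#' @return A `kinetic_trace`: data.frame (time, signal) with attributes
#'   `kind = "association"` and `conc`.
#' @export
simulate_association_trace <- function(k_on, conc, t_grid = NULL, s_max = 1,
                                       noise_sd = 0, seed = NULL) {
  stopifnot(k_on > 0, conc > 0)
  k_obs <- k_on * conc
  if (is.null(t_grid)) t_grid <- seq(0, 5 / k_obs, length.out = 60L)
  check_time_grid(t_grid)
  if (!is.null(seed)) rng <- local_rng(seed)
  s <- s_max * (1 - exp(-k_obs * t_grid))
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), sd = noise_sd)
  kinetic_trace(t_grid, s, kind = "association", conc = conc)
}

#' Simulate a dissociation (signal-decay) trace
#'
#' `S(t) = s0 * exp(-k_off * t)` plus noise. `k_off = 0` models the avidite
#' regime of persistent signal during imaging; a large `k_off` models the
#' monovalent nucleotide whose signal collapses at the start of imaging.
#'
#' @param k_off Dissociation rate (per second, >= 0).
#' @param t_grid Strictly increasing time grid (seconds).
#' @param s0 Initial signal.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Optional integer seed.
#' @return A `kinetic_trace` with `kind = "dissociation"`.
#' @export
simulate_dissociation_trace <- function(k_off, t_grid, s0 = 1, noise_sd = 0,
                                        seed = NULL) {
  if (k_off < 0) stop("k_off must be >= 0")
  check_time_grid(t_grid)
  if (!is.null(seed)) rng <- local_rng(seed)
  s <- s0 * exp(-k_off * t_grid)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), sd = noise_sd)
  kinetic_trace(t_grid, s, kind = "dissociation", conc = NA_real_)
}

#' Simulate quench-flow incorporation time series
#'
#' Product fraction `F(t) = 1 - exp(-k_obs * t)` with
#' `k_obs = k_pol * c / (kd_app + c)` at each concentration `c`, with
#' multiplicative Gaussian noise of fractional sd `noise_frac`.
#'
#' @param k_pol Maximum incorporation rate (per second).
#' @param kd_app Apparent dissociation constant (same unit as `concs`).
#' @param concs Positive substrate concentrations.
#' @param t_grid Strictly increasing times (seconds).
#' @param noise_frac Multiplicative noise fraction (e.g. 0.05 for 5%).
#' @param seed Optional integer seed.
#' @return List of `kinetic_trace` objects, one per concentration, each with
#'   attributes `conc` and `k_obs_true`.
#' @export
simulate_quench_flow <- function(k_pol, kd_app, concs, t_grid,
                                 noise_frac = 0, seed = NULL) {
  stopifnot(k_pol > 0, kd_app > 0, all(concs > 0), noise_frac >= 0)
  check_time_grid(t_grid)
  if (!is.null(seed)) rng <- local_rng(seed)
  lapply(concs, function(cc) {
    k_obs <- k_pol * cc / (kd_app + cc)
    f <- 1 - exp(-k_obs * t_grid)
    if (noise_frac > 0) f <- f * (1 + stats::rnorm(length(f), sd = noise_frac))
    tr <- kinetic_trace(t_grid, f, kind = "association", conc = cc)
    attr(tr, "k_obs_true") <- k_obs
    tr
  })
}

kinetic_trace <- function(time, signal, kind, conc) {
  stopifnot(all(is.finite(signal)))
  structure(data.frame(time = time, signal = signal),
            kind = kind, conc = conc, class = c("kinetic_trace", "data.frame"))
}

check_time_grid <- function(t_grid) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("time grid must be strictly increasing with >= 2 points")
  }
  invisible(t_grid)
}

# All stochastic entry points route their seed through here.
local_rng <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(seed)
}
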