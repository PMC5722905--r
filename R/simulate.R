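#' Configuration of the synthetic time-course generator
#'
#' The generator emulates a multi-series time-course study (several tissues
#' or subjects profiled over the same schedule): regulator genes follow a
#' shared smooth latent activity (cyclic by default, emulating circadian
#' drive), each planted target integrates a saturating function of its
#' regulator's activity through a linear production-degradation model with
#' a gene-specific mRNA decay rate, decoy genes drift smoothly and
#' independently in each series, and every gene picks up a per-series
#' baseline offset that dominates within-series variance — the confound
#' that decouples steady-state level from transcriptional activity.
#'
#' Defaults describe a 6-series, 24-sample cyclic design sampled every 2 h
#' over 48 h with a 24 h period. Expression is on an arbitrary positive
#' scale: signal amplitudes are O(1) around a baseline of 10, observation
#' noise SD 0.1, between-series offset SD 2.
#'
#' @param n_series number of series (tissues/subjects).
#' @param samples_per_series time points per series.
#' @param interval nominal sampling interval (time units, "hours").
#' @param t_start first sampling time.
#' @param sampling `"even"` or `"uneven"` (per-series jittered grids).
#' @param jitter_sd SD of the time jitter for uneven sampling, as a
#'   fraction of `interval`.
#' @param cyclic logical: do series wrap (shared periodic drive)?
#' @param period period of the cyclic drive, same units as `interval`.
#' @param n_regulators,n_targets_per_regulator,n_decoys gene counts.
#' @param degradation_range range (min, max) of per-target mRNA decay
#'   rates, in 1/time units; the default 0.04-0.12 h^-1 (half-lives ~6-17 h)
#'   is slow against a 24 h period, so target levels lag and smooth the
#'   regulator signal.
#' @param regulation_strength scales the variable part of each target's
#'   production; 0 disconnects targets from regulators entirely.
#' @param amplitude_range range (min, max) of the fundamental sinusoid
#'   amplitude drawn per regulator (log scale); c(0, 0) gives constant
#'   periodic drive.
#' @param activity_noise_sd stationary SD of the smooth stochastic
#'   modulation (Ornstein-Uhlenbeck) of each regulator's latent activity,
#'   drawn independently per regulator and series. This is what makes a
#'   regulator statistically identifiable: tissues sharing only a common
#'   periodic drive would make all regulators interchangeable encoders of
#'   clock phase.
#' @param activity_noise_tau correlation time of that modulation (time
#'   units).
#' @param repression_fraction fraction of planted edges using the
#'   repressive (decreasing) response, to exercise negative rate signs.
#' @param target_mean nominal mean signal level of targets and regulators.
#' @param noise_sd SD of i.i.d. observation noise added to every value.
#' @param offset_sd SD of the per-gene, per-series baseline offset.
#' @param baseline constant added to all values to keep them positive.
#' @param seed root seed; every stochastic choice flows from it through
#'   named substreams, so datasets are reproducible.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_series = 6L, samples_per_series = 24L,
                              interval = 2, t_start = 0,
                              sampling = c("even", "uneven"),
                              jitter_sd = 0.25, cyclic = TRUE, period = 24,
                              n_regulators = 5L,
                              n_targets_per_regulator = 20L,
                              n_decoys = 100L,
                              degradation_range = c(0.04, 0.12),
                              regulation_strength = 1,
                              amplitude_range = c(0.6, 1.0),
                              activity_noise_sd = 0.5,
                              activity_noise_tau = 4,
                              repression_fraction = 0,
                              target_mean = 3, noise_sd = 0.1,
                              offset_sd = 2, baseline = 10, seed = 1L) {
  sampling <- match.arg(sampling)
  cfg <- list(n_series = as.integer(n_series),
              samples_per_series = as.integer(samples_per_series),
              interval = interval, t_start = t_start, sampling = sampling,
              jitter_sd = jitter_sd, cyclic = isTRUE(cyclic), period = period,
              n_regulators = as.integer(n_regulators),
              n_targets_per_regulator = as.integer(n_targets_per_regulator),
              n_decoys = as.integer(n_decoys),
              degradation_range = as.numeric(degradation_range),
              regulation_strength = regulation_strength,
              amplitude_range = as.numeric(amplitude_range),
              activity_noise_sd = activity_noise_sd,
              activity_noise_tau = activity_noise_tau,
              repression_fraction = repression_fraction,
              target_mean = target_mean, noise_sd = noise_sd,
              offset_sd = offset_sd, baseline = baseline,
              seed = as.integer(seed))
  counts <- c(cfg$n_series, cfg$samples_per_series, cfg$n_regulators,
              cfg$n_targets_per_regulator)
  if (any(counts < 1L)) stop("all counts must be positive")
  if (cfg$n_decoys < 0L) stop("n_decoys must be >= 0")
  if (cfg$samples_per_series < 2L) stop("need >= 2 samples per series")
  if (any(cfg$degradation_range <= 0)) stop("degradation rates must be > 0")
  if (cfg$noise_sd < 0 || cfg$offset_sd < 0) stop("noise SDs must be >= 0")
  structure(cfg, class = "SimulationConfig")
}

# deterministic substream seed from the root seed and a stream name
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65011L)
}

with_substream <- function(seed, name, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(substream_seed(seed, name))
  force(expr)
}

# stationary Ornstein-Uhlenbeck path on a time grid: smooth, mean-zero,
# bounded in practice (clipped at 3 SD)
ou_path <- function(grid, sd, tau) {
  if (sd == 0) return(numeric(length(grid)))
  x <- numeric(length(grid))
  x[1L] <- stats::rnorm(1L, 0, sd)
  for (i in seq_along(grid)[-1L]) {
    a <- exp(-(grid[i] - grid[i - 1L]) / tau)
    x[i] <- a * x[i - 1L] + stats::rnorm(1L, 0, sd * sqrt(1 - a^2))
  }
  pmin(pmax(x, -3 * sd), 3 * sd)
}

# per-series sampling grids; list of numeric time vectors
sampling_times <- function(cfg) {
  base <- cfg$t_start + cfg$interval * (seq_len(cfg$samples_per_series) - 1L)
  if (cfg$sampling == "even")
    return(rep(list(base), cfg$n_series))
  with_substream(cfg$seed, "times", lapply(seq_len(cfg$n_series), function(s) {
    tt <- base + stats::rnorm(length(base), 0, cfg$jitter_sd * cfg$interval)
    tt <- sort(tt)
    # enforce a minimal gap so slopes stay finite
    gap <- cfg$interval * 0.1
    for (i in seq_along(tt)[-1L])
      if (tt[i] - tt[i - 1L] < gap) tt[i] <- tt[i - 1L] + gap
    tt
  }))
}

#' Latent regulator activity curves
#'
#' In cyclic mode each regulator's activity is the exponential of a sum of
#' two sinusoids (fundamental period plus its first harmonic) with random
#' amplitudes and phases shared by all series — a common periodic drive —
#' plus a smooth stochastic modulation (a mean-reverting
#' Ornstein-Uhlenbeck path, correlation time `activity_noise_tau`) drawn
#' independently for every regulator in every series. The modulation is
#' what distinguishes regulators with similar phases: it is the
#' regulator-specific signal a target integrates, in every tissue, that no
#' other gene shares. In non-cyclic mode each regulator follows an
#' independent smoothed random walk per series (subjects drifting on their
#' own trajectories).
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `RegulatorActivity`: `fn(r, s, t)` evaluating
#'   regulator `r`'s activity in series `s` at arbitrary times `t`;
#'   `at_samples` (n_regulators x total-samples matrix); `times` (list of
#'   per-series time vectors); `params`.
#' @export
simulate_regulator <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  times <- sampling_times(cfg)
  R <- cfg$n_regulators
  if (cfg$cyclic) {
    span <- range(unlist(times))
    grid <- seq(span[1L] - 2.5 * cfg$period, span[2L] + cfg$interval,
                by = cfg$interval / 2)
    gen <- with_substream(cfg$seed, "regulators", {
      ar <- cfg$amplitude_range
      par <- data.frame(
        a1 = stats::runif(R, ar[1L], ar[2L]),
        phi1 = stats::runif(R, 0, 2 * pi),
        a2 = stats::runif(R, 0, 0.4 * (ar[2L] > 0)),
        phi2 = stats::runif(R, 0, 2 * pi))
      mods <- lapply(seq_len(R), function(r)
        lapply(seq_len(cfg$n_series), function(s)
          stats::splinefun(grid, ou_path(grid, cfg$activity_noise_sd,
                                         cfg$activity_noise_tau))))
      list(par = par, mods = mods)
    })
    par <- gen$par
    fn <- function(r, s, t) {
      exp(par$a1[r] * sin(2 * pi * t / cfg$period + par$phi1[r]) +
          par$a2[r] * sin(4 * pi * t / cfg$period + par$phi2[r]) +
          gen$mods[[r]][[s]](t))
    }
  } else {
    # smoothed random walk per regulator per series, on a fine grid
    span <- range(unlist(times))
    grid <- seq(span[1L] - 2 * cfg$period, span[2L] + cfg$interval,
                by = cfg$interval / 2)
    walks <- with_substream(cfg$seed, "regulators",
      lapply(seq_len(R), function(r) lapply(seq_len(cfg$n_series), function(s) {
        w <- cumsum(stats::rnorm(length(grid), 0, 0.25))
        w <- as.numeric(stats::filter(w, rep(1 / 7, 7), sides = 2))
        ok <- which(!is.na(w))            # moving average leaves NA at the rim
        w[seq_len(ok[1L] - 1L)] <- w[ok[1L]]
        w[seq.int(ok[length(ok)] + 1L, length.out = length(w) - ok[length(ok)])] <-
          w[ok[length(ok)]]
        w <- w - mean(w)
        stats::splinefun(grid, pmin(pmax(w, -1.5), 1.5))
      })))
    par <- NULL
    fn <- function(r, s, t) exp(walks[[r]][[s]](t))
  }
  at <- matrix(NA_real_, R, cfg$n_series * cfg$samples_per_series)
  for (s in seq_len(cfg$n_series)) {
    jj <- (s - 1L) * cfg$samples_per_series + seq_len(cfg$samples_per_series)
    for (r in seq_len(R)) at[r, jj] <- fn(r, s, times[[s]])
  }
  rownames(at) <- paste0("REG", seq_len(R))
  structure(list(fn = fn, at_samples = at, times = times, params = par,
                 cfg = cfg), class = "RegulatorActivity")
}

# saturating response of a target to regulator activity, normalised to
# mean 1 over the sampled grid; sense = +1 activation, -1 repression
regulation_drive <- function(activity, r, sense = 1) {
  h <- function(a) if (sense >= 0) a / (1 + a) else 1 / (1 + a)
  vals <- h(activity$at_samples[r, ])
  hbar <- mean(vals)
  list(fun = function(s, t) h(activity$fn(r, s, t)) / hbar,
       at_samples = vals / hbar)
}

#' Planted target trajectories from a production-degradation model
#'
#' Each target obeys `dY/dt = k(t) - delta * Y`, where the production
#' `k(t) = delta * target_mean * (1 + w * (drive(t) - 1))` modulates a
#' saturating (Hill coefficient 1) response to the regulator's activity
#' with regulation strength `w`, and `delta` is the target's mRNA decay
#' rate. Slow decay makes the level a lagged, smoothed integral of the
#' regulator signal (weak level correlation, strong rate coupling); large
#' decay pins the level to the quasi-steady state `k(t)/delta`. Integration
#' uses explicit fixed sub-steps, automatically refined so that
#' `delta * dt <= 0.1`, initialised at the quasi-steady state and burnt in
#' for two periods before the first sample. Trajectories are noiseless;
#' observation noise and series offsets are added in [assemble_dataset()].
#'
#' @param activity a [simulate_regulator()] result.
#' @param cfg the same [simulation_config()].
#' @return a list of class `TargetDynamics`: `values` (targets x samples,
#'   clean), `drive` (same shape: the normalised production drive at the
#'   sample times, i.e. the quasi-steady-state limit divided by
#'   `target_mean` when `regulation_strength` is 1), `params` (data.frame:
#'   `target`, `regulator`, `degradation`, `strength`, `sense`).
#' @export
simulate_targets <- function(activity, cfg = activity$cfg) {
  stopifnot(inherits(activity, "RegulatorActivity"))
  R <- cfg$n_regulators; Tg <- cfg$n_targets_per_regulator
  n_t <- R * Tg
  params <- with_substream(cfg$seed, "targets", data.frame(
    target = paste0("TGT", rep(seq_len(R), each = Tg), "_", rep(seq_len(Tg), R)),
    regulator = paste0("REG", rep(seq_len(R), each = Tg)),
    reg_index = rep(seq_len(R), each = Tg),
    degradation = stats::runif(n_t, cfg$degradation_range[1L],
                               cfg$degradation_range[2L]),
    strength = rep(cfg$regulation_strength, n_t),
    sense = ifelse(stats::runif(n_t) < cfg$repression_fraction, -1, 1),
    stringsAsFactors = FALSE))

  n_samp <- cfg$n_series * cfg$samples_per_series
  values <- drive_mat <- matrix(NA_real_, n_t, n_samp,
                                dimnames = list(params$target, NULL))
  for (i in seq_len(n_t)) {
    dr <- regulation_drive(activity, params$reg_index[i], params$sense[i])
    delta <- params$degradation[i]; w <- params$strength[i]
    prod_rate <- function(s, t)
      delta * cfg$target_mean * pmax(0, 1 + w * (dr$fun(s, t) - 1))
    for (s in seq_len(cfg$n_series)) {
      tt <- activity$times[[s]]
      t0 <- tt[1L] - 2 * cfg$period          # burn-in from quasi-steady state
      y <- prod_rate(s, t0) / delta
      dt_max <- min(0.1 / delta, cfg$interval / 4)
      out <- numeric(length(tt))
      t_now <- t0
      for (j in seq_along(tt)) {
        while (t_now < tt[j] - 1e-12) {
          dt <- min(dt_max, tt[j] - t_now)
          y <- y + dt * (prod_rate(s, t_now) - delta * y)
          t_now <- t_now + dt
        }
        out[j] <- y
      }
      jj <- (s - 1L) * cfg$samples_per_series + seq_len(cfg$samples_per_series)
      values[i, jj] <- out
      drive_mat[i, jj] <- dr$fun(s, tt)
    }
  }
  structure(list(values = values, drive = drive_mat, params = params),
            class = "TargetDynamics")
}

#' Assemble a complete synthetic dataset
#'
#' Builds the full expression matrix: regulator mRNA profiles (scaled
#' activity plus noise), planted targets from [simulate_targets()], decoy
#' genes following independent smooth per-series drifts, then per-gene
#' per-series baseline offsets and i.i.d. observation noise on top of a
#' constant baseline (values are floored at 0). Returns the matrix together
#' with the ground truth: `true_edges` holds the planted pairs with
#' non-zero regulation strength; the complete nominal assignment, including
#' disconnected (strength 0) pairs, stays in `params`.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `SyntheticDataset`: `expr`
#'   (an [expression_matrix()]), `regulators` (ids), `true_edges`
#'   (data.frame `regulator`, `target`), `params` (per-target ground
#'   truth), `cfg`.
#' @export
assemble_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  act <- simulate_regulator(cfg)
  tgt <- simulate_targets(act, cfg)
  n_samp <- cfg$n_series * cfg$samples_per_series

  reg_vals <- cfg$target_mean * act$at_samples /
    rowMeans(act$at_samples)

  n_d <- cfg$n_decoys
  decoy_vals <- matrix(0, 0L, n_samp)
  if (n_d > 0L) {
    decoy_vals <- with_substream(cfg$seed, "decoys", {
      m <- matrix(NA_real_, n_d, n_samp)
      for (i in seq_len(n_d)) {
        per <- stats::runif(1L, 0.5, 2) * cfg$period
        for (s in seq_len(cfg$n_series)) {
          tt <- act$times[[s]]
          a1 <- stats::runif(1L, 0.3, 1); ph <- stats::runif(1L, 0, 2 * pi)
          jj <- (s - 1L) * cfg$samples_per_series + seq_len(cfg$samples_per_series)
          m[i, jj] <- cfg$target_mean * exp(a1 * sin(2 * pi * tt / per + ph)) /
            exp(a1^2 / 4)
        }
      }
      m
    })
    rownames(decoy_vals) <- paste0("DEC", seq_len(n_d))
  }

  signal <- rbind(reg_vals, tgt$values, decoy_vals)
  n_g <- nrow(signal)
  offsets <- with_substream(cfg$seed, "offsets",
    matrix(stats::rnorm(n_g * cfg$n_series, 0, cfg$offset_sd), n_g,
           cfg$n_series))
  noise <- with_substream(cfg$seed, "noise",
    matrix(stats::rnorm(n_g * n_samp, 0, cfg$noise_sd), n_g, n_samp))
  series_of <- rep(seq_len(cfg$n_series), each = cfg$samples_per_series)
  obs <- pmax(cfg$baseline + signal + offsets[, series_of] + noise, 0)

  sample_ids <- paste0("S", series_of, "_T",
                       rep(seq_len(cfg$samples_per_series), cfg$n_series))
  colnames(obs) <- sample_ids
  design <- data.frame(sample_id = sample_ids,
                       series_id = paste0("S", series_of),
                       time = unlist(act$times),
                       cyclic = cfg$cyclic, stringsAsFactors = FALSE)
  expr <- expression_matrix(obs, design)

  connected <- tgt$params$strength != 0
  true_edges <- data.frame(regulator = tgt$params$regulator[connected],
                           target = tgt$params$target[connected],
                           stringsAsFactors = FALSE)
  structure(list(expr = expr, regulators = rownames(reg_vals),
                 true_edges = true_edges, params = tgt$params, cfg = cfg),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset:", nrow(x$expr$values), "genes (",
      length(x$regulators), "regulators,", nrow(x$params), "targets,",
      x$cfg$n_decoys, "decoys) x", ncol(x$expr$values), "samples;",
      nrow(x$true_edges), "planted edges\n")
  invisible(x)
}
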