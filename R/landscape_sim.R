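#' Configure a two-population divergence scenario
#'
#' Parameters of the forward Wright-Fisher simulator. An ancestral
#' population of `N` diploids evolves for `T_burn` generations, splits
#' into two daughters of size `N`, and diverges for `T_div` generations.
#' Mutations landing in the two distal thirds of the chromosome may have
#' fitness effects depending on the scenario; the central third always
#' evolves neutrally, generating broad-scale variation in the strength of
#' indirect selection along the chromosome:
#'
#' * `neutral` — no fitness effects;
#' * `bgs` — tail mutations deleterious with probability `prop_neg`;
#' * `bdmi` — as `bgs` in the ancestor; after the split each new selected
#'   tail mutation is deleterious in one (randomly chosen) population and
#'   neutral in the other, with symmetric migration `Nm`;
#' * `positive` — tail mutations beneficial with probability `prop_pos`;
#' * `bgs_positive` — both deleterious and beneficial classes;
#' * `local_adaptation` — beneficial in one population only, with
#'   migration, and at the split each segregating neutral tail mutation is
#'   recruited as locally beneficial with probability `prop_pos`.
#'
#' The selection parameter is given as `Ns` with `s = Ns / N`, so rescaled
#' runs preserve it automatically.
#'
#' @param scenario one of `"neutral"`, `"bgs"`, `"bdmi"`, `"positive"`,
#'   `"bgs_positive"`, `"local_adaptation"`. Scenario-specific defaults
#'   for `prop_neg`, `prop_pos` and `Nm` are filled in when not supplied.
#' @param N diploid population size.
#' @param L chromosome length in bp.
#' @param mu,r per-bp per-generation mutation and recombination rates.
#' @param Ns_neg,prop_neg strength (positive number) and fraction of
#'   deleterious tail mutations.
#' @param Ns_pos,prop_pos beneficial counterparts.
#' @param Nm migrants per generation (only `bdmi` and
#'   `local_adaptation` allow migration).
#' @param T_burn,T_div burn-in and divergence durations in generations
#'   (default `10 N` each).
#' @param window_bp window size for the output statistics.
#' @param n_sample diploid individuals sampled per population.
#' @param n_timepoints number of equally spaced sampling times during
#'   divergence (a sample at the split, time 0, is always added).
#' @param ancestral_selection keep ancestor-phase background selection in
#'   the `bdmi` scenario.
#' @param seed integer seed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(scenario = c("neutral", "bgs", "bdmi", "positive",
                                      "bgs_positive", "local_adaptation"),
                         N = 10000, L = 21e6, mu = 1e-8, r = 1.5e-8,
                         Ns_neg = 100, prop_neg = NULL,
                         Ns_pos = 100, prop_pos = NULL,
                         Nm = NULL,
                         T_burn = 10 * N, T_div = 10 * N,
                         window_bp = 5e5, n_sample = 20,
                         n_timepoints = 10,
                         ancestral_selection = TRUE,
                         seed = 1) {
  scenario <- match.arg(scenario)
  defaults <- list(
    neutral = list(prop_neg = 0, prop_pos = 0, Nm = 0),
    bgs = list(prop_neg = 0.1, prop_pos = 0, Nm = 0),
    bdmi = list(prop_neg = 0.05, prop_pos = 0, Nm = 0.1),
    positive = list(prop_neg = 0, prop_pos = 0.001, Nm = 0),
    bgs_positive = list(prop_neg = 0.1, prop_pos = 0.005, Nm = 0),
    local_adaptation = list(prop_neg = 0, prop_pos = 0.001, Nm = 0.1)
  )[[scenario]]
  if (is.null(prop_neg)) prop_neg <- defaults$prop_neg
  if (is.null(prop_pos)) prop_pos <- defaults$prop_pos
  if (is.null(Nm)) Nm <- defaults$Nm
  if (Nm > 0 && !scenario %in% c("bdmi", "local_adaptation")) {
    stop("migration is only part of the bdmi and local_adaptation scenarios")
  }
  stopifnot(prop_neg + prop_pos <= 1, L %% window_bp == 0, N >= 2)
  structure(as.list(environment())[!names(as.list(environment())) %in%
                                     "defaults"],
            class = "sim_scenario")
}

#' Rescale a scenario for desk-scale simulation
#'
#' Standard population-size rescaling: `N' = N / Q`, times divided by Q,
#' per-bp rates multiplied by Q, so that the population-scaled compound
#' parameters (theta = 4 N mu, rho = 4 N r, Ns, Nm) are invariant. The
#' per-mutation selection coefficient grows as `s' = s Q`; a warning is
#' issued when `s'` exceeds 0.1 and an error when it exceeds 0.5, where
#' the diffusion-scale equivalence breaks down.
#'
#' @param config a [sim_scenario()].
#' @param Q rescaling factor (>= 1; `N / Q` must stay >= 100).
#' @return The rescaled `sim_scenario`.
#' @export
rescale <- function(config, Q) {
  stopifnot(inherits(config, "sim_scenario"), Q >= 1)
  if (config$N / Q < 100) stop("N/Q below 100: rescaling too aggressive")
  s_max <- max(config$Ns_neg * (config$prop_neg > 0),
               config$Ns_pos * (config$prop_pos > 0)) / (config$N / Q)
  if (s_max > 0.5) stop("rescaled |s| = ", signif(s_max, 3),
                        " > 0.5: strong-selection regime broken")
  if (s_max > 0.1) warning("rescaled |s| = ", signif(s_max, 3), " > 0.1")
  config$N <- config$N / Q
  config$T_burn <- round(config$T_burn / Q)
  config$T_div <- round(config$T_div / Q)
  config$mu <- config$mu * Q
  config$r <- config$r * Q
  config
}

#' Run a divergence scenario
#'
#' Runs the forward Wright-Fisher engine for each replicate, samples
#' `n_sample` diploids per population at the split (time 0) and at
#' `n_timepoints` equally spaced times during divergence, and computes
#' per-window diversity (`pi_a`, `pi_b`), divergence (`dxy`) and
#' differentiation (`fst`) through the same pairwise-mismatch kernel as
#' the empirical pipeline, with the window length as denominator (the
#' simulated sample has no missing data, and every bp of the window is a
#' genotyped site). Identical seed and configuration give identical
#' output.
#'
#' @param config a [sim_scenario()].
#' @param reps number of replicate simulations (default 5).
#' @return List of class `sim_output`: `windows` (data frame `replicate`,
#'   `timepoint` in generations after the split, `window`, `start`,
#'   `pi_a`, `pi_b`, `dxy`, `fst`), `correlations` (from
#'   [sim_correlation_course()]), `migrants` (per replicate x generation),
#'   `config`.
#' @export
run_scenario <- function(config, reps = 5) {
  stopifnot(inherits(config, "sim_scenario"))
  scen_code <- match(config$scenario,
                     c("neutral", "bgs", "bdmi", "positive",
                       "bgs_positive", "local_adaptation")) - 1L
  sample_times <- unique(sort(c(
    0L, as.integer(round(seq_len(config$n_timepoints) *
                           config$T_div / config$n_timepoints))
  )))
  sample_times <- sample_times[sample_times <= config$T_div]
  n_win <- config$L / config$window_bp
  starts <- (seq_len(n_win) - 1L) * config$window_bp
  out <- vector("list", reps)
  migrants <- vector("list", reps)
  for (rep in seq_len(reps)) {
    res <- .wf_simulate_cpp(
      N = as.integer(config$N), L = config$L, mu = config$mu, rec = config$r,
      s_neg = -config$Ns_neg / config$N, prop_neg = config$prop_neg,
      s_pos = config$Ns_pos / config$N, prop_pos = config$prop_pos,
      mig = config$Nm / config$N, scenario = scen_code,
      ancestral_selection = config$ancestral_selection,
      standing_prop = if (config$scenario == "local_adaptation") config$prop_pos else 0,
      t_burn = as.integer(config$T_burn), t_div = as.integer(config$T_div),
      sample_times = sample_times, n_sample = as.integer(config$n_sample),
      seed = as.integer(config$seed + 7919L * (rep - 1L))
    )
    migrants[[rep]] <- res$migrants
    tabs <- lapply(seq_along(res$samples), function(s) {
      smp <- res$samples[[s]]
      stats <- sim_window_stats(smp$positions, smp$dosage, starts,
                               config$window_bp, config$n_sample)
      data.frame(replicate = rep,
                 timepoint = as.integer(names(res$samples)[s]),
                 window = seq_len(n_win), start = starts, stats)
    })
    out[[rep]] <- do.call(rbind, tabs)
  }
  windows <- do.call(rbind, out)
  res <- structure(list(windows = windows, migrants = migrants,
                        config = config, reps = reps),
                   class = "sim_output")
  res$correlations <- sim_correlation_course(res)
  res
}

# Per-window pi/dxy/fst from a complete-data dosage sample (columns:
# n_sample individuals of pop a, then n_sample of pop b).
sim_window_stats <- function(positions, dosage, starts, window_bp, n_sample) {
  ia <- seq_len(n_sample)
  ib <- n_sample + seq_len(n_sample)
  n_win <- length(starts)
  out <- matrix(NA_real_, n_win, 4,
                dimnames = list(NULL, c("pi_a", "pi_b", "dxy", "fst")))
  win_of <- findInterval(positions, starts)
  for (w in seq_len(n_win)) {
    D <- dosage[win_of == w, , drop = FALSE]
    mm <- mismatch_matrices(D)
    out[w, "pi_a"] <- mean_pair_ratio(mm$M, mm$J, within_pairs(ia),
                                      total_sites = window_bp)["value"]
    out[w, "pi_b"] <- mean_pair_ratio(mm$M, mm$J, within_pairs(ib),
                                      total_sites = window_bp)["value"]
    out[w, "dxy"] <- mean_pair_ratio(mm$M, mm$J, between_pairs(ia, ib),
                                     total_sites = window_bp)["value"]
    out[w, "fst"] <- kst_from_matrices(mm, n_sample, n_sample,
                                       n_sites = nrow(D),
                                       total_sites = window_bp)["fst"]
  }
  as.data.frame(out)
}

#' Correlation time course of a simulation
#'
#' Pearson correlations, across windows, between `dxy` and mean
#' diversity and between `fst` and mean diversity at each timepoint of
#' each replicate (`pi` is the mean of the two daughter populations).
#' Zero-variance landscapes give `NA`.
#'
#' @param output a [run_scenario()] result.
#' @return Data frame `replicate`, `timepoint`, `r_dxy_pi`, `r_fst_pi`.
#' @export
sim_correlation_course <- function(output) {
  w <- output$windows
  if (length(unique(w$window)) < 3) stop("need at least 3 windows")
  grp <- split(w, list(w$replicate, w$timepoint), drop = TRUE)
  out <- lapply(grp, function(g) {
    pi_mean <- (g$pi_a + g$pi_b) / 2
    safe_cor <- function(x, y) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])
    }
    data.frame(replicate = g$replicate[1], timepoint = g$timepoint[1],
               r_dxy_pi = safe_cor(g$dxy, pi_mean),
               r_fst_pi = safe_cor(g$fst, pi_mean))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$replicate, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' @method print sim_output
#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "sim_output: scenario '%s', N = %g, L = %g bp, %d replicate(s), %d timepoints\n",
    x$config$scenario, x$config$N, x$config$L, x$reps,
    length(unique(x$windows$timepoint))
  ))
  invisible(x)
}
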