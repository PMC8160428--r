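#' Draw a synthetic species pool
#'
#' Each species gets a unimodal (Gaussian) thermal germination response with
#' peak probability `p_max` at optimum `t_opt` and breadth `t_sd`, log-odds
#' shifts for the alternating-temperature regime (`alt_effect`) and wet-cold
#' storage (`coldstrat_effect`), a memoryless per-day germination hazard
#' (`timing_hazard`), and an abundance model: baseline log abundance plus a
#' nitrogen-response slope per normalized dose.  The slope is
#' `sum_t gamma_t * standardized(trait_t) + Normal(0, noise_sd)` with the
#' couplings taken from the configuration, so downstream inference can be
#' checked by parameter recovery.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `species_pool`, one row per species, with the
#'   simulation parameters plus the closed-form true trait values
#'   (`true_btn`, `true_gp5`) used by the couplings.
#' @export
draw_species_pool <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$rng_seed, "species_pool"))
  n <- config$n_species
  pool <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    p_max = rbeta(n, 4, 2),
    t_opt = runif(n, 5, 25),
    t_sd = rlnorm(n, log(6), 0.4),
    alt_effect = rnorm(n, 0.5, 0.7),
    coldstrat_effect = rnorm(n, 0.3, 0.7),
    timing_hazard = runif(n, 0.03, 0.5),
    base_log_abundance = rnorm(n, 0, 1),
    stringsAsFactors = FALSE
  )
  pool$true_btn <- true_btn(pool$t_opt, pool$t_sd)
  pool$true_gp5 <- pool$p_max * exp(-(5 - pool$t_opt)^2 / (2 * pool$t_sd^2))

  std <- function(x) {
    s <- sd(x)
    if (length(x) > 1 && isTRUE(s > 0)) (x - mean(x)) / s else
      rep(0, length(x))
  }
  traits <- list(GP_low_T = pool$true_gp5, BTN = pool$true_btn,
                 alt_effect = pool$alt_effect,
                 coldstrat_effect = pool$coldstrat_effect)
  slope <- rnorm(n, 0, config$noise_sd)
  for (nm in names(config$coupling))
    slope <- slope + config$coupling[[nm]] * std(traits[[nm]])
  pool$n_response_slope <- slope
  class(pool) <- c("species_pool", "data.frame")
  pool
}

# Closed-form breadth of temperature niche implied by the Gaussian thermal
# response: occupation O_j = g_j / max(g), BTN = mean(O_j); p_max cancels.
true_btn <- function(t_opt, t_sd, temps = CONSTANT_TEMPS) {
  vapply(seq_along(t_opt), function(i) {
    g <- exp(-(temps - t_opt[i])^2 / (2 * t_sd[i]^2))
    mean(g / max(g))
  }, numeric(1))
}

#' True germination probability of a synthetic species
#'
#' Constant temperatures follow the Gaussian thermal response
#' `p_max * exp(-(T - t_opt)^2 / (2 t_sd^2))`; the 5/25 alternating regime
#' shifts the 15-degree probability by `alt_effect` on the log-odds scale;
#' wet-cold storage adds `coldstrat_effect` on the same scale.  The result
#' is clamped to (1e-9, 1 - 1e-9) before binomial sampling.
#'
#' @param sp one row of a species pool (list or single-row data.frame).
#' @param condition condition label (see `GERM_CONDITIONS`).
#' @param storage storage label (`"DRY_WARM"` or `"DRY_WARM_WET_COLD"`).
#' @return germination probability.
#' @export
true_germination_probability <- function(sp, condition,
                                         storage = "DRY_WARM") {
  stopifnot(length(condition) == 1, condition %in% GERM_CONDITIONS,
            length(storage) == 1, storage %in% STORAGES)
  if (condition == "ALT_5_25") {
    p15 <- sp$p_max * exp(-(15 - sp$t_opt)^2 / (2 * sp$t_sd^2))
    eta <- qlogis(clamp01(p15)) + sp$alt_effect
  } else {
    temp <- condition_mean_temperature(condition)
    p <- sp$p_max * exp(-(temp - sp$t_opt)^2 / (2 * sp$t_sd^2))
    eta <- qlogis(clamp01(p))
  }
  if (storage == "DRY_WARM_WET_COLD") eta <- eta + sp$coldstrat_effect
  clamp01(plogis(eta))
}

clamp01 <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)

# Condition x storage grid actually incubated: the six regimes with dry-warm
# stored seeds (experiment 1) plus the alternating regime after wet-cold
# storage, giving the storage contrast (experiment 2).
trial_grid <- function() {
  rbind(data.frame(condition = GERM_CONDITIONS, storage = "DRY_WARM",
                   stringsAsFactors = FALSE),
        data.frame(condition = "ALT_5_25", storage = "DRY_WARM_WET_COLD",
                   stringsAsFactors = FALSE))
}

#' Simulate germination trials
#'
#' For every species x condition x storage cell of the design grid and each
#' replicate dish, the number of germinating seeds is binomial with the
#' species' true probability; each germinating seed's day is geometric with
#' the species' timing hazard (1-based), truncated at the trial duration
#' (seeds past the end are recorded as not germinated).
#'
#' @param pool a species pool from [draw_species_pool()].
#' @param config a [sim_config()].
#' @return a `germ_trials` object (see [read_trials()]).
#' @export
simulate_trials <- function(pool, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$rng_seed, "germination_trials"))
  grid <- trial_grid()
  nrep <- config$replicates
  nsow <- config$seeds_per_replicate
  dur <- config$duration_days

  trials <- list(); counts <- list(); tid <- 0L
  for (s in seq_len(nrow(pool))) {
    sp <- pool[s, ]
    for (g in seq_len(nrow(grid))) {
      p <- true_germination_probability(sp, grid$condition[g], grid$storage[g])
      for (r in seq_len(nrep)) {
        tid <- tid + 1L
        k <- rbinom(1, nsow, p)
        trials[[tid]] <- data.frame(
          trial_id = tid, species_id = sp$species_id,
          condition = grid$condition[g], storage = grid$storage[g],
          replicate = r, n_sown = nsow, stringsAsFactors = FALSE)
        if (k > 0) {
          days <- rgeom(k, sp$timing_hazard) + 1L
          days <- days[days <= dur]
          if (length(days) > 0) {
            tab <- table(days)
            counts[[length(counts) + 1L]] <- data.frame(
              trial_id = tid, day = as.integer(names(tab)),
              count = as.integer(tab))
          }
        }
      }
    }
  }
  trials <- do.call(rbind, trials)
  counts <- if (length(counts) > 0) do.call(rbind, counts) else
    data.frame(trial_id = integer(), day = integer(), count = integer())
  new_germ_trials(trials = trials, counts = counts)
}

#' Simulate vegetation quadrats
#'
#' Species' expected relative abundances in the quadrat of block `b` at dose
#' `d` are proportional to `exp(base_log_abundance + n_response_slope *
#' d/max(d) + blockEffect)`, with a species-by-block normal effect of SD
#' `block_sd` (shared by all doses within the block, inducing the block-level
#' correlation the mixed models consume).  Quadrat totals are Poisson with
#' the configured mean (redrawn in the zero-probability event of an empty
#' quadrat) and species counts multinomial.
#'
#' @param pool a species pool from [draw_species_pool()].
#' @param config a [sim_config()].
#' @return data.frame of class `quadrats` (see [read_quadrats()]).
#' @export
simulate_quadrats <- function(pool, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$rng_seed, "vegetation_quadrats"))
  nb <- config$n_blocks
  doses <- config$n_doses
  dmax <- max(doses)
  levels <- if (length(doses) == length(N_LEVELS)) N_LEVELS else
    sprintf("N%d", seq_along(doses) - 1L)
  blockeff <- matrix(rnorm(nrow(pool) * nb, 0, config$block_sd),
                     nrow(pool), nb)
  out <- list()
  for (b in seq_len(nb)) {
    for (d in seq_along(doses)) {
      eta <- pool$base_log_abundance +
        pool$n_response_slope * doses[d] / dmax + blockeff[, b]
      pr <- exp(eta - max(eta))
      pr <- pr / sum(pr)
      total <- rpois(1, config$quadrat_total_individuals)
      while (total == 0) total <- rpois(1, config$quadrat_total_individuals)
      cnt <- as.integer(rmultinom(1, total, pr))
      keep <- cnt > 0
      out[[length(out) + 1L]] <- data.frame(
        block_id = sprintf("b%d", b), n_level = levels[d],
        species_id = pool$species_id[keep], count = cnt[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("quadrats", "data.frame")
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper drawing the species pool and both data tables.
#'
#' @param config a [sim_config()].
#' @return list with `pool`, `trials`, `quadrats`.
#' @export
simulate_study <- function(config = sim_config()) {
  pool <- draw_species_pool(config)
  list(pool = pool,
       trials = simulate_trials(pool, config),
       quadrats = simulate_quadrats(pool, config))
}
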