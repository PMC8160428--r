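#' Analysis configuration
#'
#' Bundles the tunable constants of the analysis pipeline.  Defaults mirror
#' the emulated study design: 60-day germination trials, the five constant
#' incubation temperatures defining the temperature-niche axis, and a 5%
#' significance level.
#'
#' @param trial_duration_days length of a germination trial in days.
#' @param niche_temperatures ordered constant temperatures (degrees C)
#'   defining the niche axis; its length is the `R` of the breadth index.
#' @param boundary_epsilon tolerance used to detect response values lying on
#'   the closed-interval boundaries (-1/+1 before transformation) that beta
#'   regression cannot accommodate.
#' @param fd_axes number of trait-space axes for functional diversity, or
#'   `"auto"` (`min(7, S_min - 1)` with a floor of 2, where `S_min` is the
#'   smallest community species count after trait filtering).
#' @param rng_seed integer seed for any randomized step.
#' @param significance_level alpha used by Tukey comparisons.
#' @param gp_pooling how replicate dishes are pooled into a germination
#'   percentage: `"pooled"` (ratio of summed counts, exact for binomial
#'   sampling) or `"mean"` (average of per-replicate proportions).
#' @param gr_pooling how replicate germination-rate indices are pooled:
#'   `"mean"` (average of per-replicate values) or `"pooled"` (computed on
#'   summed daily counts).
#' @param rf_pooling relative abundance entering the fertilization response:
#'   `"pooled"` (counts summed over blocks per treatment) or `"per_block"`
#'   (per-block responses averaged).
#' @param min_beta_cases minimum number of usable cases a beta regression
#'   requires; fits with fewer are refused with a diagnostic.
#' @return an object of class `germ_config` (a validated list).
#' @export
germ_config <- function(trial_duration_days = 60,
                        niche_temperatures = CONSTANT_TEMPS,
                        boundary_epsilon = 1e-8,
                        fd_axes = "auto",
                        rng_seed = 1L,
                        significance_level = 0.05,
                        gp_pooling = c("pooled", "mean"),
                        gr_pooling = c("mean", "pooled"),
                        rf_pooling = c("pooled", "per_block"),
                        min_beta_cases = 10L) {
  cfg <- list(
    trial_duration_days = as.integer(trial_duration_days),
    niche_temperatures = as.numeric(niche_temperatures),
    boundary_epsilon = as.numeric(boundary_epsilon),
    fd_axes = if (identical(fd_axes, "auto")) "auto" else as.integer(fd_axes),
    rng_seed = as.integer(rng_seed),
    significance_level = as.numeric(significance_level),
    gp_pooling = match.arg(gp_pooling),
    gr_pooling = match.arg(gr_pooling),
    rf_pooling = match.arg(rf_pooling),
    min_beta_cases = as.integer(min_beta_cases)
  )
  stopifnot(
    cfg$trial_duration_days >= 1,
    length(cfg$niche_temperatures) >= 2,
    !anyDuplicated(cfg$niche_temperatures),
    cfg$boundary_epsilon > 0,
    identical(cfg$fd_axes, "auto") || cfg$fd_axes >= 1,
    cfg$significance_level > 0, cfg$significance_level < 1,
    cfg$min_beta_cases >= 3
  )
  class(cfg) <- "germ_config"
  cfg
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The defaults reproduce the
#' emulated study design: 63 species, 5 blocks x 4 nitrogen levels
#' (0/5/10/20 g N m-2 yr-1) with one quadrat per plot, germination trials of
#' 3 replicates x 50 seeds over 60 days at five constant temperatures plus a
#' 5/25 degree alternating regime, and a dry-warm vs dry-warm + wet-cold
#' storage contrast.
#'
#' The `coupling` map ties species' true germination traits to their
#' fertilization response: each species' log-abundance slope along the
#' (normalized) nitrogen dose is `sum_t gamma_t * standardized(trait_t)` plus
#' `Normal(0, noise_sd)` noise.  Couplings may reference `GP_low_T` (true
#' germination probability at 5 degrees C), `BTN` (true temperature-niche
#' breadth), `alt_effect` and `coldstrat_effect`.  The default coupling
#' reproduces the qualitative filtering the study observed: broad-niche and
#' gap-cued germinators favoured, cold-stratification responders disfavoured.
#'
#' @param n_species number of species in the pool.
#' @param n_blocks number of spatial blocks.
#' @param n_doses nitrogen doses (g N m-2 yr-1), one plot per block per dose.
#' @param replicates germination-trial replicates per condition.
#' @param seeds_per_replicate seeds sown per replicate dish.
#' @param duration_days germination-trial duration.
#' @param quadrat_total_individuals expected total individual count per
#'   quadrat (Poisson mean).
#' @param coupling named numeric vector of trait-to-slope effect sizes.
#' @param block_sd between-block SD on species log abundance.
#' @param noise_sd residual SD of the species' nitrogen-response slope.
#' @param rng_seed integer root seed; every generator draw descends from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 63L,
                       n_blocks = 5L,
                       n_doses = c(0, 5, 10, 20),
                       replicates = 3L,
                       seeds_per_replicate = 50L,
                       duration_days = 60L,
                       quadrat_total_individuals = 400,
                       coupling = c(BTN = 2, alt_effect = 1,
                                    coldstrat_effect = -1),
                       block_sd = 0.3,
                       noise_sd = 0.3,
                       rng_seed = 1L) {
  coupling <- unlist(coupling)
  if (length(coupling) == 0) coupling <- c(BTN = 0)
  allowed <- c("GP_low_T", "BTN", "alt_effect", "coldstrat_effect")
  bad <- setdiff(names(coupling), allowed)
  if (length(bad) > 0)
    stop("unknown coupling key(s): ", paste(bad, collapse = ", "))
  cfg <- list(
    n_species = as.integer(n_species),
    n_blocks = as.integer(n_blocks),
    n_doses = as.numeric(n_doses),
    replicates = as.integer(replicates),
    seeds_per_replicate = as.integer(seeds_per_replicate),
    duration_days = as.integer(duration_days),
    quadrat_total_individuals = as.numeric(quadrat_total_individuals),
    coupling = coupling,
    block_sd = as.numeric(block_sd),
    noise_sd = as.numeric(noise_sd),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_species >= 1, cfg$n_blocks >= 1,
    length(cfg$n_doses) >= 2, !anyDuplicated(cfg$n_doses),
    all(cfg$n_doses >= 0), max(cfg$n_doses) > 0,
    cfg$replicates >= 1, cfg$seeds_per_replicate >= 1,
    cfg$duration_days >= 1, cfg$quadrat_total_individuals > 0,
    cfg$block_sd >= 0, cfg$noise_sd >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML (or flat `key: value`) file and builds the matching
#' configuration objects.  Keys under `analysis:` feed [germ_config()], keys
#' under `simulation:` feed [sim_config()]; unknown keys are an error.
#'
#' @param path path to a YAML configuration file.
#' @return list with elements `analysis` (`germ_config`) and `simulation`
#'   (`sim_config`), either possibly built from defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  take <- function(block, builder) {
    args <- raw[[block]]
    if (is.null(args)) return(builder())
    known <- names(formals(builder))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0)
      stop("unknown ", block, " config key(s): ", paste(bad, collapse = ", "))
    do.call(builder, args)
  }
  list(analysis = take("analysis", germ_config),
       simulation = take("simulation", sim_config))
}

# Derive a reproducible substream seed for a named pipeline stage so that
# adding one stage never perturbs another stage's draws.  Kept below 2^31.
substream_seed <- function(root_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 48271 + h * 2654435) %% 2147483647)
}
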