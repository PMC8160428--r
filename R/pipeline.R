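#' Run the full analysis in memory
#'
#' Executes every stage in dependency order: (simulated or supplied) trials
#' and quadrats, species germination profiles, abundance responses,
#' community-weighted means, functional diversity, species-level beta
#' regressions, community-level mixed-model tests with Tukey letters, and
#' the CWM PCA.
#'
#' @param sim a [sim_config()], used when `trials` / `quadrats` are not
#'   supplied.
#' @param analysis a [germ_config()].
#' @param trials,quadrats optional pre-loaded data (a `germ_trials` object
#'   and a `quadrats` data.frame); both must be given to skip simulation.
#' @param fd logical: compute functional diversity?
#' @return list of class `germ_run` with elements `pool` (NULL for real
#'   data), `trials`, `quadrats`, `profiles`, `responses`, `cwm`, `space`,
#'   `fd`, `species_fits`, `community_fits`, `tukey`, `pca`, `analysis`,
#'   `sim`.
#' @export
run_study <- function(sim = sim_config(), analysis = germ_config(),
                      trials = NULL, quadrats = NULL, fd = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  pool <- NULL
  if (is.null(trials) != is.null(quadrats))
    stop("supply both trials and quadrats, or neither")
  if (is.null(trials)) {
    pool <- stage("simulate", draw_species_pool(sim))
    trials <- stage("simulate", simulate_trials(pool, sim))
    quadrats <- stage("simulate", simulate_quadrats(pool, sim))
  }
  profiles <- stage("profiles", build_profiles(trials, analysis))
  responses <- stage("responses", abundance_response(quadrats, analysis))
  cwm <- stage("cwm", summarize_communities(quadrats, profiles))
  space <- fdres <- NULL
  if (fd) {
    space <- stage("fd", build_trait_space(profiles, quadrats,
                                           m = analysis$fd_axes))
    fdres <- stage("fd", fd_all(space, quadrats))
  }
  species_fits <- stage("fit-species",
                        fit_species_regressions(responses, profiles,
                                                analysis))
  community_fits <- stage("fit-community", community_tests(cwm, fdres))
  tukey <- stage("fit-community",
                 tukey_letter_table(cwm, fdres, analysis$significance_level))
  pca <- stage("pca", pca_cwm(cwm))
  structure(list(pool = pool, trials = trials, quadrats = quadrats,
                 profiles = profiles, responses = responses, cwm = cwm,
                 space = space, fd = fdres, species_fits = species_fits,
                 community_fits = community_fits, tukey = tukey, pca = pca,
                 analysis = analysis, sim = sim),
            class = "germ_run")
}

#' @export
print.germ_run <- function(x, ...) {
  cat("germination-trait filtering analysis\n")
  cat(sprintf("  %d species, %d quadrats, %d species-level fits\n",
              nrow(x$profiles), nrow(unique(x$quadrats[, 1:2])),
              nrow(x$species_fits)))
  invisible(x)
}

# Tukey compact-letter tables for the treatment comparisons shown per
# temperature (CWM_GP, CWM_GR) and marginally (single-factor responses).
tukey_letter_table <- function(summaries, fd = NULL, alpha = 0.05) {
  rows <- list()
  add <- function(resp, values, groups) {
    tk <- tryCatch(tukey_groups(values, groups, alpha),
                   error = function(e) NULL)
    if (is.null(tk)) return()
    lv <- names(tk$letters)
    rows[[length(rows) + 1L]] <<- data.frame(
      response = resp, n_level = lv, mean = unname(tk$means[lv]),
      letters = unname(tk$letters), stringsAsFactors = FALSE)
  }
  for (fam in c("gp", "gr")) for (tp in CONSTANT_TEMPS) {
    v <- summaries[[paste0("cwm_", fam, "_", tp)]]
    ok <- !is.na(v)
    add(sprintf("cwm_%s_%s", fam, tp), v[ok], summaries$n_level[ok])
  }
  for (resp in c("cwm_btn", "cwm_r_alt", "cwm_r_wc")) {
    v <- summaries[[resp]]
    ok <- !is.na(v)
    add(resp, v[ok], summaries$n_level[ok])
  }
  if (!is.null(fd)) for (resp in c("fric", "feve", "fdiv")) {
    v <- fd[[resp]]
    ok <- !is.na(v)
    add(resp, v[ok], fd$n_level[ok])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the pipeline and write its outputs
#'
#' Orchestrates [run_study()] and writes `profiles.csv`, `responses.csv`,
#' `cwm.csv`, `fd.csv`, `species_fits.csv`, `community_fits.csv`,
#' `tukey.csv`, `pca.csv` and `manifest.json` to `out_dir`.  Identical
#' configuration and seed yield byte-identical CSVs.
#'
#' @param out_dir output directory (created if missing).
#' @param sim a [sim_config()] (ignored when input paths are given).
#' @param analysis a [germ_config()].
#' @param trials_path,quadrats_path optional CSV inputs replacing
#'   simulation; both must be given together.
#' @param seed optional integer overriding both configurations' seeds.
#' @param fd logical: compute functional diversity?
#' @return invisibly, the manifest (also written as JSON).
#' @export
run_pipeline <- function(out_dir, sim = sim_config(),
                         analysis = germ_config(),
                         trials_path = NULL, quadrats_path = NULL,
                         seed = NULL, fd = TRUE) {
  if (is.null(trials_path) != is.null(quadrats_path))
    stop("supply both trials_path and quadrats_path, or neither")
  if (!is.null(seed)) {
    sim$rng_seed <- as.integer(seed)
    analysis$rng_seed <- as.integer(seed)
  }
  inputs <- character()
  trials <- quadrats <- NULL
  if (!is.null(trials_path)) {
    for (p in c(trials_path, quadrats_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    trials <- read_trials(trials_path, analysis)
    quadrats <- read_quadrats(quadrats_path)
    inputs <- c(trials_path, quadrats_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- proc.time()[["elapsed"]]
  run <- run_study(sim, analysis, trials = trials, quadrats = quadrats,
                   fd = fd)
  t1 <- proc.time()[["elapsed"]]

  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    outputs <<- c(outputs, name)
  }
  emit(run$profiles, "profiles.csv")
  emit(run$responses, "responses.csv")
  emit(run$cwm, "cwm.csv")
  if (fd) {
    fdout <- run$fd
    fdout$reason <- ifelse(is.na(fdout$fric), "degenerate_or_too_few_species",
                           NA_character_)
    emit(fdout, "fd.csv")
  }
  emit(run$species_fits, "species_fits.csv")
  emit(run$community_fits, "community_fits.csv")
  emit(run$tukey, "tukey.csv")
  ve <- run$pca$variance_explained
  pca_long <- do.call(rbind, lapply(seq_along(ve), function(k) {
    data.frame(component = paste0("PC", k),
               variance_explained = ve[k],
               variable = run$pca$variable_names,
               loading = run$pca$loadings[, k],
               stringsAsFactors = FALSE)
  }))
  emit(pca_long, "pca.csv")
  if (!is.null(run$pool)) emit(run$pool, "truth.csv")

  manifest <- list(
    package_version = as.character(packageVersion("germfilter")),
    rng_seed = sim$rng_seed,
    config = list(simulation = if (is.null(trials)) unclass(sim),
                  analysis = unclass(analysis)),
    inputs = as.list(setNames(as.character(tools::md5sum(inputs)), inputs)),
    outputs = outputs,
    output_digests = as.list(setNames(
      as.character(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    fd_enabled = fd,
    stage_seconds = list(total = round(t1 - t0, 3))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

fmt_table <- function(df, digits = 4) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], digits)
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  body <- apply(df, 1, function(r)
    paste(ifelse(is.na(r), "", trimws(r)), collapse = " | "))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render a run report
#'
#' Reads a pipeline manifest and the CSVs beside it and renders a markdown
#' summary: the species-level regression battery, the community mixed-model
#' tests, CWM means by treatment with Tukey letters, functional diversity
#' by treatment, and the PCA variance shares with leading loadings.
#' Regenerating the report from the same manifest yields identical text.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return the report as a single character string (invisibly printed with
#'   `cat` by the caller if desired).
#' @export
report <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  grab <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("manifest references missing file: ", p)
    read.csv(p, stringsAsFactors = FALSE)
  }
  parts <- character()
  add <- function(...) parts <<- c(parts, ...)
  add(sprintf("# Germination-trait filtering report (seed %s)\n",
              man$rng_seed))

  sf <- grab("species_fits.csv")
  add("## Species-level beta regressions (response: transformed R_f)\n",
      fmt_table(sf[, c("predictor", "intercept", "slope", "z_slope",
                       "p_slope", "pseudo_r2", "n_used")]), "\n")

  cf <- grab("community_fits.csv")
  add("## Community-level mixed-model tests (block random intercept)\n",
      fmt_table(cf), "\n")

  tk <- grab("tukey.csv")
  add("## CWM by treatment with Tukey letters\n", fmt_table(tk), "\n")

  if (isTRUE(man$fd_enabled)) {
    fd <- grab("fd.csv")
    agg <- do.call(rbind, lapply(split(fd, fd$n_level), function(d)
      data.frame(n_level = d$n_level[1],
                 fric = mean(d$fric, na.rm = TRUE),
                 feve = mean(d$feve, na.rm = TRUE),
                 fdiv = mean(d$fdiv, na.rm = TRUE))))
    add("## Functional diversity by treatment (means)\n", fmt_table(agg),
        "\n")
  } else {
    add("## Functional diversity\n", "skipped\n")
  }

  pca <- grab("pca.csv")
  ve <- unique(pca[, c("component", "variance_explained")])
  add("## PCA of community-weighted means\n",
      sprintf("First two components: %.2f%% + %.2f%% = %.2f%%\n",
              100 * ve$variance_explained[1], 100 * ve$variance_explained[2],
              100 * sum(ve$variance_explained[1:2])))
  top <- do.call(rbind, lapply(c("PC1", "PC2"), function(pc) {
    d <- pca[pca$component == pc, ]
    d <- d[order(-abs(d$loading)), ][1:5, c("component", "variable",
                                            "loading")]
    d
  }))
  add(fmt_table(top), "\n")
  paste(parts, collapse = "\n")
}
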