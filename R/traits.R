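#' Germination percentage of one species x condition
#'
#' Final fraction of sown seeds that germinated, pooled over replicate
#' dishes.  With `pooling = "pooled"` (default) counts are summed before
#' dividing (the exact estimator for binomial dishes); `"mean"` averages
#' per-replicate proportions.
#'
#' @param trials a `germ_trials` object holding the replicates of a single
#'   species x condition x storage cell.
#' @param pooling `"pooled"` or `"mean"`.
#' @return proportion in `[0, 1]`.
#' @export
germination_percentage <- function(trials, pooling = c("pooled", "mean")) {
  pooling <- match.arg(pooling)
  assert_one_cell(trials)
  gfin <- germinated_totals(trials)
  if (pooling == "pooled") sum(gfin) / sum(trials$trials$n_sown)
  else mean(gfin / trials$trials$n_sown)
}

#' Germination rate (speed) of one species x condition
#'
#' Day-weighted germination index `GR = (1/n) * sum_i G_i / i`, where `G_i`
#' is the number of seeds germinating on day `i` (1-based): 1 when every
#' sown seed germinates on the first day, and discounting later germination
#' by `1/i`.  Replicates are averaged by default (`"mean"`); `"pooled"`
#' computes the index on summed counts.
#'
#' @inheritParams germination_percentage
#' @param pooling `"mean"` or `"pooled"`.
#' @return index in `[0, 1]`.
#' @export
germination_rate <- function(trials, pooling = c("mean", "pooled")) {
  pooling <- match.arg(pooling)
  assert_one_cell(trials)
  dw <- day_weighted_totals(trials)
  if (pooling == "pooled") sum(dw) / sum(trials$trials$n_sown)
  else mean(dw / trials$trials$n_sown)
}

assert_one_cell <- function(trials) {
  stopifnot(inherits(trials, "germ_trials"))
  if (nrow(trials$trials) == 0) stop("no trials supplied")
  cell <- unique(trials$trials[, c("species_id", "condition", "storage")])
  if (nrow(cell) != 1)
    stop("trials span more than one species x condition x storage cell")
  invisible(trials)
}

# Normalized difference (a - b) / (a + b): the shared form of the
# fertilization, alternating-temperature and wet-cold response indices.
# Undefined (NA) when both terms are zero.
normalized_difference <- function(a, b) {
  s <- a + b
  ifelse(is.na(a) | is.na(b) | s == 0, NA_real_, (a - b) / s)
}

#' Germination response to the alternating-temperature regime
#'
#' `R_5/25 = (GP_alt - GP_15) / (GP_alt + GP_15)` for dry-warm stored seeds;
#' +1 means germination only under the fluctuating regime (a canopy-gap
#' cue), undefined (NA) when neither regime yielded germination.
#'
#' @param gp_alt pooled germination proportion under the 5/25 regime.
#' @param gp_15 pooled germination proportion at constant 15 degrees C.
#' @return number in `[-1, 1]` or NA.
#' @export
response_alternating <- function(gp_alt, gp_15) {
  normalized_difference(gp_alt, gp_15)
}

#' Germination response to wet-cold storage
#'
#' `R_wc = (GP_wc - GP_dr) / (GP_wc + GP_dr)` at the storage-contrast
#' incubation regime; +1 means an absolute cold-stratification requirement.
#'
#' @param gp_wc pooled germination proportion after dry-warm + wet-cold
#'   storage.
#' @param gp_dr pooled germination proportion after dry-warm storage only.
#' @return number in `[-1, 1]` or NA.
#' @export
response_wet_cold <- function(gp_wc, gp_dr) {
  normalized_difference(gp_wc, gp_dr)
}

#' Temperature-niche metrics from constant-temperature germination
#'
#' Given germination proportions `g_j` at the `R` constant temperatures:
#' occupation `O_j = g_j / g_max`, niche proportion `P_j = O_j / sum(O)`,
#' and breadth `BTN = mean(O_j)`, bounded in `[1/R, 1]`.  All three are
#' undefined when no germination occurred at any temperature.
#'
#' @param gp_by_temperature named numeric vector of germination proportions,
#'   names the constant temperatures as character.
#' @param temperatures the configured niche axis (default 5..25 degrees C).
#' @return list with `occupation`, `proportion_niche` (named vectors) and
#'   `btn`, all NA when undefined.
#' @export
niche_metrics <- function(gp_by_temperature,
                          temperatures = CONSTANT_TEMPS) {
  want <- as.character(temperatures)
  if (length(gp_by_temperature) != length(want) ||
      !setequal(names(gp_by_temperature), want))
    stop("expected germination proportions at exactly the temperatures ",
         paste(want, collapse = ", "))
  g <- gp_by_temperature[want]
  nas <- setNames(rep(NA_real_, length(want)), want)
  if (anyNA(g)) return(list(occupation = nas, proportion_niche = nas,
                            btn = NA_real_))
  gmax <- max(g)
  if (gmax == 0) return(list(occupation = nas, proportion_niche = nas,
                             btn = NA_real_))
  occ <- g / gmax
  list(occupation = occ, proportion_niche = occ / sum(occ), btn = mean(occ))
}

# suffix used in profile column names for each condition label
condition_suffix <- function(condition) {
  ifelse(condition == "ALT_5_25", "alt",
         sub("^T", "", condition))
}

#' Build species germination profiles
#'
#' Computes every species-level index from a trial collection: germination
#' percentage and rate per incubation condition, the wet-cold storage
#' percentage, the alternating-temperature and wet-cold response indices,
#' and the temperature-niche occupation, proportion and breadth metrics.
#' Missing conditions or zero germination yield NA indices with a reason
#' code (`missing_condition` / `no_germination`) rather than imputed zeros.
#'
#' @param trials a `germ_trials` object covering one or more species.
#' @param config a [germ_config()].
#' @return data.frame of class `germ_profiles`, one row per species:
#'   `gp_*` / `gr_*` per condition (suffixes 5..25 and `alt`), `gp_wc`,
#'   `r_alt`, `r_wc`, `o_*` / `p_*` per constant temperature, `btn`, and
#'   reason columns for the undefined indices.
#' @export
build_profiles <- function(trials, config = germ_config()) {
  stopifnot(inherits(trials, "germ_trials"))
  species <- unique(trials$trials$species_id)
  gfin <- germinated_totals(trials)
  dw <- day_weighted_totals(trials)
  tt <- trials$trials
  temps <- config$niche_temperatures

  one <- function(sp) {
    sel <- tt$species_id == sp
    row <- list(species_id = sp)
    gp <- gr <- setNames(rep(NA_real_, length(GERM_CONDITIONS)),
                         GERM_CONDITIONS)
    for (cond in GERM_CONDITIONS) {
      i <- sel & tt$condition == cond & tt$storage == "DRY_WARM"
      if (any(i)) {
        gp[cond] <- if (config$gp_pooling == "pooled")
          sum(gfin[i]) / sum(tt$n_sown[i]) else mean(gfin[i] / tt$n_sown[i])
        gr[cond] <- if (config$gr_pooling == "pooled")
          sum(dw[i]) / sum(tt$n_sown[i]) else mean(dw[i] / tt$n_sown[i])
      }
    }
    sfx <- condition_suffix(GERM_CONDITIONS)
    row[paste0("gp_", sfx)] <- as.list(unname(gp))
    row[paste0("gr_", sfx)] <- as.list(unname(gr))

    i <- sel & tt$condition == "ALT_5_25" & tt$storage == "DRY_WARM_WET_COLD"
    row$gp_wc <- if (any(i)) {
      if (config$gp_pooling == "pooled")
        sum(gfin[i]) / sum(tt$n_sown[i]) else mean(gfin[i] / tt$n_sown[i])
    } else NA_real_

    res <- function(a, b) {
      if (is.na(a) || is.na(b)) list(NA_real_, "missing_condition")
      else if (a + b == 0) list(NA_real_, "no_germination")
      else list((a - b) / (a + b), NA_character_)
    }
    ra <- res(gp[["ALT_5_25"]], gp[["T15"]])
    row$r_alt <- ra[[1]]; row$reason_r_alt <- ra[[2]]
    rw <- res(row$gp_wc, gp[["ALT_5_25"]])
    row$r_wc <- rw[[1]]; row$reason_r_wc <- rw[[2]]

    const <- setNames(gp[paste0("T", temps)], as.character(temps))
    if (anyNA(const)) {
      nm <- niche_metrics(setNames(rep(0, length(temps)),
                                   as.character(temps)), temps)
      nm$occupation[] <- NA_real_; nm$proportion_niche[] <- NA_real_
      nm$btn <- NA_real_
      row$reason_niche <- "missing_condition"
    } else {
      nm <- niche_metrics(const, temps)
      row$reason_niche <- if (is.na(nm$btn)) "no_germination" else
        NA_character_
    }
    row[paste0("o_", temps)] <- as.list(unname(nm$occupation))
    row[paste0("p_", temps)] <- as.list(unname(nm$proportion_niche))
    row$btn <- nm$btn
    as.data.frame(row, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(species, one))
  class(out) <- c("germ_profiles", "data.frame")
  out
}

#' @export
print.germ_profiles <- function(x, ...) {
  cat(sprintf("germination profiles: %d species (%d with defined BTN)\n",
              nrow(x), sum(!is.na(x$btn))))
  invisible(x)
}
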