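#' Relative abundance of species at one fertilization level
#'
#' Counts are summed across all blocks sampled at the level and divided by
#' the grand total, giving one relative-abundance vector per treatment over
#' the whole species list of the survey (species absent at the level get 0).
#'
#' @param quadrats a `quadrats` data.frame (see [read_quadrats()]).
#' @param level a fertilization level label present in the data.
#' @return named proportion vector over every species in `quadrats`.
#' @export
relative_abundance <- function(quadrats, level) {
  species <- sort(unique(quadrats$species_id))
  sel <- quadrats$n_level == level
  if (!any(sel)) stop("no quadrats at level ", level)
  ra <- setNames(numeric(length(species)), species)
  agg <- rowsum(quadrats$count[sel], quadrats$species_id[sel])
  ra[rownames(agg)] <- agg[, 1]
  ra / sum(ra)
}

#' Fertilization response of a species
#'
#' `R_f = (RA_N3 - RA_N0) / (RA_N3 + RA_N0)`: the normalized change of
#' relative abundance between the highest nitrogen dose and the control.
#' +1 means the species occurs only under high N; undefined (NA) when it is
#' absent from both treatments.
#'
#' @param ra_n0,ra_n3 relative abundances under control and high N
#'   (vectorized).
#' @return number(s) in `[-1, 1]` or NA.
#' @export
fertilization_response <- function(ra_n0, ra_n3) {
  normalized_difference(ra_n3, ra_n0)
}

#' Species abundance responses along the gradient
#'
#' Per-species relative abundance at each fertilization level and the
#' fertilization response index contrasting the highest dose with control.
#' With `rf_pooling = "pooled"` (default) relative abundances aggregate
#' counts over the replicate blocks of each treatment; `"per_block"`
#' computes a response per block and averages the defined ones.
#'
#' @param quadrats a `quadrats` data.frame.
#' @param config a [germ_config()].
#' @return data.frame: `species_id`, `ra_<level>` columns, `r_f`,
#'   `reason_r_f`.
#' @export
abundance_response <- function(quadrats, config = germ_config()) {
  levels <- sort(unique(quadrats$n_level))
  lo <- levels[1]; hi <- levels[length(levels)]
  species <- sort(unique(quadrats$species_id))
  out <- data.frame(species_id = species, stringsAsFactors = FALSE)
  for (lv in levels) out[[paste0("ra_", lv)]] <-
    unname(relative_abundance(quadrats, lv)[species])
  if (config$rf_pooling == "pooled") {
    rf <- fertilization_response(out[[paste0("ra_", lo)]],
                                 out[[paste0("ra_", hi)]])
  } else {
    blocks <- unique(quadrats$block_id)
    per <- sapply(blocks, function(b) {
      q <- quadrats[quadrats$block_id == b, , drop = FALSE]
      ra <- function(lv) {
        v <- setNames(numeric(length(species)), species)
        s <- q$n_level == lv
        if (any(s)) {
          agg <- rowsum(q$count[s], q$species_id[s])
          v[rownames(agg)] <- agg[, 1] / sum(agg[, 1])
        }
        v
      }
      fertilization_response(ra(lo), ra(hi))
    })
    rf <- rowMeans(per, na.rm = TRUE)
    rf[is.nan(rf)] <- NA_real_
  }
  out$r_f <- rf
  out$reason_r_f <- ifelse(is.na(rf), "absent_both_treatments", NA_character_)
  out
}

#' Community-weighted mean of one trait in one quadrat
#'
#' `CWM = sum_i trait_i * RA_i` with relative abundances renormalized over
#' the species whose trait is defined, so the CWM stays a convex combination
#' of observed trait values.  `coverage` reports the abundance share carried
#' by those species before renormalization.
#'
#' @param counts named individual counts of the quadrat.
#' @param trait_values named trait values (NA = undefined) covering the
#'   quadrat's species.
#' @return list with `cwm` and `coverage` (both NA, with a reason attribute,
#'   when no species with a defined trait occurs).
#' @export
community_weighted_mean <- function(counts, trait_values) {
  stopifnot(!is.null(names(counts)))
  tv <- trait_values[names(counts)]
  ok <- !is.na(tv) & counts > 0
  if (!any(ok)) {
    out <- list(cwm = NA_real_, coverage = NA_real_)
    attr(out, "reason") <- "no_defined_trait"
    return(out)
  }
  w <- counts[ok] / sum(counts[ok])
  list(cwm = sum(w * tv[ok]), coverage = sum(counts[ok]) / sum(counts))
}

# The community-level trait variables: germination percentage and rate at
# the five constant temperatures, niche breadth, occupation and proportion
# per temperature, and the two response indices (23 variables; the
# alternating-regime GP/GR stay species-level only).
cwm_variables <- function(temps = CONSTANT_TEMPS) {
  c(paste0("gp_", temps), paste0("gr_", temps), "btn",
    paste0("o_", temps), paste0("p_", temps), "r_alt", "r_wc")
}

#' Community trait summaries (CWMs) per quadrat
#'
#' Community-weighted means of the 23 germination-trait variables for every
#' quadrat, with per-variable coverage (abundance share of trait-defined
#' species).
#'
#' @param quadrats a `quadrats` data.frame.
#' @param profiles a `germ_profiles` data.frame from [build_profiles()].
#' @return data.frame of class `community_summary`: `block_id`, `n_level`,
#'   `cwm_<var>` and `cov_<var>` columns.
#' @export
summarize_communities <- function(quadrats, profiles) {
  vars <- cwm_variables()
  miss <- setdiff(vars, names(profiles))
  if (length(miss) > 0)
    stop("profiles lack variable(s): ", paste(miss, collapse = ", "))
  cells <- unique(quadrats[, c("block_id", "n_level")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    q <- quadrats[quadrats$block_id == cells$block_id[i] &
                    quadrats$n_level == cells$n_level[i], , drop = FALSE]
    counts <- setNames(q$count, q$species_id)
    row <- list(block_id = cells$block_id[i], n_level = cells$n_level[i])
    for (v in vars) {
      tv <- setNames(profiles[[v]], profiles$species_id)
      cw <- community_weighted_mean(counts, tv)
      row[[paste0("cwm_", v)]] <- cw$cwm
      row[[paste0("cov_", v)]] <- cw$coverage
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block_id, out$n_level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("community_summary", "data.frame")
  out
}
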