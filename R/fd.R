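#' Build the shared germination-trait space
#'
#' Functional diversity is computed in one trait space common to all
#' communities so volumes are comparable across treatments.  The space is
#' built on seven variables: germination percentage at the five constant
#' temperatures and the responses to the alternating regime and to wet-cold
#' storage.  Species missing any variable are dropped (with a reason);
#' remaining columns are z-score standardized.  With `m = "auto"` the
#' dimensionality is `min(7, S_min - 1)` (floor 2), where `S_min` is the
#' smallest retained species count over the supplied communities; when
#' `m < 7` coordinates are the first `m` principal coordinates of the
#' Euclidean distance matrix on standardized traits.
#'
#' @param profiles a `germ_profiles` data.frame.
#' @param quadrats optional `quadrats` data.frame, needed for `m = "auto"`.
#' @param m integer dimensionality or `"auto"`.
#' @return object of class `trait_space`: `species_ids`, `coordinates`
#'   (species x axes matrix), `axes_used`, `dropped_species`.
#' @export
build_trait_space <- function(profiles, quadrats = NULL, m = "auto") {
  vars <- c(paste0("gp_", CONSTANT_TEMPS), "r_alt", "r_wc")
  X <- as.matrix(profiles[, vars])
  rownames(X) <- profiles$species_id
  bad <- apply(X, 1, anyNA)
  dropped <- data.frame(
    species_id = profiles$species_id[bad],
    reason = vapply(which(bad), function(i) {
      paste0("undefined_", paste(vars[is.na(X[i, ])], collapse = ",")
      )
    }, character(1)),
    stringsAsFactors = FALSE)
  X <- X[!bad, , drop = FALSE]
  if (nrow(X) < 3)
    stop("fewer than 3 species with all trait variables defined")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero variance in trait column(s): ",
         paste(vars[sds == 0], collapse = ", "))
  Z <- scale(X)

  if (identical(m, "auto")) {
    if (is.null(quadrats)) {
      m <- ncol(Z)
    } else {
      keep <- quadrats$species_id %in% rownames(Z)
      counts <- table(paste(quadrats$block_id[keep], quadrats$n_level[keep]))
      s_min <- if (length(counts) > 0) min(counts) else ncol(Z) + 1
      m <- max(2L, min(ncol(Z), as.integer(s_min) - 1L))
    }
  }
  m <- as.integer(m)
  stopifnot(m >= 1, m <= ncol(Z))
  coords <- if (m == ncol(Z)) {
    unclass(Z)
  } else {
    co <- cmdscale(dist(Z), k = m)
    rownames(co) <- rownames(Z)
    co
  }
  structure(list(species_ids = rownames(Z), coordinates = coords,
                 axes_used = m, dropped_species = dropped),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait space: %d species x %d axes (%d species dropped)\n",
              length(x$species_ids), x$axes_used, nrow(x$dropped_species)))
  invisible(x)
}

community_coords <- function(space, community) {
  stopifnot(!is.null(names(community)), all(community >= 0))
  ids <- names(community)[community > 0]
  missing <- setdiff(ids, space$species_ids)
  ids <- setdiff(ids, missing)
  list(coords = space$coordinates[ids, , drop = FALSE],
       weights = community[ids] / sum(community[ids]))
}

#' Functional richness (FRic)
#'
#' Volume of the convex hull spanned by the community's species in the
#' trait space (length, area, volume, ... in standardized trait units to
#' the power of the axis count).  Undefined (NA) when the community has at
#' most `m` species or its points are affinely degenerate.
#'
#' @param space a `trait_space`.
#' @param community named non-negative abundance (weight) vector; species
#'   absent from the space are ignored.
#' @return hull volume or NA.
#' @export
fric <- function(space, community) {
  cc <- community_coords(space, community)
  P <- cc$coords
  m <- ncol(P)
  if (nrow(P) <= m) return(NA_real_)
  if (m == 1) return(max(P[, 1]) - min(P[, 1]))
  h <- convhull_cpp(P)
  h$volume
}

# hull vertex ids (species) for FDiv's reference centroid
hull_vertices <- function(P) {
  if (ncol(P) == 1) {
    rownames(P)[c(which.min(P[, 1]), which.max(P[, 1]))]
  } else {
    h <- convhull_cpp(P)
    if (is.na(h$volume)) NULL else rownames(P)[h$vertices]
  }
}

#' Functional evenness (FEve)
#'
#' Regularity of species packing along the minimum spanning tree of the
#' community's trait-space points, weighted by abundance: each branch gets
#' `EW = dist / (w_i + w_j)`, the partial weights `PEW = EW / sum(EW)` are
#' capped at `1/(S-1)`, and the capped sum is rescaled to `[0, 1]` (1 when
#' all capped weights are equal).  The tree is built with [ape::mst()].
#'
#' @inheritParams fric
#' @return number in `[0, 1]`, or NA when fewer than 3 species.
#' @export
feve <- function(space, community) {
  cc <- community_coords(space, community)
  P <- cc$coords; w <- cc$weights
  S <- nrow(P)
  if (S < 3) return(NA_real_)
  D <- as.matrix(dist(P))
  adj <- unclass(ape::mst(dist(P)))
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  ew <- D[idx] / (w[idx[, 1]] + w[idx[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence (FDiv)
#'
#' Measures whether abundance is concentrated toward the extremes of the
#' occupied trait space.  With `G` the centroid of the convex-hull vertices,
#' `dG_i` the species' distances to `G` and `dbar` their unweighted mean:
#' `FDiv = (sum w_i (dG_i - dbar) + dbar) / (sum w_i |dG_i - dbar| + dbar)`.
#'
#' @inheritParams fric
#' @return number in `[0, 1]`, or NA when the hull is undefined.
#' @export
fdiv <- function(space, community) {
  cc <- community_coords(space, community)
  P <- cc$coords; w <- cc$weights
  if (nrow(P) <= ncol(P)) return(NA_real_)
  verts <- hull_vertices(P)
  if (is.null(verts)) return(NA_real_)
  G <- colMeans(P[verts, , drop = FALSE])
  dG <- sqrt(colSums((t(P) - G)^2))
  dbar <- mean(dG)
  dd <- sum(w * (dG - dbar))
  dad <- sum(w * abs(dG - dbar))
  (dd + dbar) / (dad + dbar)
}

#' Functional diversity per quadrat
#'
#' Applies [fric()], [feve()] and [fdiv()] to every quadrat, weighting by
#' within-quadrat relative abundance over the species retained in the trait
#' space.
#'
#' @param space a `trait_space`.
#' @param quadrats a `quadrats` data.frame.
#' @return data.frame: `block_id`, `n_level`, `fric`, `feve`, `fdiv`,
#'   `s_used` (species in both quadrat and trait space).
#' @export
fd_all <- function(space, quadrats) {
  cells <- unique(quadrats[, c("block_id", "n_level")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    q <- quadrats[quadrats$block_id == cells$block_id[i] &
                    quadrats$n_level == cells$n_level[i], , drop = FALSE]
    com <- setNames(q$count, q$species_id)
    s_used <- sum(names(com)[com > 0] %in% space$species_ids)
    data.frame(block_id = cells$block_id[i], n_level = cells$n_level[i],
               fric = fric(space, com), feve = feve(space, com),
               fdiv = fdiv(space, com), s_used = s_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block_id, out$n_level), , drop = FALSE]
  rownames(out) <- NULL
  out
}
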