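# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package internals: plain loops over raw rows, facet
# enumeration instead of incremental hulls, Prim's algorithm instead of
# ape::mst.

# ---- trial fixtures ---------------------------------------------------------

# Build a germ_trials object from a long data.frame written through a CSV, so
# fixtures exercise the real reader.
trials_from_df <- function(df, config = germ_config()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  read_trials(path, config)
}

# One fully crossed random trial set: every condition/storage cell of the
# design for each species, with uniform random daily counts.
random_trial_df <- function(n_species, seed, n_sown = 20L, reps = 2L,
                            max_days = 12L) {
  set.seed(seed)
  grid <- expand.grid(condition = c("T5", "T10", "T15", "T20", "T25",
                                    "ALT_5_25"),
                      storage = "DRY_WARM", stringsAsFactors = FALSE)
  grid <- rbind(grid, data.frame(condition = "ALT_5_25",
                                 storage = "DRY_WARM_WET_COLD"))
  rows <- list()
  for (s in seq_len(n_species)) {
    for (g in seq_len(nrow(grid))) {
      for (r in seq_len(reps)) {
        total <- sample(0:n_sown, 1)
        cnt <- if (total > 0) {
          k <- sample(1:min(3, max_days), 1)
          dd <- sample(seq_len(max_days), k)
          cc <- as.vector(rmultinom(1, total, rep(1, k)))
          keep <- cc > 0
          data.frame(day = dd[keep], count = cc[keep])
        } else data.frame(day = NA_integer_, count = NA_integer_)
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = sprintf("s%02d", s), condition = grid$condition[g],
          storage = grid$storage[g], replicate = r, n_sown = n_sown,
          day = cnt$day, count = cnt$count, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# ---- germination-index oracle ----------------------------------------------

# Recompute every species index from the raw long rows with naive loops.
oracle_profiles <- function(df, config = germ_config()) {
  df <- df[!is.na(df$count) & df$count > 0 | is.na(df$day), , drop = FALSE]
  species <- unique(df$species_id)
  gp_of <- function(sp, cond, sto) {
    sel <- df$species_id == sp & df$condition == cond & df$storage == sto
    if (!any(sel)) return(NA_real_)
    reps <- unique(df$replicate[sel])
    tot_g <- 0; tot_n <- 0
    for (r in reps) {
      rs <- sel & df$replicate == r
      tot_g <- tot_g + sum(df$count[rs], na.rm = TRUE)
      tot_n <- tot_n + df$n_sown[rs][1]
    }
    tot_g / tot_n
  }
  gr_of <- function(sp, cond, sto) {
    sel <- df$species_id == sp & df$condition == cond & df$storage == sto
    if (!any(sel)) return(NA_real_)
    reps <- unique(df$replicate[sel])
    vals <- numeric(0)
    for (r in reps) {
      rs <- which(sel & df$replicate == r)
      acc <- 0
      for (i in rs)
        if (!is.na(df$day[i])) acc <- acc + df$count[i] / df$day[i]
      vals <- c(vals, acc / df$n_sown[rs[1]])
    }
    mean(vals)
  }
  nd <- function(a, b) {
    if (is.na(a) || is.na(b) || a + b == 0) NA_real_ else (a - b) / (a + b)
  }
  out <- list()
  for (sp in species) {
    row <- list(species_id = sp)
    for (cond in c("T5", "T10", "T15", "T20", "T25", "ALT_5_25")) {
      sfx <- if (cond == "ALT_5_25") "alt" else sub("T", "", cond)
      row[[paste0("gp_", sfx)]] <- gp_of(sp, cond, "DRY_WARM")
      row[[paste0("gr_", sfx)]] <- gr_of(sp, cond, "DRY_WARM")
    }
    row$gp_wc <- gp_of(sp, "ALT_5_25", "DRY_WARM_WET_COLD")
    row$r_alt <- nd(row$gp_alt, row$gp_15)
    row$r_wc <- nd(row$gp_wc, row$gp_alt)
    g <- c(row$gp_5, row$gp_10, row$gp_15, row$gp_20, row$gp_25)
    if (anyNA(g) || max(g) == 0) {
      occ <- pro <- rep(NA_real_, 5); btn <- NA_real_
    } else {
      occ <- g / max(g); pro <- occ / sum(occ); btn <- sum(occ) / 5
    }
    for (k in 1:5) {
      row[[paste0("o_", c(5, 10, 15, 20, 25)[k])]] <- occ[k]
      row[[paste0("p_", c(5, 10, 15, 20, 25)[k])]] <- pro[k]
    }
    row$btn <- btn
    out[[length(out) + 1L]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

# ---- convex hull / FD oracles ----------------------------------------------

# Exact hull volume and vertex set by brute-force facet enumeration: every
# m-subset whose hyperplane has all remaining points strictly on one side is
# a facet.  O(S^(m+1)); fine for S <= 12, m <= 3.
oracle_hull <- function(P) {
  S <- nrow(P); m <- ncol(P)
  if (m == 1) {
    return(list(volume = max(P) - min(P),
                vertices = unique(c(which.min(P[, 1]), which.max(P[, 1])))))
  }
  if (S <= m) return(list(volume = NA_real_, vertices = integer()))
  centre <- colMeans(P)
  vol <- 0; verts <- logical(S); any_facet <- FALSE
  for (sub in utils::combn(S, m, simplify = FALSE)) {
    A <- P[sub, , drop = FALSE]
    M <- sweep(A[-1, , drop = FALSE], 2, A[1, ])
    qrm <- qr(t(M))
    if (qrm$rank < m - 1) next
    normal <- qr.Q(qrm, complete = TRUE)[, m]
    side <- as.vector(sweep(P[-sub, , drop = FALSE], 2, A[1, ]) %*% normal)
    if (all(side > 1e-10) || all(side < -1e-10)) {
      any_facet <- TRUE
      verts[sub] <- TRUE
      D <- sweep(A, 2, centre)
      vol <- vol + abs(det(D)) / factorial(m)
    }
  }
  if (!any_facet) return(list(volume = NA_real_, vertices = integer()))
  list(volume = vol, vertices = which(verts))
}

# Prim's O(S^2) minimum spanning tree; returns the edge list.
oracle_mst <- function(D) {
  S <- nrow(D)
  intree <- c(1); edges <- NULL
  while (length(intree) < S) {
    best <- c(NA, NA); bd <- Inf
    for (i in intree) for (j in setdiff(seq_len(S), intree)) {
      if (D[i, j] < bd) { bd <- D[i, j]; best <- c(i, j) }
    }
    edges <- rbind(edges, best)
    intree <- c(intree, best[2])
  }
  edges
}

oracle_feve <- function(P, w) {
  S <- nrow(P)
  if (S < 3) return(NA_real_)
  w <- w / sum(w)
  D <- as.matrix(dist(P))
  ed <- oracle_mst(D)
  ew <- apply(ed, 1, function(e) D[e[1], e[2]] / (w[e[1]] + w[e[2]]))
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

oracle_fdiv <- function(P, w) {
  w <- w / sum(w)
  h <- oracle_hull(P)
  if (is.na(h$volume)) return(NA_real_)
  G <- colMeans(P[h$vertices, , drop = FALSE])
  dG <- sqrt(colSums((t(P) - G)^2))
  dbar <- mean(dG)
  (sum(w * (dG - dbar)) + dbar) / (sum(w * abs(dG - dbar)) + dbar)
}

# ---- community-weighted-mean oracle ----------------------------------------

oracle_cwm <- function(counts, trait) {
  num <- 0; den <- 0; used <- 0; tot <- 0
  for (sp in names(counts)) {
    tot <- tot + counts[[sp]]
    tv <- trait[[sp]]
    if (!is.null(tv) && !is.na(tv) && counts[[sp]] > 0) {
      num <- num + tv * counts[[sp]]
      den <- den + counts[[sp]]
      used <- used + counts[[sp]]
    }
  }
  if (den == 0) list(cwm = NA_real_, coverage = NA_real_)
  else list(cwm = num / den, coverage = used / tot)
}

# random orthogonal matrix (Haar via QR)
random_rotation <- function(m) {
  qrd <- qr(matrix(rnorm(m * m), m))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))), m)
}
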