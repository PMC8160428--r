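# build a trait_space directly from a coordinate matrix
space_from_coords <- function(P) {
  if (is.null(rownames(P))) rownames(P) <- paste0("s", seq_len(nrow(P)))
  structure(list(species_ids = rownames(P), coordinates = P,
                 axes_used = ncol(P),
                 dropped_species = data.frame(species_id = character(),
                                              reason = character())),
            class = "trait_space")
}

equal_weights <- function(P) setNames(rep(1, nrow(P)), rownames(P))

test_that("FRic gives exact simple volumes and flags degeneracy", {
  tri <- space_from_coords(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  expect_equal(fric(tri, equal_weights(tri$coordinates)), 0.5)

  line <- space_from_coords(matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE))
  expect_true(is.na(fric(line, equal_weights(line$coordinates))))

  # too few points for the dimensionality
  two <- space_from_coords(matrix(rnorm(4), 2, 2))
  expect_true(is.na(fric(two, equal_weights(two$coordinates))))
})

test_that("FEve is 1 for evenly spaced, equally weighted collinear points", {
  for (S in c(3, 5, 8)) {
    P <- cbind(seq_len(S), 2 * seq_len(S))  # equally spaced on a line
    sp <- space_from_coords(P)
    expect_equal(feve(sp, equal_weights(sp$coordinates)), 1,
                 tolerance = 1e-12)
  }
  # one dominating branch drags FEve below 1, monotonically
  vals <- sapply(c(5, 20, 100), function(g) {
    P <- cbind(c(0, 1, 1 + g), c(0, 0, 0.01))
    feve(space_from_coords(P), setNames(rep(1, 3), paste0("s", 1:3)))
  })
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 1))
})

test_that("FDiv is 1 for equidistant species and small near the centroid", {
  theta <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- space_from_coords(cbind(cos(theta), sin(theta)))
  w <- setNames(runif(6, 0.5, 2), rownames(ring$coordinates))
  expect_equal(fdiv(ring, w), 1, tolerance = 1e-12)

  # abundance piled onto a species at the hull-vertex centroid
  P <- rbind(cbind(cos(theta), sin(theta)), c(0, 0))
  rownames(P) <- paste0("s", 1:7)
  sp <- space_from_coords(P)
  w <- setNames(c(rep(0.005, 6), 0.97), rownames(P))
  expect_lt(fdiv(sp, w), 0.5)
})

test_that("FD indices agree with brute-force oracles on random instances", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:100) {
    m <- sample(2:3, 1)
    S <- sample((m + 2):12, 1)
    P <- matrix(rnorm(S * m), S, m)
    rownames(P) <- paste0("s", seq_len(S))
    sp <- space_from_coords(P)
    w <- setNames(runif(S, 0.1, 1), rownames(P))

    h <- oracle_hull(P)
    expect_equal(fric(sp, w), h$volume, tolerance = 0.01)
    expect_equal(feve(sp, w), oracle_feve(P, w), tolerance = 1e-9)
    expect_equal(fdiv(sp, w), oracle_fdiv(P, w), tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("FRic is monotone under species addition and rotation-invariant", {
  set.seed(17)
  for (i in 1:10) {
    m <- sample(2:4, 1)
    P <- matrix(rnorm(20 * m), 20, m)
    rownames(P) <- paste0("s", 1:20)
    sp <- space_from_coords(P)
    sub <- sample(rownames(P), sample((m + 2):15, 1))
    w_all <- equal_weights(P)
    w_sub <- w_all[sub]
    f_all <- fric(sp, w_all)
    f_sub <- fric(sp, w_sub)
    if (!is.na(f_sub)) expect_lte(f_sub, f_all + 1e-9)

    R <- random_rotation(m)
    spr <- space_from_coords(P %*% R)
    expect_equal(fric(spr, w_all), f_all, tolerance = 1e-8)
  }
})

test_that("FEve and FDiv ignore the scale of the weight vector", {
  set.seed(23)
  P <- matrix(rnorm(18), 9, 2)
  rownames(P) <- paste0("s", 1:9)
  sp <- space_from_coords(P)
  w <- setNames(runif(9), rownames(P))
  expect_equal(feve(sp, w), feve(sp, w * 123), tolerance = 1e-12)
  expect_equal(fdiv(sp, w), fdiv(sp, w * 123), tolerance = 1e-12)
})

test_that("trait space drops incomplete species and standardizes", {
  cfg <- sim_config(n_species = 25, rng_seed = 13)
  study <- simulate_study(cfg)
  prof <- build_profiles(study$trials)
  prof$r_wc[3] <- NA
  sp <- build_trait_space(prof, study$quadrats)
  expect_false(prof$species_id[3] %in% sp$species_ids)
  expect_true(any(grepl("r_wc",
                        sp$dropped_species$reason[
                          sp$dropped_species$species_id ==
                            prof$species_id[3]])))
  expect_equal(unname(colMeans(sp$coordinates)),
               rep(0, ncol(sp$coordinates)), tolerance = 1e-10)

  # full-dimensional case: coordinates are the standardized traits
  expect_equal(sp$axes_used, min(7, min(table(paste(
    study$quadrats$block_id,
    study$quadrats$n_level)[study$quadrats$species_id %in%
                              sp$species_ids])) - 1))

  prof2 <- prof
  prof2$gp_5 <- 0.5  # constant column
  expect_error(build_trait_space(prof2, study$quadrats), "gp_5")

  # explicit reduced dimensionality via principal coordinates
  sp3 <- build_trait_space(prof, study$quadrats, m = 3)
  expect_equal(ncol(sp3$coordinates), 3)
  # PCoA of Euclidean distances preserves distances in the leading axes:
  # reduced-space distances never exceed trait-space distances
  d7 <- as.matrix(dist(sp$coordinates))
  d3 <- as.matrix(dist(sp3$coordinates[sp$species_ids, ]))
  expect_true(all(d3 <= d7 + 1e-8))
})

test_that("fd_all covers the design and detects trait filtering", {
  cfg <- sim_config(coupling = c(BTN = 3), noise_sd = 0, rng_seed = 41)
  study <- simulate_study(cfg)
  prof <- build_profiles(study$trials)
  sp <- build_trait_space(prof, study$quadrats)
  fd <- fd_all(sp, study$quadrats)
  expect_equal(nrow(fd), 20)
  expect_true(all(fd$feve >= 0 & fd$feve <= 1, na.rm = TRUE))
  expect_true(all(fd$fdiv >= 0 & fd$fdiv <= 1, na.rm = TRUE))
  # strong positive BTN filtering shrinks occupied trait space at high N
  expect_lt(mean(fd$fric[fd$n_level == "N3"], na.rm = TRUE),
            mean(fd$fric[fd$n_level == "N0"], na.rm = TRUE))
})
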