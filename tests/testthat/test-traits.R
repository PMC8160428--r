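one_cell_trials <- function(rep_days_counts, n_sown = 50) {
  rows <- list()
  for (r in seq_along(rep_days_counts)) {
    dc <- rep_days_counts[[r]]
    if (nrow(dc) == 0) dc <- data.frame(day = NA, count = NA)
    rows[[r]] <- data.frame(species_id = "sp", condition = "T15",
                            storage = "DRY_WARM", replicate = r,
                            n_sown = n_sown, day = dc$day, count = dc$count)
  }
  trials_from_df(do.call(rbind, rows))
}

test_that("germination percentage pools counts across replicates", {
  tr <- one_cell_trials(list(data.frame(day = c(2, 5), count = c(12, 8))))
  expect_equal(germination_percentage(tr), 0.40)

  tr3 <- one_cell_trials(list(data.frame(day = 1, count = 10),
                              data.frame(day = 1, count = 20),
                              data.frame(day = 1, count = 30)))
  expect_equal(germination_percentage(tr3), 0.40)
  expect_equal(germination_percentage(tr3, pooling = "mean"), 0.40)

  none <- one_cell_trials(list(data.frame(day = numeric(),
                                          count = numeric())))
  expect_equal(germination_percentage(none), 0)
})

test_that("germination rate is the day-weighted index in [0, 1]", {
  all_day1 <- one_cell_trials(list(data.frame(day = 1, count = 50)))
  expect_equal(germination_rate(all_day1), 1.0)

  two_days <- one_cell_trials(list(data.frame(day = c(1, 2),
                                              count = c(10, 10))))
  expect_equal(germination_rate(two_days), 0.30)

  none <- one_cell_trials(list(data.frame(day = numeric(),
                                          count = numeric())))
  expect_equal(germination_rate(none), 0)
})

test_that("response indices are normalized differences with NA at 0/0", {
  expect_equal(response_alternating(0.4, 0.4), 0)
  expect_equal(response_alternating(0.6, 0.2), 0.5)
  expect_true(is.na(response_alternating(0, 0)))
  expect_equal(response_wet_cold(0.8, 0), 1)
  expect_equal(response_wet_cold(0.3, 0.6), -1 / 3)
  # antisymmetry
  for (ab in list(c(0.2, 0.7), c(0.5, 0.1), c(0, 0.3))) {
    expect_equal(response_wet_cold(ab[1], ab[2]),
                 -response_wet_cold(ab[2], ab[1]))
  }
})

test_that("niche metrics match their definitions and bounds", {
  temps <- as.character(c(5, 10, 15, 20, 25))
  eq <- niche_metrics(setNames(rep(0.3, 5), temps))
  expect_equal(unname(eq$occupation), rep(1, 5))
  expect_equal(unname(eq$proportion_niche), rep(0.2, 5))
  expect_equal(eq$btn, 1)

  only15 <- niche_metrics(setNames(c(0, 0, 0.5, 0, 0), temps))
  expect_equal(unname(only15$occupation), c(0, 0, 1, 0, 0))
  expect_equal(unname(only15$proportion_niche), c(0, 0, 1, 0, 0))
  expect_equal(only15$btn, 0.2)  # lower bound 1/R with R = 5

  hump <- niche_metrics(setNames(c(0.2, 0.4, 0.8, 0.4, 0.2), temps))
  expect_equal(unname(hump$occupation), c(0.25, 0.5, 1, 0.5, 0.25))
  expect_equal(hump$btn, 0.5)
  expect_equal(unname(hump$proportion_niche), c(0.1, 0.2, 0.4, 0.2, 0.1))

  expect_error(niche_metrics(setNames(rep(0.1, 4), temps[1:4])),
               "exactly the temperatures")
})

test_that("niche metrics are scale-free and proportions sum to one", {
  temps <- as.character(c(5, 10, 15, 20, 25))
  set.seed(31)
  for (i in 1:25) {
    g <- runif(5)
    a <- niche_metrics(setNames(g, temps))
    b <- niche_metrics(setNames(g * runif(1, 0.1, 9), temps))
    expect_equal(a$btn, b$btn, tolerance = 1e-12)
    expect_equal(sum(a$proportion_niche), 1, tolerance = 1e-12)
    expect_true(a$btn >= 0.2 && a$btn <= 1)
    expect_equal(max(a$occupation), 1)
  }
})

test_that("profiles hit the all-germinate limit and zero-germination case", {
  cfg <- sim_config(n_species = 4, rng_seed = 2)
  pool <- draw_species_pool(cfg)
  pool$p_max <- 1 - 1e-12; pool$t_sd <- 1e9; pool$timing_hazard <- 1
  pool$alt_effect <- 0; pool$coldstrat_effect <- 0
  prof <- build_profiles(simulate_trials(pool, cfg))
  for (v in c(paste0("gp_", c(5, 10, 15, 20, 25)), "gp_alt",
              paste0("gr_", c(5, 10, 15, 20, 25)), "btn"))
    expect_equal(prof[[v]], rep(1, 4), info = v)

  pool$p_max <- 1e-12
  prof0 <- build_profiles(simulate_trials(pool, cfg))
  expect_true(all(is.na(prof0$btn)))
  expect_true(all(prof0$reason_niche == "no_germination"))
  expect_true(all(prof0$reason_r_alt == "no_germination"))
  expect_true(all(is.na(prof0$r_wc)))
})

test_that("profiles match an independent brute-force recomputation", {
  for (seed in c(101, 202)) {
    df <- random_trial_df(12, seed)
    prof <- build_profiles(trials_from_df(df))
    orac <- oracle_profiles(df)
    orac <- orac[match(prof$species_id, orac$species_id), ]
    for (v in setdiff(names(orac), "species_id")) {
      expect_equal(is.na(prof[[v]]), is.na(orac[[v]]), info = v)
      ok <- !is.na(orac[[v]])
      expect_equal(prof[[v]][ok], orac[[v]][ok], tolerance = 1e-14,
                   info = v)
    }
  }
})

test_that("GR never exceeds GP and both respond monotonically", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(1:4, 1)
    days <- sample(1:30, k)
    cnt <- as.vector(rmultinom(1, sample(5:40, 1), rep(1, k)))
    tr <- one_cell_trials(list(data.frame(day = days, count = cnt)[cnt > 0,
                                                                   ]))
    gp <- germination_percentage(tr)
    gr <- germination_rate(tr)
    expect_lte(gr, gp + 1e-14)

    # adding germinated seeds on a new day never decreases GP
    extra <- data.frame(day = c(days, 31), count = c(cnt, 3))
    tr2 <- one_cell_trials(list(extra[extra$count > 0, ]))
    expect_gte(germination_percentage(tr2), gp)

    # moving an event one day earlier never decreases GR
    j <- which.max(days)
    if (days[j] > 1 && !((days[j] - 1) %in% days)) {
      days2 <- days; days2[j] <- days[j] - 1
      tr3 <- one_cell_trials(list(data.frame(day = days2,
                                             count = cnt)[cnt > 0, ]))
      expect_gte(germination_rate(tr3), gr)
    }
  }
})
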