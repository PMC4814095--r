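test_that("rain intensity is precipitation per rain day", {
  g <- tiny_grid(1, 3)
  ri <- rain_intensity(raster_layer(g, c(365, 600, 0)),
                       raster_layer(g, c(365, 50, 0)))
  expect_equal(ri$values, c(1, 12, 0))
  expect_error(rain_intensity(raster_layer(g, c(10, 0, 0)),
                              raster_layer(g, c(0, 1, 1))),
               "cell\\(s\\) 1")
  set.seed(25)
  g2 <- tiny_grid(6, 6)
  p <- runif(36, 100, 900); d <- runif(36, 20, 200)
  got <- rain_intensity(raster_layer(g2, p), raster_layer(g2, d))$values
  oracle <- vapply(1:36, function(i) p[i] / d[i], numeric(1))
  expect_equal(got, oracle)
})

make_access_layers <- function(g, pop, road, dl, dm) {
  list(population_density = raster_layer(g, pop),
       road_density = raster_layer(g, road),
       dist_large_cities = raster_layer(g, dl),
       dist_medium_cities = raster_layer(g, dm))
}

test_that("bias-model search enumerates all 16 subsets with correct BIC", {
  set.seed(26)
  g <- tiny_grid(20, 25)
  n <- 500
  pop <- rexp(n); road <- runif(n); dl <- runif(n, 0, 20); dm <- runif(n, 0, 10)
  y_cells <- which(rbinom(n, 1, plogis(-2 + 1.2 * scale(pop)[, 1])) == 1)
  bm <- select_bias_model(y_cells, g, make_access_layers(g, pop, road, dl, dm))
  expect_equal(bm$n_candidates, 16)
  expect_equal(nrow(bm$ranking), 16)
  # BIC identity -2 logLik + k ln(n), recomputed independently
  expect_equal(bm$ranking$bic,
               -2 * bm$ranking$loglik + bm$ranking$k * log(n),
               tolerance = 1e-6)
  expect_equal(min(bm$ranking$bic), bm$bic)
})

test_that("bias-model selection is consistent under strong and null signals", {
  g <- tiny_grid(40, 50)
  n <- 2000
  with_pop <- 0
  for (seed in 1:20) {
    set.seed(300 + seed)
    pop <- rexp(n); road <- runif(n); dl <- runif(n, 0, 20); dm <- runif(n, 0, 10)
    y <- rbinom(n, 1, plogis(-1.5 + 1.5 * scale(pop)[, 1]))
    bm <- select_bias_model(which(y == 1), g,
                            make_access_layers(g, pop, road, dl, dm))
    if ("population_density" %in% bm$included_predictors)
      with_pop <- with_pop + 1
  }
  expect_gte(with_pop, 19)  # the true driver selected in >= 95% of replicates
  null_intercept <- 0
  for (seed in 1:20) {
    set.seed(400 + seed)
    pop <- rexp(n); road <- runif(n); dl <- runif(n, 0, 20); dm <- runif(n, 0, 10)
    y <- rbinom(n, 1, 0.12)
    bm <- select_bias_model(which(y == 1), g,
                            make_access_layers(g, pop, road, dl, dm))
    if (length(bm$included_predictors) == 0) null_intercept <- null_intercept + 1
  }
  expect_gt(null_intercept, 10)  # intercept-only wins the majority under the null
})

test_that("sampling weights are reciprocal probabilities with a floor", {
  set.seed(27)
  g <- tiny_grid(10, 10)
  slope <- raster_layer(g, runif(100, 0, 15))
  ri <- raster_layer(g, runif(100, 1, 12))
  bare <- raster_layer(g, runif(100))
  cells <- sample(100, 30)
  # a flat sampling field reproduces the unweighted fit exactly
  m_unw <- quiet(fit_discovery(cells, g, slope, ri, bare))
  m_flat <- quiet(fit_discovery(cells, g, slope, ri, bare,
                                sampling_prob = raster_layer(g, rep(0.5, 100))))
  expect_equal(m_flat$coefficients, m_unw$coefficients)
  expect_equal(m_flat$weights, rep(1, 100))
  # reciprocal structure: p = 0.25 cells weigh twice p = 0.5 cells
  sp <- raster_layer(g, rep(c(0.5, 0.25), 50))
  m_w <- quiet(fit_discovery(cells, g, slope, ri, bare, sampling_prob = sp))
  expect_equal(m_w$weights[2] / m_w$weights[1], 2)
  expect_equal(mean(m_w$weights), 1)
  # the floor bounds any single weight
  tiny <- raster_layer(g, c(1e-6, rep(0.5, 99)))
  m_t <- quiet(fit_discovery(cells, g, slope, ri, bare, sampling_prob = tiny,
                             epsilon = 0.01))
  expect_lte(max(m_t$weights), (1 / 0.01) / mean(1 / pmax(tiny$values, 0.01)))
  expect_error(fit_discovery(cells, g, slope, ri, bare, epsilon = 0),
               "epsilon")
})

test_that("discovery predictions ignore the bias weights", {
  set.seed(28)
  g <- tiny_grid(10, 10)
  slope <- raster_layer(g, runif(100, 0, 15))
  ri <- raster_layer(g, runif(100, 1, 12))
  bare <- raster_layer(g, runif(100))
  cells <- sample(100, 30)
  m <- quiet(fit_discovery(cells, g, slope, ri, bare))
  s1 <- predict_discovery(m, slope, ri, bare)
  # hand-check the standardized-slope log-odds contrast
  g2 <- tiny_grid(1, 2)
  sl2 <- raster_layer(g2, m$center["slope"] + m$scale["slope"] * c(0, 1))
  s2 <- predict_discovery(m, sl2,
                          raster_layer(g2, rep(m$center["rain_intensity"], 2)),
                          raster_layer(g2, rep(m$center["bare_soil"], 2)))
  expect_equal(qlogis(s2$raw)[2] - qlogis(s2$raw)[1],
               unname(m$coefficients["slope"]), tolerance = 1e-9)
  # all-zero coefficients give a flat surface
  m0 <- m; m0$coefficients[] <- 0
  s0 <- predict_discovery(m0, slope, ri, bare)
  expect_equal(unique(s0$raw), 0.5)
  expect_equal(unique(s0$values), 0.5)  # flat rank surface
})

test_that("reciprocal weighting reduces slope bias under effort saturation", {
  # Fossil presence saturates where prospecting effort is high (near cities)
  # and reflects true discoverability elsewhere; accessibility correlates
  # negatively with slope. Weighting by inverse sampling probability should
  # shrink the resulting bias in the slope coefficient.
  beta_true <- 0.5
  reps <- 60
  bias_unw <- bias_wt <- numeric(reps)
  g <- tiny_grid(50, 60)   # 3000 cells
  for (r in seq_len(reps)) {
    set.seed(500 + r)
    n <- 3000
    slope <- rnorm(n); rain <- rnorm(n); bare <- rnorm(n)
    acc <- -0.8 * slope + rnorm(n, 0, 0.6)
    effort <- 1 + 15 * plogis(2 * (acc - 0.5))
    lam <- -log(1 - plogis(-1.5 + beta_true * slope + 0.3 * rain + 0.3 * bare))
    y <- rbinom(n, 1, 1 - exp(-lam * effort))
    cells <- which(y == 1)
    sl <- raster_layer(g, slope); ri <- raster_layer(g, rain)
    bs <- raster_layer(g, bare)
    samp <- raster_layer(g, plogis(-0.2 + 1.5 * acc))
    mu <- quiet(fit_discovery(cells, g, sl, ri, bs))
    mw <- quiet(fit_discovery(cells, g, sl, ri, bs, sampling_prob = samp))
    bias_unw[r] <- abs(mu$coefficients_raw["slope"] - beta_true)
    bias_wt[r] <- abs(mw$coefficients_raw["slope"] - beta_true)
  }
  expect_lt(mean(bias_wt), mean(bias_unw))
})
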