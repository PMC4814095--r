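test_that("pseudo-absence eligibility follows the percentile-band rule", {
  set.seed(6)
  pres <- clim_df(temperature = seq(10, 20, length.out = 100),
                  precipitation = rep(500, 100))
  # candidate outside the temperature band is eligible, inside is not
  cand <- clim_df(temperature = c(25, 15), precipitation = c(500, 500),
                  cell = c(101, 102))
  got <- sample_pseudo_absences(pres, cand, ratio = 10, seed = 1)
  expect_equal(got$cell, 101)
  expect_error(sample_pseudo_absences(pres[0, ], cand), "no presences")
  inband <- clim_df(temperature = 15, precipitation = 500, cell = 103)
  expect_error(sample_pseudo_absences(pres, inband), "no eligible")
})

test_that("pseudo-absence counts follow the ten-to-one rule and its cap", {
  set.seed(7)
  make <- function(n_pres, n_cand) {
    pres <- clim_df(temperature = rnorm(n_pres, 20, 1),
                    precipitation = rnorm(n_pres, 500, 20))
    cand <- clim_df(temperature = rnorm(n_cand, 40, 1),  # far outside envelope
                    precipitation = rnorm(n_cand, 500, 20),
                    cell = 1000 + seq_len(n_cand))
    list(pres = pres, cand = cand)
  }
  d <- make(23, 500)
  expect_equal(nrow(sample_pseudo_absences(d$pres, d$cand, 10, seed = 2)), 230)
  # with fewer eligible candidates than the target, all are returned
  d2 <- make(148, 1312)
  expect_equal(nrow(sample_pseudo_absences(d2$pres, d2$cand, 10, seed = 2)), 1312)
  # draws are reproducible given the seed and disjoint from ineligibles
  a <- sample_pseudo_absences(d$pres, d$cand, 10, seed = 9)
  b <- sample_pseudo_absences(d$pres, d$cand, 10, seed = 9)
  expect_identical(a, b)
})

test_that("bioclim scoring matches its definition and a brute-force oracle", {
  pres <- clim_df(temperature = 1:100, precipitation = rep(c(400, 600), 50))
  fit <- fit_bioclim(pres)
  med <- data.frame(temperature = 50, precipitation = 500)
  expect_equal(predict(fit, med), 1)
  out <- data.frame(temperature = 150, precipitation = 500)
  expect_equal(predict(fit, out), 0)
  q25 <- data.frame(temperature = 25, precipitation = 500)
  expect_equal(predict(fit, q25), 0.5)
  set.seed(8)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    p <- clim_df(temperature = sample(0:40, n, TRUE),
                 precipitation = sample(100:900, n, TRUE))
    f <- fit_bioclim(p)
    pts <- cbind(temperature = runif(20, -5, 45),
                 precipitation = runif(20, 0, 1000))
    expect_equal(predict(f, pts), bioclim_oracle(clim_matrix_test(p), pts),
                 tolerance = 1e-12)
  }
  # constant variable: score 1 at the value, 0 elsewhere
  pc <- clim_df(temperature = rep(20, 4), precipitation = c(1, 2, 4, 5))
  fc <- fit_bioclim(pc)
  expect_equal(predict(fc, data.frame(temperature = 20, precipitation = 3)), 1)
  expect_equal(predict(fc, data.frame(temperature = 21, precipitation = 3)), 0)
})

test_that("the quadratic GLM recovers simulated coefficients", {
  set.seed(9)
  n <- 5000
  t <- runif(n, 0, 30); p <- runif(n, 0, 1000)
  beta <- c(-2, 0.4, 0.004, -0.012, -0.000004)
  eta <- beta[1] + beta[2] * t + beta[3] * p + beta[4] * t^2 + beta[5] * p^2
  y <- rbinom(n, 1, plogis(eta))
  pres <- clim_df(temperature = t[y == 1], precipitation = p[y == 1])
  abs_ <- clim_df(temperature = t[y == 0], precipitation = p[y == 0])
  fit <- fit_glm(pres, abs_)
  co <- fit$parameters$coef
  ref <- glm(y ~ t + p + I(t^2) + I(p^2), family = binomial)
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(unname(co) - beta) < 3 * se))
  # duplicating every row leaves the MLE unchanged
  fit2 <- fit_glm(rbind(pres, pres), rbind(abs_, abs_))
  expect_equal(fit2$parameters$coef, co, tolerance = 1e-6)
})

test_that("a label-independent GLM estimates a flat response", {
  set.seed(10)
  n <- 5000
  t <- rnorm(n, 20, 5); p <- rnorm(n, 500, 100)
  y <- rbinom(n, 1, 0.2)
  fit <- fit_glm(clim_df(temperature = t[y == 1], precipitation = p[y == 1]),
                 clim_df(temperature = t[y == 0], precipitation = p[y == 0]))
  sc <- predict(fit, data.frame(temperature = c(10, 20, 30),
                                precipitation = c(300, 500, 700)))
  expect_true(all(abs(sc - 0.2) < 0.05))
})

test_that("the MaxEnt-style model behaves across its penalty range", {
  set.seed(11)
  # heavy regularization flattens the surface
  pres <- clim_df(temperature = rnorm(50, 25), precipitation = rnorm(50, 700, 50))
  bg <- clim_df(temperature = rnorm(500, 15, 5), precipitation = rnorm(500, 500, 150))
  flat <- fit_maxent_like(pres, bg, regularization = 1e6)
  expect_equal(max(abs(as.numeric(flat$parameters$fit$beta))), 0)
  # single-variable separation: high held-out AUC
  t1 <- rnorm(1000, 28, 1); t0 <- rnorm(1000, 12, 1)
  fit <- fit_maxent_like(
    clim_df(temperature = t1[1:800], precipitation = rnorm(800, 500, 50)),
    clim_df(temperature = t0[1:800], precipitation = rnorm(800, 500, 50)))
  sp <- predict(fit, data.frame(temperature = t1[801:1000],
                                precipitation = rnorm(200, 500, 50)))
  sa <- predict(fit, data.frame(temperature = t0[801:1000],
                                precipitation = rnorm(200, 500, 50)))
  expect_gt(compute_auc(sp, sa), 0.9)
  # permuted labels: held-out AUC near one half
  all_t <- rnorm(2000, 20, 4); all_p <- rnorm(2000, 500, 100)
  lab <- sample(rep(0:1, 1000))
  fitp <- fit_maxent_like(
    clim_df(temperature = all_t[lab == 1][1:800],
            precipitation = all_p[lab == 1][1:800]),
    clim_df(temperature = all_t[lab == 0][1:800],
            precipitation = all_p[lab == 0][1:800]))
  spp <- predict(fitp, data.frame(temperature = all_t[lab == 1][801:1000],
                                  precipitation = all_p[lab == 1][801:1000]))
  sap <- predict(fitp, data.frame(temperature = all_t[lab == 0][801:1000],
                                  precipitation = all_p[lab == 0][801:1000]))
  expect_lt(abs(compute_auc(spp, sap) - 0.5), 0.1)
})

test_that("TSS and AUC match their printed definitions", {
  expect_equal(compute_tss(10, 0, 10, 0), 1)
  expect_equal(compute_tss(8, 2, 90, 10), 0.7)
  expect_equal(compute_tss(5, 5, 50, 50), 0)
  expect_error(compute_tss(0, 0, 5, 5), "presences")
  expect_equal(compute_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(compute_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
})

test_that("cross-validation counts rounds and nails separable data", {
  set.seed(12)
  pres <- clim_df(temperature = rnorm(40, 28, 0.5),
                  precipitation = rnorm(40, 800, 10),
                  cell = 1:40, slice_age = rep(c(10, 20, 30, 40), 10))
  pa <- clim_df(temperature = rnorm(200, 10, 0.5),
                precipitation = rnorm(200, 300, 10),
                cell = 101:300, slice_age = rep(c(10, 20, 30, 40), 50))
  ds <- occurrence_dataset("T", pres, pa)
  sk <- quiet(cross_validate(ds, "bioclim", "temporal_only"))
  expect_equal(length(unique(sk$round)), 4)  # one round per fossil slice
  sk2 <- quiet(cross_validate(ds, "glm", "spatio_temporal", rounds = 2, seed = 3))
  expect_equal(median(sk2$tss), 1)
  expect_equal(median(sk2$auc), 1)
  expect_equal(nrow(sk2), 10)  # 2 rounds x 5 folds, none skipped
  # identical seed reproduces the folds exactly
  sk3 <- quiet(cross_validate(ds, "glm", "spatio_temporal", rounds = 2, seed = 3))
  expect_identical(sk2, sk3)
})

test_that("ensemble projection weights, bounds and extrapolation flags", {
  g <- tiny_grid(2, 2)
  # hand-checkable weighted mean via constant-scoring stubs
  stub <- function(vals, w) {
    structure(list(method = "stub", vals = vals, tss_weight = w,
                   training_ranges = rbind(min = c(temperature = 0, precipitation = 0),
                                           max = c(temperature = 40, precipitation = 1000))),
              class = c("stub_fit", "envelope_fit"))
  }
  registerS3method("predict", "stub_fit",
                   function(object, newdata, ...) rep(object$vals, nrow(newdata)),
                   envir = asNamespace("stats"))
  sl <- const_slice(10, g, 20, 500)
  fits <- list(stub(1.0, 0.9), stub(0.5, 0.6), stub(0.0, 0.3))
  surf <- project_ensemble(fits, sl)
  expect_equal(unique(surf$values), (0.9 * 1 + 0.6 * 0.5 + 0.3 * 0) / 1.8,
               tolerance = 1e-12)
  # a zero-weight model is excluded; equal weights give the simple mean
  surf2 <- project_ensemble(list(stub(1, 0.5), stub(0, 0.5), stub(0.4, 0)), sl)
  expect_equal(unique(surf2$values), 0.5)
  expect_error(project_ensemble(list(stub(1, 0), stub(0, -0.2)), sl),
               "non-positive")
  # climates outside the pooled training range are flagged
  hot <- const_slice(5, g, 90, 500)
  expect_true(all(project_ensemble(fits, hot)$extrapolation))
  expect_false(any(surf$extrapolation))
})

test_that("multi-temporal averaging includes only the taxon's lifetime", {
  g <- tiny_grid(1, 3)
  mk <- function(age, vals) {
    s <- paleofind:::new_surface(g, vals, slice_age = age)
    s
  }
  s10 <- mk(10, c(0.9, 0.1, 0.5)); s20 <- mk(20, c(0.2, 0.2, 0.8))
  s30 <- mk(30, c(0.8, 0.4, 0.8))
  # youngest fossil at 20 ka: the 10-ka slice is excluded
  avg <- multi_temporal_average(list(s10, s20, s30), 20)
  raw <- (c(0.2, 0.2, 0.8) + c(0.8, 0.4, 0.8)) / 2  # 0.5, 0.3, 0.8
  expect_equal(order(avg$values), order(raw))
  expect_equal(avg$values, c(0.5, 0, 1))  # rank-rescaled
  # constant input stays constant (rank 0.5 everywhere)
  cst <- multi_temporal_average(list(mk(10, rep(0.4, 3)), mk(20, rep(0.4, 3))), 0)
  expect_equal(cst$values, rep(0.5, 3))
  expect_error(multi_temporal_average(list(), 0), "no surfaces")
})

test_that("envelope recovery: fitted surface tracks true suitability", {
  set.seed(13)
  # presences drawn from a known Gaussian envelope; background uniform
  n_bg <- 3000
  t_bg <- runif(n_bg, 0, 35); p_bg <- runif(n_bg, 0, 1200)
  true_suit <- function(t, p) exp(-0.5 * ((t - 22) / 3)^2 - 0.5 * ((p - 700) / 150)^2)
  keep <- runif(n_bg) < true_suit(t_bg, p_bg)
  pres <- clim_df(temperature = t_bg[keep][1:120],
                  precipitation = p_bg[keep][1:120], cell = 1:120)
  cand <- clim_df(temperature = runif(2000, 0, 35),
                  precipitation = runif(2000, 0, 1200), cell = 2000 + 1:2000)
  pa <- sample_pseudo_absences(pres, cand, ratio = 10, seed = 4)
  ds <- occurrence_dataset("T", pres, pa)
  grid_t <- runif(800, 0, 35); grid_p <- runif(800, 0, 1200)
  pts <- data.frame(temperature = grid_t, precipitation = grid_p)
  for (m in c("bioclim", "glm", "maxent_like")) {
    fit <- quiet(paleofind:::fit_envelope_method(m, ds$presences, ds$pseudo_absences))
    rho <- cor(predict(fit, pts), true_suit(grid_t, grid_p), method = "spearman")
    expect_gt(rho, 0.7)
  }
})
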