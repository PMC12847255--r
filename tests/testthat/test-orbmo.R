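test_that("Circle map variants evaluate to their closed-form values", {
  expect_equal(circle_map_step(0.5, "standard"), 0.7, tolerance = 1e-12)
  expect_equal(circle_map_step(0, "improved"), 0.3, tolerance = 1e-12)
  expect_equal(circle_map_step(0.5, "improved"), 0.739161,
               tolerance = 1e-5)
  ## mod keeps every iterate in [0, 1)
  set.seed(1)
  x <- runif(100)
  for (v in c("standard", "improved")) {
    y <- circle_map_step(x, v)
    expect_true(all(y >= 0 & y < 1))
  }
})

test_that("chaotic initialization is in-bounds, seeded and more uniform when improved", {
  sp <- search_space(c(10, 3, 2), c(300, 30, 20))
  p1 <- init_population_circle(30, sp, "improved", seed = 4)
  p2 <- init_population_circle(30, sp, "improved", seed = 4)
  expect_identical(p1, p2)
  expect_true(all(sweep(p1, 2, sp$lb, ">=")))
  expect_true(all(sweep(p1, 2, sp$ub, "<=")))
  ## chi-square against uniform, 20 bins, 1e4 iterates
  chisq20 <- function(v) {
    o <- tabulate(pmin(floor(v * 20) + 1, 20), 20)
    sum((o - length(v) / 20)^2 / (length(v) / 20))
  }
  iterate <- function(variant, x0) {
    out <- numeric(1e4); x <- x0
    for (i in seq_len(1e4)) { x <- circle_map_step(x, variant); out[i] <- x }
    out
  }
  set.seed(2); x0 <- runif(1)
  expect_lt(chisq20(iterate("improved", x0)),
            chisq20(iterate("standard", x0)))
})

test_that("golden-sine update satisfies its fixed-point identities", {
  x <- c(1, 2, 3); xf <- c(4, 5, 6)
  expect_equal(golden_sine_update(x, xf, r = 0, theta = 1), x)
  phi <- (sqrt(5) - 1) / 2
  expect_equal(golden_sine_update(phi * xf, xf, r = 0.7, theta = 2),
               phi * xf)
  expect_equal(golden_sine_update(0, 1, r = 1, theta = pi / 2),
               0.6180339887, tolerance = 1e-9)
})

test_that("Mantegna Levy steps have the right scale and heavy tail", {
  expect_equal(levy_sigma(1.5), 0.6966, tolerance = 1e-3 / 0.6966)
  expect_error(levy_sigma(2.5), "lam")
  set.seed(3)
  s1 <- levy_step(1.5, 10)
  set.seed(3)
  s2 <- levy_step(1.5, 10)
  expect_identical(s1, s2)
  set.seed(4)
  draws <- abs(levy_step(1.5, 1e5))
  expect_gt(quantile(draws, 0.999), 10 * median(draws))
})

test_that("the hybrid update reduces to golden-sine at alpha zero", {
  x <- c(0.5, -1); xf <- c(2, 2)
  expect_equal(gs_lf_update(x, xf, alpha = 0, r = 0.3, theta = 1),
               golden_sine_update(x, xf, r = 0.3, theta = 1))
  expect_equal(gs_lf_update(x, xf, alpha = 0, r = 0, theta = 1), x)
  ## alpha > 0: equals GS plus alpha times the same seeded Levy vector
  set.seed(6)
  got <- gs_lf_update(x, xf, alpha = 0.01, lam = 1.5, r = 0.3, theta = 1)
  set.seed(6)
  lv <- levy_step(1.5, 2)
  expect_equal(got, golden_sine_update(x, xf, r = 0.3, theta = 1) +
                 0.01 * lv)
})

test_that("Metropolis acceptance matches its closed form and frozen limit", {
  expect_equal(sa_accept_prob(0, 10), 1)
  expect_equal(sa_accept_prob(-5, 10), 1)
  expect_equal(sa_accept_prob(10, 10), exp(-1), tolerance = 1e-6)
  expect_equal(sa_accept_prob(5, 0), 0)
  expect_equal(sa_accept_prob(-5, 0), 1)
})

test_that("temperature schedules hit their endpoints", {
  expect_equal(anneal_temperature(0, 100, t0 = 100, schedule = "linear"),
               100)
  expect_equal(anneal_temperature(100, 100, t0 = 100,
                                  schedule = "linear"), 0)
  expect_equal(anneal_temperature(0, 100, t0 = 100, beta = 0.01,
                                  schedule = "adaptive"), 100)
  expect_equal(anneal_temperature(100, 100, t0 = 100, beta = 0.01,
                                  schedule = "adaptive"), 36.7879,
               tolerance = 1e-3 / 36.7879)
})

test_that("annealing perturbation scales with temperature and stays in bounds", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  best <- c(0, 1, -2)
  expect_equal(asa_perturb_best(best, 0, 100, sp), best)
  set.seed(8)
  for (i in 1:1000) {
    cand <- asa_perturb_best(best, 50, 100, sp)
    expect_true(all(cand >= sp$lb & cand <= sp$ub))
  }
  ## folded-normal mean of the displacement at T = T0
  sp1 <- search_space(-1e6, 1e6)  # wide box: no clipping
  set.seed(9)
  disp <- replicate(1e5, asa_perturb_best(0, 100, 100, sp1) - 0)
  expect_equal(mean(abs(disp)), 0.1 * 2e6 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("optimizer history is elitist, deterministic and in-bounds", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  sphere <- function(x) sum(x^2)
  r1 <- orbmo_optimize(sphere, sp, n = 15, t_max = 40, seed = 11)
  r2 <- orbmo_optimize(sphere, sp, n = 15, t_max = 40, seed = 11)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 0))
  expect_true(all(r1$best >= sp$lb & r1$best <= sp$ub))
  expect_error(orbmo_optimize(sphere, sp, n = 1, t_max = 1), "budget")
})

test_that("a non-finite objective value is treated as +Inf with a warning", {
  sp <- search_space(-1, 1)
  bad <- function(x) if (abs(x) < 0.5) NaN else x^2
  w <- capture_warnings(res <- orbmo_optimize(bad, sp, n = 5, t_max = 5,
                                              seed = 2))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res$best_fitness))
})

test_that("all eight strategy combinations run and keep elitism", {
  sp <- search_space(rep(-5, 2), rep(5, 2))
  ras <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  tab <- run_ablation(ras, sp, n = 10, t_max = 15, seeds = 1:2)
  expect_equal(nrow(tab), 8)
  expect_true(all(is.finite(tab$median_best)))
  for (circle in c(FALSE, TRUE)) for (gss in c(FALSE, TRUE))
    for (asa in c(FALSE, TRUE)) {
      cfg <- orbmo_config(use_circle_init = circle, use_gss = gss,
                          use_asa = asa)
      r <- orbmo_optimize(ras, sp, n = 10, t_max = 15, cfg = cfg,
                          seed = 3)
      expect_true(all(diff(r$history) <= 0))
    }
})

test_that("worse annealing candidates are accepted at the Metropolis rate", {
  set.seed(13)
  accepted <- mean(runif(1e4) < sa_accept_prob(7, 7))
  expect_equal(accepted, exp(-1), tolerance = 0.03 / exp(-1))
})
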