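make_grid_set <- function(n = 4, step = 1) {
  wl <- seq(350, 2500, by = step)
  set.seed(99)
  spectrum_set(wl, matrix(runif(n * length(wl), 0.2, 0.8), n),
               labels = rep(c("a", "b"), length.out = n))
}

test_that("cropping keeps inclusive endpoints and preserves samples", {
  s <- make_grid_set()
  expect_length(s$wavelengths, 2151)
  cr <- crop_range(s, 400, 2400)
  expect_length(cr$wavelengths, 2001)
  expect_equal(nrow(cr$reflect), nrow(s$reflect))
  expect_identical(cr$labels, s$labels)
  ## identity crop
  same <- crop_range(s, 350, 2500)
  expect_equal(same$reflect, s$reflect)
  expect_error(crop_range(s, 3000, 4000), "overlap")
  expect_error(crop_range(s, 500, 400), "lo_nm")
})

test_that("Savitzky-Golay reproduces low-order polynomials and smooths noise", {
  wl <- seq_len(200)
  poly_row <- 2 + 0.03 * wl - 1e-4 * wl^2
  s <- spectrum_set(wl, rbind(poly_row, rep(0.5, 200)))
  sm <- sg_smooth(s, window = 11, polyorder = 2)
  expect_equal(sm$reflect[1, ], s$reflect[1, ], tolerance = 1e-8)
  expect_equal(sm$reflect[2, ], s$reflect[2, ], tolerance = 1e-10)
  ## seeded noisy sine: smoothing must reduce residual variance
  set.seed(7)
  clean <- sin(wl / 15)
  noisy <- clean + rnorm(200, 0, 0.05)
  sm2 <- sg_smooth(spectrum_set(wl, rbind(noisy)), 21, 3)
  expect_lt(var(sm2$reflect[1, ] - clean), var(noisy - clean))
  expect_error(sg_smooth(spectrum_set(1:10, matrix(1, 1, 10)),
                         window = 11), "smaller")
  expect_error(sg_smooth(s, window = 10), "odd")
})

test_that("MSC inverts the gain/offset scatter model exactly", {
  wl <- seq_len(120)
  ref <- 0.5 + 0.2 * sin(wl / 9)
  s <- spectrum_set(wl, rbind(ref, 2 * ref + 3, 0.5 * ref - 1))
  out <- msc(s, reference = ref)
  expect_equal(out$reflect[1, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(out$reflect[2, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(out$reflect[3, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MSC regression coefficients match the normal-equations oracle", {
  set.seed(11)
  wl <- seq_len(80)
  ref <- colMeans(matrix(runif(5 * 80), 5))
  X <- matrix(runif(5 * 80), 5)
  s <- spectrum_set(wl, X)
  out <- msc(s, reference = ref)
  for (i in 1:5) {
    fit <- lm(X[i, ] ~ ref)     # independent least-squares oracle
    a <- coef(fit)[1]; b <- coef(fit)[2]
    expect_equal(out$reflect[i, ], (X[i, ] - a) / b, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  ## refit check: corrected rows regress on ref with slope 1, intercept 0
  for (i in 1:5) {
    fit <- lm(out$reflect[i, ] ~ ref)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-8)
  }
})

test_that("near-zero MSC slope leaves the row unchanged with a warning", {
  wl <- seq_len(50)
  ref <- 0.3 + 0.1 * sin(wl / 5)
  flat <- rep(0.4, 50)
  s <- spectrum_set(wl, rbind(ref, flat))
  expect_warning(out <- msc(s, reference = ref), "near-zero slope")
  expect_equal(out$reflect[2, ], flat, ignore_attr = TRUE)
})

test_that("preprocessing dispatch matches its components", {
  spec <- fixture_spec("easy", wl_step = 10)
  s <- fixture_spectra(spec, 5, seed = 3)
  expect_equal(preprocess_spectra(s, "SG")$reflect,
               sg_smooth(s)$reflect)
  expect_equal(preprocess_spectra(s, "SG_MSC")$reflect,
               msc(sg_smooth(s))$reflect)
  expect_equal(preprocess_spectra(s, "MSC")$reflect, msc(s)$reflect)
  expect_error(preprocess_spectra(s, "SNV"))
  ## shape and label alignment preserved by every method
  for (m in c("SG", "MSC", "SG_MSC")) {
    out <- preprocess_spectra(s, m)
    expect_equal(dim(out$reflect), dim(s$reflect))
    expect_identical(out$labels, s$labels)
  }
})

test_that("spectra CSV round-trips through write and read", {
  spec <- fixture_spec("easy", wl_step = 50)
  s <- fixture_spectra(spec, 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  back <- read_spectra_csv(path)
  expect_equal(back$wavelengths, s$wavelengths)
  expect_equal(back$reflect, s$reflect, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(s$labels))
})
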