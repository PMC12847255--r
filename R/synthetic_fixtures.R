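## Synthetic fixtures with known ground truth: multi-seed board images
## (ellipse-like seeds on a dark background, class-dependent size and
## texture) and reflectance spectra (class-dependent Gaussian absorption
## features plus multiplicative/additive scatter and white noise). The
## scatter model is exactly the generative form MSC assumes, so scatter
## correction is testable by construction.

#' Fixture specification
#'
#' Defines the study conditions the generators emulate: four seed
#' classes, 65 samples per class (260 in total, split 7:3), board images
#' of ellipse-like seeds, and reflectance on a 350-2500 nm grid with
#' two shared water-absorption bands plus three class-informative bands.
#' The `easy`, `medium` and `null` presets scale the between-class
#' separations (null makes all classes identical).
#'
#' @param preset `"easy"`, `"medium"` or `"null"`.
#' @param n_classes number of classes (default 4).
#' @param samples_per_class spectra/seeds per class (default 65).
#' @param seeds_per_image seeds placed on one board image.
#' @param image_size `c(H, W)` in px.
#' @param wl_step wavelength grid step in nm (default 1 nm over
#'   350-2500 nm).
#' @param gain_sd,offset_sd multiplicative/additive scatter SDs.
#' @param noise_sd white-noise SD on reflectance.
#' @param informative_nm centers (nm) of the class-informative
#'   absorption bands, within 400-2400 nm.
#' @return a `fixture_spec` list; `informative_nm` holds the planted
#'   class-informative band centers.
#' @export
fixture_spec <- function(preset = c("easy", "medium", "null"),
                         n_classes = 4, samples_per_class = 65,
                         seeds_per_image = 13,
                         image_size = c(400, 400), wl_step = 1,
                         gain_sd = 0.08, offset_sd = 0.03,
                         noise_sd = 0.004,
                         informative_nm = c(670, 1100, 1670)) {
  preset <- match.arg(preset)
  stopifnot(n_classes >= 2)
  cls <- seq_len(n_classes)
  sep <- switch(preset, easy = 1, medium = 0.4, null = 0)
  ## shape: per-class ellipse semi-axes (px); null collapses to one shape
  base_axes <- cbind(a = c(24, 28, 33, 19), b = c(20, 14, 11, 18))
  if (n_classes > 4)
    base_axes <- base_axes[rep(1:4, length.out = n_classes), ]
  base_axes <- base_axes[cls, , drop = FALSE]
  mean_axes <- matrix(c(24, 18), n_classes, 2, byrow = TRUE)
  axes <- mean_axes + sep * (base_axes - mean_axes)
  grain <- 0.06 + sep * (seq(-0.04, 0.08, length.out = n_classes))
  ## spectra: shared water bands + three class-informative bands
  if (any(informative_nm < 400 | informative_nm > 2400))
    abort_input("informative band centers must lie within 400-2400 nm")
  depth_inc <- 0.035 * sep
  ## distinct per-class on/off depth signatures, one binary column per
  ## band: no single band separates all classes, so every planted band
  ## carries independent information and recovery of the full set is
  ## meaningful
  base_cols <- list(c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 1, 1, 0),
                    c(1, 0, 0, 1), c(1, 1, 0, 0))
  pattern <- vapply(seq_along(informative_nm), function(j)
    rep(base_cols[[(j - 1) %% length(base_cols) + 1]],
        length.out = n_classes), numeric(n_classes))
  structure(list(
    preset = preset, n_classes = n_classes,
    samples_per_class = samples_per_class,
    seeds_per_image = seeds_per_image, image_size = image_size,
    axes_mean = axes, axes_sd = 1.2, grain = grain,
    wavelengths = seq(350, 2500, by = wl_step),
    baseline_intercept = 0.68, baseline_slope = -5e-5,
    common_centers = c(1450, 1940), common_depths = c(0.15, 0.18),
    common_widths = c(40, 45),
    informative_nm = informative_nm,
    ## narrow class-informative features: ground truth must be
    ## identifiable at a few-grid-position resolution for recovery tests
    informative_widths = rep(c(8, 10, 12, 9, 11),
                             length.out = length(informative_nm)),
    informative_base_depth = 0.05, informative_depth_inc = depth_inc,
    informative_pattern = pattern,
    gain_sd = gain_sd, offset_sd = offset_sd, noise_sd = noise_sd),
    class = "fixture_spec")
}

## smooth per-seed texture: blurred white noise, amplitude = class grain
value_noise <- function(h, w, amplitude, sigma = 2) {
  if (amplitude <= 0) return(matrix(0, h, w))
  z <- matrix(rnorm(h * w), h, w)
  z <- EBImage::gblur(z, sigma = sigma)
  amplitude * z / max(sd(z), 1e-12)
}

#' Generate one synthetic multi-seed board image
#'
#' Places `n_seeds` non-overlapping filled ellipses with class-dependent
#' axes on a dark noisy background and adds class-dependent smooth
#' intra-seed texture. The true centers, axes and orientations are
#' returned for segmentation tests.
#'
#' @param spec a [fixture_spec()].
#' @param class_id class index in `1..n_classes`.
#' @param n_seeds number of seeds (default `spec$seeds_per_image`).
#' @param seed integer RNG seed.
#' @return list with `image` (a [seed_image()]) and `truth` (data frame
#'   of `center_row`, `center_col`, `axis_a`, `axis_b`, `angle`).
#' @export
make_seed_image <- function(spec, class_id, n_seeds = NULL, seed = 1) {
  stopifnot(inherits(spec, "fixture_spec"),
            class_id >= 1, class_id <= spec$n_classes)
  n_seeds <- n_seeds %||% spec$seeds_per_image
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(seed, {
    gray <- matrix(20 / 255, h, w) +
      matrix(rnorm(h * w, 0, 3 / 255), h, w)
    placed <- data.frame(center_row = numeric(0), center_col = numeric(0),
                         axis_a = numeric(0), axis_b = numeric(0),
                         angle = numeric(0))
    attempts <- 0
    while (nrow(placed) < n_seeds) {
      attempts <- attempts + 1
      if (attempts > 1000)
        abort_input("could not place ", n_seeds,
                    " non-overlapping seeds after 1000 attempts")
      a <- max(6, rnorm(1, spec$axes_mean[class_id, 1], spec$axes_sd))
      b <- max(5, rnorm(1, spec$axes_mean[class_id, 2], spec$axes_sd))
      if (b > a) { tmp <- a; a <- b; b <- tmp }
      ang <- runif(1, 0, pi)
      pad <- a + 4
      cr <- runif(1, pad, h - pad); cc <- runif(1, pad, w - pad)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed$center_row - cr)^2 + (placed$center_col - cc)^2)
        if (any(dd < placed$axis_a + a + 6)) next
      }
      rows <- max(1, floor(cr - a)):min(h, ceiling(cr + a))
      cols <- max(1, floor(cc - a)):min(w, ceiling(cc + a))
      rr <- outer(rows - cr, rep(1, length(cols)))
      cc2 <- outer(rep(1, length(rows)), cols - cc)
      u <- rr * cos(ang) + cc2 * sin(ang)
      v <- -rr * sin(ang) + cc2 * cos(ang)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      tex <- value_noise(length(rows), length(cols),
                         spec$grain[class_id])
      body <- 150 / 255 + tex + matrix(rnorm(length(rows) * length(cols),
                                             0, 4 / 255),
                                       length(rows), length(cols))
      patch <- gray[rows, cols]
      patch[inside] <- pmin(pmax(body[inside], 0.35), 1)
      gray[rows, cols] <- patch
      placed <- rbind(placed,
                      data.frame(center_row = cr, center_col = cc,
                                 axis_a = a, axis_b = b, angle = ang))
    }
    gray <- pmin(pmax(gray, 0), 1)
    img <- seed_image(array(rep(gray * 255, 3), c(h, w, 3)))
    list(image = img, truth = placed)
  })
}

fixture_clean_spectrum <- function(spec, class_id) {
  wl <- spec$wavelengths
  refl <- spec$baseline_intercept + spec$baseline_slope * (wl - 350)
  for (k in seq_along(spec$common_centers)) {
    refl <- refl - spec$common_depths[k] *
      exp(-(wl - spec$common_centers[k])^2 / (2 * spec$common_widths[k]^2))
  }
  for (k in seq_along(spec$informative_nm)) {
    depth <- spec$informative_base_depth +
      spec$informative_depth_inc * spec$informative_pattern[class_id, k]
    refl <- refl - depth *
      exp(-(wl - spec$informative_nm[k])^2 /
            (2 * spec$informative_widths[k]^2))
  }
  refl
}

#' Generate synthetic reflectance spectra for one class
#'
#' `reflectance = gain * (baseline - sum of Gaussian absorption bands) +
#' offset + white noise`, with per-sample gain and offset — exactly the
#' scatter model MSC inverts. Class differences are confined to the
#' declared informative band centers.
#'
#' @param spec a [fixture_spec()].
#' @param class_id class index.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @param scatter,noise switch the scatter/noise layers off for exact
#'   model checks.
#' @return a [spectrum_set()] labelled with `class_id`.
#' @export
make_spectra <- function(spec, class_id, n, seed = 1, scatter = TRUE,
                         noise = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  clean <- fixture_clean_spectrum(spec, class_id)
  p <- length(clean)
  with_seed(seed, {
    gains <- if (scatter) rnorm(n, 1, spec$gain_sd) else rep(1, n)
    offs <- if (scatter) rnorm(n, 0, spec$offset_sd) else rep(0, n)
    X <- outer(gains, clean) + offs
    if (noise) X <- X + matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    spectrum_set(spec$wavelengths, X,
                 labels = rep(paste0("class", class_id), n))
  })
}

#' Generate a complete fused classification task
#'
#' Composes the image and spectrum generators and runs the real
#' pipeline stages on them: segmentation + descriptor extraction on the
#' board images, SG + MSC preprocessing and 400-2400 nm cropping of the
#' spectra, CARS band selection and RFE morphological-feature selection
#' on the training rows only, then z-score fusion with training-split
#' statistics. Samples are split 7:3 stratified by class.
#'
#' @param spec a [fixture_spec()].
#' @param seed integer RNG seed for everything.
#' @param select run the two selectors (`FALSE` fuses all features).
#' @param cars_runs,spa_max passed to the selectors.
#' @return list: `fused` (a `fused_dataset` over all samples), `split`
#'   (train/test indices), `truth` (informative band centers in nm and
#'   the per-class shape parameters), `bands` (the CARS subset),
#'   `morph_kept`.
#' @export
make_fused_task <- function(spec, seed = 1, select = TRUE,
                            cars_runs = 30, spa_max = 15) {
  stopifnot(inherits(spec, "fixture_spec"))
  npc <- spec$samples_per_class
  ## --- images -> morphological table -------------------------------
  morph_rows <- list()
  for (cl in seq_len(spec$n_classes)) {
    got <- 0; img_i <- 0
    while (got < npc) {
      img_i <- img_i + 1
      im <- make_seed_image(spec, cl,
                            seed = derive_seed(seed, cl * 100 + img_i))
      tab <- extract_morphology(im$image,
                                image_id = sprintf("c%d_i%d", cl, img_i))
      if (nrow(tab) == 0) next
      take <- min(nrow(tab), npc - got)
      morph_rows[[length(morph_rows) + 1]] <- tab[seq_len(take), ]
      got <- got + take
    }
  }
  morph <- do.call(rbind, morph_rows)
  Xm <- as.matrix(morph[, morph_feature_names()])
  y <- rep(paste0("class", seq_len(spec$n_classes)), each = npc)
  ## --- spectra -> preprocessed matrix ------------------------------
  specs <- lapply(seq_len(spec$n_classes), function(cl)
    make_spectra(spec, cl, npc, seed = derive_seed(seed, 200 + cl)))
  all_s <- spectrum_set(spec$wavelengths,
                        do.call(rbind, lapply(specs, `[[`, "reflect")),
                        labels = y)
  prep <- crop_range(preprocess_spectra(all_s, "SG_MSC"), 400, 2400)
  ## --- split, select on training rows only -------------------------
  split <- stratified_split(y, 0.7, seed = derive_seed(seed, 300))
  tr <- split$train
  if (select) {
    bands <- cars_select(prep$reflect[tr, ], y[tr], n_runs = cars_runs,
                         seed = derive_seed(seed, 301),
                         wavelengths = prep$wavelengths)
    sel_m <- rfe_select(Xm[tr, ], y[tr], seed = derive_seed(seed, 302))
    morph_kept <- sel_m$kept
  } else {
    bands <- band_subset(seq_along(prep$wavelengths), prep$wavelengths,
                         NA_real_, 1, method = "none")
    morph_kept <- colnames(Xm)
  }
  Xb <- prep$reflect[, bands$indices, drop = FALSE]
  colnames(Xb) <- paste0("nm", prep$wavelengths[bands$indices])
  fused <- fuse_features(Xm[, morph_kept, drop = FALSE], Xb, y,
                         train = tr, morph_total = ncol(Xm),
                         bands_total = length(prep$wavelengths))
  list(fused = fused, split = split,
       truth = list(informative_nm = spec$informative_nm,
                    axes_mean = spec$axes_mean),
       bands = bands, morph_kept = morph_kept,
       morph_table = cbind(morph[, c("image_id", "seed_id")],
                           as.data.frame(Xm), label = y),
       prep = prep)
}
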