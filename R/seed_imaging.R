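## Seed segmentation from multi-seed board images and computation of the
## 34 morphological descriptors: 18 geometric (perimeter, area, axes,
## inscribed-circle radius, shape ratios, Hu invariant moments) and 16
## texture (grey-level co-occurrence statistics, local binary pattern
## histogram).
##
## Images are plain numeric arrays, H x W x 3, intensities in [0, 255],
## row-major with the origin at the top-left corner (0-based pixel
## coordinates in all reported geometry).

#' Validate a seed-board image
#'
#' @param pixels numeric array `H x W x 3` with intensities in
#'   \[0, 255\].
#' @return the validated array, invisibly classed as `seed_image`.
#' @export
seed_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    abort_input("seed image must be an H x W x 3 array (3 channels)")
  if (d[1] < 1 || d[2] < 1) abort_input("empty image")
  if (min(pixels) < 0 || max(pixels) > 255)
    abort_input("intensities must lie in [0, 255]")
  structure(pixels, class = "seed_image")
}

#' Read an image file as a seed image
#'
#' @param path PNG/JPEG/TIFF path.
#' @return a [seed_image()].
#' @export
read_seed_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  ## EBImage stores x (column) as the first dimension
  seed_image(aperm(a, c(2, 1, 3)) * 255)
}

#' Segmentation settings
#'
#' @param blur_sigma Gaussian blur standard deviation in px.
#' @param opening_radius structuring-element radius in px for the
#'   morphological opening.
#' @param min_area minimum component area in px^2; smaller components
#'   are dropped.
#' @param margin_px outward expansion of each bounding box in px.
#' @return a settings list.
#' @export
segmentation_config <- function(blur_sigma = 1, opening_radius = 2,
                                min_area = 200, margin_px = 15) {
  list(blur_sigma = blur_sigma, opening_radius = opening_radius,
       min_area = min_area, margin_px = margin_px)
}

rgb_to_gray <- function(pixels) {
  (0.2989 * pixels[, , 1] + 0.5870 * pixels[, , 2] +
     0.1140 * pixels[, , 3]) / 255
}

#' Segment individual seeds from a board image
#'
#' Pipeline: grayscale conversion, Gaussian blur, Otsu binarization,
#' morphological opening, connected-component labelling with boundary
#' tracing, per-component minimum axis-aligned bounding rectangle, and
#' outward margin expansion (clipped to the image). Components smaller
#' than `min_area` are dropped; regions are returned sorted by
#' `(row0, col0)`. Regions whose tight box touches the image border are
#' kept but flagged.
#'
#' @param image a [seed_image()] or an `H x W x 3` array.
#' @param cfg a [segmentation_config()].
#' @return list of `seed_region` objects; empty when no foreground
#'   survives the opening.
#' @export
segment_seeds <- function(image, cfg = segmentation_config()) {
  if (!inherits(image, "seed_image")) image <- seed_image(image)
  gray <- rgb_to_gray(image)
  g <- if (cfg$blur_sigma > 0) EBImage::gblur(gray, sigma = cfg$blur_sigma)
       else gray
  if (diff(range(g)) < 1e-12) return(list())
  thr <- EBImage::otsu(g, range = range(g))
  bw <- g > thr
  if (cfg$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * cfg$opening_radius + 1, "disc")
    bw <- EBImage::opening(bw, brush)
  }
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(bw)
  contours <- EBImage::ocontour(lab)  # 0-based (row, col) boundary chains
  h <- nrow(gray); w <- ncol(gray)
  regions <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    area <- sum(comp)
    if (area < cfg$min_area) next
    px <- which(comp, arr.ind = TRUE)
    r0 <- min(px[, 1]) - 1L; r1 <- max(px[, 1])  # half-open, 0-based
    c0 <- min(px[, 2]) - 1L; c1 <- max(px[, 2])
    m <- cfg$margin_px
    er0 <- max(r0 - m, 0L); ec0 <- max(c0 - m, 0L)
    er1 <- min(r1 + m, h); ec1 <- min(c1 + m, w)
    crop <- gray[(er0 + 1):er1, (ec0 + 1):ec1, drop = FALSE]
    mask <- comp[(er0 + 1):er1, (ec0 + 1):ec1, drop = FALSE]
    regions[[length(regions) + 1]] <- structure(list(
      contour = contours[[k]],
      bbox = c(row0 = r0, col0 = c0, row1 = r1, col1 = c1),
      bbox_expanded = c(row0 = er0, col0 = ec0, row1 = er1, col1 = ec1),
      crop = crop, mask = mask, area = area,
      touches_border = r0 == 0 || c0 == 0 || r1 == h || c1 == w),
      class = "seed_region")
  }
  ord <- order(vapply(regions, function(r) r$bbox["row0"], numeric(1)),
               vapply(regions, function(r) r$bbox["col0"], numeric(1)))
  regions[ord]
}

#' Build a seed region directly from a binary mask
#'
#' Convenience constructor for computing descriptors of a known shape
#' (and in tests): traces the boundary, sets the bounding box and uses
#' `crop` (or the mask itself) as the intensity crop.
#'
#' @param mask logical or 0/1 matrix.
#' @param crop optional numeric matrix of the same shape.
#' @return a `seed_region`.
#' @export
region_from_mask <- function(mask, crop = NULL) {
  mask <- mask > 0
  if (!any(mask)) abort_input("empty mask")
  storage.mode(mask) <- "integer"
  cont <- EBImage::ocontour(mask)[[1]]
  px <- which(mask > 0, arr.ind = TRUE)
  structure(list(
    contour = cont,
    bbox = c(row0 = min(px[, 1]) - 1L, col0 = min(px[, 2]) - 1L,
             row1 = max(px[, 1]), col1 = max(px[, 2])),
    bbox_expanded = c(row0 = 0L, col0 = 0L, row1 = nrow(mask),
                      col1 = ncol(mask)),
    crop = crop %||% (mask * 1.0), mask = mask > 0,
    area = sum(mask > 0), touches_border = FALSE),
    class = "seed_region")
}

contour_arclength <- function(contour) {
  ## closed 8-connected chain, diagonal steps weighted sqrt(2), scaled by
  ## Kulpa's digital-perimeter correction pi*(1+sqrt(2))/8: the raw chain
  ## overestimates smooth boundaries by ~5.5% (a rasterized disk would
  ## otherwise report circularity ~0.91 instead of ~1)
  n <- nrow(contour)
  if (n < 2) return(0)
  d <- contour[c(2:n, 1), , drop = FALSE] - contour
  sum(sqrt(rowSums(d^2))) * pi * (1 + sqrt(2)) / 8
}

min_area_rect_area <- function(mask) {
  ## min-area oriented rectangle over the union of pixel squares:
  ## hull of the 4 corners of every foreground pixel, rotating calipers
  px <- which(mask, arr.ind = TRUE)
  corners <- rbind(
    cbind(px[, 1] - 0.5, px[, 2] - 0.5), cbind(px[, 1] - 0.5, px[, 2] + 0.5),
    cbind(px[, 1] + 0.5, px[, 2] - 0.5), cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  hull <- corners[chull(corners), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3) return(max(1, diff(range(corners[, 1]))) *
                       max(1, diff(range(corners[, 2]))))
  best <- Inf
  for (i in seq_len(nh)) {
    e <- hull[if (i == nh) 1 else i + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    a <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (a < best) best <- a
  }
  best
}

hu_moments <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  x <- px[, 2]; y <- px[, 1]
  m00 <- length(x)
  xc <- mean(x); yc <- mean(y)
  mu <- function(p, q) sum((x - xc)^p * (y - yc)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
  ## log scaling keeps the seven invariants on comparable magnitudes
  -sign(h) * log10(abs(h) + 1e-30)
}

#' 18 geometric descriptors of a seed region
#'
#' Area `A` is the foreground pixel count; perimeter `S` the closed
#' contour arc length with sqrt(2)-weighted diagonal steps; `L`/`W` the
#' major/minor axis lengths of the best-fit ellipse from second-order
#' central moments; `r` the inscribed-circle radius (max of the Euclidean
#' distance transform); aspect ratio `K = L/W`; dispersion (compactness)
#' `e = S^2/A`; circularity `C = 4 pi A / S^2`; elongation
#' `E = (L-W)/(L+W)`; rectangularity `R = A / area of the oriented
#' minimum-area bounding rectangle`; equivalent-circle diameter
#' `Ed = sqrt(4A/pi)`; plus the seven log-scaled Hu invariant moments.
#'
#' @param region a `seed_region`.
#' @return named numeric vector of length 18.
#' @export
geometric_features <- function(region) {
  mask <- region$mask
  A <- sum(mask)
  if (A == 0) abort_input("empty region mask")
  S <- contour_arclength(region$contour)
  px <- which(mask, arr.ind = TRUE)
  xc <- colMeans(px)
  cc <- sweep(px, 2, xc)
  cov <- crossprod(cc) / A
  ev <- eigen(cov, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  L <- 4 * sqrt(ev[1]); W <- 4 * sqrt(ev[2])
  if (W < 1e-9) abort_input("degenerate region: zero minor axis")
  dm <- EBImage::distmap(mask * 1L)
  r_in <- max(dm)
  rect_area <- min_area_rect_area(mask)
  c(S = S, A = A, L = L, W = W, r = r_in,
    K = L / W, e = S^2 / A, C = 4 * pi * A / S^2,
    E = (L - W) / (L + W), R = A / rect_area,
    Ed = sqrt(4 * A / pi),
    setNames(hu_moments(mask), paste0("H", 0:6)))
}

glcm_matrix <- function(q, mask, levels, angles) {
  ## q: integer levels 1..levels, NA outside mask; symmetric, normalized,
  ## averaged over the requested angles
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  acc <- matrix(0, levels, levels)
  n_used <- 0
  h <- nrow(q); w <- ncol(q)
  for (ang in angles) {
    o <- offs[[as.character(ang)]]
    if (is.null(o)) abort_input("angle must be one of 0, 45, 90, 135")
    r1 <- max(1, 1 - o[1]):min(h, h - o[1])
    c1 <- max(1, 1 - o[2]):min(w, w - o[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- table(factor(a[ok], levels = 1:levels),
                    factor(b[ok], levels = 1:levels))
    m <- unclass(counts) + t(unclass(counts))  # symmetric
    acc <- acc + m / sum(m)
    n_used <- n_used + 1
  }
  if (n_used == 0) abort_input("no valid co-occurrence pairs")
  p <- acc / n_used
  stopifnot(abs(sum(p) - 1) < 1e-9)
  p
}

glcm_stats <- function(p) {
  lev <- nrow(p)
  i <- matrix(1:lev, lev, lev)
  j <- t(i)
  con <- sum(p * (i - j)^2)
  dis <- sum(p * abs(i - j))
  hom <- sum(p / (1 + (i - j)^2))
  asm <- sum(p^2)
  mui <- sum(i * p); muj <- sum(j * p)
  si <- sqrt(sum((i - mui)^2 * p)); sj <- sqrt(sum((j - muj)^2 * p))
  corr <- if (si < 1e-12 || sj < 1e-12) {
    ## constant crop: correlation undefined, 0 by convention
    message("glcm: zero variance, correlation set to 0")
    0
  } else sum(p * (i - mui) * (j - muj)) / (si * sj)
  c(Con = con, Dis = dis, Hom = hom, ASM = asm, Ene = sqrt(asm),
    Corr = corr)
}

lbp_histogram <- function(crop, mask) {
  h <- nrow(crop); w <- ncol(crop)
  if (h < 3 || w < 3) abort_input("crop must be at least 3 x 3 for LBP")
  ## 8 neighbours in circular order (radius 1)
  offs <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  ctr <- crop[2:(h - 1), 2:(w - 1), drop = FALSE]
  bits <- array(0L, c(h - 2, w - 2, 8))
  for (k in 1:8) {
    o <- offs[k, ]
    nb <- crop[2:(h - 1) + o[1], 2:(w - 1) + o[2], drop = FALSE]
    bits[, , k] <- (nb >= ctr) * 1L
  }
  ones <- apply(bits, c(1, 2), sum)
  trans <- array(0L, c(h - 2, w - 2))
  for (k in 1:8) {
    k2 <- if (k == 8) 1 else k + 1
    trans <- trans + (bits[, , k] != bits[, , k2])
  }
  ## rotation-invariant uniform coding: uniform patterns (<= 2
  ## transitions) binned by their number of ones (0..8), the rest in bin 9
  code <- ifelse(trans <= 2, ones, 9L)
  keep <- mask[2:(h - 1), 2:(w - 1), drop = FALSE]
  vals <- code[keep]
  if (length(vals) == 0) vals <- as.vector(code)
  hist <- tabulate(vals + 1L, nbins = 10)
  hist <- hist / sum(hist)
  stopifnot(abs(sum(hist) - 1) < 1e-9)
  setNames(hist, paste0("hist", 0:9))
}

#' 16 texture descriptors of a seed region
#'
#' The grey-level co-occurrence matrix is computed on the masked crop
#' quantized to `levels` grey levels at distance 1, symmetric,
#' normalized and averaged over the requested angles; from it contrast,
#' dissimilarity, homogeneity, angular second moment, energy
#' (`sqrt(ASM)`) and correlation (0 by convention for a constant crop).
#' The local binary pattern uses the rotation-invariant uniform
#' 8-neighbour coding at radius 1, giving a normalized 10-bin histogram
#' over the mask.
#'
#' @param region a `seed_region` with a crop of at least 3 x 3.
#' @param levels grey-level quantization for the GLCM (default 32).
#' @param angles co-occurrence angles in degrees, subset of
#'   `c(0, 45, 90, 135)`.
#' @return named numeric vector of length 16.
#' @export
texture_features <- function(region, levels = 32,
                             angles = c(0, 45, 90, 135)) {
  crop <- region$crop; mask <- region$mask
  if (nrow(crop) < 3 || ncol(crop) < 3)
    abort_input("crop must be at least 3 x 3")
  vals <- crop[mask]
  rng <- range(vals)
  if (diff(rng) < 1e-12) {
    q <- matrix(NA_integer_, nrow(crop), ncol(crop))
    q[mask] <- 1L
  } else {
    qv <- pmin(floor((crop - rng[1]) / diff(rng) * levels), levels - 1) + 1
    q <- matrix(NA_integer_, nrow(crop), ncol(crop))
    q[mask] <- as.integer(qv[mask])
  }
  g <- glcm_stats(glcm_matrix(q, mask, levels, angles))
  c(g, lbp_histogram(crop, mask))
}

#' Names of the 34 morphological descriptors, in canonical order
#' @return character vector of length 34.
#' @export
morph_feature_names <- function() {
  c("S", "A", "L", "W", "r", "K", "e", "C", "E", "R", "Ed",
    paste0("H", 0:6),
    "Con", "Dis", "Hom", "ASM", "Ene", "Corr", paste0("hist", 0:9))
}

#' Full morphological feature vector of one region
#'
#' @param region a `seed_region`.
#' @return named numeric vector of length 34 in [morph_feature_names()]
#'   order.
#' @export
morph_features <- function(region) {
  v <- c(geometric_features(region), texture_features(region))
  v[morph_feature_names()]
}

#' Segment an image and tabulate all seed descriptors
#'
#' @param image a [seed_image()] or array.
#' @param cfg a [segmentation_config()].
#' @param image_id identifier recorded in the output.
#' @return data frame with `image_id`, `seed_id` and the 34 descriptor
#'   columns, one row per segmented seed.
#' @export
extract_morphology <- function(image, cfg = segmentation_config(),
                               image_id = "img") {
  regions <- segment_seeds(image, cfg)
  if (length(regions) == 0)
    return(cbind(data.frame(image_id = character(0),
                            seed_id = integer(0)),
                 as.data.frame(matrix(numeric(0), 0, 34,
                   dimnames = list(NULL, morph_feature_names())))))
  feats <- t(vapply(regions, morph_features, numeric(34)))
  cbind(data.frame(image_id = image_id,
                   seed_id = seq_along(regions)),
        as.data.frame(feats))
}
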