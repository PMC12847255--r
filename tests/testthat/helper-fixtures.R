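# shared builders for geometric and spectral test objects

disk_mask <- function(radius, size = 2 * radius + 20,
                      center = size / 2) {
  idx <- seq_len(size)
  outer(idx, idx, function(i, j) (i - center)^2 + (j - center)^2 <=
          radius^2)
}

rect_mask <- function(h, w, size = c(100, 100), at = c(41, 21)) {
  m <- matrix(FALSE, size[1], size[2])
  m[at[1]:(at[1] + h - 1), at[2]:(at[2] + w - 1)] <- TRUE
  m
}

gray_board <- function(mask, fg = 180, bg = 10) {
  g <- matrix(bg, nrow(mask), ncol(mask))
  g[mask] <- fg
  array(rep(g, 3), c(dim(mask), 3))
}

## independent connected-component counter (4-connected flood fill),
## used as the oracle for segmentation counts
flood_count <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  seen <- matrix(FALSE, h, w)
  count <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!bw[i, j] || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            bw[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  count
}

## small labelled spectra set from the fixture generator
fixture_spectra <- function(spec, n_per_class, seed) {
  sets <- lapply(seq_len(spec$n_classes), function(cl)
    make_spectra(spec, cl, n_per_class, seed = seed * 10 + cl))
  spectrum_set(spec$wavelengths,
               do.call(rbind, lapply(sets, `[[`, "reflect")),
               labels = rep(seq_len(spec$n_classes), each = n_per_class))
}

## planted-feature classification table: feature 1 tracks the class,
## the rest are pure noise
planted_feature_data <- function(n_per_class = 15, n_classes = 4,
                                 n_noise = 9, seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(n_classes), each = n_per_class)
  n <- length(y)
  X <- cbind(y + rnorm(n, 0, 0.05),
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(X) <- paste0("f", seq_len(n_noise + 1))
  list(X = X, y = y)
}
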