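## Reflectance preprocessing: wavelength cropping, Savitzky-Golay
## smoothing and multiplicative scatter correction (MSC).

#' Construct a spectrum set
#'
#' Container for a wavelength grid with a samples-by-wavelengths
#' reflectance matrix and optional class labels.
#'
#' @param wavelengths strictly increasing numeric grid in nm.
#' @param reflect numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param labels optional class label per sample (factor or coercible).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, reflect, labels = NULL) {
  wavelengths <- as.numeric(wavelengths)
  reflect <- as.matrix(reflect)
  if (any(diff(wavelengths) <= 0))
    abort_input("wavelengths must be strictly increasing")
  if (ncol(reflect) != length(wavelengths))
    abort_input("reflect must have one column per wavelength")
  if (anyNA(reflect)) abort_input("reflect contains NA values")
  if (!is.null(labels)) {
    labels <- factor(labels)
    if (length(labels) != nrow(reflect))
      abort_input("labels length must match sample count")
  }
  colnames(reflect) <- format(wavelengths, trim = TRUE)
  structure(list(wavelengths = wavelengths, reflect = reflect,
                 labels = labels),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d samples x %d wavelengths (%g-%g nm)%s\n",
              nrow(x$reflect), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", nlevels(x$labels))))
  invisible(x)
}

#' Crop a spectrum set to a wavelength range
#'
#' Keeps wavelengths `w` with `lo_nm <= w <= hi_nm` (inclusive). The
#' usual use is discarding the noisy instrument extremes, e.g. keeping
#' 400-2400 nm of a 350-2500 nm sweep.
#'
#' @param s a [spectrum_set()].
#' @param lo_nm,hi_nm range bounds in nm, `lo_nm < hi_nm`.
#' @return cropped `spectrum_set`.
#' @export
crop_range <- function(s, lo_nm, hi_nm) {
  stopifnot(inherits(s, "spectrum_set"))
  if (lo_nm >= hi_nm) abort_input("lo_nm must be < hi_nm")
  keep <- s$wavelengths >= lo_nm & s$wavelengths <= hi_nm
  if (!any(keep))
    abort_input("crop range [", lo_nm, ", ", hi_nm,
                "] does not overlap the wavelength grid")
  spectrum_set(s$wavelengths[keep], s$reflect[, keep, drop = FALSE],
               s$labels)
}

#' Savitzky-Golay smoothing
#'
#' Applies a zero-derivative Savitzky-Golay filter to every spectrum
#' (row). Edges are handled by the filter's boundary polynomial fits, so
#' a row that is exactly a polynomial of degree `<= polyorder` passes
#' through unchanged.
#'
#' @param s a [spectrum_set()].
#' @param window odd filter length (default 21 points).
#' @param polyorder polynomial order, `< window` (default 3).
#' @return smoothed `spectrum_set` of identical shape.
#' @export
sg_smooth <- function(s, window = 21, polyorder = 3) {
  stopifnot(inherits(s, "spectrum_set"))
  if (window %% 2 != 1 || window <= polyorder)
    abort_input("window must be odd and greater than polyorder")
  if (window >= length(s$wavelengths))
    abort_input("window must be smaller than the number of wavelengths")
  sm <- t(apply(s$reflect, 1, signal::sgolayfilt, p = polyorder,
                n = window))
  spectrum_set(s$wavelengths, sm, s$labels)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum by ordinary
#' least squares, `x ~ a + b * ref`, and corrected to `(x - a) / b`. This
#' removes per-sample multiplicative gain and additive offset caused by
#' surface scatter. The reference defaults to the column-mean spectrum.
#' Rows with `|b| < 1e-12` are left unchanged with a warning.
#'
#' @param s a [spectrum_set()].
#' @param reference optional reference spectrum (length = grid size).
#' @return corrected `spectrum_set`.
#' @export
msc <- function(s, reference = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.null(reference)) {
    if (nrow(s$reflect) < 2)
      abort_input("msc needs >= 2 samples unless a reference is supplied")
    reference <- colMeans(s$reflect)
  }
  if (length(reference) != ncol(s$reflect))
    abort_input("reference length must match the wavelength grid")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- s$reflect
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    b <- sum((x - mean(x)) * rc) / denom
    a <- mean(x) - b * mean(reference)
    if (abs(b) < 1e-12) {
      warning(sprintf("msc: row %d has near-zero slope; left unchanged", i),
              call. = FALSE)
    } else {
      out[i, ] <- (x - a) / b
    }
  }
  spectrum_set(s$wavelengths, out, s$labels)
}

#' Dispatch spectral preprocessing
#'
#' `"SG"` applies Savitzky-Golay smoothing, `"MSC"` multiplicative
#' scatter correction, `"SG_MSC"` smoothing first then scatter
#' correction.
#'
#' @param s a [spectrum_set()].
#' @param method one of `"SG"`, `"MSC"`, `"SG_MSC"`.
#' @param window,polyorder passed to [sg_smooth()].
#' @param reference passed to [msc()].
#' @return preprocessed `spectrum_set`.
#' @export
preprocess_spectra <- function(s, method = c("SG_MSC", "SG", "MSC"),
                               window = 21, polyorder = 3,
                               reference = NULL) {
  method <- match.arg(method)
  switch(method,
         SG = sg_smooth(s, window, polyorder),
         MSC = msc(s, reference),
         SG_MSC = msc(sg_smooth(s, window, polyorder), reference))
}

#' Read a wide-format spectra CSV
#'
#' Expected layout: first column `sample_id`, second `label`, remaining
#' columns named by wavelength in nm.
#'
#' @param path CSV file path.
#' @return a [spectrum_set()] with `sample_id` kept as an attribute.
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("sample_id", "label")))
    abort_input("expected columns: sample_id, label, <wavelengths...>")
  wl <- as.numeric(names(df)[-(1:2)])
  if (anyNA(wl)) abort_input("wavelength column names must be numeric (nm)")
  s <- spectrum_set(wl, as.matrix(df[, -(1:2)]), labels = df$label)
  attr(s, "sample_id") <- df$sample_id
  s
}

#' Write a spectrum set as a wide-format CSV
#'
#' @param s a [spectrum_set()].
#' @param path output path.
#' @param sample_id optional ids (defaults to attribute or row number).
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path, sample_id = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  sample_id <- sample_id %||% attr(s, "sample_id") %||%
    seq_len(nrow(s$reflect))
  df <- data.frame(sample_id = sample_id,
                   label = if (is.null(s$labels)) NA else
                     as.character(s$labels),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(s$reflect, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
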