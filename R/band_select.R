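## Characteristic-wavelength selection: successive projections algorithm
## (SPA) and competitive adaptive reweighted sampling (CARS).
##
## Both selectors are regression-native, so class labels are handled as
## one-hot indicator responses (PLS2 / multi-response least squares),
## standard chemometric practice for classification tasks.

one_hot <- function(y) {
  y <- factor(y)
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

## SIMPLS (de Jong 1993) multi-response partial least squares.
## Small and dependency-free; cross-checked in the test suite against an
## independent PLS implementation.
simpls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ncomp <- min(ncomp, p, n - 1)
  xm <- colMeans(X); ym <- colMeans(Y)
  X0 <- sweep(X, 2, xm); Y0 <- sweep(Y, 2, ym)
  S <- crossprod(X0, Y0)
  R <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  TT <- matrix(0, n, ncomp); V <- matrix(0, p, ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(S^2)) < 1e-12) break
    qa <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% qa
    tt <- X0 %*% r
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-12) break
    tt <- tt / nt; r <- r / nt
    pp <- crossprod(X0, tt)
    qq <- crossprod(Y0, tt)
    v <- pp
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], pp)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- qq; TT[, a] <- tt; V[, a] <- v
    used <- a
  }
  if (used == 0L) {
    B <- matrix(0, p, q)
  } else {
    B <- R[, 1:used, drop = FALSE] %*% t(Q[, 1:used, drop = FALSE])
  }
  list(coef = B, x_means = xm, y_means = ym, ncomp = used)
}

simpls_predict <- function(fit, X) {
  sweep(as.matrix(X), 2, fit$x_means) %*% fit$coef +
    matrix(fit$y_means, nrow(X), length(fit$y_means), byrow = TRUE)
}

#' Build one successive-projections chain
#'
#' Starting from column `start`, repeatedly appends the column whose
#' projection onto the orthogonal complement of the span of the chosen
#' columns has maximal norm. Operates on the matrix as given (no
#' standardization), so chains can be inspected against hand
#' computations.
#'
#' @param X numeric matrix (samples x bands).
#' @param start 1-based starting column.
#' @param m_max maximum chain length.
#' @return integer vector of column indices in selection order (may be
#'   shorter than `m_max` if the residuals become rank-deficient).
#' @export
spa_chain <- function(X, start, m_max) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(start >= 1, start <= p, m_max >= 1)
  chain <- integer(0)
  R <- X
  sel <- as.integer(start)
  for (k in seq_len(min(m_max, p))) {
    chain <- c(chain, sel)
    v <- R[, sel]
    nv <- sum(v^2)
    if (nv < 1e-24) break
    R <- R - (v %*% crossprod(v, R)) / nv
    norms <- colSums(R^2)
    norms[chain] <- -Inf
    if (k == min(m_max, p)) break
    if (max(norms) < 1e-12) break  # rank-deficient: stop the chain early
    sel <- as.integer(unname(which.max(norms)))
  }
  chain
}

ridge_ls_rmse <- function(Xtr, Ytr, Xval, Yval, lambda = 1e-6) {
  Xtr1 <- cbind(1, Xtr)
  A <- crossprod(Xtr1) + diag(lambda, ncol(Xtr1))
  B <- tryCatch(solve(A, crossprod(Xtr1, Ytr)),
                error = function(e) NULL)
  if (is.null(B)) return(Inf)
  pred <- cbind(1, Xval) %*% B
  sqrt(mean((pred - Yval)^2))
}

#' SPA characteristic-wavelength selection
#'
#' Classic successive projections: orthogonal-projection chains built
#' from several starting wavelengths on the column-centered matrix,
#' then each chain prefix of length `k` is scored by the validation RMSE
#' of a multi-response (one-vs-rest) ridge least-squares model on a
#' fixed seeded 70/30 row split. The returned subset is the chain prefix
#' minimizing RMSE (ties broken toward fewer bands).
#'
#' @param X samples x bands matrix.
#' @param y class labels.
#' @param m_max maximum subset size, `< min(n_samples - 1, n_bands)`.
#' @param seed integer seed (validation split and start sampling).
#' @param n_starts number of chain starts; all columns when the grid is
#'   small, otherwise this many evenly spaced starts.
#' @param wavelengths optional grid in nm for reporting.
#' @param lambda ridge regularization for the scoring fits.
#' @return object of class `band_subset` with `indices` (ascending),
#'   `wavelengths_nm`, `score_curve` (RMSE vs subset size),
#'   `chosen` (the selected size).
#' @export
spa_select <- function(X, y, m_max, seed = 1, n_starts = 50,
                       wavelengths = NULL, lambda = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (m_max >= min(n - 1, p))
    abort_input("m_max must be < min(n_samples - 1, n_bands)")
  ## columns are mean-centered but kept on their physical reflectance
  ## scale: unit-variance scaling would inflate pure-noise bands to the
  ## same norm as structured ones and derail the projection chains
  Xs <- scale(X, center = TRUE, scale = FALSE)
  Y <- one_hot(y)
  with_seed(seed, {
    idx_val <- sample(n, max(1, round(0.3 * n)))
    starts <- if (p <= n_starts) seq_len(p) else
      unique(round(seq(1, p, length.out = n_starts)))
    best_rmse_by_k <- rep(Inf, m_max)
    best_prefix_by_k <- vector("list", m_max)
    for (s0 in starts) {
      chain <- spa_chain(Xs, s0, m_max)
      for (k in seq_along(chain)) {
        sub <- chain[1:k]
        rmse <- ridge_ls_rmse(Xs[-idx_val, sub, drop = FALSE],
                              Y[-idx_val, , drop = FALSE],
                              Xs[idx_val, sub, drop = FALSE],
                              Y[idx_val, , drop = FALSE], lambda)
        if (rmse < best_rmse_by_k[k]) {
          best_rmse_by_k[k] <- rmse
          best_prefix_by_k[[k]] <- sub
        }
      }
    }
    kept_sizes <- which(is.finite(best_rmse_by_k))
    chosen <- kept_sizes[which.min(best_rmse_by_k[kept_sizes])]
    idx <- sort(best_prefix_by_k[[chosen]])
    band_subset(idx, wavelengths, best_rmse_by_k[kept_sizes], chosen,
                method = "SPA")
  })
}

band_subset <- function(indices, wavelengths, score_curve, chosen,
                        method) {
  indices <- as.integer(unname(indices))
  structure(list(indices = indices,
                 wavelengths_nm = if (is.null(wavelengths)) NULL else
                   wavelengths[indices],
                 score_curve = as.numeric(score_curve),
                 chosen = chosen, method = method),
            class = "band_subset")
}

#' @export
print.band_subset <- function(x, ...) {
  cat(sprintf("%s band subset: %d bands (criterion minimum %.4g at %s %d)\n",
              x$method, length(x$indices), min(x$score_curve),
              if (x$method == "CARS") "iteration" else "size", x$chosen))
  if (!is.null(x$wavelengths_nm))
    cat("  nm:", paste(format(x$wavelengths_nm, trim = TRUE),
                       collapse = " "), "\n")
  invisible(x)
}

#' Exponentially decreasing retention ratio for CARS
#'
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2) / (N-1)`, so that `r_1 = 1` and `r_N = 2/p`.
#'
#' @param i iteration number(s), 1-based.
#' @param p initial band count.
#' @param n_runs total number of Monte-Carlo runs N.
#' @return retention ratio(s) in (0, 1].
#' @export
cars_retention <- function(i, p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * i)
}

#' CARS characteristic-wavelength selection
#'
#' Competitive adaptive reweighted sampling: at each Monte-Carlo run a
#' PLS2 model is fitted on 80% of the samples using the currently
#' retained bands; bands are weighted by the summed absolute PLS
#' regression coefficients; an exponentially decreasing fraction
#' ([cars_retention()]) is kept by a forced top-weight cut followed by
#' adaptive reweighted sampling; the k-fold RMSECV of the retained set is
#' recorded. The retained set of the run with minimal RMSECV is
#' returned (ties broken toward the smaller subset, then the earlier
#' run).
#'
#' @param X samples x bands matrix.
#' @param y class labels (internally one-hot for PLS2).
#' @param n_runs Monte-Carlo runs (default 50).
#' @param k_folds cross-validation folds for RMSECV (default 5).
#' @param n_pls maximum PLS components (capped at 10 and by rank).
#' @param seed integer seed.
#' @param wavelengths optional grid in nm for reporting.
#' @return object of class `band_subset`; `score_curve` holds RMSECV per
#'   run and `chosen` the selected run. `attr(, "subsets")` keeps the
#'   retained set per run.
#' @export
cars_select <- function(X, y, n_runs = 50, k_folds = 5, n_pls = 10,
                        seed = 1, wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_runs < 2) abort_input("n_runs must be >= 2")
  Y <- one_hot(y)
  with_seed(seed, {
    folds <- sample(rep(seq_len(k_folds), length.out = n))
    retained <- seq_len(p)
    rmsecv <- rep(NA_real_, n_runs)
    subsets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      mc <- sample(n, max(2, round(0.8 * n)))
      ncomp <- min(n_pls, 10, length(retained), length(mc) - 1)
      fit <- simpls_fit(X[mc, retained, drop = FALSE],
                        Y[mc, , drop = FALSE], ncomp)
      ## weight = |coefficient of the standardized predictor|: raw PLS
      ## coefficients on unscaled spectra reward low-variance columns
      w <- rowSums(abs(fit$coef)) *
        apply(X[mc, retained, drop = FALSE], 2, sd)
      m_i <- min(ceiling(cars_retention(i, p, n_runs) * p),
                 length(retained))
      if (m_i < 2) break
      ord <- order(w, decreasing = TRUE)
      cand <- retained[ord[seq_len(m_i)]]
      wc <- w[ord[seq_len(m_i)]]
      # competitive reweighted draw: m_i weighted picks, unique survivors
      if (all(wc <= 0)) wc <- rep(1, length(wc))
      draw <- sample(length(cand), m_i, replace = TRUE, prob = wc)
      new_retained <- sort(cand[unique(draw)])
      if (length(new_retained) < 2) {
        ## degenerate draw: keep the two top-weight bands so the run
        ## can still be scored
        new_retained <- sort(cand[order(wc, decreasing = TRUE)[1:2]])
      }
      retained <- new_retained
      rmsecv[i] <- pls_rmsecv(X[, retained, drop = FALSE], Y, folds,
                              n_pls)
      subsets[[i]] <- retained
    }
    done <- which(!is.na(rmsecv))
    if (length(done) == 0)
      abort_input("CARS made no complete run; increase n_runs or bands")
    ## ties: smaller subset first, then earlier iteration
    best_val <- min(rmsecv[done])
    cands <- done[rmsecv[done] <= best_val + 1e-15]
    sizes <- vapply(subsets[cands], length, integer(1))
    chosen <- cands[order(sizes, cands)][1]
    out <- band_subset(subsets[[chosen]], wavelengths,
                       rmsecv[done], chosen, method = "CARS")
    attr(out, "subsets") <- subsets[done]
    out
  })
}

pls_rmsecv <- function(X, Y, folds, n_pls) {
  err <- 0; m <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    ncomp <- min(n_pls, 10, ncol(X), sum(tr) - 1)
    fit <- tryCatch(simpls_fit(X[tr, , drop = FALSE],
                               Y[tr, , drop = FALSE], ncomp),
                    error = function(e)
                      simpls_fit(X[tr, , drop = FALSE],
                                 Y[tr, , drop = FALSE],
                                 max(1, ncomp %/% 2)))
    pred <- simpls_predict(fit, X[!tr, , drop = FALSE])
    err <- err + sum((pred - Y[!tr, , drop = FALSE])^2)
    m <- m + sum(!tr) * ncol(Y)
  }
  sqrt(err / m)
}
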