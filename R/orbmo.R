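## Improved Red-Billed Blue Magpie Optimizer (ORBMO).
##
## Base population dynamics (subgroup-mean exploration, food-guided
## exploitation with a decaying contraction factor, greedy "food storage")
## plus three switchable mechanisms: Circle chaotic initialization,
## golden-sine + Levy-flight hybrid search, and adaptive simulated-annealing
## perturbation of the incumbent best.

#' Define a box-constrained search space
#'
#' @param lb,ub numeric vectors of per-dimension lower/upper bounds,
#'   `lb < ub` elementwise.
#' @param names optional per-dimension labels.
#' @return object of class `search_space` with fields `dim`, `lb`, `ub`,
#'   `names`.
#' @export
search_space <- function(lb, ub, names = NULL) {
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != length(ub))
    abort_input("lb and ub must have equal length")
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(lb >= ub))
    abort_input("need finite lb < ub elementwise")
  if (is.null(names)) names <- paste0("x", seq_along(lb))
  structure(list(dim = length(lb), lb = lb, ub = ub, names = names),
            class = "search_space")
}

#' Strategy configuration for the optimizer
#'
#' Any subset of the three mechanisms can be switched on or off, which is
#' how ablation studies are run. `alpha` (Levy perturbation strength) and
#' `beta` (annealing cooling rate) default to `0.01 * (ub - lb)` and
#' `log(100) / t_max` respectively when left `NULL`.
#'
#' @param use_circle_init Circle chaotic population initialization.
#' @param use_gss golden-sine + Levy-flight hybrid exploitation.
#' @param use_asa adaptive simulated-annealing perturbation of the best.
#' @param circle_variant `"improved"` (default) or `"standard"` map.
#' @param alpha Levy step strength (scalar or per-dimension), `NULL` for
#'   the default.
#' @param lam Levy exponent in (1, 2].
#' @param t0 initial annealing temperature.
#' @param beta cooling rate for the adaptive schedule, `NULL` for default.
#' @param schedule `"adaptive"` (`T0 * exp(-beta * t)`) or `"linear"`
#'   (`T0 * (1 - t / t_max)`).
#' @param sa_scale0 base Gaussian perturbation scale as a fraction of the
#'   box width.
#' @param patience early-stop patience (iterations without improvement).
#' @param tol minimum fitness improvement that resets the patience counter.
#' @return a list of class `orbmo_config`.
#' @export
orbmo_config <- function(use_circle_init = TRUE, use_gss = TRUE,
                         use_asa = TRUE,
                         circle_variant = c("improved", "standard"),
                         alpha = NULL, lam = 1.5, t0 = 100, beta = NULL,
                         schedule = c("adaptive", "linear"),
                         sa_scale0 = 0.1, patience = 30, tol = 1e-12) {
  circle_variant <- match.arg(circle_variant)
  schedule <- match.arg(schedule)
  if (lam <= 1 || lam > 2) abort_input("lam must be in (1, 2]")
  structure(list(use_circle_init = use_circle_init, use_gss = use_gss,
                 use_asa = use_asa, circle_variant = circle_variant,
                 alpha = alpha, lam = lam, t0 = t0, beta = beta,
                 schedule = schedule, sa_scale0 = sa_scale0,
                 patience = patience, tol = tol),
            class = "orbmo_config")
}

#' One step of the Circle chaotic map
#'
#' Standard: `mod(x + b - (a / (2 pi)) sin(2 pi x), 1)` with `a = 0.5`,
#' `b = 0.2`. Improved: `mod(2.75 x + b - (a / (2.75 pi)) sin(2.75 pi x), 1)`
#' with `a = 0.6`, `b = 0.3`. The improved form spreads iterates more
#' uniformly over \[0, 1\], which raises initial population diversity.
#'
#' @param x current value(s) in \[0, 1\] (vectorized).
#' @param variant `"standard"` or `"improved"`.
#' @return next value(s) in \[0, 1).
#' @export
circle_map_step <- function(x, variant = c("improved", "standard")) {
  variant <- match.arg(variant)
  if (any(x < 0 | x > 1)) abort_input("x must lie in [0, 1]")
  if (variant == "standard") {
    a <- 0.5; b <- 0.2
    (x + b - (a / (2 * pi)) * sin(2 * pi * x)) %% 1
  } else {
    a <- 0.6; b <- 0.3
    (2.75 * x + b - (a / (2.75 * pi)) * sin(2.75 * pi * x)) %% 1
  }
}

#' Chaotic population initialization
#'
#' Per dimension, iterates the chosen Circle map from a seeded random
#' start in (0, 1) with a 100-step burn-in, takes `n` values and scales
#' them affinely into `[lb, ub]`.
#'
#' @param n population size (>= 2).
#' @param space a [search_space()].
#' @param variant Circle map variant.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return `n x dim` matrix of in-bounds positions.
#' @export
init_population_circle <- function(n, space, variant = "improved",
                                   seed = NULL) {
  stopifnot(inherits(space, "search_space"), n >= 2)
  with_seed(seed, {
    pos <- matrix(0, n, space$dim)
    for (d in seq_len(space$dim)) {
      x <- runif(1, 1e-6, 1 - 1e-6)
      for (i in 1:100) x <- circle_map_step(x, variant)
      seqs <- numeric(n)
      for (i in seq_len(n)) {
        x <- circle_map_step(x, variant)
        seqs[i] <- x
      }
      pos[, d] <- space$lb[d] + seqs * (space$ub[d] - space$lb[d])
    }
    colnames(pos) <- space$names
    pos
  })
}

#' Golden-sine position update
#'
#' `x' = x + r sin(theta) (phi x_food - x)` with the golden ratio
#' `phi = (sqrt(5) - 1) / 2`, `r ~ U[0, 1]`, `theta ~ U[0, 2 pi]`.
#' The update steers an individual toward a phi-scaled image of the best
#' position with a sinusoidal perturbation that keeps the path diverse.
#'
#' @param x current position vector.
#' @param x_food best position found so far.
#' @param r,theta optional fixed draws (tests); drawn from the current RNG
#'   stream when `NULL`.
#' @return updated position vector.
#' @export
golden_sine_update <- function(x, x_food, r = NULL, theta = NULL) {
  stopifnot(length(x) == length(x_food))
  if (is.null(r)) r <- runif(1)
  if (is.null(theta)) theta <- runif(1, 0, 2 * pi)
  phi <- (sqrt(5) - 1) / 2
  x + r * sin(theta) * (phi * x_food - x)
}

#' Mantegna scale parameter for Levy steps
#'
#' @param lam Levy exponent in (1, 2].
#' @return the scale `sigma_u` of the numerator Gaussian.
#' @export
levy_sigma <- function(lam) {
  if (lam <= 1 || lam > 2) abort_input("lam must be in (1, 2]")
  num <- gamma(1 + lam) * sin(pi * lam / 2)
  den <- gamma((1 + lam) / 2) * lam * 2^((lam - 1) / 2)
  (num / den)^(1 / lam)
}

#' Heavy-tailed Levy step (Mantegna's algorithm)
#'
#' `step = u / |v|^(1/lam)` with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)`.
#' The long tail produces intermittent large jumps that help escape local
#' basins.
#'
#' @param lam Levy exponent in (1, 2].
#' @param dim number of components.
#' @return numeric step vector of length `dim`.
#' @export
levy_step <- function(lam, dim) {
  su <- levy_sigma(lam)
  u <- rnorm(dim, 0, su)
  v <- rnorm(dim)
  u / abs(v)^(1 / lam)
}

#' Golden-sine update with Levy-flight perturbation
#'
#' The hybrid exploitation move: golden-sine step plus `alpha` times a
#' Levy step. `alpha = 0` reduces exactly to [golden_sine_update()].
#' Bounds are enforced by the caller.
#'
#' @inheritParams golden_sine_update
#' @param alpha perturbation strength (scalar or per-dimension, >= 0).
#' @param lam Levy exponent.
#' @return updated position vector.
#' @export
gs_lf_update <- function(x, x_food, alpha = 0.01, lam = 1.5,
                         r = NULL, theta = NULL) {
  stopifnot(all(alpha >= 0))
  gs <- golden_sine_update(x, x_food, r = r, theta = theta)
  if (all(alpha == 0)) return(gs)
  gs + alpha * levy_step(lam, length(x))
}

#' Metropolis acceptance probability
#'
#' `min(1, exp(-delta_f / T))`; improvements (`delta_f <= 0`) are always
#' accepted. At `T <= 0` the frozen limit applies: 1 for improvements,
#' 0 otherwise.
#'
#' @param delta_f fitness difference `f_new - f_old` (minimization).
#' @param temp current temperature.
#' @return acceptance probability in \[0, 1\].
#' @export
sa_accept_prob <- function(delta_f, temp) {
  if (temp <= 0) return(if (delta_f <= 0) 1 else 0)
  min(1, exp(-delta_f / temp))
}

#' Annealing temperature schedule
#'
#' Linear: `T0 * (1 - t / t_max)`. Adaptive: `T0 * exp(-beta * t)`.
#' Both start at `T0` when `t = 0`.
#'
#' @param t current iteration (0-based).
#' @param t_max maximum iterations.
#' @param t0 initial temperature.
#' @param beta cooling rate (adaptive schedule).
#' @param schedule `"linear"` or `"adaptive"`.
#' @return temperature `T >= 0`.
#' @export
anneal_temperature <- function(t, t_max, t0 = 100, beta = log(100) / t_max,
                               schedule = c("adaptive", "linear")) {
  schedule <- match.arg(schedule)
  stopifnot(t >= 0, t <= t_max)
  if (schedule == "linear") t0 * (1 - t / t_max) else t0 * exp(-beta * t)
}

#' Temperature-scaled Gaussian perturbation of the best position
#'
#' `candidate = clip(best + (T / T0) * N(0,1) * scale0 * (ub - lb))`.
#' The perturbation magnitude shrinks proportionally with the temperature,
#' so late-stage moves refine rather than disrupt.
#'
#' @param best current best position (in bounds).
#' @param temp,t0 current and initial temperature.
#' @param space a [search_space()].
#' @param scale0 base scale as a fraction of the box width.
#' @return perturbed in-bounds candidate vector.
#' @export
asa_perturb_best <- function(best, temp, t0, space, scale0 = 0.1) {
  stopifnot(inherits(space, "search_space"), length(best) == space$dim)
  cand <- best + (temp / t0) * rnorm(space$dim) * scale0 *
    (space$ub - space$lb)
  pmin(pmax(cand, space$lb), space$ub)
}

clip_bounds <- function(x, space) pmin(pmax(x, space$lb), space$ub)

eval_objective <- function(objective, x) {
  f <- objective(x)
  if (!is.finite(f)) {
    warning("objective returned a non-finite value; treated as +Inf",
            call. = FALSE)
    f <- Inf
  }
  f
}

#' One iteration of the magpie population dynamics
#'
#' Each individual explores (move toward the mean of a random subgroup)
#' with probability `1 - t / t_max`, otherwise exploits around the food
#' position `x_food` with a contraction factor
#' `CF = (1 - t / t_max)^(2 t / t_max)`. With `use_gss` the exploitation
#' move is replaced, with adaptive switching probability
#' `0.5 (1 - t / t_max)`, by the golden-sine + Levy hybrid. New positions
#' are clipped to bounds and kept only if they improve the individual's
#' fitness ("food storage"); the food position is strictly elitist.
#'
#' @param pop list with `positions` (n x dim), `fitness` (n), `food`,
#'   `food_fitness`.
#' @param objective function mapping an in-bounds vector to a scalar to
#'   minimize.
#' @param space a [search_space()].
#' @param cfg an [orbmo_config()].
#' @param t,t_max iteration counter (0-based) and maximum.
#' @return updated population list.
#' @export
rbmo_step <- function(pop, objective, space, cfg, t, t_max) {
  n <- nrow(pop$positions)
  d <- space$dim
  frac <- t / t_max
  cf <- (1 - frac)^(2 * frac)
  p_explore <- 1 - frac
  p_switch <- 0.5 * (1 - frac)
  alpha <- cfg$alpha %||% (0.01 * (space$ub - space$lb))
  for (i in seq_len(n)) {
    x <- pop$positions[i, ]
    # random subgroup mean: small groups probe locally, large ones globally
    if (runif(1) < 0.5) {
      q <- sample(2:5, 1)
    } else {
      q <- sample(10:max(10, min(n, 20)), 1)
    }
    grp <- sample(n, min(q, n))
    xbar <- colMeans(pop$positions[grp, , drop = FALSE])
    if (runif(1) < p_explore) {
      xnew <- x + runif(d) * (xbar - x)
    } else if (cfg$use_gss && runif(1) < p_switch) {
      xnew <- gs_lf_update(x, pop$food, alpha = alpha, lam = cfg$lam)
    } else {
      xnew <- pop$food + cf * runif(d) * (xbar - x)
    }
    xnew <- clip_bounds(xnew, space)
    fnew <- eval_objective(objective, xnew)
    if (fnew < pop$fitness[i]) {
      pop$positions[i, ] <- xnew
      pop$fitness[i] <- fnew
      if (fnew < pop$food_fitness) {
        pop$food <- xnew
        pop$food_fitness <- fnew
      }
    }
  }
  pop
}

#' Run the (O)RBMO optimizer
#'
#' Minimizes `objective` over the box `space`. Per iteration: population
#' update ([rbmo_step()]), then — when `use_asa` — a temperature-scaled
#' Gaussian perturbation of the incumbent best. The perturbed candidate
#' replaces the global best only if strictly better; otherwise it may
#' still replace the worst population member under Metropolis acceptance,
#' which preserves diversity while the best-so-far archive stays elitist.
#' Stops early after `cfg$patience` iterations without an improvement
#' larger than `cfg$tol`.
#'
#' @param objective function of an in-bounds numeric vector, returning a
#'   scalar to minimize.
#' @param space a [search_space()].
#' @param n population size.
#' @param t_max maximum iterations.
#' @param cfg an [orbmo_config()].
#' @param seed integer seed; the whole run is deterministic given it.
#' @return list with `best` (position), `best_fitness`, `history`
#'   (best fitness per completed iteration), `n_iter`, `evaluations`.
#' @export
orbmo_optimize <- function(objective, space, n = 30, t_max = 100,
                           cfg = orbmo_config(), seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (n * t_max < 2) abort_input("budget n * t_max must be at least 2")
  beta <- cfg$beta %||% (log(100) / t_max)
  with_seed(seed, {
    n_eval <- 0L
    obj <- function(x) { n_eval <<- n_eval + 1L; eval_objective(objective, x) }
    if (cfg$use_circle_init) {
      pos <- init_population_circle(n, space, cfg$circle_variant)
    } else {
      pos <- matrix(runif(n * space$dim), n) %*% diag(space$ub - space$lb,
                                                      space$dim) +
        matrix(space$lb, n, space$dim, byrow = TRUE)
      colnames(pos) <- space$names
    }
    fit <- apply(pos, 1, obj)
    ibest <- which.min(fit)
    pop <- list(positions = pos, fitness = fit,
                food = pos[ibest, ], food_fitness = fit[ibest])
    history <- numeric(0)
    stall <- 0L
    for (t in seq_len(t_max)) {
      prev_best <- pop$food_fitness
      pop <- rbmo_step(pop, obj, space, cfg, t - 1, t_max)
      if (cfg$use_asa) {
        temp <- anneal_temperature(t - 1, t_max, t0 = cfg$t0, beta = beta,
                                   schedule = cfg$schedule)
        cand <- asa_perturb_best(pop$food, temp, cfg$t0, space,
                                 scale0 = cfg$sa_scale0)
        fcand <- obj(cand)
        if (fcand < pop$food_fitness) {
          pop$food <- cand
          pop$food_fitness <- fcand
          iw <- which.max(pop$fitness)
          pop$positions[iw, ] <- cand
          pop$fitness[iw] <- fcand
        } else if (is.finite(fcand)) {
          # Metropolis acceptance into the worst slot keeps diversity
          # without ever touching the elitist best-so-far archive
          dfit <- fcand - pop$food_fitness
          if (runif(1) < sa_accept_prob(dfit, temp)) {
            iw <- which.max(pop$fitness)
            pop$positions[iw, ] <- cand
            pop$fitness[iw] <- fcand
          }
        }
      }
      history <- c(history, pop$food_fitness)
      if (prev_best - pop$food_fitness > cfg$tol) stall <- 0L
      else stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
    list(best = pop$food, best_fitness = pop$food_fitness,
         history = history, n_iter = length(history),
         evaluations = n_eval)
  })
}
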