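#' Map parameters to and from the unit cube
#'
#' All optimization algorithms run on parameters normalized to `[0, 1]` per
#' dimension; re-normalized (physical) values are passed to the simulator.
#'
#' @param x Physical parameter vector (must lie within bounds).
#' @param u Normalized vector in `[0, 1]^d`.
#' @param bounds Two-column matrix (or list of length-2 vectors) of
#'   `(lower, upper)` per dimension.
#' @return The mapped vector.
#' @examples
#' normalize_params(0.12, rbind(c(0, 0.6)))  # 0.2
#' @export
normalize_params <- function(x, bounds) {
  b <- as_bounds(bounds)
  if (any(x < b[, 1L] - 1e-12) || any(x > b[, 2L] + 1e-12))
    stop("parameter value outside bounds")
  (x - b[, 1L]) / (b[, 2L] - b[, 1L])
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(u, bounds) {
  b <- as_bounds(bounds)
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("normalized value outside [0, 1]")
  b[, 1L] + u * (b[, 2L] - b[, 1L])
}

as_bounds <- function(bounds) {
  b <- if (is.matrix(bounds)) bounds else do.call(rbind, bounds)
  if (ncol(b) != 2L || any(!is.finite(b)) || any(b[, 1L] >= b[, 2L]))
    stop("bounds must be finite (lower, upper) pairs with lower < upper")
  b
}

#' Optimizer settings
#'
#' @param algorithm `"EO"` (evolutionary algorithm with generational
#'   replacement and weak elitism), `"SA"` (simulated annealing), `"NM"`
#'   (Nelder-Mead downhill simplex) or `"LBFGSB"` (bound-constrained
#'   limited-memory quasi-Newton).
#' @param bounds Two-column matrix or list of `(lower, upper)` pairs, one
#'   per parameter; bounds are mandatory.
#' @param seed Integer seed; all randomness derives from it.
#' @param start Optional physical starting vector: the initial point of the
#'   local algorithms, a member of the initial population for EO, the
#'   initial state for SA.
#' @param pop_size EO population size (default 100).
#' @param generations EO generation count; also the evaluation budget scale
#'   for SA.
#' @param mutation_rate Per-gene Gaussian mutation probability (default
#'   0.25).
#' @param mutation_sigma Initial mutation standard deviation in normalized
#'   units (default 0.2); also the SA proposal width.
#' @param mutation_sigma_final Mutation standard deviation reached in the
#'   last EO generation (default 2e-4): the scale is annealed geometrically
#'   across generations, so early generations explore globally while late
#'   generations refine the optimum. Set equal to `mutation_sigma` for a
#'   constant scale.
#' @param blend_alpha Blend-crossover interval extension factor (default
#'   0.1).
#' @param tournament_size Number of candidates entering each selection
#'   tournament (default 8). Larger values increase selection pressure;
#'   with the default population of 100 a size of 8 lets the population
#'   condense around the incumbent optimum fast enough for the annealed
#'   mutation scale to refine it, which binary tournaments do not achieve
#'   at these budgets.
#' @param sa List with `T0`, `Tf`, `cooling`, `dwell` for the annealing
#'   schedule (geometric cooling every `dwell` evaluations; the Gaussian
#'   proposal scale is `mutation_sigma * sqrt(T/T0)`, shrinking as the
#'   system cools).
#' @param nm List with `max_iter` and `ftol` for Nelder-Mead (convergence is
#'   tested on the relative decrease of the cost).
#' @param lbfgsb List with `max_iter` and `accuracy` (function-value
#'   tolerance).
#' @return An object of class `nf_opt_settings`.
#' @export
optimizer_settings <- function(algorithm = c("EO", "SA", "NM", "LBFGSB"),
                               bounds, seed = 1L, start = NULL,
                               pop_size = 100L, generations = 100L,
                               mutation_rate = 0.25, mutation_sigma = 0.2,
                               mutation_sigma_final = 1e-5,
                               blend_alpha = 0.1, tournament_size = 8L,
                               sa = list(T0 = 1, Tf = 1e-4, cooling = 0.95,
                                         dwell = 20),
                               nm = list(max_iter = 500L, ftol = 1e-8),
                               lbfgsb = list(max_iter = 200L, accuracy = 1e-10)) {
  algorithm <- match.arg(algorithm)
  b <- as_bounds(bounds)
  if (algorithm == "EO" && pop_size < 2L) stop("EO needs pop_size >= 2")
  if (!is.null(start)) {
    if (length(start) != nrow(b)) stop("'start' has wrong length")
    if (any(start < b[, 1L]) || any(start > b[, 2L]))
      stop("'start' outside bounds")
  }
  structure(list(algorithm = algorithm, bounds = b, seed = as.integer(seed),
                 start = start, pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 mutation_sigma_final = mutation_sigma_final,
                 blend_alpha = blend_alpha,
                 tournament_size = as.integer(tournament_size),
                 sa = sa, nm = nm, lbfgsb = lbfgsb),
            class = "nf_opt_settings")
}

#' Minimize an objective over the unit cube with history recording
#'
#' The objective is a function of a normalized vector in `[0, 1]^d` (the
#' caller wraps denormalization and simulation). All algorithms honour the
#' bounds: candidate points are clipped to the unit cube before evaluation.
#' The best-so-far fitness of the evolutionary algorithm is non-increasing
#' across generations (weak elitism).
#'
#' @param objective Function `[0,1]^d -> finite numeric`.
#' @param settings An [optimizer_settings()].
#' @return A list of class `nf_fit_result` with `best_params` (denormalized,
#'   named after the bounds' row names when present), `best_fitness`,
#'   `history` (data frame of per-generation best/mean/median/worst),
#'   `final_population` (list with normalized matrix `u`, denormalized `x`,
#'   `fitness`), `populations` (per-generation normalized parameter
#'   snapshots, for allele statistics), `seed`, `n_evaluations`.
#' @examples
#' s <- optimizer_settings("NM", rbind(c(-2, 2), c(-2, 2)), seed = 1,
#'                         start = c(1, 1))
#' r <- optimize_params(function(u) sum((u - 0.3)^2), s)
#' r$best_fitness
#' @export
optimize_params <- function(objective, settings) {
  stopifnot(inherits(settings, "nf_opt_settings"))
  b <- settings$bounds
  d <- nrow(b)
  set.seed(settings$seed)
  n_eval <- 0L
  eval_f <- function(u) {
    if (any(u < 0) || any(u > 1))
      stop("internal error: objective evaluated outside the unit cube")
    n_eval <<- n_eval + 1L
    f <- objective(u)
    if (!is.finite(f))
      stop("objective returned a non-finite value at (",
           paste(signif(denormalize_params(u, b), 6), collapse = ", "), ")")
    f
  }
  u_start <- if (!is.null(settings$start))
    normalize_params(settings$start, b) else NULL

  res <- switch(settings$algorithm,
    EO = eo_minimize(eval_f, d, settings, u_start),
    SA = sa_minimize(eval_f, d, settings, u_start),
    NM = nm_minimize(eval_f, d, settings, u_start),
    LBFGSB = lbfgsb_minimize(eval_f, d, settings, u_start))

  x_best <- denormalize_params(res$u_best, b)
  if (!is.null(rownames(b))) names(x_best) <- rownames(b)
  structure(list(best_params = x_best, best_fitness = res$f_best,
                 history = res$history,
                 final_population = list(
                   u = res$pop_u,
                   x = sweep(sweep(res$pop_u, 2L, b[, 2L] - b[, 1L], "*"),
                             2L, b[, 1L], "+"),
                   fitness = res$pop_f),
                 populations = res$populations,
                 seed = settings$seed, algorithm = settings$algorithm,
                 n_evaluations = n_eval),
            class = "nf_fit_result")
}

hist_row <- function(gen, f) {
  data.frame(generation = gen, best = min(f), mean = mean(f),
             median = median(f), worst = max(f))
}

clip01 <- function(u) {
  u[u < 0] <- 0
  u[u > 1] <- 1
  u
}

# Evolutionary algorithm: uniform random initial population (user start
# replacing one member), binary tournament selection, blend crossover,
# per-gene Gaussian mutation, generational replacement retaining the single
# best individual (weak elitism).
eo_minimize <- function(eval_f, d, s, u_start) {
  np <- s$pop_size
  pop <- matrix(runif(np * d), nrow = np)
  if (!is.null(u_start)) pop[1L, ] <- u_start
  fit <- apply(pop, 1L, eval_f)
  history <- hist_row(0L, fit)
  populations <- list(pop)
  # geometric annealing of the mutation scale across generations
  sig_of <- function(gen) {
    if (s$generations <= 1L) return(s$mutation_sigma)
    s$mutation_sigma *
      (s$mutation_sigma_final / s$mutation_sigma)^((gen - 1) / (s$generations - 1))
  }
  for (gen in seq_len(s$generations)) {
    sigma <- sig_of(gen)
    elite_i <- which.min(fit)
    elite_u <- pop[elite_i, ]; elite_f <- fit[elite_i]
    off <- matrix(0, nrow = np, ncol = d)
    for (k in seq(1L, np, by = 2L)) {
      p1 <- pop[tournament(fit, s$tournament_size), ]
      p2 <- pop[tournament(fit, s$tournament_size), ]
      ch <- blend_crossover(p1, p2, s$blend_alpha)
      off[k, ] <- ch[[1L]]
      if (k + 1L <= np) off[k + 1L, ] <- ch[[2L]]
    }
    mut <- matrix(runif(np * d) < s$mutation_rate, nrow = np)
    off <- off + mut * matrix(rnorm(np * d, sd = sigma), nrow = np)
    off <- clip01(off)
    off_f <- apply(off, 1L, eval_f)
    # weak elitism: the best parent replaces the worst offspring if it beats
    # the best offspring
    if (elite_f < min(off_f)) {
      wi <- which.max(off_f)
      off[wi, ] <- elite_u
      off_f[wi] <- elite_f
    }
    pop <- off; fit <- off_f
    history <- rbind(history, hist_row(gen, fit))
    populations[[length(populations) + 1L]] <- pop
  }
  bi <- which.min(fit)
  list(u_best = pop[bi, ], f_best = fit[bi], history = history,
       pop_u = pop, pop_f = fit, populations = populations)
}

tournament <- function(fit, size = 8L) {
  cand <- sample.int(length(fit), min(size, length(fit)))
  cand[which.min(fit[cand])]
}

blend_crossover <- function(p1, p2, alpha) {
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  ext <- alpha * (hi - lo)
  a <- lo - ext; bb <- hi + ext
  list(clip01(a + runif(length(p1)) * (bb - a)),
       clip01(a + runif(length(p1)) * (bb - a)))
}

# Canonical simulated annealing: single state, Gaussian proposals,
# Metropolis acceptance, geometric cooling every `dwell` evaluations from T0
# until Tf or the evaluation budget (generations * dwell) is exhausted.
sa_minimize <- function(eval_f, d, s, u_start) {
  u <- if (!is.null(u_start)) u_start else runif(d)
  f <- eval_f(u)
  u_best <- u; f_best <- f
  T <- s$sa$T0
  budget <- s$generations * s$sa$dwell
  history <- hist_row(0L, f)
  k <- 0L
  while (T > s$sa$Tf && k < budget) {
    block_f <- numeric(0)
    for (i in seq_len(s$sa$dwell)) {
      if (k >= budget) break
      # proposal scale shrinks with temperature so that late, cold phases
      # refine the optimum instead of re-sampling at the exploration scale
      prop <- clip01(u + rnorm(d, sd = s$mutation_sigma * sqrt(T / s$sa$T0)))
      fp <- eval_f(prop)
      k <- k + 1L
      if (fp <= f || runif(1) < exp(-(fp - f) / T)) {
        u <- prop; f <- fp
      }
      if (f < f_best) { u_best <- u; f_best <- f }
      block_f <- c(block_f, f)
    }
    T <- T * s$sa$cooling
    if (length(block_f))
      history <- rbind(history, hist_row(nrow(history), block_f))
  }
  list(u_best = u_best, f_best = f_best, history = history,
       pop_u = matrix(u_best, nrow = 1L), pop_f = f_best,
       populations = NULL)
}

# Downhill simplex from the start (or the unit-cube center), bounds enforced
# by clipping candidate points to the cube before evaluation.
nm_minimize <- function(eval_f, d, s, u_start) {
  u0 <- if (!is.null(u_start)) u_start else rep(0.5, d)
  best_trace <- numeric(0)
  f_wrap <- function(u) {
    f <- eval_f(clip01(u))
    best_trace <<- c(best_trace, f)
    f
  }
  ans <- optim(u0, f_wrap, method = "Nelder-Mead",
               control = list(maxit = s$nm$max_iter, reltol = s$nm$ftol))
  u_best <- clip01(ans$par)
  history <- data.frame(generation = seq_along(best_trace) - 1L,
                        best = cummin(best_trace), mean = best_trace,
                        median = best_trace, worst = best_trace)
  list(u_best = u_best, f_best = ans$value, history = history,
       pop_u = matrix(u_best, nrow = 1L), pop_f = ans$value,
       populations = NULL)
}

# Bound-constrained quasi-Newton (native box constraints, finite-difference
# gradients).
lbfgsb_minimize <- function(eval_f, d, s, u_start) {
  u0 <- if (!is.null(u_start)) u_start else rep(0.5, d)
  best_trace <- numeric(0)
  f_wrap <- function(u) {
    f <- eval_f(clip01(u))
    best_trace <<- c(best_trace, f)
    f
  }
  ans <- optim(u0, f_wrap, method = "L-BFGS-B", lower = 0, upper = 1,
               control = list(maxit = s$lbfgsb$max_iter,
                              factr = s$lbfgsb$accuracy / .Machine$double.eps,
                              ndeps = rep(1e-6, d)))
  history <- data.frame(generation = seq_along(best_trace) - 1L,
                        best = cummin(best_trace), mean = best_trace,
                        median = best_trace, worst = best_trace)
  list(u_best = ans$par, f_best = ans$value, history = history,
       pop_u = matrix(ans$par, nrow = 1L), pop_f = ans$value,
       populations = NULL)
}

#' Descriptive statistics of the final population
#'
#' @param final_population The `final_population` element of an
#'   [optimize_params()] result (or any list with a `fitness` vector), or a
#'   bare numeric vector of fitness values.
#' @return Named vector with `min`, `max`, `mean`, `median`, `std`.
#' @export
population_stats <- function(final_population) {
  f <- if (is.list(final_population)) final_population$fitness
       else final_population
  if (!length(f)) stop("empty population")
  c(min = min(f), max = max(f), mean = mean(f), median = median(f),
    std = if (length(f) > 1L) sd(f) else 0)
}

#' One-dimensional slices of the cost function around an optimum
#'
#' For each parameter, the objective is evaluated on `n_points` equally
#' spaced values spanning that parameter's range (endpoints included) while
#' all other parameters stay fixed at `best`, yielding the grid plot of the
#' cost landscape near the optimum.
#'
#' @param objective Function of a physical parameter vector.
#' @param best Physical optimum (within bounds).
#' @param bounds Two-column bounds matrix as in [optimizer_settings()].
#' @param n_points Number of grid points per dimension (>= 2).
#' @param ranges Optional two-column matrix overriding the scanned range per
#'   dimension (e.g. a narrower window around the optimum).
#' @return A list, one element per dimension, each with `grid` and `values`.
#' @export
grid_slices <- function(objective, best, bounds, n_points = 20L,
                        ranges = NULL) {
  b <- as_bounds(bounds)
  if (n_points < 2L) stop("'n_points' must be at least 2")
  r <- if (is.null(ranges)) b else as_bounds(ranges)
  out <- vector("list", nrow(b))
  for (j in seq_len(nrow(b))) {
    grid <- seq(r[j, 1L], r[j, 2L], length.out = n_points)
    vals <- vapply(grid, function(g) {
      x <- best; x[j] <- g; objective(x)
    }, numeric(1))
    out[[j]] <- list(grid = grid, values = vals)
  }
  names(out) <- rownames(b)
  out
}
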