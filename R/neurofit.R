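#' Fit neuronal model parameters to a target trace set
#'
#' The central fitting function: it aligns the target with the model
#' sampling grid, builds the objective (the weighted cost of
#' [combine_features()] between simulated and target trace sets over
#' normalized parameters), minimizes it with the requested bound-constrained
#' algorithm, and returns a fitted-model object with the usual accessor
#' methods (`print`, `summary`, `coef`, `plot`, `fitted`, `residuals`,
#' `simulate`, `predict`).
#'
#' If the target is sampled faster than the model step, the simulation step
#' is adjusted to the target's; if slower, the target is linearly re-sampled
#' onto the model grid and the re-sampled set is the target from then on.
#'
#' @param target An [nf_trace_set()] of target traces (canonical units).
#' @param backend A backend contract from [get_backend()].
#' @param parameters List of [parameter_spec()] objects (order defines the
#'   parameter vector).
#' @param protocol A [protocol_spec()].
#' @param cost An [cost_spec()].
#' @param optimizer Named list of [optimizer_settings()] arguments
#'   (`algorithm`, `seed`, `pop_size`, `generations`, ...); bounds are taken
#'   from `parameters`. If every parameter carries an `initial` value the
#'   vector of initials is used as the optimizer start unless a `start` is
#'   given explicitly.
#' @param user_mapping Optional function mapping the abstract optimized
#'   parameter vector to the backend's parameters (e.g. one specific
#'   membrane resistance controlling many local conductances); the identity
#'   by default.
#' @return An object of class `neurofit`.
#' @examples
#' \donttest{
#' sur <- make_surrogate(surrogate_case("uc2_synapse_vc"))
#' fit <- neurofit(sur$target, get_backend("synaptic_vc",
#'                                         sur$config$backend$fixed),
#'                 sur$config$parameters, sur$config$protocol,
#'                 sur$config$cost,
#'                 optimizer = list(algorithm = "EO", seed = 1,
#'                                  pop_size = 30, generations = 10))
#' coef(fit)
#' }
#' @export
neurofit <- function(target, backend, parameters, protocol, cost,
                     optimizer = list(algorithm = "EO", seed = 1L),
                     user_mapping = NULL) {
  stopifnot(inherits(target, "nf_trace_set"),
            inherits(protocol, "nf_protocol"),
            inherits(cost, "nf_cost_spec"))
  al <- align_sampling(target, protocol$dt)
  target <- al$target
  protocol$dt <- al$effective_dt

  nms <- vapply(parameters, `[[`, character(1), "name")
  bounds <- cbind(vapply(parameters, `[[`, numeric(1), "lower"),
                  vapply(parameters, `[[`, numeric(1), "upper"))
  rownames(bounds) <- nms
  inits <- lapply(parameters, `[[`, "initial")
  if (is.null(optimizer$start) && !any(vapply(inits, is.null, logical(1))))
    optimizer$start <- unlist(inits)

  map <- if (is.null(user_mapping)) identity else user_mapping
  objective_x <- function(x) {
    p <- map(setNames(x, nms))
    sim <- backend$simulate(p, protocol)
    combine_features(cost, sim, target)$total
  }
  objective_u <- function(u) objective_x(denormalize_params(u, bounds))

  settings <- do.call(optimizer_settings,
                      c(list(bounds = bounds), optimizer))
  res <- optimize_params(objective_u, settings)

  best_p <- map(setNames(res$best_params, nms))
  best_sim <- backend$simulate(best_p, protocol)
  breakdown <- combine_features(cost, best_sim, target)

  structure(list(best_params = setNames(res$best_params, nms),
                 best_fitness = res$best_fitness,
                 per_feature = breakdown$per_feature,
                 weights = breakdown$weights,
                 history = res$history,
                 final_population = res$final_population,
                 populations = res$populations,
                 seed = res$seed, algorithm = res$algorithm,
                 n_evaluations = res$n_evaluations,
                 target = target, best_sim = best_sim,
                 backend = backend, protocol = protocol, cost = cost,
                 parameters = parameters, bounds = bounds,
                 user_mapping = user_mapping,
                 objective = objective_x),
            class = "neurofit")
}

#' @export
print.neurofit <- function(x, digits = 6, ...) {
  cat("Neuronal model fit (", x$backend$id, " backend, ", x$algorithm,
      " optimizer)\n", sep = "")
  cat(sprintf("  %d traces, %d evaluations, seed %d\n",
              length(x$target), x$n_evaluations, x$seed))
  cat(sprintf("  best fitness: %.*g\n", digits, x$best_fitness))
  cat("  best parameters:\n")
  print(signif(x$best_params, digits))
  invisible(x)
}

#' @export
summary.neurofit <- function(object, ...) {
  structure(list(fit = object,
                 pop_stats = population_stats(object$final_population),
                 raw_mse = raw_mse(object)),
            class = "summary.neurofit")
}

#' @export
print.summary.neurofit <- function(x, digits = 6, ...) {
  print(x$fit, digits = digits)
  cat("  weighted per-feature breakdown:\n")
  br <- x$fit$weights * x$fit$per_feature
  for (f in names(br))
    cat(sprintf("    %-18s %.*g (weight %.3g, raw %.*g)\n", f, digits,
                br[[f]], x$fit$weights[[f]], digits, x$fit$per_feature[[f]]))
  cat(sprintf("  raw mean squared error: %.*g %s\n", digits, x$raw_mse,
              if (x$fit$target$traces[[1L]]$kind == "voltage") "mV^2" else "nA^2"))
  cat("  final population fitness:\n")
  print(signif(x$pop_stats, digits))
  invisible(x)
}

#' @export
coef.neurofit <- function(object, ...) object$best_params

#' @export
fitted.neurofit <- function(object, ...) object$best_sim

#' Residual traces of a fit
#'
#' @param object A [neurofit()] object.
#' @param ... Unused.
#' @return A matrix with one column per trace pair: best simulated minus
#'   target samples.
#' @export
residuals.neurofit <- function(object, ...) {
  vapply(seq_along(object$target$traces), function(i)
    object$best_sim$traces[[i]]$values - object$target$traces[[i]]$values,
    numeric(length(object$target$traces[[1L]]$values)))
}

# plain (unnormalized) mean squared error between best trace set and target,
# averaged over samples and traces, in squared canonical units
raw_mse <- function(fit) {
  r <- residuals.neurofit(fit)
  mean(r^2)
}

#' Simulate from a fitted model
#'
#' Runs the fit's backend under the fit's protocol, at the fitted parameters
#' by default or at a user-supplied parameter vector.
#'
#' @param object A [neurofit()] object.
#' @param nsim,seed Ignored (the backends are deterministic).
#' @param params Optional named parameter vector overriding the fit.
#' @param ... Unused.
#' @return An [nf_trace_set()].
#' @export
simulate.neurofit <- function(object, nsim = 1, seed = NULL,
                              params = coef(object), ...) {
  map <- if (is.null(object$user_mapping)) identity else object$user_mapping
  object$backend$simulate(map(params), object$protocol)
}

#' @export
predict.neurofit <- function(object, params = coef(object), ...)
  simulate.neurofit(object, params = params)

#' Plot a fitted model
#'
#' `type = "fit"` overlays target and best traces (concatenated for
#' display when there are several); `type = "generations"` shows the
#' evolution of the best/mean/worst cost across generations;
#' `type = "alleles"` shows each normalized parameter's population spread
#' per generation (evolutionary algorithm only); `type = "slices"`
#' draws one-dimensional slices of the cost around the optimum.
#'
#' @param x A [neurofit()] object.
#' @param type One of `"fit"`, `"generations"`, `"alleles"`, `"slices"`.
#' @param n_points Grid points per parameter for `type = "slices"`.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.neurofit <- function(x, type = c("fit", "generations", "alleles",
                                      "slices"),
                          n_points = 15L, ...) {
  type <- match.arg(type)
  if (type == "fit") {
    tgt <- unlist(lapply(x$target$traces, `[[`, "values"))
    sim <- unlist(lapply(x$best_sim$traces, `[[`, "values"))
    dt <- x$target$traces[[1L]]$dt
    tt <- (seq_along(tgt) - 1) * dt
    unit <- if (x$target$traces[[1L]]$kind == "voltage") "mV" else "nA"
    plot(tt, tgt, type = "l", col = "blue", xlab = "time (ms)",
         ylab = paste0("recorded variable (", unit, ")"),
         main = "target vs. best fit", ...)
    lines(tt, sim, col = "red")
    legend("topright", legend = c("target", "best fit"),
           col = c("blue", "red"), lty = 1, bty = "n")
  } else if (type == "generations") {
    h <- x$history
    plot(h$generation, h$best, type = "l", col = "red", log = "y",
         xlab = "generation", ylab = "cost",
         ylim = range(c(h$best[h$best > 0], h$worst)),
         main = "cost across generations", ...)
    lines(h$generation, h$mean, col = "grey40")
    lines(h$generation, h$worst, col = "grey70")
    legend("topright", legend = c("best", "mean", "worst"),
           col = c("red", "grey40", "grey70"), lty = 1, bty = "n")
  } else if (type == "alleles") {
    if (is.null(x$populations))
      stop("allele plot is available for the evolutionary algorithm only")
    d <- ncol(x$populations[[1L]])
    means <- t(vapply(x$populations, colMeans, numeric(d)))
    matplot(seq_len(nrow(means)) - 1L, means, type = "l", lty = 1,
            xlab = "generation", ylab = "mean normalized value",
            ylim = c(0, 1), main = "allele means", ...)
    legend("topright", legend = rownames(x$bounds), col = seq_len(d),
           lty = 1, bty = "n")
  } else {
    sl <- grid_slices(x$objective, x$best_params, x$bounds, n_points)
    old <- par(mfrow = c(1, length(sl)))
    on.exit(par(old))
    for (j in seq_along(sl)) {
      plot(sl[[j]]$grid, sl[[j]]$values, type = "b",
           xlab = rownames(x$bounds)[j], ylab = "cost", ...)
      abline(v = x$best_params[j], col = "red", lty = 2)
    }
  }
  invisible(x)
}

#' Run a complete fitting session from a configuration
#'
#' Loads the target data, builds the backend and objective, runs the
#' optimization, and writes the result artifacts into the output directory:
#' the best trace set as a text file (`best_trace.txt`), a target-vs-best
#' figure (`fit.png`, and `fit.eps` when `eps = TRUE`), an HTML report
#' (`report.html`), the reproducing configuration (`config_saved.xml`) and a
#' machine-readable summary (`result.txt`, `key = value` lines).
#'
#' @param config An [session_config()], or the path of an XML config file.
#' @param seed,generations,output_dir Optional overrides of the
#'   corresponding configuration entries (so that a saved configuration can
#'   be re-run scaled down without editing the XML).
#' @param eps Also write an EPS figure.
#' @param artifacts Set to `FALSE` to skip writing artifacts.
#' @return The [neurofit()] object, with the artifact paths in
#'   `attr(, "artifacts")`.
#' @export
run_session <- function(config, seed = NULL, generations = NULL,
                        output_dir = NULL, eps = FALSE, artifacts = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "nf_config"))
  if (!is.null(seed)) config$optimizer$seed <- as.integer(seed)
  if (!is.null(generations)) config$optimizer$generations <- as.integer(generations)
  if (!is.null(output_dir)) config$output_dir <- output_dir

  kind <- config$data$kind
  target <- read_traces(config$data$path, kind, config$data$unit,
                        config$data$dt, config$data$n_traces)
  user_mapping <- NULL
  if (!is.null(config$backend$user_fun)) {
    env <- new.env(parent = globalenv())
    sys.source(config$backend$user_fun, envir = env)
    if (!exists("user_mapping", envir = env, inherits = FALSE))
      stop("user function file must define 'user_mapping'")
    user_mapping <- get("user_mapping", envir = env)
  }
  fixed <- config$backend$fixed
  if (config$backend$id == "external") {
    fixed$command <- config$backend$command
    fixed$param_names <- vapply(config$parameters, `[[`, character(1), "name")
  }
  backend <- get_backend(config$backend$id, if (is.null(fixed)) list() else fixed)

  fit <- neurofit(target, backend, config$parameters, config$protocol,
                  config$cost, config$optimizer, user_mapping)
  if (!artifacts) return(fit)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_artifacts(fit, config, eps = eps)
  attr(fit, "artifacts") <- paths
  fit
}
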