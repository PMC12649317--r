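# Shifted-and-rotated multimodal benchmark functions with self-generated
# instances, following the CEC-2017 conventions: search domain [-100, 100]^D,
# a shift vector o drawn inside the domain, an orthogonal rotation M, and a
# constant bias added so that the global minimum value is the bias.

#' Generate a shifted/rotated benchmark instance
#'
#' Creates one seeded instance of a multimodal test function: the shifted and
#' rotated Rastrigin function (`"F5"`, bias 500) or the shifted and rotated
#' Lunacek bi-Rastrigin function (`"F7"`, bias 700). The shift vector is drawn
#' uniformly from the inner 80\% of the `[-100, 100]^D` search domain and the
#' rotation matrix is a Haar-distributed orthogonal matrix obtained from the
#' QR decomposition of a standard-normal matrix. Instances are deterministic
#' given `(fun, D, seed)`.
#'
#' Hybrid and composition functions (`F16`, `F20`, `F26`, `F29`) are not
#' formula-defined in a self-contained way and are rejected.
#'
#' @param fun Function id, `"F5"` or `"F7"`.
#' @param D Problem dimension (positive integer).
#' @param seed Integer seed controlling the shift and rotation.
#' @return An object of class `bench_instance` with fields `fun`, `D`,
#'   `shift`, `rot`, `bias`, `lower`, `upper`, `shrink`, `seed`.
#' @seealso [bench_evaluate()], [run_trials()]
#' @examples
#' inst <- bench_instance("F5", D = 10, seed = 1)
#' bench_evaluate(inst, inst$shift)  # 500, the global minimum value
#' @export
bench_instance <- function(fun, D, seed) {
  if (fun %in% c("F16", "F20", "F26", "F29")) {
    stop("function '", fun, "' is a hybrid/composition function and is out ",
         "of scope; only the formula-defined functions F5 and F7 are supported",
         call. = FALSE)
  }
  fun <- match.arg(fun, c("F5", "F7"))
  stopifnot(is.numeric(D), length(D) == 1L, D >= 1, D == round(D))
  if (fun == "F7" && D < 2) {
    stop("F7 requires D >= 2: the depth constant s = 1 - 1/(2*sqrt(D+20) - ",
         "8.2) of the Lunacek bi-Rastrigin function is non-positive at D = 1",
         call. = FALSE)
  }
  D <- as.integer(D)
  lower <- -100
  upper <- 100
  gen <- with_seed(seed, {
    shift <- stats::runif(D, 0.8 * lower, 0.8 * upper)
    rot <- random_orthogonal(D)
    list(shift = shift, rot = rot)
  })
  structure(
    list(fun = fun, D = D, shift = gen$shift, rot = gen$rot,
         bias = if (fun == "F5") 500 else 700,
         lower = lower, upper = upper,
         shrink = if (fun == "F5") 5.12 / 100 else 10 / 100,
         seed = as.integer(seed)),
    class = "bench_instance")
}

# Haar-distributed random orthogonal matrix (QR of a Ginibre matrix with the
# sign of R's diagonal fixed).
random_orthogonal <- function(D) {
  A <- matrix(stats::rnorm(D * D), D, D)
  qr_dec <- qr(A)
  Q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  d[d == 0] <- 1
  Q * rep(d, each = D)
}

#' Evaluate a benchmark instance
#'
#' Computes the shifted/rotated/biased objective value at `x`. For `"F5"` the
#' base function is Rastrigin, \eqn{\sum_i (z_i^2 - 10\cos(2\pi z_i) + 10)},
#' applied to \eqn{z = M\,(s\,(x - o))} with scale factor \eqn{s = 5.12/100}.
#' For `"F7"` the base function is the Lunacek bi-Rastrigin function in its
#' standard CEC form: \eqn{y = 10(x - o)/100},
#' \eqn{\hat x_i = 2\,\mathrm{sign}(o_i)\,y_i + \mu_0},
#' \eqn{z = \Lambda^{100} M (\hat x - \mu_0)} with the ill-conditioning
#' diagonal \eqn{\Lambda^{100}_{ii} = 100^{(i-1)/(2(D-1))}}, constants
#' \eqn{\mu_0 = 2.5}, \eqn{d = 1}, \eqn{s = 1 - 1/(2\sqrt{D + 20} - 8.2)},
#' \eqn{\mu_1 = -\sqrt{(\mu_0^2 - d)/s}}, and value
#' \eqn{\min(\sum_i (\hat x_i - \mu_0)^2,\; dD + s\sum_i (\hat x_i - \mu_1)^2)
#' + 10(D - \sum_i \cos 2\pi z_i)}. In both cases `x = o` is the global
#' minimizer and `bench_evaluate(inst, inst$shift)` equals the bias.
#'
#' @param instance A `bench_instance`.
#' @param x Numeric vector of length `instance$D`.
#' @return The objective value (never below `instance$bias`).
#' @export
bench_evaluate <- function(instance, x) {
  stopifnot(inherits(instance, "bench_instance"))
  if (length(x) != instance$D) {
    stop("x has length ", length(x), " but the instance has dimension ",
         instance$D, call. = FALSE)
  }
  switch(instance$fun,
         F5 = eval_f5(instance, x),
         F7 = eval_f7(instance, x))
}

rastrigin_base <- function(z) sum(z^2 - 10 * cos(2 * pi * z) + 10)

eval_f5 <- function(instance, x) {
  z <- drop(instance$rot %*% (instance$shrink * (x - instance$shift)))
  instance$bias + rastrigin_base(z)
}

eval_f7 <- function(instance, x) {
  D <- instance$D
  mu0 <- 2.5
  d <- 1
  s <- 1 - 1 / (2 * sqrt(D + 20) - 8.2)
  mu1 <- -sqrt((mu0^2 - d) / s)
  y <- instance$shrink * (x - instance$shift)
  sg <- sign(instance$shift)
  sg[sg == 0] <- 1
  xhat <- 2 * sg * y + mu0
  lam <- if (D > 1) 100^((seq_len(D) - 1) / (2 * (D - 1))) else 1
  z <- lam * drop(instance$rot %*% (xhat - mu0))
  bowl <- min(sum((xhat - mu0)^2), d * D + s * sum((xhat - mu1)^2))
  instance$bias + bowl + 10 * (D - sum(cos(2 * pi * z)))
}

#' @export
print.bench_instance <- function(x, ...) {
  cat(sprintf("<bench_instance %s  D = %d  bias = %g  seed = %d>\n",
              x$fun, x$D, x$bias, x$seed))
  invisible(x)
}

#' Repeated independent optimization trials on a benchmark function
#'
#' Runs one optimizer `n_trials` times on freshly generated instances of a
#' benchmark function and collects per-trial best values and convergence
#' curves. Each trial uses its own instance seed and optimizer seed, both
#' derived deterministically from `seed`, so two calls with the same master
#' seed (for different strategies) are paired trial by trial: same instances,
#' same optimizer sub-seeds.
#'
#' @param strategy Optimizer strategy; see [optimizer_config()].
#' @param fun Benchmark function id (`"F5"` or `"F7"`).
#' @param D Dimension.
#' @param n_trials Number of independent trials.
#' @param N Population (or swarm) size.
#' @param G Maximum number of iterations.
#' @param seed Master seed.
#' @param ... Further arguments passed to [optimizer_config()].
#' @return A `trial_stats` object: `best_values` (length `n_trials`), their
#'   `mean` and sample standard deviation `sd`, and `curves`, an
#'   `n_trials` x `(G + 1)` matrix of best-so-far values.
#' @examples
#' st <- run_trials("de_improved", "F5", D = 2, n_trials = 3, G = 10, seed = 1)
#' st$mean
#' @export
run_trials <- function(strategy, fun = "F5", D = 10, n_trials = 30,
                       N = 20, G = 25, seed = 1, ...) {
  stopifnot(n_trials >= 1)
  subseeds <- derive_subseeds(seed, 2L * n_trials)
  best_values <- numeric(n_trials)
  curves <- matrix(NA_real_, n_trials, G + 1L)
  for (t in seq_len(n_trials)) {
    inst <- bench_instance(fun, D, subseeds[2L * t - 1L])
    cfg <- optimizer_config(strategy = strategy, D = D,
                            lower = inst$lower, upper = inst$upper,
                            N = N, G = G, seed = subseeds[2L * t], ...)
    res <- tryCatch(
      run_optimizer(function(x) bench_evaluate(inst, x), cfg),
      error = function(e) stop("trial ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    best_values[t] <- res$value
    curves[t, ] <- res$curve
  }
  structure(
    list(strategy = strategy, fun = fun, D = D, n_trials = n_trials,
         N = N, G = G, seed = seed,
         best_values = best_values,
         mean = mean(best_values),
         sd = if (n_trials > 1) stats::sd(best_values) else 0,
         curves = curves),
    class = "trial_stats")
}

#' @export
print.trial_stats <- function(x, ...) {
  cat(sprintf("<trial_stats %s on %s  D = %d  N = %d  G = %d>\n",
              x$strategy, x$fun, x$D, x$N, x$G))
  cat(sprintf("  %d trials: mean best = %.4f  sd = %.4f\n",
              x$n_trials, x$mean, x$sd))
  invisible(x)
}

#' Export trial statistics as data frames or CSV
#'
#' `trials_table()` returns one row per trial (strategy, function, master
#' seed, trial index, best value); `curves_table()` returns the convergence
#' curves in long format (trial, generation, best-so-far). The `write_*`
#' variants write them as CSV.
#'
#' @param stats A `trial_stats` object.
#' @param file Output path.
#' @return A data frame (invisibly for the writers).
#' @export
trials_table <- function(stats) {
  stopifnot(inherits(stats, "trial_stats"))
  data.frame(algorithm = stats$strategy, fun = stats$fun,
             seed = stats$seed, trial = seq_len(stats$n_trials),
             best_value = stats$best_values)
}

#' @rdname trials_table
#' @export
curves_table <- function(stats) {
  stopifnot(inherits(stats, "trial_stats"))
  G1 <- ncol(stats$curves)
  data.frame(algorithm = stats$strategy, fun = stats$fun,
             trial = rep(seq_len(stats$n_trials), each = G1),
             generation = rep(seq_len(G1) - 1L, stats$n_trials),
             best_so_far = as.vector(t(stats$curves)))
}

#' @rdname trials_table
#' @export
write_trials_csv <- function(stats, file) {
  df <- trials_table(stats)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname trials_table
#' @export
write_curves_csv <- function(stats, file) {
  df <- curves_table(stats)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
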