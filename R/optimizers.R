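# Differential evolution (classic strategies and the subpopulation-ranked
# improved variant) and standard PSO, sharing one population/evaluation
# contract. All optimizers minimize; callers negate for maximization.
#
# RNG contract: each run draws every random number from R's global generator,
# seeded once from config$seed (when non-NULL) at the start of the run, in a
# fixed documented order: initialization row by row; then per generation, per
# individual: donor indices, then any per-mutant factor draw, then the
# crossover draws (forced index first, then the D uniforms). The improved DE
# assigns subpopulations by fitness rank without consuming randomness, so a
# degenerate configuration (all-middle partition, alpha3 = 0, alpha2 = F,
# F2 = lambda) reproduces DE/rand-to-best/1/bin draw for draw.

#' Optimizer configuration
#'
#' Collects every constant an optimizer run needs. Defaults for the improved
#' differential evolution follow the published setting: `alpha1 = 1`,
#' `F2 = 0.4`, `alpha2 = alpha3 = 0.3`, `CR = 0.75`, with subpopulation
#' ratios 2:5:3 (early), 4:4:2 (middle) and 6:3:1 (late stage of the
#' iteration process). The classic-DE mutation factor `F` defaults to 0.5 and
#' the rand-to-best weight `lambda` to 0.5 (mid-range conventional values;
#' no published values exist for the classic runs). PSO uses the standard
#' linearly decreasing inertia weight 0.9 to 0.4 with `c1 = c2 = 2`.
#'
#' @param strategy One of `"de_rand_1"`, `"de_best_1"`, `"de_rand_to_best_1"`,
#'   `"de_improved"`, `"pso"`.
#' @param D Dimension of the decision vector.
#' @param lower,upper Per-coordinate bounds (recycled to length `D`).
#' @param N Population size. The improved DE requires `N >= 5` so every
#'   stage ratio can produce non-empty subpopulations.
#' @param G Maximum number of iterations.
#' @param F Classic mutation factor in `[0, 2]`.
#' @param CR Crossover probability in `[0, 1]`.
#' @param lambda Best-attraction weight of the rand-to-best strategy.
#' @param alpha1,alpha2,alpha3,F2 Improved-DE factor constants: the elite
#'   factor is `F1 = alpha1 * u * (1 - g/G)^2` with `u` uniform, re-drawn per
#'   mutant; the middle-subpopulation factors are the constant `F2` and the
#'   schedule `F3 = alpha2 + alpha3 * (1 - sqrt(g/G))`.
#' @param stage_ratios 3 x 3 matrix of `ELS:MIS:INS` fractions per stage
#'   (rows early/middle/late, each summing to 1). Override only for
#'   controlled experiments.
#' @param pso_w_start,pso_w_end Inertia weight at `g = 0` and `g = G`.
#' @param pso_c1,pso_c2 Cognitive and social acceleration constants.
#' @param pso_vmax_frac Velocity clamp as a fraction of each coordinate range.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(strategy = c("de_improved", "de_rand_1",
                                          "de_best_1", "de_rand_to_best_1",
                                          "pso"),
                             D, lower, upper, N = 20L, G = 25L,
                             F = 0.5, CR = 0.75, lambda = 0.5,
                             alpha1 = 1, alpha2 = 0.3, alpha3 = 0.3, F2 = 0.4,
                             stage_ratios = default_stage_ratios(),
                             pso_w_start = 0.9, pso_w_end = 0.4,
                             pso_c1 = 2, pso_c2 = 2, pso_vmax_frac = 0.2,
                             seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(D >= 1, D == round(D), N >= 4, G >= 1, CR >= 0, CR <= 1)
  lower <- rep_len(as.numeric(lower), D)
  upper <- rep_len(as.numeric(upper), D)
  if (any(lower > upper)) stop("lower bound exceeds upper bound", call. = FALSE)
  if (strategy == "de_improved" && N < 5) {
    stop("the improved DE requires N >= 5", call. = FALSE)
  }
  stage_ratios <- as.matrix(stage_ratios)
  stopifnot(dim(stage_ratios) == c(3L, 3L), all(stage_ratios >= 0),
            all(abs(rowSums(stage_ratios) - 1) < 1e-12))
  structure(
    list(strategy = strategy, D = as.integer(D),
         lower = lower, upper = upper,
         N = as.integer(N), G = as.integer(G),
         F = F, CR = CR, lambda = lambda,
         alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, F2 = F2,
         stage_ratios = stage_ratios,
         pso_w_start = pso_w_start, pso_w_end = pso_w_end,
         pso_c1 = pso_c1, pso_c2 = pso_c2, pso_vmax_frac = pso_vmax_frac,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "optimizer_config")
}

default_stage_ratios <- function() {
  m <- rbind(early  = c(2, 5, 3),
             middle = c(4, 4, 2),
             late   = c(6, 3, 1)) / 10
  colnames(m) <- c("els", "mis", "ins")
  m
}

#' @export
print.optimizer_config <- function(x, ...) {
  cat(sprintf("<optimizer_config %s  D = %d  N = %d  G = %d>\n",
              x$strategy, x$D, x$N, x$G))
  invisible(x)
}

#' Random population initialization within box bounds
#'
#' Draws `x[i, j] = lower[j] + u * (upper[j] - lower[j])` with `u` uniform on
#' `[0, 1]`, independently for every individual and coordinate, and evaluates
#' all members.
#'
#' @param objective Function mapping a length-`D` numeric vector to a scalar.
#' @param config An [optimizer_config()].
#' @return List with `X` (`N` x `D` matrix) and `fitness` (length `N`).
#' @export
initialize_population <- function(objective, config) {
  N <- config$N; D <- config$D
  X <- matrix(NA_real_, N, D)
  for (i in seq_len(N)) {
    X[i, ] <- config$lower + stats::runif(D) * (config$upper - config$lower)
  }
  fitness <- apply(X, 1L, objective)
  list(X = X, fitness = fitness)
}

#' Rank-based subpopulation partition
#'
#' Assigns every individual to the elite (ELS), middle (MIS) or inferior
#' (INS) subpopulation by its ascending-fitness rank. The stage is chosen by
#' real-valued comparison of the generation counter: early when `g <= G/3`,
#' middle when `G/3 < g <= 2G/3`, late when `g > 2G/3`, with size ratios
#' 2:5:3, 4:4:2 and 6:3:1. Sizes are `|ELS| = round(r_E N)`,
#' `|INS| = round(r_I N)`, `|MIS| = N - |ELS| - |INS|`; when `N >= 10` and a
#' subpopulation with a positive target ratio rounds to empty, one member is
#' moved from the largest set. Individuals keep their original indices; the
#' partition consumes no randomness.
#'
#' @param fitness Numeric vector of current fitness values (lower is better).
#' @param g Current generation (0-based).
#' @param G Maximum number of iterations.
#' @param stage_ratios Ratio matrix as in [optimizer_config()].
#' @return List with integer index vectors `els`, `mis`, `ins`, the `stage`
#'   label, and `sizes` (named length-3 integer vector).
#' @export
stage_partition <- function(fitness, g, G,
                            stage_ratios = default_stage_ratios()) {
  N <- length(fitness)
  stage <- if (g <= G / 3) "early" else if (g <= 2 * G / 3) "middle" else "late"
  r <- stage_ratios[match(stage, c("early", "middle", "late")), ]
  n_els <- round(r[[1L]] * N)
  n_ins <- round(r[[3L]] * N)
  n_mis <- N - n_els - n_ins
  sizes <- c(els = n_els, mis = n_mis, ins = n_ins)
  if (N >= 10) {
    for (k in 1:3) {
      if (r[k] > 0 && sizes[k] == 0) {
        donor <- which.max(sizes)
        sizes[donor] <- sizes[donor] - 1L
        sizes[k] <- 1L
      }
    }
  }
  stopifnot(sum(sizes) == N, all(sizes >= 0))
  ord <- order(fitness)
  els <- ord[seq_len(sizes[1L])]
  mis <- ord[seq_len(sizes[2L]) + sizes[1L]]
  ins <- ord[seq_len(sizes[3L]) + sizes[1L] + sizes[2L]]
  list(els = els, mis = mis, ins = ins, stage = stage,
       sizes = as.integer(sizes))
}

#' Adaptive mutation factors of the improved DE
#'
#' The elite factor decays quadratically with a fresh uniform draw,
#' `F1 = alpha1 * u * (1 - g/G)^2`; the middle-subpopulation difference
#' factor follows the deterministic square-root schedule
#' `F3 = alpha2 + alpha3 * (1 - sqrt(g/G))`. During an optimizer run `F1` is
#' re-sampled for every elite mutant.
#'
#' @param g Current generation (0-based), `0 <= g <= G`.
#' @param G Maximum number of iterations (`G > 0`).
#' @param alpha1,alpha2,alpha3 Schedule constants.
#' @return List with components `F1` (random) and `F3` (deterministic).
#' @export
mutation_factors <- function(g, G, alpha1 = 1, alpha2 = 0.3, alpha3 = 0.3) {
  if (G <= 0) stop("G must be positive", call. = FALSE)
  stopifnot(g >= 0, g <= G)
  list(F1 = alpha1 * stats::runif(1L) * (1 - g / G)^2,
       F3 = alpha2 + alpha3 * (1 - sqrt(g / G)))
}

# n distinct indices from 1..N excluding `exclude`, via the global RNG.
draw_indices <- function(n, N, exclude) {
  avail <- setdiff(seq_len(N), exclude)
  if (length(avail) < n) {
    stop("population too small to draw ", n, " distinct donor indices",
         call. = FALSE)
  }
  avail[sample.int(length(avail), n)]
}

#' Binomial (uniform) crossover
#'
#' Builds the trial vector coordinate by coordinate: the mutant value is
#' inherited when a uniform draw is at most `CR` or the coordinate equals a
#' forced index drawn uniformly from `1..D`, so at least one coordinate
#' always comes from the mutant. Draw order: forced index first, then the
#' `D` uniforms.
#'
#' @param target,mutant Numeric vectors of equal length.
#' @param CR Crossover probability in `[0, 1]`.
#' @return The trial vector.
#' @export
crossover_binomial <- function(target, mutant, CR) {
  stopifnot(length(target) == length(mutant))
  D <- length(target)
  forced <- sample.int(D, 1L)
  take <- stats::runif(D) <= CR
  take[forced] <- TRUE
  ifelse(take, mutant, target)
}

#' Clip a vector to box bounds
#'
#' Coordinates above the upper bound are set to the upper bound, coordinates
#' below the lower bound to the lower bound.
#'
#' @param v Numeric vector.
#' @param lower,upper Bounds (recycled).
#' @return The clipped vector.
#' @export
clip_to_bounds <- function(v, lower, upper) {
  pmin(pmax(v, lower), upper)
}

#' Greedy one-to-one selection
#'
#' The trial replaces the target only on strict improvement; ties keep the
#' target. A non-finite fitness on one side loses automatically; non-finite
#' fitness on both sides is an error.
#'
#' @param f_target,f_trial Fitness values of target and trial.
#' @return `TRUE` when the trial survives.
#' @export
select_greedy <- function(f_target, f_trial) {
  t_ok <- is.finite(f_target); u_ok <- is.finite(f_trial)
  if (!t_ok && !u_ok) stop("both fitness values are non-finite", call. = FALSE)
  if (!u_ok) return(FALSE)
  if (!t_ok) return(TRUE)
  f_trial < f_target
}

# One mutant vector for individual i under the configured strategy.
make_mutant <- function(X, fitness, i, best, g, config, part) {
  N <- config$N
  switch(config$strategy,
    de_rand_1 = {
      r <- draw_indices(3L, N, i)
      X[r[1L], ] + config$F * (X[r[2L], ] - X[r[3L], ])
    },
    de_best_1 = {
      r <- draw_indices(2L, N, i)
      X[best, ] + config$F * (X[r[1L], ] - X[r[2L], ])
    },
    de_rand_to_best_1 = {
      r <- draw_indices(2L, N, i)
      X[i, ] + config$lambda * (X[best, ] - X[i, ]) +
        config$F * (X[r[1L], ] - X[r[2L], ])
    },
    de_improved = {
      if (i %in% part$els) {
        # elite: best/1 with the decaying random factor; donors exclude the
        # best index to keep the difference informative
        r <- draw_indices(2L, N, c(i, best))
        F1 <- config$alpha1 * stats::runif(1L) * (1 - g / config$G)^2
        X[best, ] + F1 * (X[r[1L], ] - X[r[2L], ])
      } else if (i %in% part$mis) {
        # middle: current-to-best with constant F2 and the F3 schedule
        r <- draw_indices(2L, N, i)
        F3 <- config$alpha2 + config$alpha3 * (1 - sqrt(g / config$G))
        X[i, ] + config$F2 * (X[best, ] - X[i, ]) +
          F3 * (X[r[1L], ] - X[r[2L], ])
      } else {
        # inferior: fresh uniform point inside the feasible region
        config$lower + stats::runif(config$D) * (config$upper - config$lower)
      }
    },
    stop("unsupported strategy: ", config$strategy, call. = FALSE))
}

#' Run a differential evolution optimizer
#'
#' Executes initialize, then per generation (and, for the improved variant,
#' after a rank-based subpopulation partition) mutate, binomial crossover,
#' boundary clipping and greedy selection, for `G` generations. The incumbent
#' best is refreshed after each generation's selection and is the reference
#' for all best-referencing mutation rules in the next generation.
#'
#' @param objective Scalar objective function of a length-`D` vector,
#'   minimized.
#' @param config An [optimizer_config()] with a DE strategy.
#' @return An `optim_result`: `par` (best vector found), `value` (its
#'   fitness), `curve` (best-so-far trace of length `G + 1`, starting after
#'   initialization), `evaluations`, `strategy`.
#' @examples
#' cfg <- optimizer_config("de_improved", D = 2, lower = -5, upper = 5,
#'                         N = 20, G = 25, seed = 1)
#' res <- run_de(function(x) sum(x^2), cfg)
#' res$value
#' @export
run_de <- function(objective, config) {
  stopifnot(inherits(config, "optimizer_config"))
  if (config$strategy == "pso") stop("use run_pso() for strategy 'pso'",
                                     call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(objective, config)
  X <- pop$X; fitness <- pop$fitness
  N <- config$N; G <- config$G
  evals <- N
  best <- which.min(fitness)
  curve <- numeric(G + 1L)
  curve[1L] <- fitness[best]
  improved <- config$strategy == "de_improved"
  for (g in seq_len(G) - 1L) {
    part <- if (improved) {
      stage_partition(fitness, g, G, config$stage_ratios)
    }
    newX <- X; newfit <- fitness
    for (i in seq_len(N)) {
      v <- make_mutant(X, fitness, i, best, g, config, part)
      u <- crossover_binomial(X[i, ], v, config$CR)
      u <- clip_to_bounds(u, config$lower, config$upper)
      fu <- tryCatch(objective(u), error = function(e) {
        stop("objective failed at generation ", g, ": ", conditionMessage(e),
             call. = FALSE)
      })
      evals <- evals + 1L
      if (select_greedy(fitness[i], fu)) {
        newX[i, ] <- u
        newfit[i] <- fu
      }
    }
    X <- newX; fitness <- newfit
    best <- which.min(fitness)
    curve[g + 2L] <- min(curve[g + 1L], fitness[best])
  }
  structure(
    list(par = X[best, ], value = fitness[best], curve = curve,
         evaluations = evals, strategy = config$strategy),
    class = "optim_result")
}

#' Linearly decreasing inertia weight
#'
#' @param g Current iteration (0-based).
#' @param G Maximum number of iterations.
#' @param w_start,w_end Weight at `g = 0` and `g = G`.
#' @return The inertia weight, 0.9 at the start and 0.4 at the end with the
#'   standard defaults.
#' @export
inertia_weight <- function(g, G, w_start = 0.9, w_end = 0.4) {
  w_start + (w_end - w_start) * g / G
}

#' Run standard global-best particle swarm optimization
#'
#' Velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' per-coordinate uniform `r1`, `r2`, inertia weight linearly decreasing from
#' `pso_w_start` to `pso_w_end`, velocities clamped to
#' `pso_vmax_frac * (upper - lower)` and positions clipped to bounds.
#' Velocities start at zero; personal and global bests are initialized from
#' the initial swarm.
#'
#' @inheritParams run_de
#' @return An `optim_result` (the curve traces the global best).
#' @export
run_pso <- function(objective, config) {
  stopifnot(inherits(config, "optimizer_config"), config$strategy == "pso")
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(objective, config)
  X <- pop$X; fitness <- pop$fitness
  N <- config$N; G <- config$G; D <- config$D
  evals <- N
  V <- matrix(0, N, D)
  vmax <- config$pso_vmax_frac * (config$upper - config$lower)
  pbest_x <- X
  pbest_f <- fitness
  gbest <- which.min(pbest_f)
  gbest_x <- pbest_x[gbest, ]
  gbest_f <- pbest_f[gbest]
  curve <- numeric(G + 1L)
  curve[1L] <- gbest_f
  for (g in seq_len(G) - 1L) {
    w <- inertia_weight(g, G, config$pso_w_start, config$pso_w_end)
    for (i in seq_len(N)) {
      r1 <- stats::runif(D); r2 <- stats::runif(D)
      V[i, ] <- w * V[i, ] +
        config$pso_c1 * r1 * (pbest_x[i, ] - X[i, ]) +
        config$pso_c2 * r2 * (gbest_x - X[i, ])
      V[i, ] <- clip_to_bounds(V[i, ], -vmax, vmax)
      X[i, ] <- clip_to_bounds(X[i, ] + V[i, ], config$lower, config$upper)
      f <- objective(X[i, ])
      evals <- evals + 1L
      if (f < pbest_f[i]) {
        pbest_f[i] <- f
        pbest_x[i, ] <- X[i, ]
        if (f < gbest_f) {
          gbest_f <- f
          gbest_x <- X[i, ]
        }
      }
    }
    curve[g + 2L] <- gbest_f
  }
  structure(
    list(par = gbest_x, value = gbest_f, curve = curve,
         evaluations = evals, strategy = "pso"),
    class = "optim_result")
}

#' Dispatch an optimizer run by configured strategy
#'
#' @inheritParams run_de
#' @return An `optim_result` from [run_de()] or [run_pso()].
#' @export
run_optimizer <- function(objective, config) {
  if (config$strategy == "pso") run_pso(objective, config)
  else run_de(objective, config)
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("<optim_result %s  best value = %.6g  evaluations = %d>\n",
              x$strategy, x$value, x$evaluations))
  invisible(x)
}
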