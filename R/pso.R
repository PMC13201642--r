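#' Swarm optimizer configuration
#'
#' Parameters of the inertia-weighted particle swarm: each particle keeps a
#' velocity updated as
#' `v' = theta * v + alpha * eps1 * (g* - x) + beta * eps2 * (x* - x)`,
#' with `eps1`, `eps2` uniform random vectors in `[0, 1]`, followed by a
#' per-component clamp to `[-v_max, v_max]` and the position update
#' `x' = x + v' * delta_t` with reflection at the search bounds.
#'
#' @param n_particles swarm size (>= 1).
#' @param alpha,beta acceleration coefficients toward the global and
#'   personal bests (default 2, the conventional choice).
#' @param theta constant inertia weight in `[0, 1]` (default 0.7).
#' @param v_max per-dimension speed cap (> 0); defaults to half the range
#'   of each bounded dimension.
#' @param delta_t time increment (default 1).
#' @param max_iter iteration budget.
#' @param tol relative global-best improvement below which an iteration
#'   counts as stagnant.
#' @param stall_iter consecutive stagnant iterations that stop the run
#'   (default 15).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param bounds 2 x d matrix (rows: lower, upper) or list of length-2
#'   vectors, one per dimension; lower < upper.
#' @return An object of class `wmh_swarm_config`.
#' @export
swarm_config <- function(n_particles = 30, alpha = 2, beta = 2, theta = 0.7,
                         v_max = NULL, delta_t = 1, max_iter = 100,
                         tol = 1e-8, stall_iter = 15, seed = NULL,
                         bounds) {
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]", call. = FALSE)
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2))
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(bounds[1, ] >= bounds[2, ]))
    stop("bounds must be a 2 x d matrix with lower < upper", call. = FALSE)
  if (is.null(v_max)) v_max <- (bounds[2, ] - bounds[1, ]) / 2
  v_max <- rep_len(as.numeric(v_max), ncol(bounds))
  if (any(v_max <= 0)) stop("v_max must be > 0", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles), alpha = alpha,
                 beta = beta, theta = theta, v_max = v_max,
                 delta_t = delta_t, max_iter = as.integer(max_iter),
                 tol = tol, stall_iter = as.integer(stall_iter),
                 seed = seed, bounds = bounds),
            class = "wmh_swarm_config")
}

#' Velocity update of one particle
#'
#' Inertia-weighted attraction toward the global and personal bests with
#' per-component clamping to `[-v_max, v_max]`. The random vectors can be
#' injected for deterministic testing; by default they are drawn uniformly
#' in `[0, 1]` per dimension.
#'
#' @param v current velocity.
#' @param x current position.
#' @param pbest particle's personal-best position.
#' @param gbest swarm's global-best position.
#' @param config a [swarm_config()].
#' @param eps1,eps2 optional random vectors in `[0, 1]`.
#' @return Clamped velocity vector.
#' @export
pso_velocity <- function(v, x, pbest, gbest, config, eps1 = NULL,
                         eps2 = NULL) {
  d <- length(x)
  if (is.null(eps1)) eps1 <- stats::runif(d)
  if (is.null(eps2)) eps2 <- stats::runif(d)
  vn <- config$theta * v + config$alpha * eps1 * (gbest - x) +
    config$beta * eps2 * (pbest - x)
  pmin(pmax(vn, -config$v_max), config$v_max)
}

#' Position update with boundary reflection
#'
#' `x' = x + v * delta_t`; components leaving the search box are reflected
#' back inside (`lo + (lo - x')` below, `hi - (x' - hi)` above, repeated
#' until feasible). Reflection keeps particles in the feasible region
#' without zeroing their velocity.
#'
#' @param x current position.
#' @param v velocity.
#' @param config a [swarm_config()].
#' @return New position inside the bounds.
#' @export
pso_step <- function(x, v, config) {
  xn <- x + v * config$delta_t
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  for (rep in 1:100) {
    below <- xn < lo; above <- xn > hi
    if (!any(below) && !any(above)) break
    xn[below] <- 2 * lo[below] - xn[below]
    xn[above] <- 2 * hi[above] - xn[above]
  }
  pmin(pmax(xn, lo), hi)
}

#' Particle swarm optimization
#'
#' Minimizes `objective` over the configured box. Particles start uniformly
#' distributed over the bounds with zero initial velocity; iterations stop
#' at `max_iter` or after `stall_iter` consecutive iterations whose
#' relative global-best improvement is below `tol`. The global-best value
#' is monotone non-increasing and the whole trajectory is reproducible
#' under a fixed seed.
#'
#' @param objective function of a numeric vector returning a finite scalar.
#' @param config a [swarm_config()].
#' @return An object of class `wmh_pso`: list with `par` (best position),
#'   `value` (best objective), `history` (best value per iteration,
#'   including the initial evaluation), `iterations`, and `swarm` (final
#'   positions and personal bests).
#' @examples
#' cfg <- swarm_config(n_particles = 20, max_iter = 50, seed = 1,
#'                     bounds = matrix(c(-5, 5, -5, 5), 2))
#' fit <- pso_optimize(function(x) sum(x^2), cfg)
#' fit$value < 1e-2
#' @export
pso_optimize <- function(objective, config) {
  stopifnot(inherits(config, "wmh_swarm_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }
  d <- ncol(config$bounds)
  np <- config$n_particles
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  pos <- matrix(stats::runif(np * d), np, d)
  pos <- sweep(sweep(pos, 2, hi - lo, "*"), 2, lo, "+")
  vel <- matrix(0, np, d)

  eval_at <- function(x) {
    val <- objective(x)
    if (!is.finite(val))
      stop("objective is not finite at position (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    val
  }
  pvals <- apply(pos, 1, eval_at)
  pbest <- pos
  gi <- which.min(pvals)
  gbest <- pos[gi, ]; gval <- pvals[gi]
  history <- gval
  stall <- 0L
  iters <- 0L
  for (it in seq_len(config$max_iter)) {
    iters <- it
    for (p in seq_len(np)) {
      vel[p, ] <- pso_velocity(vel[p, ], pos[p, ], pbest[p, ], gbest, config)
      pos[p, ] <- pso_step(pos[p, ], vel[p, ], config)
      val <- eval_at(pos[p, ])
      if (val < pvals[p]) {
        pvals[p] <- val
        pbest[p, ] <- pos[p, ]
        if (val < gval) {
          gval <- val
          gbest <- pos[p, ]
        }
      }
    }
    improve <- (history[length(history)] - gval) /
      max(abs(history[length(history)]), .Machine$double.eps)
    history <- c(history, gval)
    stall <- if (improve < config$tol) stall + 1L else 0L
    if (stall >= config$stall_iter) break
  }
  structure(list(par = gbest, value = gval, history = history,
                 iterations = iters,
                 swarm = list(positions = pos, velocities = vel,
                              pbest = pbest, pbest_values = pvals)),
            class = "wmh_pso")
}

#' @export
print.wmh_pso <- function(x, ...) {
  cat(sprintf("<wmh_pso> best value %.6g after %d iterations\n",
              x$value, x$iterations))
  cat("  best position:", paste(signif(x$par, 6), collapse = ", "), "\n")
  invisible(x)
}
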