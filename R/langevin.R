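# Stochastic molecular generator: multi-reference Langevin dynamics in
# latent space. The continuous model is
#
#   dX/dt = alpha * sum_k a_k (X_k - X) + xi(t),
#
# where the X_k are reference latent vectors, the a_k are positive weights
# summing to one and xi is a small noise term. With sum a_k = 1 the drift
# pulls X toward the weighted reference centroid m = sum_k a_k X_k, so the
# noiseless dynamics are the Ornstein-Uhlenbeck relaxation
# X(t) = m + (X(0) - m) exp(-alpha t), and with Gaussian noise of amplitude
# sigma the stationary law has mean m and per-coordinate variance
# sigma^2 / (2 alpha). Integration is explicit Euler-Maruyama.

#' Bundle reference latent vectors with attraction weights
#'
#' @param vectors numeric matrix with one reference latent vector per row
#'   (or a list of equal-length vectors).
#' @param weights positive weights, one per reference, summing to 1. Default
#'   uniform `1/K`.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(vectors, weights = NULL) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  }
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) < 1L || !all(is.finite(vectors))) {
    stop_config("references must be one or more finite latent vectors")
  }
  k <- nrow(vectors)
  if (is.null(weights)) weights <- rep(1 / k, k)
  weights <- as.numeric(weights)
  if (length(weights) != k || any(!is.finite(weights)) || any(weights <= 0)) {
    stop_config("need one positive finite weight per reference")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_config("reference weights must sum to 1 (got ", sum(weights), ")")
  }
  structure(list(vectors = unname(vectors), weights = weights,
                 dimension = ncol(vectors)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set:", nrow(x$vectors), "references, dimension",
      x$dimension, ", weights", paste(signif(x$weights, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Generator configuration
#'
#' Parameters of the Euler-Maruyama discretization of the latent-space
#' Langevin generator.
#'
#' @param alpha drift strength, > 0. Explicit Euler stability requires
#'   `alpha * dt < 1`, enforced here.
#' @param dt integration step, > 0.
#' @param n_steps number of steps to integrate.
#' @param noise_law `"uniform"` (default), `"gaussian"` or
#'   `"clipped_gaussian"`. Uniform draws each coordinate increment from
#'   `[-A, A]` per step (the bounded "controlled noise" that keeps edited
#'   latent vectors decodable); gaussian draws `A * sqrt(dt)` times a
#'   standard normal (the theoretically clean diffusion scaling);
#'   clipped_gaussian draws the gaussian increment and clamps it to
#'   `[-A, A]`.
#' @param noise_amplitude the amplitude `A` (and gaussian sigma), >= 0.
#'   Default 0.1.
#' @param step_cap optional maximum Euclidean norm of one step's total
#'   displacement; larger moves are rescaled to this norm. `NULL` (default)
#'   disables the cap.
#' @param burn_in steps discarded before snapshots are taken; `< n_steps`.
#' @param snapshot_every snapshot stride (in steps) after burn-in.
#' @param seed integer RNG seed for the trajectory.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(alpha = 1, dt = 0.01, n_steps = 1000L,
                             noise_law = c("uniform", "gaussian",
                                           "clipped_gaussian"),
                             noise_amplitude = 0.1, step_cap = NULL,
                             burn_in = 0L, snapshot_every = 1L, seed = 1L) {
  noise_law <- match.arg(noise_law)
  chk <- function(ok, msg) if (!ok) stop_config(msg)
  chk(is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) && alpha > 0,
      "alpha must be a positive scalar")
  chk(is.numeric(dt) && length(dt) == 1L && is.finite(dt) && dt > 0,
      "dt must be a positive scalar")
  chk(alpha * dt < 1, "explicit Euler requires alpha * dt < 1")
  n_steps <- as.integer(n_steps)
  chk(length(n_steps) == 1L && !is.na(n_steps) && n_steps >= 1L,
      "n_steps must be a positive integer")
  chk(is.numeric(noise_amplitude) && length(noise_amplitude) == 1L &&
        is.finite(noise_amplitude) && noise_amplitude >= 0,
      "noise_amplitude must be a non-negative scalar")
  if (!is.null(step_cap)) {
    chk(is.numeric(step_cap) && length(step_cap) == 1L && is.finite(step_cap) &&
          step_cap > 0, "step_cap must be NULL or a positive scalar")
  }
  burn_in <- as.integer(burn_in)
  chk(length(burn_in) == 1L && !is.na(burn_in) && burn_in >= 0L,
      "burn_in must be a non-negative integer")
  chk(burn_in < n_steps, "burn_in must be smaller than n_steps")
  snapshot_every <- as.integer(snapshot_every)
  chk(length(snapshot_every) == 1L && !is.na(snapshot_every) &&
        snapshot_every >= 1L, "snapshot_every must be a positive integer")
  structure(list(alpha = alpha, dt = dt, n_steps = n_steps,
                 noise_law = noise_law, noise_amplitude = noise_amplitude,
                 step_cap = step_cap, burn_in = burn_in,
                 snapshot_every = snapshot_every, seed = as.integer(seed)),
            class = "generator_config")
}

#' Deterministic drift of the Langevin generator
#'
#' `alpha * sum_k a_k (X_k - x)`: attraction toward the weighted reference
#' centroid. Zero exactly at the centroid.
#'
#' @param x latent position.
#' @param refs a [reference_set()].
#' @param alpha drift strength.
#' @return latent vector of the same dimension as `x`.
#' @export
drift <- function(x, refs, alpha = 1) {
  x <- check_latent(x)
  stopifnot(inherits(refs, "reference_set"))
  if (length(x) != refs$dimension) {
    stop_domain("dimension mismatch: x has ", length(x), ", references have ",
                refs$dimension)
  }
  alpha * (as.numeric(refs$weights %*% refs$vectors) - sum(refs$weights) * x)
}

# One noise draw per coordinate; consumes the current RNG stream.
.draw_noise <- function(d, cfg) {
  a <- cfg$noise_amplitude
  if (a == 0) return(numeric(d))
  switch(cfg$noise_law,
         gaussian = a * sqrt(cfg$dt) * rnorm(d),
         uniform = runif(d, -a, a),
         clipped_gaussian = pmin(pmax(a * sqrt(cfg$dt) * rnorm(d), -a), a))
}

.step_impl <- function(x, refs, cfg) {
  disp <- cfg$dt * drift(x, refs, cfg$alpha) + .draw_noise(length(x), cfg)
  if (!is.null(cfg$step_cap)) {
    nrm <- sqrt(sum(disp^2))
    if (nrm > cfg$step_cap) disp <- disp * (cfg$step_cap / nrm)
  }
  x + disp
}

#' Advance the generator by one Euler-Maruyama step
#'
#' `x' = x + dt * drift(x) + eta`, with `eta` drawn from the configured
#' noise law (consuming the current RNG stream) and the optional step cap
#' applied to the total displacement.
#'
#' @inheritParams drift
#' @param cfg a [generator_config()].
#' @return the next latent position.
#' @export
langevin_step <- function(x, refs, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  x <- check_latent(x)
  .step_impl(x, refs, cfg)
}

#' Simulate a latent-space Langevin trajectory
#'
#' Integrates `n_steps` Euler-Maruyama steps from `x0`, seeded by
#' `cfg$seed` (the caller's RNG state is untouched). The result stores all
#' `n_steps + 1` states including the initial one.
#'
#' @param x0 initial latent vector (the seed compound's latent position).
#' @inheritParams langevin_step
#' @return an object of class `langevin_trajectory` with elements `states`
#'   (`(n_steps + 1) x d` matrix), `config` and `refs`.
#' @examples
#' refs <- reference_set(rbind(c(1, 0), c(0, 1)))
#' cfg <- generator_config(alpha = 1, dt = 0.05, n_steps = 100,
#'                         noise_amplitude = 0)
#' traj <- simulate_langevin(c(2, 2), refs, cfg)
#' tail(traj$states, 1)  # near the centroid (0.5, 0.5)
#' @export
simulate_langevin <- function(x0, refs, cfg) {
  stopifnot(inherits(refs, "reference_set"), inherits(cfg, "generator_config"))
  x0 <- check_latent(x0, "x0")
  if (length(x0) != refs$dimension) {
    stop_domain("x0 dimension ", length(x0), " does not match references (",
                refs$dimension, ")")
  }
  states <- matrix(NA_real_, nrow = cfg$n_steps + 1L, ncol = length(x0))
  states[1L, ] <- x0
  with_seed(cfg$seed, {
    x <- x0
    for (i in seq_len(cfg$n_steps)) {
      x <- .step_impl(x, refs, cfg)
      states[i + 1L, ] <- x
    }
  })
  structure(list(states = states, config = cfg, refs = refs),
            class = "langevin_trajectory")
}

#' @export
print.langevin_trajectory <- function(x, ...) {
  cfg <- x$config
  cat("Langevin trajectory:", nrow(x$states) - 1L, "steps, dimension",
      ncol(x$states), "\n")
  cat("  alpha =", cfg$alpha, ", dt =", cfg$dt, ", noise =", cfg$noise_law,
      "(A =", cfg$noise_amplitude, "), seed =", cfg$seed, "\n")
  invisible(x)
}

#' @export
plot.langevin_trajectory <- function(x, coords = seq_len(min(4L, ncol(x$states))),
                                     ...) {
  t <- (seq_len(nrow(x$states)) - 1L) * x$config$dt
  graphics::matplot(t, x$states[, coords, drop = FALSE], type = "l", lty = 1,
                    xlab = "time", ylab = "latent coordinate", ...)
  invisible(x)
}

#' Snapshot indices of a trajectory
#'
#' Steps at which candidates are emitted: `burn_in`, `burn_in +
#' snapshot_every`, ... up to `n_steps` (0-based step numbers).
#'
#' @param cfg a [generator_config()].
#' @return integer vector of step indices.
#' @export
snapshot_steps <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  seq.int(cfg$burn_in, cfg$n_steps, by = cfg$snapshot_every)
}

#' Decode trajectory snapshots into candidate molecules
#'
#' Decodes the latent states at the snapshot indices through `codec`, then
#' drops duplicated SMILES keeping the first occurrence (order preserved).
#' Each candidate keeps its source latent vector in `z0..z{d-1}` columns
#' and the step it was emitted at.
#'
#' @param traj a [simulate_langevin()] trajectory.
#' @param codec a codec whose dimension matches the trajectory.
#' @param cfg the [generator_config()] holding the snapshot policy
#'   (defaults to the trajectory's own config).
#' @return data.frame with columns `id`, `smiles`, `step` and the source
#'   latent columns `z0..z{d-1}`; one row per unique decoded molecule.
#' @export
generate_candidates <- function(traj, codec, cfg = traj$config) {
  stopifnot(inherits(traj, "langevin_trajectory"),
            inherits(cfg, "generator_config"))
  d <- ncol(traj$states)
  if (!is.null(codec$dimension) && codec$dimension != d) {
    stop_domain("codec dimension ", codec$dimension,
                " does not match trajectory dimension ", d)
  }
  steps <- snapshot_steps(cfg)
  z <- traj$states[steps + 1L, , drop = FALSE]
  smiles <- decode(codec, z)
  ids <- if (!is.null(codec$smiles) && !is.null(codec$ids)) {
    codec$ids[match(smiles, codec$smiles)]
  } else {
    smiles
  }
  keep <- !duplicated(smiles)
  out <- data.frame(id = ids[keep], smiles = smiles[keep], step = steps[keep],
                    stringsAsFactors = FALSE)
  zk <- z[keep, , drop = FALSE]
  colnames(zk) <- paste0("z", seq_len(d) - 1L)
  cbind(out, as.data.frame(zk))
}

#' Extract the latent-vector matrix from a candidate table
#'
#' @param candidates data.frame with `z0..z{d-1}` columns (from
#'   [generate_candidates()] or [read_latents()]).
#' @return numeric matrix of latent vectors, rows aligned with the table.
#' @export
latent_matrix <- function(candidates) {
  zc <- grep("^z[0-9]+$", names(candidates), value = TRUE)
  if (length(zc) == 0L) stop_data("no z0..z{d-1} latent columns present")
  zc <- zc[order(as.integer(sub("^z", "", zc)))]
  as.matrix(candidates[, zc, drop = FALSE])
}
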