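#' Simulation protocol configuration
#'
#' Bundles the sampling protocol used to turn a circuit model into a synthetic
#' expression compendium: how many clones (samples) to draw, how many cells are
#' averaged per clone, the initial-condition distribution, the parameter and
#' cell-to-cell noise levels, and the integrator settings.
#'
#' @param n_clones number of clones (columns of the simulated matrix); each
#'   clone is one "microarray" sampled under its own random condition.
#' @param cells_per_clone number of cells averaged per clone. `1` reads out a
#'   single representative cell; `100` emulates clone-level population
#'   averaging that can mask single-cell switching.
#' @param init_low,init_high bounds of the uniform initial-condition
#'   distribution, applied per gene.
#' @param param_cv coefficient of variation of the multiplicative Gaussian
#'   parameter noise across clones (`0.2` = 20% variation); draws are truncated
#'   below at 10% of the nominal value so rates stay positive.
#' @param cell_cv coefficient of variation of the Gaussian cell-to-cell spread
#'   of initial expression within a clone (truncated at 0).
#' @param t_end integration horizon (model time units).
#' @param h fixed Runge-Kutta step size.
#' @param steady_tol max-norm derivative tolerance declaring a steady state.
#' @param measurement_noise_sd additive Gaussian noise applied to the log2
#'   readout (0 = off).
#' @param seed RNG seed making the whole sampling protocol reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 100, cells_per_clone = 1,
                       init_low = 0, init_high = 12,
                       param_cv = 0.2, cell_cv = 0.1,
                       t_end = 500, h = 0.01, steady_tol = 1e-6,
                       measurement_noise_sd = 0, seed = 1L) {
  cfg <- list(n_clones = as.integer(n_clones),
              cells_per_clone = as.integer(cells_per_clone),
              init_low = init_low, init_high = init_high,
              param_cv = param_cv, cell_cv = cell_cv,
              t_end = t_end, h = h, steady_tol = steady_tol,
              measurement_noise_sd = measurement_noise_sd,
              seed = as.integer(seed))
  if (cfg$param_cv < 0 || cfg$param_cv >= 1) validation_error("`param_cv` must be in [0, 1)")
  if (cfg$cell_cv < 0 || cfg$cell_cv >= 1) validation_error("`cell_cv` must be in [0, 1)")
  if (cfg$init_low < 0) validation_error("`init_low` must be >= 0")
  if (cfg$init_high <= cfg$init_low) validation_error("`init_high` must exceed `init_low`")
  if (cfg$t_end <= 0 || cfg$h <= 0) validation_error("`t_end` and `h` must be positive")
  if (cfg$steady_tol <= 0) validation_error("`steady_tol` must be positive")
  if (cfg$cells_per_clone < 1L) validation_error("`cells_per_clone` must be >= 1")
  if (cfg$measurement_noise_sd < 0) validation_error("`measurement_noise_sd` must be >= 0")
  structure(cfg, class = "sim_config")
}

# Batched fixed-step RK4 with early stop on the max-norm of the derivative.
# `state` is an n x k matrix of initial conditions integrated in parallel;
# `stimulus` and each params entry recycle to n rows. Returns final states,
# the convergence flag, and (optionally) recorded trajectories.
rk4_batch <- function(model, state, stimulus, params, h, t_end, steady_tol,
                      record_every = 0L) {
  rhs <- model$rhs
  n_steps <- ceiling(t_end / h)
  record <- record_every > 0L
  if (record) {
    keep <- seq(0L, n_steps, by = record_every)
    times <- numeric(length(keep))
    snaps <- vector("list", length(keep))
    times[1L] <- 0
    snaps[[1L]] <- state
    ptr <- 1L
  }
  converged <- FALSE
  t <- 0
  step <- 0L
  while (step < n_steps) {
    k1 <- rhs(state, stimulus, params)
    if (max(abs(k1)) < steady_tol) {
      converged <- TRUE
      break
    }
    k2 <- rhs(state + (h / 2) * k1, stimulus, params)
    k3 <- rhs(state + (h / 2) * k2, stimulus, params)
    k4 <- rhs(state + h * k3, stimulus, params)
    state <- state + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    step <- step + 1L
    t <- t + h
    if (!all(is.finite(state))) {
      abort(sprintf("integration of model '%s' produced non-finite state at step %d (t = %g)",
                    model$name, step, t),
            class = "switchscan_integration_error")
    }
    if (record && step %% record_every == 0L) {
      ptr <- ptr + 1L
      times[ptr] <- t
      snaps[[ptr]] <- state
    }
  }
  kf <- rhs(state, stimulus, params)
  row_norm <- apply(abs(kf), 1L, max)
  if (!converged && max(row_norm) < steady_tol) converged <- TRUE
  out <- list(final = state, converged = converged,
              row_converged = row_norm < steady_tol, t_final = t)
  if (record) {
    out$times <- times[seq_len(ptr)]
    out$snapshots <- snaps[seq_len(ptr)]
    if (converged && out$times[ptr] < t) {
      out$times <- c(out$times, t)
      out$snapshots <- c(out$snapshots, list(state))
    }
  }
  out
}

#' Integrate a circuit model to steady state
#'
#' Classic fixed-step fourth-order Runge-Kutta integration of a single initial
#' condition, stopping early once the max-norm of the derivative falls below
#' `steady_tol`. The final state is the steady-state expression readout.
#'
#' @param model a [circuit_model][circuits].
#' @param init numeric vector of initial expression levels (one per state),
#'   finite and non-negative.
#' @param stimulus stimulus level `i` passed to the model.
#' @param config a [sim_config()] (only the integrator fields are used).
#' @param record_every record every k-th step in the returned trajectory
#'   (0 records only the endpoints).
#' @return A `trajectory` object: tibble-backed `times`/`states`, the final
#'   state, and a `converged` flag.
#' @examples
#' tr <- integrate_circuit(circuit_toggle(), c(10, 0), 0, sim_config())
#' tr$final
#' @export
integrate_circuit <- function(model, init, stimulus, config = sim_config(),
                              record_every = 100L) {
  if (!inherits(model, "circuit_model")) validation_error("`model` must be a circuit_model")
  init <- as.numeric(init)
  if (length(init) != length(model$state_names)) {
    validation_error("`init` must have %d entries (states: %s)",
                     length(model$state_names), paste(model$state_names, collapse = ", "))
  }
  if (any(!is.finite(init)) || any(init < 0)) validation_error("`init` must be finite and >= 0")
  if (!is.finite(stimulus)) validation_error("`stimulus` must be finite")
  res <- rk4_batch(model, matrix(init, nrow = 1L), stimulus, model$params,
                   config$h, config$t_end, config$steady_tol,
                   record_every = max(1L, as.integer(record_every)))
  states <- do.call(rbind, res$snapshots)
  colnames(states) <- model$state_names
  structure(
    list(times = res$times, states = states,
         final = setNames(drop(res$final), model$state_names),
         converged = res$converged, model = model$name, stimulus = stimulus),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, stimulus %g, %d recorded points, %s\n",
              x$model, x$stimulus, length(x$times),
              if (x$converged) "converged" else "not converged"))
  cat("final state:", paste(sprintf("%s=%.4g", names(x$final), x$final), collapse = ", "), "\n")
  invisible(x)
}

# draw cell initial states around a clone mean: Gaussian with sd = cell_cv * mean,
# truncated at zero
draw_cells <- function(clone_init, cells, cell_cv) {
  k <- length(clone_init)
  if (cell_cv == 0 || cells == 1L) {
    if (cells == 1L && cell_cv > 0) {
      m <- matrix(rnorm(k, clone_init, cell_cv * clone_init), 1L)
      return(pmax(m, 0))
    }
    return(matrix(clone_init, cells, k, byrow = TRUE))
  }
  m <- matrix(rnorm(cells * k, mean = rep(clone_init, each = cells),
                    sd = rep(cell_cv * clone_init, each = cells)), cells, k)
  pmax(m, 0)
}

#' Average the steady states of the cells of one clone
#'
#' Draws `cells_per_clone` initial states from a Gaussian around the clone's
#' initial state (CV `cell_cv`, truncated at 0), integrates each to steady
#' state, and returns the arithmetic mean of the final states — emulating a
#' bulk measurement that averages over the cells of a clone.
#'
#' @inheritParams integrate_circuit
#' @param clone_init clone-level mean initial state.
#' @return Named numeric vector of clone-averaged steady-state levels, with a
#'   `converged` attribute.
#' @export
sample_clone_average <- function(model, clone_init, stimulus, config = sim_config()) {
  clone_init <- as.numeric(clone_init)
  cells <- draw_cells(clone_init, config$cells_per_clone, config$cell_cv)
  res <- rk4_batch(model, cells, stimulus, model$params,
                   config$h, config$t_end, config$steady_tol)
  out <- colMeans(res$final)
  names(out) <- model$state_names
  attr(out, "converged") <- res$converged
  out
}

#' Stimulus samplers
#'
#' Small helpers producing per-clone stimulus values for
#' [simulate_expression()]: a constant level or a uniform draw.
#'
#' @param level,min,max stimulus levels.
#' @return A function of `n` returning `n` stimulus values.
#' @export
stimulus_constant <- function(level = 0) {
  force(level)
  function(n) rep(level, n)
}

#' @rdname stimulus_constant
#' @export
stimulus_uniform <- function(min = 0, max = 10) {
  force(min); force(max)
  function(n) runif(n, min, max)
}

#' Simulate a synthetic expression compendium from a circuit
#'
#' Samples `n_clones` clones: for each clone a stimulus is drawn from
#' `stimulus_sampler`, a noisy parameter set is drawn (multiplicative Gaussian,
#' CV `param_cv`, truncated at 10% of nominal), an initial state is drawn
#' uniformly in `[init_low, init_high]` per gene, and the clone-averaged steady
#' state is computed over `cells_per_clone` cells. Readouts are `log2(x + 1)`
#' transformed with optional additive measurement noise, mimicking log-scale
#' microarray intensities. Optionally appends planted non-circuit reporter
#' genes: graded genes (level proportional to the stimulus) and unimodal noise
#' genes.
#'
#' The RNG draw order is fixed and documented: per clone — stimulus, parameter
#' factors, initial state, cell offsets — then the measurement-noise matrix,
#' then extra reporter genes. Identical `config$seed` gives identical output.
#'
#' @inheritParams integrate_circuit
#' @param stimulus_sampler function of `n` returning `n` stimulus values; see
#'   [stimulus_constant()] / [stimulus_uniform()].
#' @param extra_graded,extra_noise number of planted graded / unimodal noise
#'   reporter genes appended to the matrix.
#' @return A `switch_dataset` list: `expression` (genes x samples log2
#'   matrix), `truth` (tibble: gene_id, is_switch, circuit_role), `annotations`
#'   (tibble: sample_id, stimulus, condition_category), and bookkeeping
#'   (`converged_fraction`, `config`).
#' @examples
#' ds <- simulate_expression(circuit_toggle(),
#'                           sim_config(n_clones = 20, seed = 7))
#' dim(ds$expression)
#' @export
simulate_expression <- function(model, config = sim_config(),
                                stimulus_sampler = stimulus_uniform(0, 10),
                                extra_graded = 0L, extra_noise = 0L) {
  if (!inherits(model, "circuit_model")) validation_error("`model` must be a circuit_model")
  if (config$n_clones < 2L) validation_error("`n_clones` must be >= 2")
  with_seed(config$seed, {
    n <- config$n_clones
    cells <- config$cells_per_clone
    k <- length(model$state_names)
    par_names <- names(model$params)

    stim_clone <- numeric(n)
    par_clone <- matrix(0, n, length(par_names), dimnames = list(NULL, par_names))
    inits <- matrix(0, n * cells, k)
    for (i in seq_len(n)) {
      stim_clone[i] <- stimulus_sampler(1L)
      fac <- rnorm(length(par_names), 1, config$param_cv)
      par_clone[i, ] <- pmax(fac, 0.1) * unlist(model$params)
      clone_init <- runif(k, config$init_low, config$init_high)
      rows <- (i - 1L) * cells + seq_len(cells)
      inits[rows, ] <- draw_cells(clone_init, cells, config$cell_cv)
    }

    params <- lapply(par_names, function(nm) rep(par_clone[, nm], each = cells))
    names(params) <- par_names
    res <- rk4_batch(model, inits, rep(stim_clone, each = cells), params,
                     config$h, config$t_end, config$steady_tol)
    finals <- res$final
    clone_id <- rep(seq_len(n), each = cells)
    avg <- rowsum(finals, clone_id) / cells          # n x k clone averages
    vals <- t(log2(pmax(avg, 0) + 1))                # genes x samples
    if (config$measurement_noise_sd > 0) {
      vals <- vals + matrix(rnorm(length(vals), 0, config$measurement_noise_sd),
                            nrow(vals), ncol(vals))
    }
    rownames(vals) <- model$state_names

    roles <- rep("graded", k)
    roles[grep("^(A|B|switch)$", model$state_names)] <- "switch"
    roles[model$state_names == "effector"] <- "effector"
    if (model$name == "self_activation") roles <- "switch"

    if (extra_graded > 0L) {
      g <- t(vapply(seq_len(extra_graded), function(j) {
        gain <- pmax(rnorm(n, 1, config$param_cv), 0.1)
        log2(pmax(gain * stim_clone, 0) + 1)
      }, numeric(n)))
      if (config$measurement_noise_sd > 0) {
        g <- g + matrix(rnorm(length(g), 0, config$measurement_noise_sd), nrow(g), ncol(g))
      }
      rownames(g) <- paste0("graded_extra", seq_len(extra_graded))
      vals <- rbind(vals, g)
      roles <- c(roles, rep("graded", extra_graded))
    }
    if (extra_noise > 0L) {
      mu <- runif(extra_noise, 2, 8)
      sdv <- runif(extra_noise, 0.3, 1)
      nz <- matrix(rnorm(extra_noise * n, mu, sdv), extra_noise, n)
      rownames(nz) <- paste0("noise_extra", seq_len(extra_noise))
      vals <- rbind(vals, nz)
      roles <- c(roles, rep("noise", extra_noise))
    }

    colnames(vals) <- sprintf("S%03d", seq_len(n))
    qs <- quantile(stim_clone, c(0, 1 / 3, 2 / 3, 1))
    if (length(unique(qs)) == 4L) {
      categ <- cut(stim_clone, breaks = qs,
                   labels = c("stim_low", "stim_mid", "stim_high"),
                   include.lowest = TRUE)
    } else {
      categ <- factor(rep("baseline", n))
    }
    structure(
      list(
        expression = vals,
        truth = tibble::tibble(gene_id = rownames(vals),
                               is_switch = roles %in% c("switch", "effector"),
                               circuit_role = roles),
        annotations = tibble::tibble(sample_id = colnames(vals),
                                     stimulus = stim_clone,
                                     condition_category = as.character(categ)),
        converged_fraction = mean(res$row_converged),
        config = unclass(config), model = model$name
      ),
      class = "switch_dataset"
    )
  })
}

#' @export
print.switch_dataset <- function(x, ...) {
  cat(sprintf("<switch_dataset> %s: %d genes x %d samples (%d planted switch genes)\n",
              x$model, nrow(x$expression), ncol(x$expression), sum(x$truth$is_switch)))
  invisible(x)
}

#' Steady-state stimulus sweeps and hysteresis
#'
#' `sweep_steady_states()` integrates the model to steady state at each
#' stimulus in `stimuli`, always starting from the same initial condition, and
#' returns a tibble of steady levels per state. `hysteresis_sweep()` runs two
#' such branches — one started low, one started high — and reports the
#' stimulus window over which the branches disagree. Because the OFF state of
#' the self-activating switch is stable at every stimulus (production is
#' quadratic in the gene's own level), bistability shows up as a
#' history-dependent window rather than as a single threshold: the branch
#' started high stays ON across the window while the branch started low stays
#' OFF, which is the operational signature of hysteresis.
#'
#' @inheritParams integrate_circuit
#' @param stimuli numeric vector of stimulus levels to probe.
#' @param init initial state used for every stimulus.
#' @return `sweep_steady_states()`: tibble (stimulus, state, level, converged).
#' @export
sweep_steady_states <- function(model, stimuli, init, config = sim_config()) {
  k <- length(model$state_names)
  n <- length(stimuli)
  inits <- matrix(rep(as.numeric(init), each = n), n, k)
  res <- rk4_batch(model, inits, stimuli, model$params,
                   config$h, config$t_end, config$steady_tol)
  colnames(res$final) <- model$state_names
  tibble::as_tibble(res$final) |>
    dplyr::mutate(stimulus = stimuli, converged = res$row_converged, .before = 1L) |>
    tidyr::pivot_longer(-c("stimulus", "converged"),
                        names_to = "state", values_to = "level")
}

#' @rdname sweep_steady_states
#' @param low_init,high_init initial levels (recycled across states) for the
#'   low- and high-start branches.
#' @param level_tol branch difference (on the first state) above which the two
#'   branches are called distinct.
#' @return `hysteresis_sweep()`: a `hysteresis` object with the per-branch
#'   tibble, the bistable window bounds, and its width.
#' @export
hysteresis_sweep <- function(model, stimuli = seq(0, 60, length.out = 121),
                             low_init = 0, high_init = 10,
                             config = sim_config(), level_tol = 0.5) {
  k <- length(model$state_names)
  lo <- sweep_steady_states(model, stimuli, rep(low_init, k), config) |>
    dplyr::mutate(branch = "low_start")
  hi <- sweep_steady_states(model, stimuli, rep(high_init, k), config) |>
    dplyr::mutate(branch = "high_start")
  first_state <- model$state_names[1L]
  wide <- dplyr::bind_rows(lo, hi) |>
    dplyr::filter(.data$state == first_state) |>
    tidyr::pivot_wider(id_cols = "stimulus", names_from = "branch", values_from = "level")
  bistable <- abs(wide$high_start - wide$low_start) > level_tol
  window <- if (any(bistable)) range(wide$stimulus[bistable]) else c(NA_real_, NA_real_)
  structure(
    list(branches = dplyr::bind_rows(lo, hi),
         window_low = window[1L], window_high = window[2L],
         window_width = if (any(bistable)) diff(window) else 0,
         state = first_state),
    class = "hysteresis"
  )
}

#' @export
print.hysteresis <- function(x, ...) {
  if (x$window_width > 0) {
    cat(sprintf("<hysteresis> bistable window on %s: stimulus %.3g .. %.3g (width %.3g)\n",
                x$state, x$window_low, x$window_high, x$window_width))
  } else {
    cat("<hysteresis> no bistable window detected\n")
  }
  invisible(x)
}
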