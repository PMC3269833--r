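#' Bistable gene-circuit models
#'
#' Constructors for the ODE circuits used throughout the package: a
#' self-activating switch gene repressed by a stimulus-controlled inhibitor, a
#' two-gene mutual-repression toggle, and a small stand-in network combining one
#' switch gene, a downstream effector, and graded (non-switch) reporter genes.
#'
#' A circuit model is a list with a vectorised right-hand side: `rhs(state,
#' stimulus, params)` takes an `n x k` state matrix (one row per cell/clone
#' integrated in parallel), a stimulus scalar or length-`n` vector, and a named
#' parameter list whose entries may be scalars or length-`n` vectors (so each
#' row can carry its own noisy parameter draw). It returns the matrix of time
#' derivatives.
#'
#' @section Self-activating switch:
#' The single gene `A` activates its own transcription cooperatively and is
#' repressed by an inhibitor `R` whose level is set by the stimulus `i`:
#' \deqn{dA/dt = p A^2/(1+A^2) \cdot 1/(1+R^2) - A/2.5 - d A,\qquad
#'       R(i) = 10 (1-Ki)/(1+Ki).}
#' The fixed `-A/2.5` decay is part of the model; `d A` is the additional
#' linear degradation. With the defaults `p = 4, K = 0.03, d = 0.1` the system
#' is bistable (OFF at `A = 0`, ON near `A = 7.87`) for stimuli in roughly
#' `(23.5, 47.2)`.
#'
#' @section Toggle switch:
#' Two genes repress each other:
#' \deqn{dA/dt = \alpha/(1+B^2) - d A,\qquad dB/dt = \alpha/(1+A^2) - d B.}
#' With `alpha = 10, d = 1` the two stable states are near `(9.90, 0.10)` and
#' its mirror image; the diagonal `A = B` is invariant and contains the saddle.
#'
#' @param p,K,d,alpha positive rate parameters (see the model equations).
#' @return An object of class `circuit_model`: a list with elements `name`,
#'   `state_names`, `rhs`, and `params`.
#' @examples
#' m <- circuit_toggle()
#' m$rhs(matrix(c(10, 0), 1), stimulus = 0, m$params)
#' @name circuits
NULL

new_circuit_model <- function(name, state_names, rhs, params) {
  structure(
    list(name = name, state_names = state_names, rhs = rhs, params = params),
    class = "circuit_model"
  )
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("<circuit_model> ", x$name, "\n", sep = "")
  cat("  states: ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  params: ",
      paste(sprintf("%s=%g", names(x$params), unlist(x$params)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname circuits
#' @export
circuit_self_activation <- function(p = 4, K = 0.03, d = 0.1) {
  params <- list(p = p, K = K, d = d)
  assert_positive(params, c("p", "K", "d"))
  rhs <- function(state, stimulus, params) {
    A <- state[, 1L]
    R <- 10 * (1 - params$K * stimulus) / (1 + params$K * stimulus)
    dA <- params$p * A^2 / (1 + A^2) * (1 / (1 + R^2)) - A / 2.5 - params$d * A
    cbind(dA)
  }
  new_circuit_model("self_activation", "A", rhs, params)
}

#' @rdname circuits
#' @export
circuit_toggle <- function(alpha = 10, d = 1) {
  params <- list(alpha = alpha, d = d)
  assert_positive(params, c("alpha", "d"))
  rhs <- function(state, stimulus, params) {
    A <- state[, 1L]
    B <- state[, 2L]
    cbind(params$alpha / (1 + B^2) - params$d * A,
          params$alpha / (1 + A^2) - params$d * B)
  }
  new_circuit_model("toggle", c("A", "B"), rhs, params)
}

#' @rdname circuits
#' @param n_graded number of graded reporter genes (>= 1) in the stand-in
#'   network. Graded genes have linear production in the stimulus and linear
#'   degradation, so their steady level is proportional to the stimulus.
#' @param beta,K_eff,d_eff effector production strength, half-activation level
#'   and degradation rate: the effector is activated by the switch gene through
#'   a Hill function `beta * A^2 / (K_eff^2 + A^2)` and therefore inherits its
#'   two steady states.
#' @param c_g,d_g graded-gene production coefficient and degradation rate.
#' @export
circuit_standin <- function(n_graded = 2, p = 4, K = 0.03, d = 0.1,
                            beta = 5, K_eff = 2, d_eff = 0.5,
                            c_g = 0.1, d_g = 0.5) {
  if (!is.numeric(n_graded) || length(n_graded) != 1L || n_graded < 1 ||
      n_graded != round(n_graded)) {
    validation_error("`n_graded` must be a positive integer")
  }
  n_graded <- as.integer(n_graded)
  params <- list(p = p, K = K, d = d, beta = beta, K_eff = K_eff,
                 d_eff = d_eff, c_g = c_g, d_g = d_g)
  assert_positive(params, names(params))
  state_names <- c("switch", "effector", paste0("graded", seq_len(n_graded)))
  rhs <- function(state, stimulus, params) {
    A <- state[, 1L]
    E <- state[, 2L]
    R <- 10 * (1 - params$K * stimulus) / (1 + params$K * stimulus)
    dA <- params$p * A^2 / (1 + A^2) * (1 / (1 + R^2)) - A / 2.5 - params$d * A
    dE <- params$beta * A^2 / (params$K_eff^2 + A^2) - params$d_eff * E
    dG <- matrix(params$c_g * stimulus, nrow(state), ncol(state) - 2L) -
      params$d_g * state[, -(1:2), drop = FALSE]
    cbind(dA, dE, dG)
  }
  new_circuit_model("standin_network", state_names, rhs, params)
}
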