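#' Build the generator matrix of the null model's Markov chain
#'
#' The continuous-time Markov chain companion of the agent simulation:
#' states are the `n` boxes followed by the active directed transit states
#' `(i, j)` (those with a positive departure rate, including `i -> i`
#' self-loops). Box `i` flows to transit `(i, j)` at `leave[i, j]`, transit
#' `(i, j)` flows to box `j` at `transit[i, j]`; diagonals make row sums
#' zero. The chain must be irreducible.
#'
#' @param model A [rate_model()].
#' @return List with `Q` (dense generator matrix with state names),
#'   `states` (labels, `"box:i"` / `"transit:i->j"`), and `state_code`
#'   (the integer encoding used by [simulate_colony()]).
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  n <- length(model$boxes)
  act <- which(model$leave > 0, arr.ind = TRUE)
  act <- act[order(act[, 1], act[, 2]), , drop = FALSE]
  n_tr <- nrow(act)
  m <- n + n_tr
  states <- c(paste0("box:", model$boxes),
              sprintf("transit:%s->%s", model$boxes[act[, 1]],
                      model$boxes[act[, 2]]))
  state_code <- c(seq_len(n), n + (act[, 1] - 1L) * n + act[, 2])
  Q <- matrix(0, m, m, dimnames = list(states, states))
  for (k in seq_len(n_tr)) {
    i <- act[k, 1]; j <- act[k, 2]
    Q[i, n + k] <- model$leave[i, j]
    Q[n + k, j] <- model$transit[i, j]
  }
  diag(Q) <- -rowSums(Q)
  adj <- (Q > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1) {
    main <- which.max(tabulate(comp$membership))
    stray <- states[comp$membership != main]
    abort(sprintf("Markov chain is not irreducible; state(s) outside the main component: %s",
                  paste(stray, collapse = ", ")))
  }
  list(Q = Q, states = states, state_code = as.integer(state_code))
}

#' Stationary distribution of a generator matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`, `pi >= 0` by a dense linear solve of
#' the transposed balance equations with the normalisation appended.
#'
#' @param Q A conservative generator matrix (rows sum to zero), e.g. from
#'   [build_generator()].
#' @return Named numeric vector `pi`.
#' @export
stationary_distribution <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) abort("`Q` must be a square matrix.")
  if (max(abs(rowSums(Q))) > 1e-8 * max(abs(Q))) {
    abort("`Q` is not conservative (row sums must be zero).")
  }
  m <- nrow(Q)
  A <- rbind(t(Q), rep(1, m))
  b <- c(rep(0, m), 1)
  pi_hat <- qr.solve(A, b)
  if (any(pi_hat < -1e-10)) {
    abort("Stationary solve produced negative mass; is the chain irreducible?")
  }
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- rownames(Q)
  resid <- max(abs(pi_hat %*% Q))
  if (resid > 1e-8) {
    abort(sprintf("Stationary residual %.3g too large; chain may be reducible.", resid))
  }
  pi_hat
}

#' Relax a point mass towards stationarity
#'
#' Evolves an initial distribution concentrated on one state through
#' `p(t) = p(0) exp(Q t)` (dense matrix exponential). As `t` grows the
#' distribution converges to the stationary one, which is how the chain's
#' mixing can be compared with observed occupancy after a re-settlement.
#'
#' @param Q Generator matrix.
#' @param start State index or name receiving all initial mass.
#' @param t Time(s), seconds (vectorised).
#' @return If `t` is scalar, a named probability vector; otherwise a matrix
#'   with one row per time.
#' @export
relax_from_point <- function(Q, start, t) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) abort("`Q` must be a square matrix.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  m <- nrow(Q)
  if (is.character(start)) start <- match(start, rownames(Q))
  if (is.na(start) || start < 1 || start > m) abort("Unknown start state.")
  p0 <- rep(0, m); p0[start] <- 1
  out <- matrix(NA_real_, nrow = length(t), ncol = m,
                dimnames = list(NULL, rownames(Q)))
  for (k in seq_along(t)) {
    if (t[k] == 0) {
      out[k, ] <- p0
    } else {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t[k])))
      out[k, ] <- as.numeric(p0 %*% E)
    }
  }
  if (length(t) == 1) out[1, ] else out
}

#' Box-state marginal of a state distribution
#'
#' Collapses a distribution over the full box + transit state space to the
#' per-box occupancy probabilities (mass currently inside each box,
#' ignoring agents in transit), normalised to sum 1.
#'
#' @param p Named probability vector over generator states (names
#'   `"box:..."` / `"transit:..."`).
#' @return Named vector over boxes.
#' @export
box_marginal <- function(p) {
  if (is.null(names(p))) abort("`p` must be named with generator state labels.")
  keep <- startsWith(names(p), "box:")
  out <- p[keep]
  names(out) <- sub("^box:", "", names(out))
  out / sum(out)
}
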