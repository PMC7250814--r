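# Synthetic model generation: random consistency-valid transition models
# and curated degenerate fixtures, so every solver is testable without any
# external data.

#' Generate a random consistency-valid transition model
#'
#' Off-diagonal rates are drawn independently: each possible transition is
#' present with probability `density` and its rate is Exponential with mean
#' `rate_scale`. A random spanning cycle over the prey states (and one over
#' the predator states) is always added to the spontaneous matrices, which
#' guarantees irreducibility. Diagonals are then set to minus the column
#' sums, so the conservativity conditions hold exactly by construction.
#'
#' @param m,n state counts (>= 1).
#' @param density probability that any given off-diagonal transition
#'   channel is present, in (0, 1].
#' @param rate_scale mean of the Exponential rate draws.
#' @param seed integer seed; the same seed reproduces the same model.
#' @param with_interactions if `FALSE`, `B` and `C` are left zero (linear
#'   model).
#' @return A [transition_model()].
#' @export
random_model <- function(m, n, density = 0.5, rate_scale = 1, seed = 1L,
                         with_interactions = TRUE) {
  stopifnot(m >= 1, n >= 1, density > 0, density <= 1, rate_scale > 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  rand_offdiag <- function(k) {
    M <- matrix(0, k, k)
    if (k == 1L) return(M)
    off <- which(row(M) != col(M))
    keep <- stats::runif(length(off)) < density
    M[off[keep]] <- stats::rexp(sum(keep), rate = 1 / rate_scale)
    # spanning cycle through a random permutation keeps the chain irreducible
    perm <- sample(k)
    for (i in seq_len(k)) {
      from <- perm[i]
      to <- perm[if (i == k) 1L else i + 1L]
      M[to, from] <- M[to, from] + stats::rexp(1, rate = 1 / rate_scale)
    }
    M
  }
  set_diag <- function(M) {
    diag(M) <- 0
    diag(M) <- -colSums(M)
    M
  }
  zero_diag_slice <- function(S) {
    diag(S) <- 0
    diag(S) <- -colSums(S)
    S
  }

  A <- set_diag(rand_offdiag(m))
  D <- set_diag(rand_offdiag(n))
  B <- array(0, dim = c(m, m, n))
  C <- array(0, dim = c(n, n, m))
  if (with_interactions) {
    for (j in seq_len(n)) {
      S <- rand_offdiag(m)
      # mediated channels are sparser than spontaneous ones
      S[stats::runif(length(S)) > density] <- 0
      B[, , j] <- zero_diag_slice(S)
    }
    for (j in seq_len(m)) {
      S <- rand_offdiag(n)
      S[stats::runif(length(S)) > density] <- 0
      C[, , j] <- zero_diag_slice(S)
    }
  }
  transition_model(A, D, B, C,
                   name = sprintf("random(m=%d,n=%d,seed=%d)", m, n, seed))
}

#' Curated degenerate fixtures
#'
#' Named models exercising the failure and boundary modes of the solvers:
#'
#' * `flat`: a relaxed model with `A = D = B = C = 0`; every state
#'   distribution is stationary, so the uniqueness probe must report
#'   multiple equilibria. An analytically transparent stand-in for the
#'   class of zero-diagonal counterexamples to uniqueness.
#' * `reducible`: a linear model whose prey chain has two disconnected
#'   closed classes; the stationary solver must raise.
#' * `boundary`: a well-posed two-state model intended for evaluation at
#'   `X = 0`, where the prey equilibrium is the zero vector.
#'
#' @return Named list of [transition_model()] objects.
#' @export
degenerate_fixtures <- function() {
  flat <- transition_model(matrix(0, 2, 2), matrix(0, 2, 2),
                           relaxed = TRUE, name = "flat")
  # two isolated prey pairs: states {1,2} and {3,4} never communicate
  Ared <- matrix(0, 4, 4)
  Ared[2, 1] <- 1; Ared[1, 1] <- -1
  Ared[1, 2] <- 1; Ared[2, 2] <- -1
  Ared[4, 3] <- 1; Ared[3, 3] <- -1
  Ared[3, 4] <- 1; Ared[4, 4] <- -1
  reducible <- transition_model(Ared, matrix(c(-1, 1, 1, -1), 2, 2),
                                name = "reducible")
  boundary <- transition_model(matrix(c(-1, 1, 2, -2), 2, 2),
                               matrix(c(-1, 1, 1, -1), 2, 2),
                               name = "boundary")
  list(flat = flat, reducible = reducible, boundary = boundary)
}
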