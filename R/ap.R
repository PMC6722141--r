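#' Affinity-propagation clustering
#'
#' Exemplar-based clustering by responsibility/availability message passing
#' on a similarity matrix. The number of clusters is not pre-specified; it
#' emerges from the shared diagonal preference (here conventionally the
#' median of the off-diagonal similarities, see [build_similarity]).
#' Deterministic for fixed inputs: no random initialisation is used and all
#' argmax ties are broken by the lowest index.
#'
#' If message passing ends with no vertex accumulating positive exemplar
#' evidence (degenerate inputs such as all-identical items), the whole set
#' is returned as one cluster whose exemplar is the index minimising total
#' distance (lowest index on ties).
#'
#' @param S square similarity matrix (diagonal = preferences).
#' @param damping message damping factor in `[0.5, 1)`.
#' @param max_iter maximum number of message-passing sweeps.
#' @param conv_iter stop after this many sweeps with unchanged exemplar set.
#' @return A list with `clusters` (list of integer member vectors),
#'   `exemplars` (integer vector, one per cluster), `converged` (logical),
#'   `iterations`.
#' @export
affinity_propagation <- function(S, damping = 0.5, max_iter = 500L,
                                 conv_iter = 50L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), nrow(S) >= 2)
  if (damping < 0.5 || damping >= 1) stop("`damping` must be in [0.5, 1)")
  n <- nrow(S)
  S <- unclass(S)
  # tiny deterministic tie-break jitter, scaled to the similarity spread
  spread <- max(abs(S))
  if (spread == 0) spread <- 1
  tie <- outer(seq_len(n), seq_len(n),
               function(i, j) (i * n + j) %% 17L - 8L) * spread * 1e-12
  S0 <- S
  S <- S + tie

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  last_ex <- NULL
  stable <- 0L
  iterations <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    m1 <- apply(AS, 1, max)
    k1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), k1)] <- -Inf
    m2 <- apply(AS2, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), k1)] <- S[cbind(seq_len(n), k1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= conv_iter && length(ex) > 0) {
      iterations <- it
      converged <- TRUE
      break
    }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0) {
    # degenerate: no exemplar evidence — one cluster around the most central
    exemplar <- which.max(rowSums(S0))
    return(list(clusters = list(seq_len(n)), exemplars = exemplar,
                converged = converged, iterations = iterations))
  }
  # assign every point to its best exemplar (exemplars to themselves)
  assign_idx <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  assign_idx[ex] <- match(ex, ex)
  clusters <- lapply(seq_along(ex), function(k) which(assign_idx == k))
  keep <- lengths(clusters) > 0
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning the current partition")
  list(clusters = clusters[keep], exemplars = ex[keep],
       converged = converged, iterations = iterations)
}
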