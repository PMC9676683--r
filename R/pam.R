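#' Deterministic PAM (k-medoids) clustering
#'
#' Partitioning around medoids with the classic two phases. BUILD is greedy:
#' the first medoid minimizes total distance to all points, each subsequent
#' medoid maximizes the decrease in total cost; ties break toward the lowest
#' row index. SWAP repeatedly applies the single best strictly-improving
#' (medoid, non-medoid) exchange until none exists, so the objective (total
#' distance of points to their nearest medoid) is non-increasing by
#' construction. No randomness is involved.
#'
#' @param x Numeric matrix (rows are points) or a `dist` object.
#' @param k Number of medoids, `1 <= k <= n`.
#' @param max_iter Safety cap on SWAP iterations.
#' @return List: `medoids` (row indices), `cluster` (assignment per row),
#'   `objective` (final cost), `objective_trace` (cost after BUILD and after
#'   each accepted swap).
#' @export
pam_kmedoids <- function(x, k, max_iter = 200L) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(d)
  if (k < 1L || k > n) abort(sprintf("k must be in [1, %d]", n))

  # BUILD
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    dmin <- apply(d[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(dmin - d[, j], 0))
    }, 0)
    medoids <- c(medoids, which.max(gain))   # which.max: first (lowest index) on ties
  }

  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1, min))
  trace <- cost_of(medoids)

  # SWAP: best improving exchange, repeated
  for (iter in seq_len(max_iter)) {
    dm <- d[, medoids, drop = FALSE]
    nearest <- apply(dm, 1, which.min)
    d1 <- dm[cbind(seq_len(n), nearest)]
    best <- list(delta = 0)
    for (mi in seq_along(medoids)) {
      # nearest distance excluding medoid mi
      if (length(medoids) == 1L) {
        d_wo <- rep(Inf, n)
      } else {
        d_wo <- apply(dm[, -mi, drop = FALSE], 1, min)
      }
      for (h in setdiff(seq_len(n), medoids)) {
        delta <- sum(pmin(d_wo, d[, h])) - sum(d1)
        if (delta < best$delta - 1e-12) best <- list(delta = delta, mi = mi, h = h)
      }
    }
    if (is.null(best$mi)) break
    medoids[best$mi] <- best$h
    trace <- c(trace, cost_of(medoids))
  }

  dm <- d[, medoids, drop = FALSE]
  cluster <- apply(dm, 1, which.min)
  list(medoids = medoids, cluster = as.integer(cluster),
       objective = trace[length(trace)], objective_trace = trace)
}
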