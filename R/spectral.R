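#' Symmetric / anti-symmetric decomposition
#'
#' Splits W into S = (W + W')/2 and A = (W - W')/2 with S + A = W exactly.
#' Symmetric and anti-symmetric components carry the real and imaginary
#' eigenvalue content respectively.
#'
#' @param W square matrix.
#' @return list with components `S` and `A`.
#' @export
sym_antisym_decompose <- function(W) {
  W <- as_weight_matrix(W)
  S <- (W + t(W)) / 2
  list(S = S, A = W - S)
}

#' Projection of activity onto a memory plane
#'
#' \eqn{p_u = u^\top x/\sqrt N}, \eqn{p_v = v^\top x/\sqrt N},
#' \eqn{r = \sqrt{p_u^2 + p_v^2}} — the radial overlap of the network state
#' with the plane.
#'
#' @param x state vector.
#' @param item a [memory_item()].
#' @return named numeric vector `c(p_u, p_v, r)`.
#' @export
project_onto_plane <- function(x, item) {
  sN <- sqrt(length(x))
  p_u <- sum(item$u * x) / sN
  p_v <- sum(item$v * x) / sN
  c(p_u = p_u, p_v = p_v, r = sqrt(p_u^2 + p_v^2))
}

#' Overlap between two planes
#'
#' Each spanning pair is orthonormalized, then the projections of the first
#' plane's spanning vectors onto the second plane are combined:
#' \eqn{r_{u_1} = \sqrt{(u_1\cdot u_2)^2 + (u_1\cdot v_2)^2}}, likewise
#' \eqn{r_{v_1}}, and raw overlap \eqn{\sqrt{r_{u_1}^2 + r_{v_1}^2}}. The raw
#' value lies in [0, sqrt(2)] (sqrt(2) for identical planes); `normalized`
#' divides by sqrt(2) so identical planes score 1. The measure is symmetric
#' in its two arguments and invariant to orthonormal re-basing within each
#' plane.
#'
#' @param u1,v1 spanning vectors of the first plane.
#' @param u2,v2 spanning vectors of the second plane.
#' @return object of class `plane_overlap`: list(raw, normalized).
#' @export
plane_overlap <- function(u1, v1, u2, v2) {
  b1 <- .orthonormal_pair(u1, v1)
  b2 <- .orthonormal_pair(u2, v2)
  ru <- sqrt(sum(b1[, 1] * b2[, 1])^2 + sum(b1[, 1] * b2[, 2])^2)
  rv <- sqrt(sum(b1[, 2] * b2[, 1])^2 + sum(b1[, 2] * b2[, 2])^2)
  raw <- sqrt(ru^2 + rv^2)
  structure(list(raw = raw, normalized = raw / sqrt(2)), class = "plane_overlap")
}

.orthonormal_pair <- function(u, v) {
  nu <- sqrt(sum(u^2))
  if (nu < .Machine$double.eps^0.5) stop("degenerate (zero-norm) spanning vector", call. = FALSE)
  u <- u / nu
  v <- v - sum(u * v) * u
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) stop("degenerate (collinear) spanning pair", call. = FALSE)
  cbind(u, v / nv)
}

## ---------------------------------------------------------------------------
## Minimum-cost assignment (Jonker-Volgenant shortest augmenting path)
## ---------------------------------------------------------------------------

#' Minimum-cost assignment of a square cost matrix
#'
#' Exact linear-assignment solver (shortest augmenting path with dual
#' potentials, O(n^3)), used to match eigenvalue identities between
#' consecutive snapshots.
#'
#' @param cost n x n numeric cost matrix (finite).
#' @return integer permutation `p` with `p[i]` the column assigned to row i.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials, slot n+1 = virtual start column
  p <- integer(n + 1L)   # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)
      u[p[usedc]] <- u[p[usedc]] + delta
      v[usedc] <- v[usedc] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  perm <- integer(n)
  perm[p[seq_len(n)]] <- seq_len(n)
  perm
}

#' Identity-matched eigenvalue trajectories of a matrix time series
#'
#' Computes the eigendecomposition of each snapshot and matches eigenvalue
#' identities between consecutive snapshots by minimum-cost assignment, with
#' cost \eqn{|\lambda_i - \lambda_j|/s + w\,(1 - |\langle v_i, v_j\rangle|)}
#' combining eigenvalue distance (scaled by the median nearest-neighbour
#' spacing s of the current spectrum) and eigenvector dissimilarity. Using
#' eigenvectors prevents identity swaps when trajectories cross in the
#' complex plane. For slowly varying matrix families the resulting
#' trajectories are continuous in time.
#'
#' @param snapshots list of N x N matrices (or 3-d array T x N x N).
#' @param times optional numeric snapshot times (defaults to 1..T).
#' @param vector_weight weight w of the eigenvector dissimilarity. The
#'   default 2 makes a full eigenvector mismatch more expensive than a
#'   one-spacing eigenvalue jump: at a symmetric crossing (two trajectories
#'   exchanging values exactly) a weight of 1 would tie and the match could
#'   swap.
#' @param keep_vectors retain matched eigenvectors in the result?
#' @return object of class `spectrum_trace`: list with `times`, `eigvals`
#'   (T x N complex, consistent column identity), and optionally `eigvecs`
#'   (list of N x N complex matrices, columns matched like eigvals).
#' @export
track_eigenvalues <- function(snapshots, times = NULL, vector_weight = 2,
                              keep_vectors = FALSE) {
  if (is.array(snapshots) && length(dim(snapshots)) == 3L) {
    snapshots <- lapply(seq_len(dim(snapshots)[1]), function(k) snapshots[k, , ])
  }
  Tn <- length(snapshots)
  stopifnot(Tn >= 1L)
  N <- nrow(snapshots[[1]])
  eigvals <- matrix(NA_complex_, Tn, N)
  eigvecs <- if (keep_vectors) vector("list", Tn) else NULL
  prev_val <- NULL
  prev_vec <- NULL
  for (k in seq_len(Tn)) {
    e <- eigen(as_weight_matrix(snapshots[[k]]))
    val <- e$values
    vec <- e$vectors
    if (!is.complex(val)) val <- as.complex(val)
    if (!is.complex(vec)) vec <- matrix(as.complex(vec), N, N)
    if (!is.null(prev_val)) {
      dist <- abs(outer(prev_val, val, `-`))
      s <- .median_spacing(val)
      ovl <- abs(Conj(t(prev_vec)) %*% vec)  # |<v_prev_i, v_j>|
      cost <- dist / s + vector_weight * (1 - ovl)
      perm <- solve_assignment(cost)
      val <- val[perm]
      vec <- vec[, perm, drop = FALSE]
    }
    eigvals[k, ] <- val
    if (keep_vectors) eigvecs[[k]] <- vec
    prev_val <- val
    prev_vec <- vec
  }
  structure(list(times = if (is.null(times)) seq_len(Tn) else times,
                 eigvals = eigvals, eigvecs = eigvecs),
            class = "spectrum_trace")
}

.median_spacing <- function(val) {
  n <- length(val)
  if (n < 2L) return(1)
  d <- abs(outer(val, val, `-`))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  # a degenerate cluster (numerically repeated eigenvalues) would drive the
  # scale to zero; measure spacing over the resolved part of the spectrum
  resolved <- nn > 1e-9 * max(Mod(val), 1)
  s <- if (any(resolved)) stats::median(nn[resolved]) else stats::median(nn)
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Write a spectrum trace as long-format CSV (time, traj_id, re, im)
#' @param trace a `spectrum_trace`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(trace, path) {
  Tn <- nrow(trace$eigvals)
  N <- ncol(trace$eigvals)
  df <- data.frame(
    time = rep(trace$times, each = N),
    traj_id = rep(seq_len(N), times = Tn),
    re = as.vector(t(Re(trace$eigvals))),
    im = as.vector(t(Im(trace$eigvals)))
  )
  utils::write.csv(.format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Memory eigenpair extraction
## ---------------------------------------------------------------------------

.conjugate_pairs <- function(values, tol = 1e-9) {
  which(Im(values) > tol)
}

.eigvec_plane <- function(z) {
  .orthonormal_pair(Re(z), Im(z))
}

#' Eigenpair associated with a memory plane
#'
#' Among the conjugate eigenvalue pairs of W, returns the one whose
#' real-ified eigenplane (orthonormalized span of Re z, Im z of the
#' eigenvector) maximizes the normalized overlap with the item's (u, v)
#' plane. For an all-real spectrum (e.g. symmetric W) the pair is flagged
#' absent.
#'
#' @param W real square matrix.
#' @param item a [memory_item()].
#' @return list with `lambda` (eigenvalue with positive imaginary part),
#'   `plane` (N x 2 orthonormal basis), `overlap` (normalized, in [0,1]),
#'   and `absent` flag.
#' @export
memory_eigenpair <- function(W, item) {
  e <- eigen(as_weight_matrix(W))
  idx <- .conjugate_pairs(e$values)
  if (length(idx) == 0L) {
    return(list(lambda = NA_complex_, plane = NULL, overlap = NA_real_, absent = TRUE))
  }
  best <- NULL
  best_ov <- -Inf
  for (j in idx) {
    pl <- .eigvec_plane(e$vectors[, j])
    ov <- plane_overlap(pl[, 1], pl[, 2], item$u, item$v)$normalized
    if (ov > best_ov) {
      best_ov <- ov
      best <- list(lambda = e$values[j], plane = pl, overlap = ov, absent = FALSE)
    }
  }
  best
}

#' Eigenpair with the largest imaginary part
#'
#' @param W real square matrix.
#' @return as [memory_eigenpair()], without the overlap field; `absent` is
#'   `TRUE` when the spectrum is entirely real.
#' @export
top_imaginary_eigenpair <- function(W) {
  e <- eigen(as_weight_matrix(W))
  idx <- .conjugate_pairs(e$values)
  if (length(idx) == 0L) {
    return(list(lambda = NA_complex_, plane = NULL, absent = TRUE))
  }
  j <- idx[which.max(Im(e$values)[idx])]
  list(lambda = e$values[j], plane = .eigvec_plane(e$vectors[, j]), absent = FALSE)
}

#' Real outlier eigenvalue aligned with a pattern
#'
#' Returns the eigenvalue whose eigenvector has the largest modulus overlap
#' with the direction u; used to read out the amplitude of a real-coded
#' memory from a snapshot.
#'
#' @param W real square matrix.
#' @param u pattern vector.
#' @return list with `lambda` (complex), `alignment` (|<u, v>| in [0,1]).
#' @export
aligned_real_eigenvalue <- function(W, u) {
  e <- eigen(as_weight_matrix(W))
  un <- u / sqrt(sum(u^2))
  al <- abs(as.vector(Conj(t(e$vectors)) %*% un))
  j <- which.max(al)
  list(lambda = e$values[j], alignment = al[j])
}

#' Dominant oscillation frequency of a time series
#'
#' Frequency (cycles per unit time) of the periodogram maximum after mean
#' removal, refined by parabolic interpolation of log-power around the peak.
#' A flat or effectively constant series is flagged by returning `NA` with
#' attribute `no_peak = TRUE`. For a limit cycle generated by an imaginary
#' eigenvalue pair \eqn{\pm i\rho}, the expected frequency is about
#' \eqn{\rho/2\pi}.
#'
#' @param series numeric vector (length >= 64).
#' @param dt_record sampling interval of the series.
#' @return frequency in cycles per unit time, or flagged `NA`.
#' @export
dominant_frequency <- function(series, dt_record) {
  n <- length(series)
  if (n < 64L) stop("series too short for a frequency estimate", call. = FALSE)
  y <- series - mean(series)
  if (stats::sd(y) < 1e-12 * (1 + abs(mean(series)))) {
    return(structure(NA_real_, no_peak = TRUE))
  }
  spec <- Mod(stats::fft(y))^2
  half <- 2:(n %/% 2)                     # drop DC and fold
  pw <- spec[half]
  j <- which.max(pw)
  freq_bin <- (half[j] - 1) / (n * dt_record)
  # parabolic refinement in log power
  if (j > 1L && j < length(pw)) {
    la <- log(pw[j - 1L] + 1e-300); lb <- log(pw[j] + 1e-300); lc <- log(pw[j + 1L] + 1e-300)
    denom <- la - 2 * lb + lc
    shift <- if (abs(denom) > 1e-12) 0.5 * (la - lc) / denom else 0
    freq_bin <- freq_bin + shift / (n * dt_record)
  }
  freq_bin
}
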