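# Dynamic time alignment kernel over a precomputed frame kernel.

.kernelMat <- function(F) {
  if (methods::is(F, "FrameKernel")) F@F else as.matrix(F)
}

.checkRange <- function(r, N, what = "segment") {
  r <- as.integer(r)
  if (length(r) != 2L) stop(what, " must be a (start, end) pair")
  if (r[2L] <= r[1L]) stop(what, " must be non-empty")
  if (r[1L] < 0L || r[2L] > N) stop(what, " must lie within [0, N)")
  r
}

#' Dynamic time alignment kernel between two segments
#'
#' Alignment-aware similarity between the frame ranges `a = [a0, a1)` and
#' `b = [b0, b1)` (0-based, half-open) under the frame kernel `F`. The DP
#' table is `u(p, q) = max(u(p-1, q) + f, u(p-1, q-1) + 2 f, u(p, q-1) + f)`
#' with `f = F[a0 + p, b0 + q]` and `u(0, 0) = 2 f(0, 0)`; the kernel value is
#' `tau = u(n_a - 1, n_b - 1) / (n_a + n_b)`. For a unit-diagonal `F` with
#' entries in (0, 1], `tau` lies in (0, 1], is symmetric in its arguments, and
#' equals 1 for a segment against itself.
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param a,b integer pairs `(start, end)`, 0-based half-open frame ranges.
#' @return scalar similarity in (0, 1].
#' @examples
#' F <- diag(4) * 0.5 + 0.5
#' dtak(F, c(0, 2), c(2, 4))
#' @export
dtak <- function(F, a, b) {
  Fm <- .kernelMat(F)
  a <- .checkRange(a, nrow(Fm), "segment a")
  b <- .checkRange(b, nrow(Fm), "segment b")
  .cpp_dtak(Fm, a[1L], a[2L] - a[1L], b[1L], b[2L] - b[1L])
}

#' Pairwise DTAK matrix over the segments of a segmentation
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param segmentation a \linkS4class{Segmentation}.
#' @return symmetric `M x M` matrix of DTAK similarities.
#' @export
dtakMatrix <- function(F, segmentation) {
  Fm <- .kernelMat(F)
  starts <- head(segmentation@boundaries, -1L)
  lens <- diff(segmentation@boundaries)
  .cpp_dtak_matrix(Fm, starts, lens)
}
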