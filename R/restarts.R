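# Multi-restart minimum-energy protocol shared by all four algorithms.

#' Run a temporal clustering algorithm with seeded restarts
#'
#' Runs `n_init` independent initializations of the requested algorithm
#' (restart `i` uses seed `base_seed + i - 1`) and returns the minimum-energy
#' solution. The energy is the ACA objective `J` for `"aca"`/`"haca"`, the
#' negative log-likelihood for `"gmm"`, and the k-means inertia in the
#' spectral embedding for `"sc"`. All restart energies are recorded in the
#' returned segmentation's `metadata$energies`. With `n_init = 1` the result
#' is identical to a single run with `base_seed`.
#'
#' @param algorithm one of `"aca"`, `"haca"`, `"gmm"`, `"sc"`.
#' @param input the algorithm input: a kernel matrix /
#'   \linkS4class{FrameKernel} for ACA/HACA, a frames-x-channels matrix for
#'   GMM, a spectral embedding for SC (use [gmmSegment()] /
#'   [spectralSegment()] for the user-level surface).
#' @param n_init number of restarts (the study used 5).
#' @param base_seed integer base seed.
#' @param config an [ACAConfig-class] (ACA/HACA only).
#' @param K component count (GMM/SC only).
#' @param ... further arguments for the single-run backends (e.g. `level1_K`,
#'   `l_max_1`, `l_max_2` for HACA).
#' @return A \linkS4class{Segmentation}, the minimum-energy run.
#' @export
runWithRestarts <- function(algorithm = c("aca", "haca", "gmm", "sc"), input,
                            n_init = 5L, base_seed = 1L, config = NULL,
                            K = NULL, ...) {
  algorithm <- match.arg(algorithm)
  n_init <- as.integer(n_init)
  if (n_init < 1L) stop("n_init must be at least 1")
  single <- switch(algorithm,
    aca = function(s) .acaSingle(.kernelMat(input), config, s),
    haca = function(s) .hacaSingle(.kernelMat(input), config, s, ...),
    gmm = function(s) .gmmSingle(input, K, s),
    sc = function(s) .scSingle(input, K, s))
  if (algorithm == "haca") {
    dots <- list(...)
    single <- function(s) .hacaSingle(.kernelMat(input), config,
                                      level1_K = dots$level1_K,
                                      l_max_1 = dots$l_max_1,
                                      l_max_2 = dots$l_max_2, seed = s)
  }
  seeds <- base_seed + seq_len(n_init) - 1L
  runs <- lapply(seeds, single)
  energies <- vapply(runs, `[[`, numeric(1L), "energy")
  best <- which.min(energies)
  seg <- runs[[best]]$segmentation
  seg@metadata$energies <- energies
  seg@metadata$seeds <- seeds
  seg@metadata$algorithm <- algorithm
  seg
}
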