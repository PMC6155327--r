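# Dataset subsampling and splitting. Training sets are drawn from long MD
# trajectories; to keep the energy (Maxwell-Boltzmann) distribution of the
# source trajectory, subsampling is stratified over energy bins.

#' Energy-distribution preserving subsampling
#'
#' Draws `m` frames by stratified sampling over `bins` equal-width energy
#' bins with proportional allocation (largest-remainder rounding), so that
#' the energy histogram of the subsample tracks that of the full set. This
#' preserves the Maxwell-Boltzmann energy distribution of a thermostatted
#' trajectory.
#'
#' @param dataset A [mol_dataset()] whose frames all carry energies.
#' @param m Number of frames to keep (1 <= m <= number of frames).
#' @param bins Number of equal-width energy bins (default 25).
#' @param seed Integer seed.
#' @return A [mol_dataset()] with `m` frames (a subset of the input, original
#'   relative order preserved).
#' @export
subsample_boltzmann <- function(dataset, m, bins = 25L, seed = 0L) {
  stopifnot(inherits(dataset, "mol_dataset"))
  M <- length(dataset)
  m <- as.integer(m)
  if (m < 1L || m > M) stop("argument error: m must be in 1..", M)
  E <- dataset_energies(dataset)
  bins <- max(1L, as.integer(bins))
  rng <- range(E)
  if (diff(rng) == 0) {
    idx <- with_seed(seed, sort(sample.int(M, m)))
    return(dataset[idx])
  }
  # equal-width bins; put the minimum into bin 1 by widening the left edge
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  edges[1L] <- edges[1L] - 1e-9 * max(1, abs(edges[1L]))
  bin <- cut(E, breaks = edges, labels = FALSE)
  counts <- tabulate(bin, nbins = bins)
  # proportional allocation with largest-remainder rounding, capped at the
  # bin occupancy (spare demand is passed to the next-largest remainders)
  exact <- counts * m / M
  alloc <- floor(exact)
  rem <- exact - alloc
  shortfall <- m - sum(alloc)
  ord <- order(rem, decreasing = TRUE)
  k <- 1L
  while (shortfall > 0L && k <= 2L * bins) {
    b <- ord[((k - 1L) %% bins) + 1L]
    if (alloc[b] < counts[b]) {
      alloc[b] <- alloc[b] + 1L
      shortfall <- shortfall - 1L
    }
    k <- k + 1L
  }
  if (shortfall > 0L) {
    # pathological rounding corner: fill from any bins with spare capacity
    for (b in order(counts - alloc, decreasing = TRUE)) {
      add <- min(shortfall, counts[b] - alloc[b])
      alloc[b] <- alloc[b] + add
      shortfall <- shortfall - add
      if (shortfall == 0L) break
    }
  }
  idx <- with_seed(seed, {
    picked <- integer(0)
    for (b in seq_len(bins)) {
      if (alloc[b] == 0L) next
      members <- which(bin == b)
      picked <- c(picked,
                  if (length(members) == 1L) members
                  else sample(members, alloc[b]))
    }
    sort(picked)
  })
  dataset[idx]
}

#' Split a dataset into disjoint train/validation/test parts
#'
#' @param dataset A [mol_dataset()].
#' @param n_train,n_valid,n_test Sizes of the three parts
#'   (their sum must not exceed the dataset size).
#' @param seed Integer seed.
#' @return A list with elements `train`, `valid`, `test` (a part of size 0 is
#'   `NULL`) and the index vectors `idx_train`, `idx_valid`, `idx_test`.
#' @export
split_dataset <- function(dataset, n_train, n_valid, n_test, seed = 0L) {
  stopifnot(inherits(dataset, "mol_dataset"))
  M <- length(dataset)
  n_train <- as.integer(n_train); n_valid <- as.integer(n_valid)
  n_test <- as.integer(n_test)
  if (min(n_train, n_valid, n_test) < 0L) stop("argument error: negative split size")
  if (n_train + n_valid + n_test > M) {
    stop("argument error: split sizes exceed dataset size ", M)
  }
  idx <- with_seed(seed, sample.int(M, n_train + n_valid + n_test))
  it <- sort(idx[seq_len(n_train)])
  iv <- sort(idx[n_train + seq_len(n_valid)])
  ix <- sort(idx[n_train + n_valid + seq_len(n_test)])
  list(train = if (n_train > 0L) dataset[it] else NULL,
       valid = if (n_valid > 0L) dataset[iv] else NULL,
       test  = if (n_test > 0L) dataset[ix] else NULL,
       idx_train = it, idx_valid = iv, idx_test = ix)
}
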