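#' Mitochondrial bead population
#'
#' A `mito_state` holds the evolving organelle population: bead positions,
#' unique particle ids, chain ids partitioning beads into organelles, and a
#' per-chain polarity (+1 anterograde, -1 retrograde).  Beads of a chain are
#' stored contiguously in head-to-tail order, so within-chain bonds are simply
#' consecutive rows.
#'
#' @param positions numeric n x 3 matrix of bead positions (m).
#' @param chain_id integer vector; equal values mark beads of one organelle
#'   and must form a contiguous run.
#' @param polarity +1/-1 per bead (or one value per chain, recycled);
#'   constant within a chain.
#' @param particle_id unique integer per bead; defaults to `seq_len(n)`.
#' @return An object of class `mito_state`.
#' @export
#' @examples
#' # a straight anterograde 3-bead chain at rest spacing
#' s <- mito_state(cbind(c(0, 250e-9, 500e-9), 0, 0), chain_id = c(1, 1, 1),
#'                 polarity = 1)
#' chain_table(s)
mito_state <- function(positions, chain_id, polarity, particle_id = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  chain_id <- as.integer(chain_id)
  if (length(chain_id) != n) stop("chain_id must have one entry per bead")
  if (n > 0) {
    runs <- rle(chain_id)
    if (anyDuplicated(runs$values))
      stop("beads of a chain must be stored contiguously")
  }
  if (is.null(particle_id)) particle_id <- seq_len(n)
  particle_id <- as.integer(particle_id)
  if (length(particle_id) != n || anyDuplicated(particle_id))
    stop("particle_id must be unique, one per bead")
  polarity <- as.integer(polarity)
  if (n > 0) {
    if (length(polarity) == 1) polarity <- rep(polarity, n)
    if (length(polarity) == length(unique(chain_id)) && length(polarity) != n)
      polarity <- rep(polarity, times = rle(chain_id)$lengths)
    if (length(polarity) != n || !all(polarity %in% c(-1L, 1L)))
      stop("polarity must be +1 or -1 per bead (or per chain)")
    if (any(stats::ave(polarity, chain_id, FUN = function(p) length(unique(p))) != 1))
      stop("polarity must be constant within a chain")
  } else {
    polarity <- integer(0)
  }
  structure(list(pos = unname(positions), particle_id = particle_id,
                 chain_id = chain_id, polarity = polarity),
            class = "mito_state")
}

empty_mito_state <- function() {
  mito_state(matrix(numeric(0), 0, 3), integer(0), integer(0), integer(0))
}

#' Number of beads in a population
#' @param state a [mito_state()].
#' @return Integer count.
#' @export
n_beads <- function(state) nrow(state$pos)

#' Per-chain summary of a population
#'
#' @param state a [mito_state()].
#' @return A data.frame with one row per chain: `chain_id`, `start` (row of
#'   the first bead), `length`, `polarity`.
#' @export
chain_table <- function(state) {
  if (n_beads(state) == 0)
    return(data.frame(chain_id = integer(0), start = integer(0),
                      length = integer(0), polarity = integer(0)))
  runs <- rle(state$chain_id)
  start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  data.frame(chain_id = runs$values, start = start, length = runs$lengths,
             polarity = state$polarity[start])
}

# Bonded pairs (consecutive beads of a chain), as a m x 2 matrix of row
# indices.
chain_bonds <- function(state) {
  ct <- chain_table(state)
  out <- lapply(seq_len(nrow(ct)), function(i) {
    if (ct$length[i] < 2) return(NULL)
    idx <- ct$start[i]:(ct$start[i] + ct$length[i] - 1L)
    cbind(idx[-length(idx)], idx[-1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Bending triples (j, i, k) around each interior bead i.
chain_triples <- function(state) {
  ct <- chain_table(state)
  out <- lapply(seq_len(nrow(ct)), function(i) {
    if (ct$length[i] < 3) return(NULL)
    idx <- ct$start[i]:(ct$start[i] + ct$length[i] - 1L)
    m <- length(idx)
    cbind(idx[1:(m - 2)], idx[2:(m - 1)], idx[3:m])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

# Chain index (1..n_chains) and order-in-chain (0-based) per bead.
bead_chain_index <- function(state) {
  ct <- chain_table(state)
  chain <- rep(seq_len(nrow(ct)), times = ct$length)
  ord <- unlist(lapply(ct$length, function(l) seq_len(l) - 1L), use.names = FALSE)
  if (is.null(ord)) ord <- integer(0)
  list(chain = as.integer(chain), ord = as.integer(ord))
}

#' @export
print.mito_state <- function(x, ...) {
  ct <- chain_table(x)
  cat(sprintf("<mito_state> %d beads in %d chains (%d anterograde, %d retrograde)\n",
              n_beads(x), nrow(ct), sum(ct$polarity > 0), sum(ct$polarity < 0)))
  invisible(x)
}

#' Mean chain length of a population
#'
#' Arithmetic mean of the number of beads per organelle.
#'
#' @param state a [mito_state()].
#' @return Beads per chain (dimensionless).
#' @export
mean_chain_length <- function(state) {
  n <- n_beads(state)
  if (n == 0) stop("undefined: population is empty")
  n / nrow(chain_table(state))
}
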