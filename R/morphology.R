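# Connected components over voxel coordinate sets.
#
# Suprathreshold cluster formation and parcel pruning both need connected
# components of an arbitrary voxel subset under 6-, 18- or 26-neighbour
# connectivity. Components are computed on 0-based integer coordinates, so
# the same routine serves masks and labelings.

neighbour_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Connected components of a voxel set
#'
#' @param coords Integer matrix (n x 3) of 0-based voxel indices.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return Integer vector of length n giving a component id per voxel;
#'   components are numbered by decreasing size (1 = largest), ties broken
#'   by the smallest canonical voxel position.
#' @export
connected_components <- function(coords, connectivity = 26) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  # hash coordinates into a dense key space
  lo <- apply(coords, 2, min)
  span <- apply(coords, 2, max) - lo + 3L  # pad so neighbours never wrap
  key <- function(m) {
    (m[, 1] - lo[1] + 1L) +
      span[1] * ((m[, 2] - lo[2] + 1L) + span[2] * (m[, 3] - lo[3] + 1L))
  }
  lookup <- new.env(hash = TRUE, size = n * 2L)
  ks <- key(coords)
  for (i in seq_len(n)) assign(as.character(ks[i]), i, envir = lookup)
  offs <- neighbour_offsets(connectivity)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(offs, 2, as.integer(coords[v, ]), `+`)
      nk <- as.character(key(nb))
      for (k in nk) {
        j <- lookup[[k]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  # renumber by decreasing size, ties by first canonical voxel
  sizes <- tabulate(comp)
  first <- vapply(seq_len(max(comp)), function(c) min(which(comp == c)), 0L)
  ord <- order(-sizes, first)
  match(comp, ord)
}
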