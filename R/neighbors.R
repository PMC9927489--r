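#' Cross-group neighbour search
#'
#' Finds exactly the atom pairs (one from each group) at Euclidean distance
#' \code{<= cutoff}. A uniform spatial grid with cell size \code{cutoff} is
#' used, so only the 27 neighbouring cells of each atom are scanned; the
#' result is contract-equivalent to the all-pairs scan.
#'
#' @param group_a,group_b atom \code{data.frame}s or n x 3 coordinate
#'   matrices.
#' @param cutoff distance cutoff, Angstrom (> 0).
#' @return \code{data.frame} with columns \code{i} (row in \code{group_a}),
#'   \code{j} (row in \code{group_b}) and \code{distance}; each qualifying
#'   pair appears once, ordered by \code{i} then \code{j}.
#' @export
neighbor_pairs <- function(group_a, group_b, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  xa <- atom_coords_any(group_a)
  xb <- atom_coords_any(group_b)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (nrow(xa) == 0 || nrow(xb) == 0) return(empty)
  cell_a <- floor(xa / cutoff)
  cell_b <- floor(xb / cutoff)
  key_b <- paste(cell_b[, 1], cell_b[, 2], cell_b[, 3])
  bins <- split(seq_len(nrow(xb)), key_b)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- vector("list", nrow(xa))
  out_j <- vector("list", nrow(xa))
  out_d <- vector("list", nrow(xa))
  cut2 <- cutoff^2
  for (i in seq_len(nrow(xa))) {
    keys <- paste(cell_a[i, 1] + offs[, 1], cell_a[i, 2] + offs[, 2],
                  cell_a[i, 3] + offs[, 3])
    cand <- unlist(bins[intersect(keys, names(bins))], use.names = FALSE)
    if (!length(cand)) next
    dx <- xb[cand, 1] - xa[i, 1]
    dy <- xb[cand, 2] - xa[i, 2]
    dz <- xb[cand, 3] - xa[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    hit <- d2 <= cut2
    if (any(hit)) {
      jj <- cand[hit]
      ord <- order(jj)
      out_i[[i]] <- rep.int(i, length(jj))
      out_j[[i]] <- jj[ord]
      out_d[[i]] <- sqrt(d2[hit])[ord]
    }
  }
  data.frame(i = unlist(out_i) %||% integer(),
             j = unlist(out_j) %||% integer(),
             distance = unlist(out_d) %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
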