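# Connected-component machinery shared by field segmentation and marker
# labeling. Pure vectorized flood fill: frontiers are expanded wholesale via
# linear-index shifts, so the cost is O(area) with per-iteration vector ops.

# Neighbor linear indices of `idx` in an nr x nc matrix, guarding row/column
# wrap-around. R matrices are column-major: +-1 moves within a column,
# +-nr moves between columns.
.neighbor_idx <- function(idx, nr, nc, connectivity = 8L) {
  r <- ((idx - 1L) %% nr) + 1L
  ok_up <- r > 1L
  ok_dn <- r < nr
  ok_lf <- idx > nr
  ok_rt <- idx <= nr * (nc - 1L)
  nb <- c(idx[ok_up] - 1L, idx[ok_dn] + 1L, idx[ok_lf] - nr, idx[ok_rt] + nr)
  if (connectivity == 8L) {
    nb <- c(nb,
            idx[ok_lf & ok_up] - nr - 1L,
            idx[ok_lf & ok_dn] - nr + 1L,
            idx[ok_rt & ok_up] + nr - 1L,
            idx[ok_rt & ok_dn] + nr + 1L)
  }
  nb
}

# Label connected regions of a logical/binary matrix. Returns an integer
# matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(.neighbor_idx(frontier, nr, nc, connectivity))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Fill interior holes of a foreground region: background pixels not
# 4-connected to the matrix border become foreground. (4-connectivity on the
# complement pairs with 8-connectivity on the region.)
fill_holes <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(seq_len(nr), (nc - 1L) * nr + seq_len(nr),
                     (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr))
  bg <- !mask
  reached <- matrix(FALSE, nr, nc)
  frontier <- border[bg[border]]
  reached[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(.neighbor_idx(frontier, nr, nc, 4L))
    nb <- nb[bg[nb] & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  mask | (bg & !reached)
}
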