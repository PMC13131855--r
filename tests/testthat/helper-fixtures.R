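# A full 56-mask atlas on a tiny grid: one 1 x ny x nz slab per region.
tiny_full_atlas <- function(ny = 4, nz = 4) {
  tab <- wm_lobe_regions()
  names56 <- as.vector(t(outer(c("L-", "R-"), tab$region, paste0)))
  shp <- c(length(names56), ny, nz)
  masks <- lapply(seq_along(names56), function(i) {
    m <- array(FALSE, dim = shp)
    m[i, , ] <- TRUE
    m
  })
  names(masks) <- names56
  region_atlas(masks, voxel_size = 1, require_full = TRUE)
}

# Independent flood-fill component count (BFS over an explicit queue).
flood_fill_count <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2,
                    "26" = nrm >= 1), , drop = FALSE]
  seen <- array(FALSE, dim = d)
  count <- 0L
  todo <- which(mask != 0)
  for (start in todo) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- cc + off[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (mask[lin] != 0 && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  count
}

# All permutations of seq_len(n) as an n x n! index matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  # insert n at every position of every (n-1)-permutation
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (j in seq_len(ncol(sub))) {
    p <- sub[, j]
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[, k] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
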