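# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately share no code with the package internals.

tiny_grid <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), frame_id = "CT") {
  voxel_grid(shape, spacing = spacing, origin = origin, frame_id = frame_id)
}

mask_from_indices <- function(grid, idx0) {
  v <- array(FALSE, grid$shape)
  if (length(idx0)) v[matrix(as.integer(idx0), ncol = 3) + 1L] <- TRUE
  binary_mask(grid, v)
}

# stack-based flood fill over the raw array: the labeling oracle
flood_fill_components <- function(voxels, connectivity = 26) {
  d <- dim(voxels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  seen <- array(FALSE, d)
  comps <- list()
  fg <- which(voxels, arr.ind = TRUE)
  for (s in seq_len(nrow(fg))) {
    start <- fg[s, ]
    if (seen[start[1], start[2], start[3]]) next
    stack <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    comp <- matrix(integer(), 0, 3)
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      comp <- rbind(comp, cur)
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (voxels[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
    comps[[length(comps) + 1]] <- unname(comp) - 1L  # 0-based
  }
  comps
}

# exhaustive surface-distance percentile: the HD oracle
brute_hd <- function(a, b, probs = 0.95) {
  surf <- function(m) {
    v <- m$voxels
    d <- dim(v)
    idx <- which(v, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(idx)), function(i) {
      p <- idx[i, ]
      for (ax in 1:3) for (dd in c(-1, 1)) {
        q <- p
        q[ax] <- q[ax] + dd
        if (any(q < 1) || any(q > d) || !v[q[1], q[2], q[3]]) return(TRUE)
      }
      FALSE
    }, TRUE)
    voxel_to_mm(m$grid, unname(idx[keep, , drop = FALSE]) - 1L)
  }
  sa <- surf(a)
  sb <- surf(b)
  d2 <- outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb)
  dmat <- sqrt(pmax(d2, 0))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  unname(stats::quantile(pooled, probs = probs, type = 7))
}

random_mask <- function(grid, p = 0.15) {
  binary_mask(grid, array(stats::runif(prod(grid$shape)) < p, grid$shape))
}

random_rigid <- function(source = "PET", target = "CT") {
  rigid_from_params(stats::runif(3, -10, 10), stats::runif(3, -20, 20),
                    center_mm = stats::runif(3, -50, 50),
                    source_frame = source, target_frame = target)
}

# a two-structure cuboid OAR set on a small grid for region tests
cuboid_oars <- function() {
  g <- tiny_grid(c(32, 32, 32), spacing = c(2, 2, 2))
  box <- function(lo, hi) {
    v <- array(FALSE, g$shape)
    ax <- lapply(1:3, function(d) 2 * (seq_len(32) - 1))
    ins <- lapply(1:3, function(d) ax[[d]] >= lo[d] & ax[[d]] <= hi[d])
    v[ins[[1]], ins[[2]], ins[[3]]] <- TRUE
    binary_mask(g, v)
  }
  oar_set(list(
    top = box(c(10, 10, 40), c(50, 30, 60)),
    bottom = box(c(12, 14, 4), c(48, 26, 20)),
    wide = box(c(2, 2, 22), c(60, 58, 38)),
    level_2a = box(c(4, 10, 30), c(56, 28, 44)),
    level_2b = box(c(4, 10, 10), c(56, 28, 28)),
    level_3 = box(c(20, 12, 32), c(40, 24, 40))  # nested inside level_2a
  ))
}
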