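# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# stream. All stochastic operations in the package take an explicit seed and
# route through this, so nothing depends on global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# Trilinear interpolation of a 3D array at fractional 1-based voxel
# coordinates given as an n x 3 matrix. Out-of-field samples return `fill`
# with edge = "zero", or replicate the nearest edge value with edge =
# "clamp" (the registration objective needs the latter: zero-filling makes
# the cost discontinuous whenever content touches a volume face).
interp3_linear <- function(vol, pts, fill = 0, edge = c("zero", "clamp")) {
  edge <- match.arg(edge)
  d <- dim(vol)
  if (edge == "clamp") {
    pts <- cbind(pmin(pmax(pts[, 1], 1), d[1]),
                 pmin(pmax(pts[, 2], 1), d[2]),
                 pmin(pmax(pts[, 3], 1), d[3]))
  }
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  out <- rep(fill, length(x))
  # clamp the integer corner so boundary points interpolate within the grid
  x0c <- pmin(pmax(x0, 1), d[1] - 1)
  y0c <- pmin(pmax(y0, 1), d[2] - 1)
  z0c <- pmin(pmax(z0, 1), d[3] - 1)
  inb <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (any(inb)) {
    xi <- x0c[inb]; yi <- y0c[inb]; zi <- z0c[inb]
    gx <- x[inb] - xi; gy <- y[inb] - yi; gz <- z[inb] - zi
    idx <- function(i, j, k) vol[cbind(i, j, k)]
    v000 <- idx(xi,     yi,     zi)
    v100 <- idx(xi + 1, yi,     zi)
    v010 <- idx(xi,     yi + 1, zi)
    v110 <- idx(xi + 1, yi + 1, zi)
    v001 <- idx(xi,     yi,     zi + 1)
    v101 <- idx(xi + 1, yi,     zi + 1)
    v011 <- idx(xi,     yi + 1, zi + 1)
    v111 <- idx(xi + 1, yi + 1, zi + 1)
    out[inb] <-
      v000 * (1 - gx) * (1 - gy) * (1 - gz) +
      v100 * gx       * (1 - gy) * (1 - gz) +
      v010 * (1 - gx) * gy       * (1 - gz) +
      v110 * gx       * gy       * (1 - gz) +
      v001 * (1 - gx) * (1 - gy) * gz +
      v101 * gx       * (1 - gy) * gz +
      v011 * (1 - gx) * gy       * gz +
      v111 * gx       * gy       * gz
  }
  out
}

# Nearest-neighbour lookup at fractional 1-based voxel coordinates.
interp3_nearest <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  inb <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(pts))
  out[inb] <- vol[cbind(i[inb], j[inb], k[inb])]
  out
}

# 6-connected components of a logical 3D mask; returns an integer label
# array (0 = background) with components numbered by decreasing size.
connected_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nxt <- 0L
  arr_ind <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  comp <- integer(length(idx))
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (s in seq_along(idx)) {
    if (visited[s]) next
    nxt <- nxt + 1L
    queue <- s; visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      comp[cur] <- nxt
      p <- arr_ind[cur, ]
      for (o in seq_len(6)) {
        q <- p + offs[o, ]
        if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2] ||
            q[3] < 1 || q[3] > d[3]) next
        t <- pos[q[1], q[2], q[3]]
        if (t > 0L && !visited[t]) { visited[t] <- TRUE; queue <- c(queue, t) }
      }
    }
  }
  sizes <- tabulate(comp, nxt)
  rank <- order(sizes, decreasing = TRUE)
  remap <- integer(nxt); remap[rank] <- seq_len(nxt)
  lab[idx] <- remap[comp]
  lab
}
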