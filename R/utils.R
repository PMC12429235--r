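# Internal image utilities: connected-component labeling, dilation,
# bilinear sampling, small numeric helpers.

round_half_up <- function(x) floor(x + 0.5)

# 8-connected labeling of a binary matrix. Returns an integer matrix of the
# same shape with labels 1..k (0 = background).
label_components_2d <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  fg <- which(m > 0)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) {
    return(lab)
  }
  # edges to 4 forward neighbours (E, S, SE, SW) cover the 8-neighbourhood
  row_i <- (fg - 1L) %% nr + 1L
  col_i <- (fg - 1L) %/% nr + 1L
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    ok <- row_i + s[1] >= 1L & row_i + s[1] <= nr & col_i + s[2] <= nc
    nb <- fg[ok] + s[1] + s[2] * nr
    keep <- m[nb] > 0
    edges[[length(edges) + 1L]] <- cbind(fg[ok][keep], nb[keep])
  }
  edges <- do.call(rbind, edges)
  vid <- match(fg, fg) # 1..n
  if (is.null(edges) || nrow(edges) == 0L) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, 1], fg), match(edges[, 2], fg)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb[vid])
  lab
}

# binary 3x3 dilation (Chebyshev radius 1)
dilate3x3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- m > 0
  pads <- function(x, dr, dc) {
    y <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    y[rs, cs] <- x[rs - dr, cs - dc]
    y
  }
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out | pads(m > 0, dr, dc)
    }
  }
  out
}

# 26-connected 3D labeling with per-slice 8-connected sub-labels.
# Vectorized: one edge list over all foreground voxels (in-plane 8-neighbour
# edges plus the 9 cross-slice offsets), two igraph components calls.
# Returns per-slice label matrices, a per-slice map slice-label -> global
# component id, and global component sizes (voxel counts).
label_components_3d <- function(arr) {
  dm <- dim(arr)
  nx <- dm[1]
  ny <- dm[2]
  nz <- dm[3]
  fg <- which(arr > 0)
  if (!length(fg)) {
    return(list(
      slice_labels = lapply(seq_len(nz), function(k) matrix(0L, nx, ny)),
      global = vector("list", nz), sizes = integer(0)
    ))
  }
  idx_map <- array(0L, dm)
  idx_map[fg] <- seq_along(fg)

  pair_from_offset <- function(dx, dy, dz) {
    xr_a <- max(1L, 1L - dx):min(nx, nx - dx)
    yr_a <- max(1L, 1L - dy):min(ny, ny - dy)
    zr_a <- max(1L, 1L - dz):min(nz, nz - dz)
    a <- idx_map[xr_a, yr_a, zr_a, drop = FALSE]
    b <- idx_map[xr_a + dx, yr_a + dy, zr_a + dz, drop = FALSE]
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  inplane <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  e2 <- do.call(rbind, lapply(inplane, function(s) pair_from_offset(s[1], s[2], 0L)))
  cross <- expand.grid(dx = -1:1, dy = -1:1)
  e3 <- do.call(rbind, lapply(seq_len(nrow(cross)), function(i) {
    pair_from_offset(cross$dx[i], cross$dy[i], 1L)
  }))

  n <- length(fg)
  comp_of <- function(edges) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
    as.integer(igraph::components(g)$membership)
  }
  memb2 <- comp_of(e2) # in-plane only: distinct per slice by construction
  memb3 <- comp_of(rbind(e2, e3)) # full 26-connectivity

  kz <- (fg - 1L) %/% (nx * ny) + 1L
  lab_arr <- array(0L, dm)
  slice_labels <- vector("list", nz)
  global <- vector("list", nz)
  for (k in seq_len(nz)) {
    sel <- which(kz == k)
    if (!length(sel)) {
      slice_labels[[k]] <- matrix(0L, nx, ny)
      global[[k]] <- integer(0)
      next
    }
    codes <- as.integer(factor(memb2[sel]))
    lab_arr[fg[sel]] <- codes
    slice_labels[[k]] <- lab_arr[, , k]
    firsts <- !duplicated(codes)
    gl <- integer(max(codes))
    gl[codes[firsts]] <- memb3[sel[firsts]]
    global[[k]] <- gl
  }
  list(
    slice_labels = slice_labels,
    global = global,
    sizes = as.numeric(tabulate(memb3))
  )
}

# Bilinear sample of matrix z at fractional index coordinates (xi, yi),
# 1-based voxel-centre convention; outside the grid returns `outside`.
bilinear_at <- function(z, xi, yi, outside = 0) {
  nr <- nrow(z)
  nc <- ncol(z)
  x0 <- floor(xi)
  y0 <- floor(yi)
  fx <- xi - x0
  fy <- yi - y0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  g <- function(ix, iy) z[cbind(cl(ix, nr), cl(iy, nc))]
  v <- (1 - fx) * (1 - fy) * g(x0, y0) +
    fx * (1 - fy) * g(x0 + 1, y0) +
    (1 - fx) * fy * g(x0, y0 + 1) +
    fx * fy * g(x0 + 1, y0 + 1)
  out <- xi < 0.5 | xi > nr + 0.5 | yi < 0.5 | yi > nc + 0.5
  v[out] <- outside
  v
}

# centred moving average with shrinking windows at the ends
moving_average <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
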