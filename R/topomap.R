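## ---- Delaunay triangulation (Bowyer-Watson), used for piecewise-linear
## scattered interpolation over the 32 electrode sites ------------------

## circumcircle (center, squared radius) of a triangle
.circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(c = c(ux, uy), r2 = (ax - ux)^2 + (ay - uy)^2)
}

## Delaunay triangulation of a small 2-D point set; returns an integer
## matrix of vertex-index triples.  Positions here are generic (no four
## electrodes are cocircular), so the triangulation is unique and in
## particular mirror-symmetric for the symmetric montage.
.delaunay <- function(pts) {
  n <- nrow(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v)))) * 10 + 1
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  super <- rbind(c(cx - 2 * span, cy - span), c(cx + 2 * span, cy - span),
                 c(cx, cy + 2 * span))
  P <- rbind(pts, super)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      cc <- .circumcircle(P[tris[[t]][1], ], P[tris[[t]][2], ], P[tris[[t]][3], ])
      bad[t] <- !is.null(cc) &&
        (p[1] - cc$c[1])^2 + (p[2] - cc$c[2])^2 < cc$r2 - 1e-12
    }
    ## boundary polygon = edges of bad triangles not shared by two of them
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))))
    tris <- tris[!bad]
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    uniq <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (e in seq_len(nrow(uniq)))
      tris[[length(tris) + 1L]] <- c(uniq[e, 1], uniq[e, 2], i)
  }
  keep <- vapply(tris, function(tr) all(tr <= n), TRUE)
  do.call(rbind, tris[keep])
}

## barycentric interpolation weights of query points `q` (m x 2) w.r.t.
## triangulated sites `pts`; rows of the returned m x n matrix sum to 1.
## Points outside the convex hull get nearest-site weights (ties within
## tol are averaged, keeping the midline exactly symmetric).
.interp_weights <- function(pts, q, tris) {
  n <- nrow(pts); m <- nrow(q)
  W <- matrix(0, m, n)
  done <- logical(m)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    a <- pts[v[1], ]; b <- pts[v[2], ]; c <- pts[v[3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(det) < 1e-14) next
    idx <- which(!done)
    if (!length(idx)) break
    l1 <- ((b[2] - c[2]) * (q[idx, 1] - c[1]) +
           (c[1] - b[1]) * (q[idx, 2] - c[2])) / det
    l2 <- ((c[2] - a[2]) * (q[idx, 1] - c[1]) +
           (a[1] - c[1]) * (q[idx, 2] - c[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    hit <- idx[inside]
    if (!length(hit)) next
    W[cbind(hit, v[1])] <- l1[inside]
    W[cbind(hit, v[2])] <- l2[inside]
    W[cbind(hit, v[3])] <- l3[inside]
    done[hit] <- TRUE
  }
  if (any(!done)) {
    out <- which(!done)
    d2 <- outer(q[out, 1], pts[, 1], `-`)^2 + outer(q[out, 2], pts[, 2], `-`)^2
    for (j in seq_along(out)) {
      tie <- which(d2[j, ] <= min(d2[j, ]) + 1e-12)
      W[out[j], tie] <- 1 / length(tie)
    }
  }
  W
}

## channel permutation mapping each electrode to its left/right mirror
## homolog (identity on the midline), or NULL if the montage has no exact
## mirror structure
.mirror_permutation <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  perm <- integer(n)
  for (i in seq_len(n)) {
    d <- abs(pts[, 1] + pts[i, 1]) + abs(pts[, 2] - pts[i, 2])
    j <- which.min(d)
    if (d[j] > tol) return(NULL)
    perm[i] <- j
  }
  if (!identical(sort(perm), seq_len(n))) return(NULL)
  perm
}

## per-(res) cache of grid geometry and interpolation weights for the
## standard montage
.topo_cache <- new.env(parent = emptyenv())

.topo_geometry <- function(montage, res) {
  key <- paste0("r", res, "_",
                format(sum(montage$positions * seq_along(montage$positions)),
                       digits = 15))
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  gx <- seq(-1, 1, length.out = res)
  gy <- seq(1, -1, length.out = res)       # row 1 = top of the head
  ## column-major over (row = y, col = x): flat index k = (j-1)*res + i
  grid <- cbind(x = rep(gx, each = res), y = rep(gy, res))
  mask <- grid[, 1]^2 + grid[, 2]^2 <= 1
  tris <- .delaunay(montage$positions)
  W <- matrix(0, res * res, nrow(montage$positions))
  W[mask, ] <- .interp_weights(montage$positions, grid[mask, , drop = FALSE],
                               tris)
  ## for mirror-symmetric montages, average the interpolant with its
  ## mirror image: near-cocircular electrode quads make the Delaunay
  ## diagonal choice ambiguous, and the average restores exact left/right
  ## symmetry while preserving electrode exactness and linear precision
  chan_mirror <- .mirror_permutation(montage$positions)
  if (!is.null(chan_mirror)) {
    i_idx <- rep(seq_len(res), res)              # row index per flat pixel
    j_idx <- rep(seq_len(res), each = res)       # column index per flat pixel
    pix_mirror <- (res - j_idx) * res + i_idx    # column res+1-j, same row
    W <- 0.5 * (W + W[pix_mirror, chan_mirror])
  }
  geom <- list(mask = matrix(mask, res, res), W = W, tris = tris,
               gx = gx, gy = gy)
  .topo_cache[[key]] <- geom
  geom
}

#' Interpolate 32 channel values onto the head grid
#'
#' Piecewise-linear interpolation over the Delaunay triangulation of the
#' electrode positions (the scattered-data realization of bilinear
#' interpolation): exact at electrode sites, reproduces linear fields
#' inside the convex hull, and mirror-symmetric for mirrored inputs.
#' Grid nodes inside the head disc but outside the electrode hull take
#' the nearest electrode's value.
#'
#' @param values Numeric vector of 32 finite channel values, canonical
#'   order (names, if present, are checked).
#' @param montage [standard_montage()].
#' @param res Grid resolution.
#' @param value_range Length-2 range used later for color scaling.
#' @return Object of class `topo_map`: `grid` (res x res, NA outside the
#'   head), `mask`, `channel_values`, `montage`, `value_range`.
#' @export
interpolate_topo <- function(values, montage = standard_montage(), res = 128,
                             value_range = c(0, 1)) {
  if (length(values) != nrow(montage$positions))
    stop("need one value per electrode")
  if (any(!is.finite(values))) stop("channel values must be finite")
  if (!is.null(names(values)) &&
      !identical(names(values), rownames(montage$positions)))
    values <- values[rownames(montage$positions)]
  geom <- .topo_geometry(montage, res)
  flat <- as.numeric(geom$W %*% as.numeric(values))
  grid <- matrix(NA_real_, res, res)
  grid[geom$mask] <- flat[geom$mask]
  structure(list(grid = grid, mask = geom$mask,
                 channel_values = stats::setNames(as.numeric(values),
                                                  rownames(montage$positions)),
                 montage = montage, value_range = value_range, res = res),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("topographic map: %d x %d grid, values in [%.3g, %.3g]\n",
              x$res, x$res, min(x$grid, na.rm = TRUE),
              max(x$grid, na.rm = TRUE)))
  invisible(x)
}

## blue -> red "jet-like" colormap: t in [0,1] -> RGB
.jet <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  anchors <- cbind(c(0.0, 0.0, 0.5),   # dark blue
                   c(0.0, 0.0, 1.0),
                   c(0.0, 1.0, 1.0),
                   c(1.0, 1.0, 0.0),
                   c(1.0, 0.0, 0.0),
                   c(0.5, 0.0, 0.0))   # dark red
  pos <- seq(0, 1, length.out = ncol(anchors))
  rgb <- sapply(1:3, function(k) stats::approx(pos, anchors[k, ], xout = t)$y)
  matrix(rgb, ncol = 3)
}

#' Render a topographic map as a PNG image
#'
#' Values are scaled by `value_range` onto a blue-to-red colormap (dark
#' blue = `vmin` = least activity, dark red = `vmax` = most); pixels
#' outside the head disc are white and the head outline is drawn in
#' black.  Output bytes are deterministic for fixed input.
#'
#' @param topo [interpolate_topo()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_png <- function(topo, path) {
  stopifnot(inherits(topo, "topo_map"))
  vr <- topo$value_range
  if (!(vr[2] > vr[1])) stop("invalid value_range (vmin must be < vmax)")
  res <- topo$res
  t <- (topo$grid - vr[1]) / (vr[2] - vr[1])
  arr <- array(1, c(res, res, 3))
  cols <- .jet(t[topo$mask])
  for (k in 1:3) {
    plane <- arr[, , k]
    plane[topo$mask] <- cols[, k]
    arr[, , k] <- plane
  }
  ## head outline: ring of pixels at the disc boundary
  gx <- seq(-1, 1, length.out = res)
  gy <- seq(1, -1, length.out = res)
  r <- sqrt(outer(gy^2, gx^2, `+`))
  ring <- abs(r - 1) <= 1.5 / res
  for (k in 1:3) {
    plane <- arr[, , k]
    plane[ring] <- 0
    arr[, , k] <- plane
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(arr, path)
  invisible(path)
}

#' Map of one conventional feature
#'
#' The classical single-feature ("common") topographic map: the channel
#' value is the mean of one feature over the trial's windows, then
#' interpolated like any other map.
#'
#' @param tensor `feature_tensor`.
#' @param feature_index Feature index 1..10 in canonical order (see
#'   [feature_names()]), or a feature name.
#' @param montage [standard_montage()].
#' @param res Grid resolution.
#' @param value_range Color-scaling range.
#' @return `topo_map`.
#' @export
single_feature_map <- function(tensor, feature_index,
                               montage = standard_montage(), res = 128,
                               value_range = c(0, 1)) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (is.character(feature_index))
    feature_index <- match(feature_index, feature_names())
  if (is.na(feature_index) || feature_index < 1 || feature_index > 10)
    stop("feature_index must be 1..10 (or a canonical feature name)")
  vals <- apply(tensor$tensor[, , feature_index, drop = FALSE], 2, mean)
  interpolate_topo(vals, montage, res, value_range)
}

#' Down-sample a map grid by block averaging
#'
#' Used to feed map grids (not rendered pixels) to the map classifier.
#' NA cells outside the head are treated as the scale midpoint.
#'
#' @param topo `topo_map`.
#' @param out_res Output resolution; must divide `topo$res`.
#' @return `out_res x out_res` numeric matrix.
#' @export
map_grid_matrix <- function(topo, out_res = 64) {
  stopifnot(inherits(topo, "topo_map"), topo$res %% out_res == 0)
  f <- topo$res %/% out_res
  g <- topo$grid
  g[is.na(g)] <- mean(topo$value_range)
  ## average f x f blocks
  m <- matrix(0, out_res, out_res)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      m <- m + g[seq(i, topo$res, by = f), seq(j, topo$res, by = f)]
    }
  }
  m / f^2
}
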