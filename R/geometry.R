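# Polygon geometry for annotation processing.
#
# All routines use 0-based pixel coordinates with x growing right and y
# growing down; a pixel (i, j) is counted as covered when its center
# (i + 0.5, j + 0.5) lies strictly inside the polygon interior under the
# even-odd fill rule.  Self-intersecting polygons are dissected into simple
# pieces via an even-odd scanline trapezoid decomposition, which is also the
# engine behind axis-aligned box clipping (tiling).

#' Construct a polygon shape
#'
#' @param vertices two-column numeric matrix of (x, y) vertex coordinates in
#'   pixels, in drawing order; the polygon is implicitly closed.
#' @param class_label character scalar; one of the canonical annotation
#'   classes (see [amf_classes()]).
#' @return an object of class `polygon_shape`.
#' @export
polygon_shape <- function(vertices, class_label) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a polygon needs a two-column vertex matrix with >= 3 vertices")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, class_label = as.character(class_label)),
            class = "polygon_shape")
}

#' Construct an annotated image
#'
#' @param image_id character identifier.
#' @param width,height image dimensions in pixels.
#' @param shapes list of [polygon_shape()] objects.
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, shapes = list()) {
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  structure(list(image_id = as.character(image_id),
                 width = as.numeric(width), height = as.numeric(height),
                 shapes = shapes),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image '%s' %gx%g, %d shape(s)>\n",
              x$image_id, x$width, x$height, length(x$shapes)))
  invisible(x)
}

#' Signed and absolute polygon area
#'
#' Shoelace area of a (simple) polygon; positive when vertices run
#' counter-clockwise in a y-up frame.
#'
#' @param vertices two-column matrix of vertex coordinates.
#' @return `polygon_area()` returns the absolute area,
#'   `polygon_signed_area()` the signed one.
#' @export
polygon_area <- function(vertices) abs(polygon_signed_area(vertices))

#' @rdname polygon_area
#' @export
polygon_signed_area <- function(vertices) {
  x <- vertices[, 1L]; y <- vertices[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.geom_tol <- function(vertices) {
  scale <- max(1, abs(vertices))
  1e-9 * scale
}

# drop consecutive duplicate vertices (incl. wrap-around) and collinear
# triples; returns NULL when fewer than 3 distinct vertices or zero area
clean_polygon <- function(P, tol = .geom_tol(P)) {
  n <- nrow(P)
  if (n < 3L) return(NULL)
  keep <- rep(TRUE, n)
  prev <- n
  for (i in seq_len(n)) {
    if (keep[prev] && abs(P[i, 1L] - P[prev, 1L]) < tol &&
        abs(P[i, 2L] - P[prev, 2L]) < tol) keep[i] <- FALSE else prev <- i
  }
  P <- P[keep, , drop = FALSE]
  n <- nrow(P)
  if (n < 3L) return(NULL)
  # collinear removal (wrap-around), repeated until stable
  repeat {
    n <- nrow(P)
    if (n < 3L) return(NULL)
    ip <- c(n, seq_len(n - 1L)); iq <- c(2:n, 1L)
    cr <- (P[, 1L] - P[ip, 1L]) * (P[iq, 2L] - P[ip, 2L]) -
          (P[, 2L] - P[ip, 2L]) * (P[iq, 1L] - P[ip, 1L])
    drop <- abs(cr) < tol * tol * 10 | (abs(P[, 1L] - P[iq, 1L]) < tol &
                                        abs(P[, 2L] - P[iq, 2L]) < tol)
    if (!any(drop)) break
    P <- P[!drop, , drop = FALSE]
  }
  if (nrow(P) < 3L) return(NULL)
  # degenerate iff all vertices collinear (signed area can legitimately be
  # zero for self-intersecting polygons, so it is no degeneracy test)
  v1 <- P[1L, ]; v2 <- P[2L, ]
  cr <- (P[, 1L] - v1[1L]) * (v2[2L] - v1[2L]) -
        (P[, 2L] - v1[2L]) * (v2[1L] - v1[1L])
  if (all(abs(cr) < tol)) return(NULL)
  P
}

.edges <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  cbind(x1 = P[, 1L], y1 = P[, 2L], x2 = P[j, 1L], y2 = P[j, 2L])
}

# y coordinates of all pairwise segment intersections (liberal: includes
# endpoint touches; extras only add scanline breaks and are harmless)
.self_intersection_ys <- function(E) {
  n <- nrow(E)
  if (n < 2L) return(numeric(0))
  ys <- numeric(0)
  for (i in seq_len(n - 1L)) {
    d1x <- E[i, 3L] - E[i, 1L]; d1y <- E[i, 4L] - E[i, 2L]
    for (j in (i + 1L):n) {
      d2x <- E[j, 3L] - E[j, 1L]; d2y <- E[j, 4L] - E[j, 2L]
      den <- d1x * d2y - d1y * d2x
      if (abs(den) < 1e-14) next
      rx <- E[j, 1L] - E[i, 1L]; ry <- E[j, 2L] - E[i, 2L]
      t <- (rx * d2y - ry * d2x) / den
      u <- (rx * d1y - ry * d1x) / den
      if (t > -1e-12 && t < 1 + 1e-12 && u > -1e-12 && u < 1 + 1e-12)
        ys <- c(ys, E[i, 2L] + t * d1y)
    }
  }
  ys
}

#' Test whether a polygon is simple
#'
#' A polygon is simple when no two non-adjacent edges cross properly.
#'
#' @param vertices two-column vertex matrix.
#' @return logical scalar.
#' @export
polygon_is_simple <- function(vertices) {
  P <- clean_polygon(as.matrix(vertices))
  if (is.null(P)) return(FALSE)
  E <- .edges(P)
  n <- nrow(E)
  eps <- 1e-9
  for (i in seq_len(n - 1L)) {
    d1x <- E[i, 3L] - E[i, 1L]; d1y <- E[i, 4L] - E[i, 2L]
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
      d2x <- E[j, 3L] - E[j, 1L]; d2y <- E[j, 4L] - E[j, 2L]
      den <- d1x * d2y - d1y * d2x
      if (abs(den) < 1e-14) next
      rx <- E[j, 1L] - E[i, 1L]; ry <- E[j, 2L] - E[i, 2L]
      t <- (rx * d2y - ry * d2x) / den
      u <- (rx * d1y - ry * d1x) / den
      if (t > eps && t < 1 - eps && u > eps && u < 1 - eps) return(FALSE)
    }
  }
  TRUE
}

# collapse near-equal sorted values
.unique_tol <- function(v, tol) {
  v <- sort(v)
  v[c(TRUE, diff(v) > tol)]
}

# Even-odd scanline trapezoid decomposition of a polygon's interior,
# optionally restricted to an axis-aligned box c(xmin, xmax, ymin, ymax).
# Returns a list of records list(y0, y1, l0, r0, l1, r1): a trapezoid with
# horizontal bottom edge [l0, r0] at y0 and top edge [l1, r1] at y1.
eo_trapezoids <- function(P, box = NULL) {
  tol <- .geom_tol(P)
  E <- .edges(P)
  ys <- c(P[, 2L], .self_intersection_ys(E))
  if (!is.null(box)) {
    # add break where an edge crosses a vertical box side, so every band is
    # uncut by the clip lines and clamping stays exact
    for (xv in box[1:2]) {
      s1 <- E[, 1L] - xv; s2 <- E[, 3L] - xv
      cross <- which(s1 * s2 < 0)
      if (length(cross))
        ys <- c(ys, E[cross, 2L] + (xv - E[cross, 1L]) /
                  (E[cross, 3L] - E[cross, 1L]) * (E[cross, 4L] - E[cross, 2L]))
    }
    ys <- ys[ys >= box[3L] - tol & ys <= box[4L] + tol]
    ys <- c(ys, box[3L], box[4L])
  }
  ys <- .unique_tol(ys, tol)
  out <- list()
  if (length(ys) < 2L) return(out)
  for (b in seq_len(length(ys) - 1L)) {
    y0 <- ys[b]; y1 <- ys[b + 1L]
    ym <- (y0 + y1) / 2
    lo <- pmin(E[, 2L], E[, 4L]); hi <- pmax(E[, 2L], E[, 4L])
    sel <- which(lo < ym & hi > ym)
    if (length(sel) < 2L) next
    xs_at <- function(y) E[sel, 1L] + (y - E[sel, 2L]) /
      (E[sel, 4L] - E[sel, 2L]) * (E[sel, 3L] - E[sel, 1L])
    xm <- xs_at(ym)
    ord <- order(xm)
    x0 <- xs_at(y0)[ord]; x1 <- xs_at(y1)[ord]
    np <- floor(length(ord) / 2)
    for (k in seq_len(np)) {
      l0 <- x0[2L * k - 1L]; r0 <- x0[2L * k]
      l1 <- x1[2L * k - 1L]; r1 <- x1[2L * k]
      if (!is.null(box)) {
        l0 <- min(max(l0, box[1L]), box[2L]); r0 <- max(min(r0, box[2L]), box[1L])
        l1 <- min(max(l1, box[1L]), box[2L]); r1 <- max(min(r1, box[2L]), box[1L])
      }
      if (r0 - l0 < tol && r1 - l1 < tol) next
      out[[length(out) + 1L]] <-
        list(y0 = y0, y1 = y1, l0 = l0, r0 = max(r0, l0),
             l1 = l1, r1 = max(r1, l1))
    }
  }
  out
}

# Merge band trapezoids that share an identical horizontal edge into maximal
# simple polygons.  Chains are kept as left/right vertex runs bottom -> top;
# collinear run vertices are collapsed on the fly.
merge_trapezoids <- function(traps, tol = 1e-9) {
  if (!length(traps)) return(list())
  ord <- order(vapply(traps, `[[`, 0, "y0"), vapply(traps, `[[`, 0, "l0"))
  traps <- traps[ord]
  open <- list()    # pieces still growing
  done <- list()
  append_pt <- function(chain, x, y) {
    m <- nrow(chain)
    if (m >= 1L && abs(chain[m, 1L] - x) < tol && abs(chain[m, 2L] - y) < tol)
      return(chain)
    if (m >= 2L) {
      cr <- (chain[m, 1L] - chain[m - 1L, 1L]) * (y - chain[m - 1L, 2L]) -
            (chain[m, 2L] - chain[m - 1L, 2L]) * (x - chain[m - 1L, 1L])
      if (abs(cr) < tol) return(rbind(chain[-m, , drop = FALSE], c(x, y)))
    }
    rbind(chain, c(x, y))
  }
  for (tr in traps) {
    hit <- 0L
    for (pi in seq_along(open)) {
      p <- open[[pi]]
      if (abs(p$top_y - tr$y0) < tol && abs(p$top_l - tr$l0) < tol &&
          abs(p$top_r - tr$r0) < tol) { hit <- pi; break }
    }
    if (hit) {
      p <- open[[hit]]
      p$left <- append_pt(p$left, tr$l1, tr$y1)
      p$right <- append_pt(p$right, tr$r1, tr$y1)
      p$top_y <- tr$y1; p$top_l <- tr$l1; p$top_r <- tr$r1
      open[[hit]] <- p
    } else {
      open[[length(open) + 1L]] <- list(
        left = rbind(c(tr$l0, tr$y0), c(tr$l1, tr$y1)),
        right = rbind(c(tr$r0, tr$y0), c(tr$r1, tr$y1)),
        top_y = tr$y1, top_l = tr$l1, top_r = tr$r1)
    }
  }
  # pieces whose top no longer matches anything are finished; with traps
  # processed bottom-up every piece is finished at the end
  for (p in open) {
    poly <- rbind(p$right, p$left[rev(seq_len(nrow(p$left))), , drop = FALSE])
    poly <- clean_polygon(poly)
    if (!is.null(poly) && polygon_area(poly) > tol)
      done[[length(done) + 1L]] <- poly
  }
  done
}

#' Repair a polygon by dissecting self-intersections
#'
#' Self-intersecting polygons are dissected into simple pieces whose union is
#' the even-odd interior of the input; total area is preserved.  Degenerate
#' input (all vertices collinear, or fewer than three distinct vertices)
#' yields an empty list.
#'
#' @param shape a [polygon_shape()], or a bare vertex matrix.
#' @return list of simple `polygon_shape` objects (or vertex matrices when
#'   the input was a matrix); empty when the input is degenerate.
#' @export
repair_polygon <- function(shape) {
  is_shape <- inherits(shape, "polygon_shape")
  P <- if (is_shape) shape$vertices else as.matrix(shape)
  if (nrow(P) < 3L) stop("a polygon needs at least 3 vertices")
  P <- clean_polygon(P)
  wrap <- function(mats) {
    if (!is_shape) return(mats)
    lapply(mats, polygon_shape, class_label = shape$class_label)
  }
  if (is.null(P)) return(list())
  if (polygon_is_simple(P)) return(wrap(list(P)))
  wrap(merge_trapezoids(eo_trapezoids(P), tol = .geom_tol(P)))
}

#' Clip a simple polygon to an axis-aligned box
#'
#' Intersection of the polygon interior with `[xmin, xmax] x [ymin, ymax]`.
#' Multi-part intersections are returned as separate polygons; pieces that
#' degenerate to points or segments are discarded.  A polygon that lies
#' entirely inside the box is returned unchanged.
#'
#' @param vertices two-column vertex matrix of a simple polygon.
#' @param xmin,xmax,ymin,ymax box bounds.
#' @return list of vertex matrices (possibly empty).
#' @export
clip_polygon_box <- function(vertices, xmin, xmax, ymin, ymax) {
  P <- clean_polygon(as.matrix(vertices))
  if (is.null(P)) return(list())
  tol <- .geom_tol(P)
  if (all(P[, 1L] >= xmin - tol & P[, 1L] <= xmax + tol &
          P[, 2L] >= ymin - tol & P[, 2L] <= ymax + tol))
    return(list(P))
  if (max(P[, 1L]) <= xmin || min(P[, 1L]) >= xmax ||
      max(P[, 2L]) <= ymin || min(P[, 2L]) >= ymax)
    return(list())
  merge_trapezoids(eo_trapezoids(P, box = c(xmin, xmax, ymin, ymax)), tol = tol)
}

#' Tile an annotated image into fixed-size squares
#'
#' Cuts the image into `tile_size` x `tile_size` squares (smaller tiles at
#' the right/bottom boundaries, no padding) and clips every polygon to each
#' tile it overlaps; clipped polygons are re-indexed to tile-local
#' coordinates.  Clipping results that degenerate to points or segments are
#' discarded.
#'
#' @param img an [annotated_image()].
#' @param tile_size tile side in pixels (default 512).
#' @param keep_empty keep tiles without any annotation? (default `FALSE`).
#' @param min_side drop tiles whose width or height is below this (default 0,
#'   i.e. keep all boundary tiles).
#' @return list of [annotated_image()] tiles; tile ids append the tile origin
#'   as `_x<left>_y<top>` to the source image id.
#' @export
tile_annotated_image <- function(img, tile_size = 512, keep_empty = FALSE,
                                 min_side = 0) {
  stopifnot(inherits(img, "annotated_image"), tile_size > 0)
  nx <- max(1L, ceiling(img$width / tile_size))
  ny <- max(1L, ceiling(img$height / tile_size))
  out <- list()
  for (ty in seq_len(ny) - 1L) {
    for (tx in seq_len(nx) - 1L) {
      x0 <- tx * tile_size; y0 <- ty * tile_size
      x1 <- min(x0 + tile_size, img$width)
      y1 <- min(y0 + tile_size, img$height)
      if (x1 - x0 < min_side || y1 - y0 < min_side) next
      shapes <- list()
      for (sh in img$shapes) {
        V <- sh$vertices
        if (max(V[, 1L]) <= x0 || min(V[, 1L]) >= x1 ||
            max(V[, 2L]) <= y0 || min(V[, 2L]) >= y1) next
        parts <- clip_polygon_box(V, x0, x1, y0, y1)
        for (pp in parts) {
          pp[, 1L] <- pp[, 1L] - x0
          pp[, 2L] <- pp[, 2L] - y0
          shapes[[length(shapes) + 1L]] <- polygon_shape(pp, sh$class_label)
        }
      }
      if (!length(shapes) && !keep_empty) next
      out[[length(out) + 1L]] <- annotated_image(
        sprintf("%s_x%d_y%d", img$image_id, as.integer(x0), as.integer(y0)),
        width = x1 - x0, height = y1 - y0, shapes = shapes)
    }
  }
  out
}

#' Rasterized pixel area of a polygon
#'
#' Number of pixel centers `(i + 0.5, j + 0.5)`, `0 <= i < width`,
#' `0 <= j < height`, lying strictly inside the even-odd interior of the
#' polygon.  Deterministic; parts of the polygon outside the raster are
#' simply not counted.
#'
#' @param shape a [polygon_shape()] or vertex matrix.
#' @param width,height raster dimensions in pixels.
#' @return integer pixel count.
#' @export
rasterized_area <- function(shape, width, height) {
  P <- if (inherits(shape, "polygon_shape")) shape$vertices else as.matrix(shape)
  stopifnot(width > 0, height > 0)
  length(rasterize_polygon(P, width, height))
}

# pixel indices (0-based, id = x + y * width) covered by the polygon
rasterize_polygon <- function(P, width, height) {
  E <- .edges(P)
  ids <- integer(0)
  jmin <- max(0L, floor(min(P[, 2L]) - 0.5))
  jmax <- min(height - 1L, ceiling(max(P[, 2L])))
  if (jmax < jmin) return(ids)
  for (j in jmin:jmax) {
    yc <- j + 0.5
    hit <- which((E[, 2L] > yc) != (E[, 4L] > yc))
    if (length(hit) < 2L) next
    xs <- sort(E[hit, 1L] + (yc - E[hit, 2L]) /
                 (E[hit, 4L] - E[hit, 2L]) * (E[hit, 3L] - E[hit, 1L]))
    for (k in seq_len(floor(length(xs) / 2))) {
      xa <- xs[2L * k - 1L]; xb <- xs[2L * k]
      i0 <- max(0, floor(xa - 0.5) + 1)        # smallest i with i + 0.5 > xa
      i1 <- min(width - 1, ceiling(xb - 0.5) - 1)  # largest i with i + 0.5 < xb
      if (i1 >= i0) ids <- c(ids, (i0:i1) + j * width)
    }
  }
  as.integer(ids)
}
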