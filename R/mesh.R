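# Graded, feature-conforming tensor-product triangulation of the axisymmetric
# half-plane. Breakpoints include every material interface line, so region
# boundaries are exact; metal cells are removed and the resulting hole edges
# are tagged metal_surface.

# Subdivide [p, q] geometrically, starting with size h_from at the end given
# by `from` ("p" or "q"), growth `ratio`, capped at h_max; sizes are rescaled
# so the last point lands exactly on the far end.
grade_interval <- function(p, q, h_from, ratio = 1.3, h_max = Inf, from = "p") {
  len <- q - p
  if (len <= h_from * 1.25) return(c(p, q))
  sizes <- h_from
  while (sum(sizes) < len) {
    sizes <- c(sizes, min(h_max, sizes[length(sizes)] * ratio))
  }
  sizes <- sizes * (len / sum(sizes))
  pts <- p + cumsum(c(0, sizes))
  pts[length(pts)] <- q
  if (from == "q") pts <- p + q - rev(pts)
  pts
}

uniform_interval <- function(p, q, h) {
  n <- max(1L, as.integer(round((q - p) / h)))
  # never create edges shorter than half the target through rounding
  if ((q - p) / n < 0.5 * h && n > 1L) n <- n - 1L
  seq(p, q, length.out = n + 1L)
}

# Breakpoints for the scenario geometry in one coordinate: uniform (near-)
# feature intervals at h0 close to the antenna/slots, geometric growth toward
# the far boundaries.
scenario_breaks <- function(geom, h0, h_max, ratio) {
  rf <- geom$r_features; zf <- geom$z_features
  r_c <- rf[5]                      # catheter radius
  rs <- unique(unlist(lapply(seq_len(4), function(i)
    uniform_interval(rf[i], rf[i + 1], h0))))
  rs <- sort(unique(c(rs, grade_interval(r_c, rf[6], h0, ratio, h_max, from = "p"))))

  zf <- sort(unique(zf))
  band <- geom$slot_band
  zs <- numeric(0)
  for (i in seq_len(length(zf) - 1)) {
    p <- zf[i]; q <- zf[i + 1]
    if (q <= band[1]) {            # feed side: refine toward the slots
      cap <- min(h_max, 1.0e-3)    # keep the coax feed axially resolved
      zs <- c(zs, grade_interval(p, q, h0, ratio, cap, from = "q"))
    } else if (p >= geom$z_cap[2]) {  # below the tip: grow away
      zs <- c(zs, grade_interval(p, q, h0, ratio, h_max, from = "p"))
    } else {
      zs <- c(zs, uniform_interval(p, q, h0))
    }
  }
  list(r = rs, z = sort(unique(zs)))
}

#' Generate a conforming triangular mesh of a tagged geometry
#'
#' Builds a graded structured triangulation: tensor-product cells whose
#' breakpoints contain every material interface of the geometry (so region
#' tags are exact), split into triangles with an alternating diagonal.
#' Element size is `min_element_size` at the antenna and slot band and grows
#' geometrically (factor `growth`, capped at `max_element_size`) toward the
#' outer boundaries. Metal cells are excluded; their exposed edges are tagged
#' `metal_surface`. Perimeter edges are tagged `axis` (r = 0), `port` (tissue
#' surface across the coax dielectric annulus) and `outer_boundary`.
#'
#' @param geometry An `mwa_geometry` from [build_scenario_geometry()] or
#'   [rectangle_geometry()].
#' @param min_element_size Target minimum element size, m (> 0).
#' @param max_element_size Size cap far from the antenna, m.
#' @param growth Geometric growth factor of the grading (> 1).
#' @return An object of class `mwa_mesh`: `nodes` (N x 2 matrix of (r, z)),
#'   `tri` (M x 3 vertex indices, counter-clockwise), `region` (length-M
#'   character), `edges` (boundary edge tibble with columns `n1`, `n2`,
#'   `tag`), and the generating `geometry`.
#' @export
generate_mesh <- function(geometry, min_element_size,
                          max_element_size = 3e-3, growth = 1.3) {
  stopifnot(inherits(geometry, "mwa_geometry"))
  if (!is.finite(min_element_size) || min_element_size <= 0) {
    rlang::abort("min_element_size must be positive", class = "mwablate_mesh_error")
  }
  if (geometry$kind == "scenario") {
    br <- scenario_breaks(geometry, min_element_size, max_element_size, growth)
  } else {
    br <- list(
      r = uniform_interval(geometry$r_features[1], geometry$r_features[2], min_element_size),
      z = uniform_interval(geometry$z_features[1], geometry$z_features[2], min_element_size))
  }
  rs <- br$r; zs <- br$z
  nr <- length(rs); nz <- length(zs)
  if (nr < 2 || nz < 2) rlang::abort("degenerate breakpoint set", class = "mwablate_mesh_error")

  # grid nodes, column-major over (i in r, j in z)
  node_id <- function(i, j) (j - 1L) * nr + i
  nodes <- cbind(r = rep(rs, nz), z = rep(zs, each = nr))

  ij <- expand.grid(i = seq_len(nr - 1L), j = seq_len(nz - 1L))
  rc <- (rs[ij$i] + rs[ij$i + 1L]) / 2
  zc <- (zs[ij$j] + zs[ij$j + 1L]) / 2
  reg <- geometry$classify(rc, zc)
  keep <- reg != "metal"
  if (!any(keep)) rlang::abort("all cells classified as metal", class = "mwablate_mesh_error")
  ij <- ij[keep, , drop = FALSE]; reg <- reg[keep]

  ll <- node_id(ij$i, ij$j);      lr <- node_id(ij$i + 1L, ij$j)
  ul <- node_id(ij$i, ij$j + 1L); ur <- node_id(ij$i + 1L, ij$j + 1L)
  even <- (ij$i + ij$j) %% 2L == 0L
  # two CCW triangles per cell (z is the second coordinate; (r,z) right-handed)
  t1 <- ifelse(rep(even, 3), c(ll, lr, ur), c(ll, lr, ul))
  t2 <- ifelse(rep(even, 3), c(ll, ur, ul), c(lr, ur, ul))
  tri <- rbind(matrix(t1, ncol = 3), matrix(t2, ncol = 3))
  region <- c(reg, reg)

  # drop unused nodes, renumber
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)

  # boundary edges: edges referenced by exactly one triangle
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bnd <- names(tab)[tab == 1L]
  first <- !duplicated(key)
  eb <- e[first & key %in% bnd, , drop = FALSE]
  etri <- rep(seq_len(nrow(tri)), 3)[first & key %in% bnd]

  tol <- 1e-12
  r1 <- nodes[eb[, 1], 1]; r2 <- nodes[eb[, 2], 1]
  z1 <- nodes[eb[, 1], 2]; z2 <- nodes[eb[, 2], 2]
  rmax <- max(rs); zmin <- min(zs); zmax <- max(zs); rmin <- min(rs)
  tag <- rep("metal_surface", nrow(eb))
  on_axis  <- r1 < tol & r2 < tol
  on_top   <- abs(z1 - zmin) < tol & abs(z2 - zmin) < tol
  on_right <- abs(r1 - rmax) < tol & abs(r2 - rmax) < tol
  on_bot   <- abs(z1 - zmax) < tol & abs(z2 - zmax) < tol
  on_left  <- rmin > tol & abs(r1 - rmin) < tol & abs(r2 - rmin) < tol
  tag[on_top] <- ifelse(region[etri[on_top]] == "coax_dielectric", "port", "outer_boundary")
  tag[on_right | on_bot | on_left] <- "outer_boundary"
  tag[on_axis] <- "axis"

  mesh <- structure(list(
    nodes = nodes, tri = tri, region = region,
    edges = tibble::tibble(n1 = eb[, 1], n2 = eb[, 2], tag = tag, tri = etri),
    geometry = geometry,
    min_element_size = min_element_size
  ), class = "mwa_mesh")
  areas <- triangle_areas(mesh)
  if (any(areas <= 0)) rlang::abort("mesher produced a non-positive triangle area",
                                    class = "mwablate_mesh_error")
  mesh
}

#' @export
print.mwa_mesh <- function(x, ...) {
  cat(sprintf("<mwa_mesh> %d nodes, %d triangles, regions: %s\n",
              nrow(x$nodes), nrow(x$tri),
              paste(sprintf("%s(%d)", names(table(x$region)), table(x$region)),
                    collapse = ", ")))
  invisible(x)
}

#' Signed triangle areas of a mesh
#' @param mesh An `mwa_mesh`.
#' @return Numeric vector of per-triangle areas (m^2), positive for
#'   counter-clockwise elements.
#' @export
triangle_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Locate points in the mesh with barycentric weights
#'
#' Scans the triangles containing each query point and returns the containing
#' triangle and its barycentric weights (non-negative, summing to 1); the
#' weights reconstruct the query coordinates exactly up to round-off.
#'
#' @param mesh An `mwa_mesh`.
#' @param points Numeric matrix (n x 2) or length-2 vector of (r, z) queries.
#' @param tol Containment tolerance on barycentric weights.
#' @return Tibble with columns `r`, `z`, `triangle`, `w1`, `w2`, `w3`.
#' @export
point_locate <- function(mesh, points, tol = 1e-10) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  out <- lapply(seq_len(nrow(points)), function(k) {
    r <- points[k, 1]; z <- points[k, 2]
    w1 <- ((p2[, 1] - r) * (p3[, 2] - z) - (p3[, 1] - r) * (p2[, 2] - z)) / det
    w2 <- ((p3[, 1] - r) * (p1[, 2] - z) - (p1[, 1] - r) * (p3[, 2] - z)) / det
    w3 <- 1 - w1 - w2
    inside <- which(w1 >= -tol & w2 >= -tol & w3 >= -tol)
    if (!length(inside)) {
      rlang::abort(sprintf("point (%.4g, %.4g) lies outside the meshed domain", r, z),
                   class = "mwablate_lookup_error")
    }
    # prefer the triangle with the most interior weights (ties: lowest index)
    i <- inside[which.max(pmin(w1[inside], pmin(w2[inside], w3[inside])))]
    c(r, z, i, max(w1[i], 0), max(w2[i], 0), max(w3[i], 0))
  })
  m <- do.call(rbind, out)
  w <- m[, 4:6, drop = FALSE] / rowSums(m[, 4:6, drop = FALSE])
  tibble::tibble(r = m[, 1], z = m[, 2], triangle = as.integer(m[, 3]),
                 w1 = w[, 1], w2 = w[, 2], w3 = w[, 3])
}

# Interpolate a nodal field at located points
interp_at <- function(mesh, loc, values) {
  v <- mesh$tri[loc$triangle, , drop = FALSE]
  loc$w1 * values[v[, 1]] + loc$w2 * values[v[, 2]] + loc$w3 * values[v[, 3]]
}

#' Export a mesh (with optional fields) as an ASCII VTU file
#'
#' Writes a VTK unstructured-grid XML file with region tags as cell data and
#' any supplied nodal (`point_data`) or per-triangle (`cell_data`) fields, for
#' inspection in ParaView-style viewers.
#'
#' @param mesh An `mwa_mesh`.
#' @param path Output file path.
#' @param point_data Named list of length-N numeric vectors.
#' @param cell_data Named list of length-M numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  fmt <- function(x) paste(format(x, digits = 9, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  da <- function(name, x, comp = 1) sprintf(
    '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">%s</DataArray>',
    name, comp, fmt(x))
  cells <- sprintf(paste0(
    '<DataArray type="Int32" Name="connectivity" format="ascii">%s</DataArray>',
    '<DataArray type="Int32" Name="offsets" format="ascii">%s</DataArray>',
    '<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>'),
    paste(t(mesh$tri) - 1L, collapse = " "),
    paste(seq_len(m) * 3L, collapse = " "),
    paste(rep(5L, m), collapse = " "))
  pts <- da("Points", as.vector(t(cbind(mesh$nodes, 0))), 3)
  pd <- paste(vapply(names(point_data),
                     function(nm) da(nm, point_data[[nm]]), ""), collapse = "")
  cd <- paste(c(da("region", as.integer(factor(mesh$region))),
                vapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]), "")),
              collapse = "")
  xml <- paste0(
    '<?xml version="1.0"?><VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">',
    '<Points>', pts, '</Points>',
    '<Cells>', cells, '</Cells>',
    '<PointData>', pd, '</PointData>',
    '<CellData>', cd, '</CellData>',
    '</Piece></UnstructuredGrid></VTKFile>')
  writeLines(xml, path)
  invisible(path)
}
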