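# Shared fixtures: default materials map, small meshes, and lazily cached
# preset runs (the four protocols are used by several test files; run once).

default_materials <- function() {
  reg <- material_registry()
  list(tissue = reg$breast, coax_dielectric = reg$coax_dielectric,
       slot = reg$coax_dielectric, catheter = reg$catheter)
}

default_mesh <- function(insertion = 40e-3, h = 0.15e-3) {
  generate_mesh(build_scenario_geometry(domain_spec(insertion_depth = insertion)), h)
}

.preset_cache <- new.env(parent = emptyenv())

preset_result <- function(i, ...) {
  key <- paste0("p", i)
  if (is.null(.preset_cache[[key]])) {
    .preset_cache[[key]] <- run_scenario(scenario_presets(i)[[1]],
                                         check = FALSE, keep_fields = TRUE)
  }
  .preset_cache[[key]]
}

# single reference triangle mesh for element-matrix oracles
one_triangle_mesh <- function(p1 = c(1, 0), p2 = c(1.4, 0.1), p3 = c(1.1, 0.5)) {
  structure(list(
    nodes = unname(rbind(p1, p2, p3)),
    tri = matrix(1:3, nrow = 1),
    region = "tissue",
    edges = tibble::tibble(n1 = c(1, 2, 3), n2 = c(2, 3, 1),
                           tag = "outer_boundary", tri = 1L),
    geometry = NULL, min_element_size = NA_real_
  ), class = "mwa_mesh")
}

# dense numeric quadrature over a triangle (high-order), independent of the
# package's 3-point rule: subdivide into k^2 congruent subtriangles and apply
# the midpoint (centroid) rule on each.
brute_tri_integral <- function(p1, p2, p3, f, k = 400) {
  area <- 0.5 * abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                    (p3[1] - p1[1]) * (p2[2] - p1[2]))
  ij <- expand.grid(i = 0:(k - 1), j = 0:(k - 1))
  ij <- ij[ij$i + ij$j <= k - 1, ]
  # up-triangles
  l1 <- (ij$i + 1 / 3) / k; l2 <- (ij$j + 1 / 3) / k
  cen_up <- cbind(l1, l2, 1 - l1 - l2)
  # down-triangles
  ij2 <- ij[ij$i + ij$j <= k - 2, ]
  l1d <- (ij2$i + 2 / 3) / k; l2d <- (ij2$j + 2 / 3) / k
  cen_dn <- cbind(l1d, l2d, 1 - l1d - l2d)
  cen <- rbind(cen_up, cen_dn)
  pts <- cen %*% rbind(p1, p2, p3)
  sum(f(pts[, 1], pts[, 2], cen)) * (area / k^2)
}
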