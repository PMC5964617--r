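#' Antenna geometry of the double short-distance slot coaxial applicator
#'
#' Radial build-up of the applicator (all lengths in metres): inner conductor,
#' coax dielectric, outer conductor, and the PTFE catheter that encases the
#' antenna. Two annular slots are cut in the outer conductor, centred
#' `slot_spacing` apart (centre-to-centre), each `slot_width` wide; the metal
#' beyond the distal slot is a closed cap of length `tip_length`. Defaults are
#' the UT-085 semi-rigid cable radii (0.51/1.68/2.20 mm diameters), a 2.58 mm
#' catheter, and 0.40 mm slot spacing.
#'
#' @param inner_conductor_radius,dielectric_radius,outer_conductor_radius,catheter_radius
#'   Radii of the coaxial build-up, m; must be strictly increasing.
#' @param slot_width Axial width of each slot, m (> 0).
#' @param slot_spacing Centre-to-centre slot separation, m (> `slot_width`).
#' @param tip_length Closed metal tip beyond the distal slot edge, m.
#' @return An object of class `mwa_antenna`.
#' @export
antenna_geometry <- function(inner_conductor_radius = 0.255e-3,
                             dielectric_radius      = 0.84e-3,
                             outer_conductor_radius = 1.10e-3,
                             catheter_radius        = 1.29e-3,
                             slot_width             = 0.30e-3,
                             slot_spacing           = 0.40e-3,
                             tip_length             = 0.50e-3) {
  r <- c(inner_conductor_radius, dielectric_radius,
         outer_conductor_radius, catheter_radius)
  if (any(!is.finite(r)) || any(r <= 0) || any(diff(r) <= 0)) {
    nm <- c("inner_conductor_radius", "dielectric_radius",
            "outer_conductor_radius", "catheter_radius")
    bad <- which(diff(r) <= 0)[1]
    rlang::abort(
      sprintf("antenna radii must be strictly increasing: %s (%.3g m) vs %s (%.3g m)",
              nm[bad], r[bad], nm[bad + 1], r[bad + 1]),
      class = "mwablate_geometry_error")
  }
  if (slot_width <= 0) {
    rlang::abort("slot_width must be positive (degenerate slot)",
                 class = "mwablate_geometry_error")
  }
  if (slot_spacing <= slot_width) {
    rlang::abort("slot_spacing (centre-to-centre) must exceed slot_width",
                 class = "mwablate_geometry_error")
  }
  if (tip_length <= 0) {
    rlang::abort("tip_length must be positive", class = "mwablate_geometry_error")
  }
  structure(list(
    inner_conductor_radius = inner_conductor_radius,
    dielectric_radius      = dielectric_radius,
    outer_conductor_radius = outer_conductor_radius,
    catheter_radius        = catheter_radius,
    slot_width             = slot_width,
    slot_spacing           = slot_spacing,
    tip_length             = tip_length
  ), class = "mwa_antenna")
}

#' Domain specification: antenna inserted in a tissue block
#'
#' The model domain is the axisymmetric half-plane `[0, tissue_radius] x
#' [0, tissue_height]`, with `z = 0` at the tissue surface and z increasing
#' with depth. The antenna runs along the symmetry axis; the midpoint between
#' its two slots sits at `z = insertion_depth`. The coaxial feed is modelled
#' from the tissue surface down to the proximal slot, with the excitation port
#' across the coax dielectric annulus at `z = 0`.
#'
#' @param tissue_radius,tissue_height Tissue block extent, m.
#' @param insertion_depth Depth of the slot midpoint below the surface, m.
#' @param antenna An [antenna_geometry()] object.
#' @param region_materials Named character vector mapping region tags to
#'   material names in the registry.
#' @return An object of class `mwa_domain`.
#' @export
domain_spec <- function(tissue_radius = 30e-3,
                        tissue_height = 80e-3,
                        insertion_depth = 40e-3,
                        antenna = antenna_geometry(),
                        region_materials = c(tissue = "breast",
                                             coax_dielectric = "coax_dielectric",
                                             slot = "coax_dielectric",
                                             catheter = "catheter")) {
  stopifnot(inherits(antenna, "mwa_antenna"))
  if (insertion_depth > tissue_height) {
    rlang::abort("insertion_depth exceeds tissue_height",
                 class = "mwablate_geometry_error")
  }
  a <- antenna
  z_prox_top <- insertion_depth - a$slot_spacing / 2 - a$slot_width / 2
  z_cap_end  <- insertion_depth + a$slot_spacing / 2 + a$slot_width / 2 +
    a$tip_length + (a$catheter_radius - a$outer_conductor_radius)
  if (z_prox_top <= 1e-3) {
    rlang::abort("insertion_depth too shallow: proximal slot must sit below the surface",
                 class = "mwablate_geometry_error")
  }
  if (z_cap_end + 2e-3 >= tissue_height) {
    rlang::abort("insertion_depth too deep: antenna tip must clear the bottom boundary",
                 class = "mwablate_geometry_error")
  }
  if (a$catheter_radius + 2e-3 >= tissue_radius) {
    rlang::abort("tissue_radius too small for the antenna radius",
                 class = "mwablate_geometry_error")
  }
  structure(list(
    tissue_radius = tissue_radius,
    tissue_height = tissue_height,
    insertion_depth = insertion_depth,
    antenna = antenna,
    region_materials = region_materials
  ), class = "mwa_domain")
}

#' Build the tagged axisymmetric scenario geometry
#'
#' Lays out the half-plane geometry of the antenna-in-tissue model: the metal
#' conductors (excluded from the mesh, their surfaces become tagged
#' boundaries), the coax dielectric column and its feed, the two
#' dielectric-filled slots in the outer conductor wall, the catheter annulus
#' and end cap, and the surrounding tissue. Returns feature break lines and a
#' point classifier used by [generate_mesh()].
#'
#' @param domain A [domain_spec()] object.
#' @return Object of class `mwa_geometry` with elements `kind`, `r_features`,
#'   `z_features`, `classify(r, z)` (vectorised region lookup returning one of
#'   `"metal"`, `"coax_dielectric"`, `"slot"`, `"catheter"`, `"tissue"`),
#'   landmark coordinates, and the originating `domain`.
#' @export
build_scenario_geometry <- function(domain) {
  stopifnot(inherits(domain, "mwa_domain"))
  a <- domain$antenna
  D <- domain$insertion_depth
  s <- a$slot_spacing; w <- a$slot_width
  z_slot1 <- c(D - s / 2 - w / 2, D - s / 2 + w / 2)  # proximal slot
  z_slot2 <- c(D + s / 2 - w / 2, D + s / 2 + w / 2)  # distal slot
  z_tip   <- c(z_slot2[2], z_slot2[2] + a$tip_length)
  z_cap   <- c(z_tip[2], z_tip[2] + (a$catheter_radius - a$outer_conductor_radius))

  r_in <- a$inner_conductor_radius; r_d <- a$dielectric_radius
  r_o  <- a$outer_conductor_radius; r_c <- a$catheter_radius

  classify <- function(r, z) {
    out <- rep("tissue", length(r))
    feed <- z < z_tip[1]
    in_slot <- (z >= z_slot1[1] & z <= z_slot1[2]) | (z >= z_slot2[1] & z <= z_slot2[2])
    out[feed & r < r_in] <- "metal"
    out[feed & r >= r_in & r < r_d] <- "coax_dielectric"
    wall <- feed & r >= r_d & r < r_o
    out[wall] <- ifelse(in_slot[wall], "slot", "metal")
    out[feed & r >= r_o & r < r_c] <- "catheter"
    tip <- z >= z_tip[1] & z < z_tip[2]
    out[tip & r < r_o] <- "metal"
    out[tip & r >= r_o & r < r_c] <- "catheter"
    cap <- z >= z_cap[1] & z < z_cap[2]
    out[cap & r < r_c] <- "catheter"
    out
  }

  structure(list(
    kind = "scenario",
    domain = domain,
    r_features = c(0, r_in, r_d, r_o, r_c, domain$tissue_radius),
    z_features = c(0, z_slot1, z_slot2, z_tip[2], z_cap[2], domain$tissue_height),
    z_slot1 = z_slot1, z_slot2 = z_slot2, z_tip = z_tip, z_cap = z_cap,
    slot_band = c(z_slot1[1], z_slot2[2]),
    classify = classify
  ), class = "mwa_geometry")
}

#' Plain rectangle geometry (verification domains)
#'
#' A single-region rectangular half-plane block `[r0, r1] x [z0, z1]`, used by
#' the manufactured-solution verification fixtures. All perimeter edges are
#' tagged `outer_boundary` (plus `axis` where `r0 = 0`).
#'
#' @param r0,r1,z0,z1 Rectangle extent, m.
#' @param region Region tag for every element.
#' @return An `mwa_geometry` of kind `"rectangle"`.
#' @export
rectangle_geometry <- function(r0 = 0, r1 = 1, z0 = 0, z1 = 1, region = "tissue") {
  if (r1 <= r0 || z1 <= z0 || r0 < 0) {
    rlang::abort("rectangle must satisfy 0 <= r0 < r1 and z0 < z1",
                 class = "mwablate_geometry_error")
  }
  structure(list(
    kind = "rectangle",
    r_features = c(r0, r1),
    z_features = c(z0, z1),
    classify = function(r, z) rep(region, length(r))
  ), class = "mwa_geometry")
}
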