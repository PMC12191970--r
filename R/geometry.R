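#' Cylindrical vessel geometry with tilt and fill
#'
#' Describes the frozen solution inside a cylindrical vessel resting on the
#' dryer shelf. The lab frame has gravity along -z and the shelf plane at
#' z = 0; the vessel axis lies in the x-z plane, raised by `tilt_angle`
#' degrees from the shelf (90 = upright, 22 = the tilted configuration),
#' with the lowest point of the vessel surface touching the shelf. The free
#' surface of the fill is a horizontal plane in the lab frame (the solution
#' froze under gravity before drying).
#'
#' @param inner_radius Inner radius of the cylinder, m.
#' @param inner_length Inner length of the cylinder, m.
#' @param tilt_angle Angle between vessel axis and shelf plane, degrees, in
#'   (0, 90].
#' @param fill_volume Volume of frozen solution, m^3; must fit the vessel.
#' @return An object of class `vesselGeometry`.
#' @export
#' @examples
#' vesselGeometry(0.0145, 0.115, 22, 16e-6)
vesselGeometry <- function(inner_radius = 0.0145, inner_length = 0.115,
                           tilt_angle = 90, fill_volume = 16e-6) {
  for (v in list(inner_radius, inner_length, tilt_angle, fill_volume))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("vesselGeometry: all arguments must be finite numeric scalars")
  if (inner_radius <= 0 || inner_length <= 0)
    stop("vesselGeometry: radius and length must be positive")
  if (tilt_angle <= 0 || tilt_angle > 90)
    stop("vesselGeometry: tilt_angle must be in (0, 90] degrees")
  capacity <- pi * inner_radius^2 * inner_length
  if (fill_volume <= 0 || fill_volume > capacity)
    stop("vesselGeometry: fill_volume must be in (0, ",
         signif(capacity, 4), "] m^3 for this vessel")
  g <- list(inner_radius = inner_radius, inner_length = inner_length,
            tilt_angle = tilt_angle, fill_volume = fill_volume)
  class(g) <- "vesselGeometry"
  g
}

#' @export
print.vesselGeometry <- function(x, ...) {
  cat(sprintf(paste0("Cylindrical vessel: r = %.1f mm, L = %.1f mm, ",
                     "tilt = %g deg, fill = %.1f mL\n"),
              x$inner_radius * 1e3, x$inner_length * 1e3,
              x$tilt_angle, x$fill_volume * 1e6))
  invisible(x)
}

## Lab-frame description of the tilted cylinder: axis direction d in the x-z
## plane, base-cap center A placed so the lowest surface point touches z = 0.
.vesselFrame <- function(vessel) {
  th <- vessel$tilt_angle * pi / 180
  s <- sin(th); c <- cos(th)
  list(th = th, sin = s, cos = c,
       d = c(c, 0, s),
       A = c(0, 0, vessel$inner_radius * c),
       zmax = vessel$inner_radius * c + vessel$inner_length * s +
         vessel$inner_radius * c)
}

## Area of the part of a disk of radius r with in-plane coordinate a <= dcut.
.diskSegmentArea <- function(dcut, r) {
  d <- pmin(r, pmax(-r, dcut))
  r^2 * (pi / 2 + asin(d / r)) + d * sqrt(pmax(0, r^2 - d^2))
}

#' Volume of fill below a horizontal plane
#'
#' Volume of the region inside the cylinder below the lab-frame plane z = h.
#' Evaluated by exact disk-segment areas integrated along the vessel axis.
#'
#' @param vessel A [vesselGeometry()].
#' @param h Plane height above the shelf, m.
#' @return Volume, m^3.
#' @export
volumeBelowPlane <- function(vessel, h) {
  fr <- .vesselFrame(vessel)
  r <- vessel$inner_radius; L <- vessel$inner_length
  if (fr$cos < 1e-9) {            # upright: horizontal slices are full disks
    return(pi * r^2 * min(max(h, 0), L))
  }
  zc <- function(t) fr$A[3] + t * fr$sin
  f <- function(t) .diskSegmentArea((h - zc(t)) / fr$cos, r)
  stats::integrate(f, 0, L, rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Height of the horizontal free-surface plane
#'
#' Solves for the lab-frame height h of the horizontal plane such that the
#' fill volume below it equals `fill_volume`, by monotone root bracketing.
#'
#' @param vessel A [vesselGeometry()].
#' @return Plane height above the shelf, m; the enclosed volume matches
#'   `fill_volume` to a relative tolerance of 1e-6.
#' @export
#' @examples
#' fillPlaneHeight(vesselGeometry(tilt_angle = 90, fill_volume = 16e-6))
fillPlaneHeight <- function(vessel) {
  fr <- .vesselFrame(vessel)
  r <- vessel$inner_radius
  if (fr$cos < 1e-9) return(vessel$fill_volume / (pi * r^2))
  V <- vessel$fill_volume
  f <- function(h) volumeBelowPlane(vessel, h) - V
  h <- stats::uniroot(f, c(0, fr$zmax), tol = fr$zmax * 1e-12)$root
  if (abs(volumeBelowPlane(vessel, h) - V) > 1e-6 * V)
    stop("fillPlaneHeight: failed to reach the requested fill volume")
  h
}

## Internal: clipped-ellipse description of the plane z = h inside the
## cylinder. Returns semi-axes and the normalized clip bounds u1, u2.
.surfaceClip <- function(vessel, h) {
  fr <- .vesselFrame(vessel)
  r <- vessel$inner_radius; L <- vessel$inner_length
  tstar <- (h - fr$A[3]) / fr$sin      # axial coordinate where plane meets axis
  aE <- r / fr$sin
  if (fr$cos < 1e-9) {
    return(list(aE = aE, u1 = -1, u2 = 1, clipped = !(h > 0 && h < L)))
  }
  lo <- -tstar / fr$cos; hi <- (L - tstar) / fr$cos
  u1 <- max(-1, lo / aE); u2 <- min(1, hi / aE)
  list(aE = aE, u1 = u1, u2 = u2, clipped = (u1 > -1 || u2 < 1))
}

#' Area of the frozen free surface exposed to the chamber
#'
#' The fill's free surface is the horizontal plane z = h clipped to the
#' cylinder interior: a circle for the upright vessel, an ellipse of
#' semi-axes (r / sin(tilt), r) for a tilted vessel, truncated exactly where
#' the end caps clip it. For fixed fill the area grows as the tilt decreases
#' from 90 degrees, which is the geometric origin of the faster drying of
#' the tilted configuration.
#'
#' @param vessel A [vesselGeometry()].
#' @param h Optional plane height, m; defaults to [fillPlaneHeight()].
#' @return Exposed surface area, m^2.
#' @export
#' @examples
#' exposedSurfaceArea(vesselGeometry(tilt_angle = 22, fill_volume = 16e-6))
exposedSurfaceArea <- function(vessel, h = fillPlaneHeight(vessel)) {
  r <- vessel$inner_radius
  cl <- .surfaceClip(vessel, h)
  if (cl$u2 <= cl$u1) return(0)
  Fu <- function(u) u * sqrt(pmax(0, 1 - u^2)) + asin(u)
  r * cl$aE * (Fu(cl$u2) - Fu(cl$u1))
}

#' Is the free-surface ellipse entirely inside the cylinder wall?
#'
#' TRUE when the fill plane is not clipped by either end cap, i.e. the
#' exposed surface is the complete ellipse/circle.
#'
#' @inheritParams exposedSurfaceArea
#' @return Logical scalar.
#' @export
fillPlaneInside <- function(vessel, h = fillPlaneHeight(vessel)) {
  !.surfaceClip(vessel, h)$clipped
}

## Vectorized point classification. P: N x 3 matrix of lab-frame points.
## Returns list(inside, frozen) logicals.
.classifyPoints <- function(P, vessel, h, fr = .vesselFrame(vessel)) {
  rel <- cbind(P[, 1] - fr$A[1], P[, 2] - fr$A[2], P[, 3] - fr$A[3])
  tau <- rel[, 1] * fr$d[1] + rel[, 3] * fr$d[3]
  rad2 <- rel[, 1]^2 + rel[, 2]^2 + rel[, 3]^2 - tau^2
  inside <- tau >= 0 & tau <= vessel$inner_length &
    rad2 <= vessel$inner_radius^2 * (1 + 1e-12)
  list(inside = inside, frozen = inside & P[, 3] <= h)
}

#' Voxelize the vessel fill for the transport solver
#'
#' Discretizes the frozen fill and the headspace immediately above it on a
#' uniform lab-frame voxel grid aligned with the shelf (z = 0). Cells are
#' labeled `frozen` (contain ice), `headspace` (inside the vessel above the
#' fill plane) or `outside`; boundary cells carry the fraction of their
#' volume inside the frozen region (8-corner convexity test, 4^3 midpoint
#' subsampling for mixed cells). Faces are tagged as exposed (frozen cell
#' against headspace, weighted by the in-vessel fraction of the face), wall
#' (frozen cell against the vessel wall or domain edge) and shelf-contact
#' (wall faces within `shelf_tol` of the shelf plane).
#'
#' @param vessel A [vesselGeometry()].
#' @param cell_size Voxel edge length, m; must give at least 8 cells across
#'   the vessel diameter.
#' @param shelf_tol Wall faces with centers within this height of z = 0 are
#'   tagged as shelf contact, m. Defaults to one cell.
#' @param contact_tol Physical contact tolerance, m: the vessel surface
#'   within this height of the shelf plane is considered thermally coupled
#'   to the shelf (frost/surface irregularities bridge small gaps). The
#'   total shelf conductance is normalized to this analytic contact area,
#'   which keeps the shelf coupling independent of the mesh resolution: an
#'   upright vessel couples over its full base disk, a tilted one only over
#'   the small patch at the rim touching the shelf.
#' @return An object of class `voxelMesh`.
#' @export
voxelize <- function(vessel, cell_size, shelf_tol = cell_size,
                     contact_tol = 5e-4) {
  stopifnot(inherits(vessel, "vesselGeometry"))
  if (!is.numeric(cell_size) || cell_size <= 0 || !is.finite(cell_size))
    stop("voxelize: cell_size must be a positive number")
  if (2 * vessel$inner_radius / cell_size < 8)
    stop("voxelize: degenerate resolution; need >= 8 cells across the diameter")
  fr <- .vesselFrame(vessel)
  r <- vessel$inner_radius; L <- vessel$inner_length; dx <- cell_size
  h <- fillPlaneHeight(vessel)

  xmin <- min(-r * fr$sin, 0) - 1e-9
  xmax <- L * fr$cos + r * fr$sin + 1e-9
  ymin <- -r - 1e-9; ymax <- r + 1e-9
  ztop <- min(fr$zmax, h + 2.5 * dx)
  nx <- max(1L, as.integer(ceiling((xmax - xmin) / dx)))
  ny <- max(1L, as.integer(ceiling((ymax - ymin) / dx)))
  nz <- max(1L, as.integer(ceiling(ztop / dx)))
  x0 <- c(xmin, ymin, 0)

  xs <- x0[1] + (seq_len(nx) - 0.5) * dx
  ys <- x0[2] + (seq_len(ny) - 0.5) * dx
  zs <- x0[3] + (seq_len(nz) - 0.5) * dx

  ## corner classification (corners of all cells at once)
  cx <- x0[1] + (0:nx) * dx; cy <- x0[2] + (0:ny) * dx; cz <- x0[3] + (0:nz) * dx
  CP <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  cfrozen <- array(.classifyPoints(CP, vessel, h, fr)$frozen,
                   dim = c(nx + 1L, ny + 1L, nz + 1L))
  corner_count <- (cfrozen[1:nx, 1:ny, 1:nz] +
                   cfrozen[2:(nx + 1), 1:ny, 1:nz] +
                   cfrozen[1:nx, 2:(ny + 1), 1:nz] +
                   cfrozen[2:(nx + 1), 2:(ny + 1), 1:nz] +
                   cfrozen[1:nx, 1:ny, 2:(nz + 1)] +
                   cfrozen[2:(nx + 1), 1:ny, 2:(nz + 1)] +
                   cfrozen[1:nx, 2:(ny + 1), 2:(nz + 1)] +
                   cfrozen[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)])

  CC <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  ctr <- .classifyPoints(CC, vessel, h, fr)
  ctr_inside <- array(ctr$inside, dim = c(nx, ny, nz))
  ctr_frozen <- array(ctr$frozen, dim = c(nx, ny, nz))

  frac <- array(0, dim = c(nx, ny, nz))
  frac[corner_count == 8L] <- 1          # cylinder-below-plane is convex
  ## cells with no frozen corner can still hold a sliver of the region near
  ## the curved wall or the tangent contact line: catch every cell whose
  ## center lies within half a cell diagonal of the frozen region
  reld <- cbind(CC[, 1] - fr$A[1], CC[, 2] - fr$A[2], CC[, 3] - fr$A[3])
  tauc <- reld[, 1] * fr$d[1] + reld[, 3] * fr$d[3]
  radc <- sqrt(pmax(0, reld[, 1]^2 + reld[, 2]^2 + reld[, 3]^2 - tauc^2))
  marg <- sqrt(3) / 2 * dx
  near <- array(tauc > -marg & tauc < L + marg & radc < r + marg &
                CC[, 3] < h + marg, dim = c(nx, ny, nz))
  mixed <- which((corner_count > 0L & corner_count < 8L) |
                 (corner_count == 0L & (ctr_frozen | near)))
  if (length(mixed)) {
    ## 4^3 midpoint subsample; the horizontal fill plane is clipped exactly
    ## within each subcell (a point test would quantize the plane cut
    ## identically across every surface cell and bias the total volume)
    off <- ((1:4) - 0.5) / 4 - 0.5       # cell units
    sub <- as.matrix(expand.grid(off, off, off)) * dx
    hz <- dx / 4
    M <- CC[mixed, , drop = FALSE]
    acc <- numeric(length(mixed))
    for (k in seq_len(nrow(sub))) {
      SP <- cbind(M[, 1] + sub[k, 1], M[, 2] + sub[k, 2], M[, 3] + sub[k, 3])
      ins <- .classifyPoints(SP, vessel, fr$zmax + 1, fr)$frozen  # inside only
      wz <- pmin(1, pmax(0, (h - (SP[, 3] - hz / 2)) / hz))
      acc <- acc + ins * wz
    }
    frac[mixed] <- acc / nrow(sub)
    frac[frac < 1e-9] <- 0    # guard against floating-point slivers
  }

  ## labels: 1 frozen, 2 headspace, 3 outside
  label <- array(3L, dim = c(nx, ny, nz))
  label[ctr_inside] <- 2L
  label[frac > 0] <- 1L

  solid <- which(label == 1L)
  ns <- length(solid)
  if (ns == 0L) stop("voxelize: no frozen cells; check fill volume")
  sidx <- array(0L, dim = c(nx, ny, nz)); sidx[solid] <- seq_len(ns)

  ## face enumeration along each axis
  int_a <- integer(0); int_b <- integer(0)
  exp_cell <- integer(0); exp_w <- numeric(0)
  exp_ctr <- matrix(0, 0, 3)
  wall_cell <- integer(0); wall_z <- numeric(0); wall_down <- logical(0)
  dims <- c(nx, ny, nz)
  lin <- array(seq_len(nx * ny * nz), dim = dims)
  for (ax in 1:3) {
    n_ax <- dims[ax]
    idxA <- switch(ax, lin[-n_ax, , , drop = FALSE], lin[, -n_ax, , drop = FALSE],
                   lin[, , -n_ax, drop = FALSE])
    idxB <- switch(ax, lin[-1, , , drop = FALSE], lin[, -1, , drop = FALSE],
                   lin[, , -1, drop = FALSE])
    la <- label[idxA]; lb <- label[idxB]
    ## internal frozen-frozen faces
    k <- which(la == 1L & lb == 1L)
    int_a <- c(int_a, sidx[idxA[k]]); int_b <- c(int_b, sidx[idxB[k]])
    ## exposed: frozen against headspace (either orientation)
    for (swap in c(FALSE, TRUE)) {
      iF <- if (swap) idxB else idxA
      iH <- if (swap) idxA else idxB
      k <- which(label[iF] == 1L & label[iH] == 2L)
      if (!length(k)) next
      fc <- CC[iF[k], , drop = FALSE]
      fc[, ax] <- fc[, ax] + (if (swap) -dx / 2 else dx / 2)
      w <- .faceInsideWeight(fc, ax, dx, vessel, fr, h)
      keep <- w > 1e-9
      exp_cell <- c(exp_cell, sidx[iF[k]][keep])
      exp_w <- c(exp_w, w[keep])
      exp_ctr <- rbind(exp_ctr, fc[keep, , drop = FALSE])
    }
    ## wall: frozen against outside (either orientation)
    for (swap in c(FALSE, TRUE)) {
      iF <- if (swap) idxB else idxA
      iO <- if (swap) idxA else idxB
      k <- which(label[iF] == 1L & label[iO] == 3L)
      if (!length(k)) next
      zc <- CC[iF[k], 3]
      if (ax == 3) zc <- zc + (if (swap) -dx / 2 else dx / 2)
      wall_cell <- c(wall_cell, sidx[iF[k]])
      wall_z <- c(wall_z, zc)
      wall_down <- c(wall_down, rep(ax == 3 && swap, length(k)))
    }
    ## domain-boundary faces of frozen cells count as wall
    for (side in 1:2) {
      slice <- switch(ax,
                      lin[if (side == 1) 1 else nx, , , drop = FALSE],
                      lin[, if (side == 1) 1 else ny, , drop = FALSE],
                      lin[, , if (side == 1) 1 else nz, drop = FALSE])
      k <- which(label[slice] == 1L)
      if (!length(k)) next
      zc <- CC[slice[k], 3]
      if (ax == 3) zc <- zc + (if (side == 1) -dx / 2 else dx / 2)
      wall_cell <- c(wall_cell, sidx[slice[k]])
      wall_z <- c(wall_z, zc)
      wall_down <- c(wall_down, rep(ax == 3 && side == 1, length(k)))
    }
  }
  ## shelf contact: downward-facing wall faces near the shelf plane,
  ## conductance-normalized to the analytic contact-patch area
  shelf <- which(wall_down & wall_z <= shelf_tol + 1e-12)
  contact_area <- shelfContactArea(vessel, contact_tol)
  shelf_scale <- if (length(shelf) > 0)
    contact_area / (length(shelf) * dx^2) else 0

  mesh <- list(
    vessel = vessel, cell_size = dx, dims = dims, origin = x0,
    fill_height = h,
    cell_labels = label,              # 1 frozen, 2 headspace, 3 outside
    cell_volume_fractions = frac,
    solid_cells = solid,              # grid linear indices of frozen cells
    solid_centers = CC[solid, , drop = FALSE],
    solid_frac = frac[solid],
    cell_volume = dx^3,
    int_faces = cbind(a = int_a, b = int_b),
    exposed_faces = list(cell = exp_cell, weight = exp_w, center = exp_ctr),
    wall_faces = list(cell = wall_cell, z = wall_z),
    shelf_contact_faces = list(cell = wall_cell[shelf], z = wall_z[shelf],
                               scale = shelf_scale),
    shelf_contact_area = contact_area
  )
  class(mesh) <- "voxelMesh"
  mesh
}

## Fraction of a voxel face (normal along axis `ax`, center fc) lying inside
## the cylinder, by 4x4 point subsampling.
.faceInsideWeight <- function(fc, ax, dx, vessel, fr, h) {
  off <- ((1:4) - 0.5) / 4 - 0.5
  grid2 <- as.matrix(expand.grid(off, off)) * dx
  tang <- setdiff(1:3, ax)
  acc <- numeric(nrow(fc))
  for (k in seq_len(nrow(grid2))) {
    P <- fc
    P[, tang[1]] <- P[, tang[1]] + grid2[k, 1]
    P[, tang[2]] <- P[, tang[2]] + grid2[k, 2]
    acc <- acc + .classifyPoints(P, vessel, h, fr)$inside
  }
  acc / nrow(grid2)
}

#' @export
print.voxelMesh <- function(x, ...) {
  cat(sprintf(paste0("Voxel mesh: %d x %d x %d grid (%.2f mm cells), ",
                     "%d frozen cells\n"),
              x$dims[1], x$dims[2], x$dims[3], x$cell_size * 1e3,
              length(x$solid_cells)))
  cat(sprintf("  frozen volume %.3f mL (fill %.3f mL), %d exposed faces, %d shelf faces\n",
              sum(x$solid_frac) * x$cell_volume * 1e6,
              x$vessel$fill_volume * 1e6,
              length(x$exposed_faces$cell),
              length(x$shelf_contact_faces$cell)))
  invisible(x)
}

#' Analytic shelf-contact area of the vessel
#'
#' Area of the vessel surface (lateral wall plus end caps) lying within
#' `contact_tol` of the shelf plane z = 0. For an upright vessel this is
#' the base disk (plus a thin wall ring); for a tilted vessel only the
#' small patch around the rim point resting on the shelf.
#'
#' @param vessel A [vesselGeometry()].
#' @param contact_tol Contact height tolerance, m.
#' @return Area, m^2.
#' @export
shelfContactArea <- function(vessel, contact_tol = 5e-4) {
  fr <- .vesselFrame(vessel)
  r <- vessel$inner_radius; L <- vessel$inner_length
  ## end caps: tilted planes; z of a cap point = z_center + a*cos(theta)
  capArea <- function(zc) {
    if (fr$cos < 1e-9)
      return(if (zc <= contact_tol) pi * r^2 else 0)
    .diskSegmentArea((contact_tol - zc) / fr$cos, r)
  }
  A_caps <- capArea(fr$A[3]) + capArea(fr$A[3] + L * fr$sin)
  ## lateral surface: z(t, phi) = zA + t*sin(theta) + r*cos(theta)*cos(phi)
  nt <- 400L; np <- 400L
  tg <- (seq_len(nt) - 0.5) / nt * L
  pg <- (seq_len(np) - 0.5) / np * 2 * pi
  zg <- outer(tg * fr$sin, r * fr$cos * cos(pg), `+`) + fr$A[3]
  A_lat <- sum(zg <= contact_tol) * (L / nt) * (2 * pi * r / np)
  A_caps + A_lat
}

#' Total frozen volume represented by the mesh
#'
#' @param mesh A [voxelize()] mesh.
#' @return Volume, m^3: sum of cell volume times frozen volume fraction.
#' @export
meshFrozenVolume <- function(mesh) {
  sum(mesh$solid_frac) * mesh$cell_volume
}

#' Exposed surface area resolved by the mesh
#'
#' Sum of face-overlap-weighted exposed face areas; approximates
#' [exposedSurfaceArea()] from the voxel side.
#'
#' @param mesh A [voxelize()] mesh.
#' @return Area, m^2.
#' @export
meshExposedArea <- function(mesh) {
  sum(mesh$exposed_faces$weight) * mesh$cell_size^2
}

#' Export cell labels and ice field as VTK image data
#'
#' Writes an ASCII VTK XML ImageData (.vti) file with the cell labels, the
#' frozen volume fractions, and optionally a simulation state's ice and
#' temperature fields, for inspection in ParaView or similar viewers.
#'
#' @param mesh A [voxelize()] mesh.
#' @param path Output file path (conventionally `.vti`).
#' @param state Optional `simulationState` whose `s` and `T` fields are
#'   written as additional cell arrays.
#' @return Invisibly, `path`.
#' @export
exportMeshVTK <- function(mesh, path, state = NULL) {
  d <- mesh$dims; dx <- mesh$cell_size; o <- mesh$origin
  arrays <- list(label = as.vector(mesh$cell_labels),
                 frozen_fraction = as.vector(mesh$cell_volume_fractions))
  if (!is.null(state)) {
    sfull <- numeric(prod(d)); Tfull <- numeric(prod(d))
    sfull[mesh$solid_cells] <- state$s
    Tfull[mesh$solid_cells] <- state$T
    arrays$ice <- sfull; arrays$temperature <- Tfull
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%g %g %g" Spacing="%g %g %g">',
            d[1], d[2], d[3], o[1], o[2], o[3], dx, dx, dx),
    sprintf('    <Piece Extent="0 %d 0 %d 0 %d">', d[1], d[2], d[3]),
    '      <CellData>'), con)
  for (nm in names(arrays)) {
    writeLines(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm), con)
    writeLines(paste(format(arrays[[nm]], digits = 8), collapse = " "), con)
    writeLines('        </DataArray>', con)
  }
  writeLines(c('      </CellData>', '    </Piece>', '  </ImageData>',
               '</VTKFile>'), con)
  invisible(path)
}
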