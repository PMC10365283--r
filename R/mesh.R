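#' Triangle surface mesh
#'
#' Minimal triangle-mesh container: an `n x 3` vertex matrix (mm) and an
#' `m x 3` integer face matrix of 1-based vertex indices, consistently
#' oriented (outward normals).
#'
#' @param vertices numeric matrix n x 3.
#' @param faces integer matrix m x 3.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3) .stopf("`vertices` must have 3 columns")
  if (ncol(faces) != 3) .stopf("mesh is not triangulated (faces must have 3 vertices)")
  if (nrow(faces) == 0) .stopf("empty mesh")
  storage.mode(faces) <- "integer"
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    .stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedron
#' volumes against the origin); the absolute value is returned, so a
#' consistently inward-oriented mesh yields the same magnitude.
#'
#' @param mesh a [surface_mesh].
#' @return volume in mm^3 (non-negative).
#' @export
mesh_volume <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) .stopf("`mesh` must be a surface_mesh")
  .check_watertight(mesh)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  cc <- v[mesh$faces[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
           a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
  abs(s) / 6
}

# closed-chain condition: every directed edge is balanced by its reverse,
# which makes the divergence-theorem volume well defined (this admits the
# benign non-manifold junctions produced by vertex-clustering decimation)
.check_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev <- paste(e[, 2], e[, 1])
  tf <- table(fwd); tr <- table(rev)
  keys <- union(names(tf), names(tr))
  cf <- as.integer(tf[keys]); cf[is.na(cf)] <- 0L
  cr <- as.integer(tr[keys]); cr[is.na(cr)] <- 0L
  if (any(cf != cr))
    .stopf("mesh is not watertight (%d unbalanced directed edges)", sum(cf != cr))
  invisible(TRUE)
}

#' Surface mesh of a voxel mask
#'
#' Emits one quad (two triangles) per exposed voxel face, producing a
#' watertight, consistently oriented mesh whose enclosed volume equals
#' the voxel count times the voxel volume exactly.
#'
#' @param mask binary [label_mask].
#' @return a [surface_mesh] in mm coordinates; carries the voxel size as
#'   attribute `voxel_size_um`.
#' @export
mask_to_mesh <- function(mask) {
  arr <- .as_logical_arr(mask$data)
  d <- dim(arr)
  dv <- .vox_mm(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  idx <- which(pad)
  pd <- dim(pad)
  i0 <- (idx - 1L) %% pd[1]
  j0 <- ((idx - 1L) %/% pd[1]) %% pd[2]
  k0 <- (idx - 1L) %/% (pd[1] * pd[2])
  # neighbour occupancy along each axis direction
  shift <- function(di, dj, dk) pad[cbind(i0 + 1L + di, j0 + 1L + dj, k0 + 1L + dk)]
  verts <- list(); faces <- list(); nv <- 0L
  # voxel (i0, j0, k0) in padded grid corresponds to original voxel index
  # (i0, j0, k0) zero-based; its corner (low) in mm:
  cx <- mask$origin_mm[1] + (i0 - 1L) * dv
  cy <- mask$origin_mm[2] + (j0 - 1L) * dv
  cz <- mask$origin_mm[3] + (k0 - 1L) * dv
  emit <- function(sel, corners_fun, flip) {
    if (!any(sel)) return(invisible(NULL))
    n <- sum(sel)
    q <- corners_fun(cx[sel], cy[sel], cz[sel], dv)   # list of 4 corner matrices
    vbase <- nv + 4 * (seq_len(n) - 1L)
    vv <- matrix(0, 4 * n, 3)
    vv[seq(1, 4 * n, 4), ] <- q[[1]]
    vv[seq(2, 4 * n, 4), ] <- q[[2]]
    vv[seq(3, 4 * n, 4), ] <- q[[3]]
    vv[seq(4, 4 * n, 4), ] <- q[[4]]
    if (flip) {
      ff <- rbind(cbind(vbase + 1L, vbase + 3L, vbase + 2L),
                  cbind(vbase + 1L, vbase + 4L, vbase + 3L))
    } else {
      ff <- rbind(cbind(vbase + 1L, vbase + 2L, vbase + 3L),
                  cbind(vbase + 1L, vbase + 3L, vbase + 4L))
    }
    verts[[length(verts) + 1L]] <<- vv
    faces[[length(faces) + 1L]] <<- ff
    nv <<- nv + 4L * n
    invisible(NULL)
  }
  quad_x <- function(x, y, z, dv, at) list(cbind(x + at, y, z), cbind(x + at, y + dv, z),
                                           cbind(x + at, y + dv, z + dv), cbind(x + at, y, z + dv))
  quad_y <- function(x, y, z, dv, at) list(cbind(x, y + at, z), cbind(x + dv, y + at, z),
                                           cbind(x + dv, y + at, z + dv), cbind(x, y + at, z + dv))
  quad_z <- function(x, y, z, dv, at) list(cbind(x, y, z + at), cbind(x + dv, y, z + at),
                                           cbind(x + dv, y + dv, z + at), cbind(x, y + dv, z + at))
  emit(!shift(-1L, 0L, 0L), function(x, y, z, dv) quad_x(x, y, z, dv, 0), flip = TRUE)
  emit(!shift(1L, 0L, 0L), function(x, y, z, dv) quad_x(x, y, z, dv, dv), flip = FALSE)
  emit(!shift(0L, -1L, 0L), function(x, y, z, dv) quad_y(x, y, z, dv, 0), flip = FALSE)
  emit(!shift(0L, 1L, 0L), function(x, y, z, dv) quad_y(x, y, z, dv, dv), flip = TRUE)
  emit(!shift(0L, 0L, -1L), function(x, y, z, dv) quad_z(x, y, z, dv, 0), flip = TRUE)
  emit(!shift(0L, 0L, 1L), function(x, y, z, dv) quad_z(x, y, z, dv, dv), flip = FALSE)
  if (length(verts) == 0) .stopf("mask is empty")
  V <- do.call(rbind, verts)
  F <- do.call(rbind, faces)
  # merge duplicated corner vertices so shared edges are identified
  key <- paste(round(V[, 1] / dv * 2), round(V[, 2] / dv * 2), round(V[, 3] / dv * 2))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  V <- V[uk, , drop = FALSE]
  F <- matrix(map[F], ncol = 3)
  m <- surface_mesh(V, F)
  attr(m, "voxel_size_um") <- mask$voxel_size_um
  attr(m, "source_mask") <- mask   # cached voxel field; avoids re-voxelization
  m
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a standard synthetic
#' test solid and the initial enclosure for the shrink-wrap backend.
#'
#' @param radius_mm sphere radius.
#' @param center_mm 3D centre.
#' @param subdivisions number of 4-fold subdivision passes (0-5).
#' @return a [surface_mesh] with `20 * 4^subdivisions` faces.
#' @export
icosphere <- function(radius_mm = 1, center_mm = c(0, 0, 0), subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    getmid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mids[[k]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 4 * nf, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  surface_mesh(sweep(v * radius_mm, 2, -as.numeric(center_mm)), f)
}

#' Decimate a mesh by vertex clustering
#'
#' Clusters vertices on a uniform grid and collapses each cluster to its
#' centroid, dropping degenerate faces. The grid size is grown until the
#' face budget is met. Topology-preserving for meshes whose features are
#' larger than the final cell size.
#'
#' @param mesh a [surface_mesh].
#' @param target_faces maximum number of output faces (>= 8).
#' @return a [surface_mesh] with at most `target_faces` faces.
#' @export
decimate_mesh <- function(mesh, target_faces) {
  if (target_faces < 8) .stopf("`target_faces` must be >= 8")
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  bb <- apply(mesh$vertices, 2, range)
  ext <- max(bb[2, ] - bb[1, ])
  cell <- ext / 64
  for (it in 1:24) {
    key <- paste(floor((mesh$vertices[, 1] - bb[1, 1]) / cell),
                 floor((mesh$vertices[, 2] - bb[1, 2]) / cell),
                 floor((mesh$vertices[, 3] - bb[1, 3]) / cell))
    grp <- match(key, unique(key))
    V <- apply(mesh$vertices, 2, function(col) tapply(col, grp, mean))
    if (is.null(dim(V))) V <- matrix(V, ncol = 3)
    F <- matrix(grp[mesh$faces], ncol = 3)
    keep <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
    F <- F[keep, , drop = FALSE]
    if (nrow(F) <= target_faces && nrow(F) >= 4) return(surface_mesh(V, F))
    cell <- cell * 1.5
  }
  .stopf("decimation failed to reach %d faces", target_faces)
}

#' Voxelize a watertight mesh
#'
#' Column-parity voxelization: for every (x, y) voxel column, ray
#' crossings with the mesh along z are accumulated and the interior
#' filled between odd/even crossing pairs.
#'
#' @param mesh a [surface_mesh].
#' @param voxel_size_um voxel size of the output grid.
#' @param pad_vox empty padding around the mesh bounding box.
#' @return a binary [label_mask].
#' @export
voxelize_mesh <- function(mesh, voxel_size_um, pad_vox = 2L) {
  dv <- voxel_size_um / 1000
  bb <- apply(mesh$vertices, 2, range)
  origin <- bb[1, ] - pad_vox * dv
  dims <- ceiling((bb[2, ] - bb[1, ]) / dv) + 2L * pad_vox
  arr <- array(FALSE, dims)
  v <- mesh$vertices
  f <- mesh$faces
  # centres of columns
  for (ti in seq_len(nrow(f))) {
    a <- v[f[ti, 1], ]; b <- v[f[ti, 2], ]; cc <- v[f[ti, 3], ]
    xr <- range(a[1], b[1], cc[1]); yr <- range(a[2], b[2], cc[2])
    i1 <- max(1L, floor((xr[1] - origin[1]) / dv - 0.5) + 1L)
    i2 <- min(dims[1], ceiling((xr[2] - origin[1]) / dv + 0.5))
    j1 <- max(1L, floor((yr[1] - origin[2]) / dv - 0.5) + 1L)
    j2 <- min(dims[2], ceiling((yr[2] - origin[2]) / dv + 0.5))
    if (i1 > i2 || j1 > j2) next
    for (i in i1:i2) for (j in j1:j2) {
      px <- origin[1] + (i - 0.5) * dv
      py <- origin[2] + (j - 0.5) * dv
      # barycentric in xy
      d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
      if (abs(d) < 1e-14) next
      l1 <- ((b[2] - cc[2]) * (px - cc[1]) + (cc[1] - b[1]) * (py - cc[2])) / d
      l2 <- ((cc[2] - a[2]) * (px - cc[1]) + (a[1] - cc[1]) * (py - cc[2])) / d
      l3 <- 1 - l1 - l2
      # half-open edge rule to avoid double-counting shared edges
      if (l1 < 0 || l2 < 0 || l3 <= 0) next
      zhit <- l1 * a[3] + l2 * b[3] + l3 * cc[3]
      k <- floor((zhit - origin[3]) / dv + 0.5) + 1L
      # toggle parity: flip all voxels above the crossing
      if (k <= dims[3]) {
        kk <- max(1L, k):dims[3]
        arr[i, j, kk] <- !arr[i, j, kk]
      }
    }
  }
  label_mask(arr, voxel_size_um, origin)
}
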