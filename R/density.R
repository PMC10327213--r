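# Density grids: CCP4/MRC input/output, model-to-density synthesis (X-ray and
# electron modes), residue footprints and target-vector extraction.
#
# Grids are P1, orthogonal, stored x-fastest; voxel centers sit at
# origin + index * spacing with 0-based indices.

#' Construct a density grid
#'
#' @param values 3-D numeric array (x, y, z; x fastest-varying on disk).
#' @param spacing voxel spacing, 3-vector, angstroms (> 0).
#' @param origin Cartesian position of voxel (0, 0, 0), angstroms.
#' @return A `density_grid`.
#' @export
density_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin),
                 cell = dim(values) * spacing),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density grid: %d x %d x %d voxels, spacing %.3f %.3f %.3f A, origin (%.2f, %.2f, %.2f)\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L],
              x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CCP4/MRC mode-2 (float32) I/O, MRC-2014 header, orthorhombic P1 only.

#' Read or write a CCP4/MRC density map
#'
#' Mode-2 (32-bit float) maps with an orthogonal cell.  On input the axis
#' order is normalized to x-fast and the origin honored from the MRC-2014
#' origin words (falling back to NXSTART-style offsets).  Non-orthogonal
#' cells are rejected.
#'
#' @param path file path.
#' @return `read_ccp4()`: a [density_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0L)
  hdr_f <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  nxyz <- hdr_i[1:3]
  mode <- hdr_i[4L]
  if (mode != 2L) stop("unsupported map mode ", mode, " (mode-2 float only)")
  nstart <- hdr_i[5:7]
  mxyz <- hdr_i[8:10]
  cella <- hdr_f[11:13]
  angles <- hdr_f[14:16]
  if (any(abs(angles - 90) > 1e-3))
    stop("unsupported cell: non-orthogonal angles (P1 orthogonal only)")
  mapcrs <- hdr_i[17:19]
  origin_mrc <- hdr_f[50:52]
  seek(con, 1024L)
  if (hdr_i[24L] > 0L) invisible(readBin(con, "raw", n = hdr_i[24L]))
  nv <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nv, size = 4L, endian = "little")
  if (length(vals) < nv) stop("truncated map data in ", path)
  arr <- array(vals, dim = nxyz)
  # normalize axis order so that array dim 1 is crystallographic X, etc.
  if (!all(mapcrs == 1:3)) {
    perm <- order(mapcrs)
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]
  }
  spacing <- cella / mxyz
  origin <- if (any(origin_mrc != 0)) origin_mrc else nstart * spacing
  density_grid(arr, spacing = spacing, origin = origin)
}

#' @rdname read_ccp4
#' @param grid a [density_grid()].
#' @return `write_ccp4()`: invisibly, the path.
#' @export
write_ccp4 <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.vector(grid$values)
  wi(d); wi(2L)                       # NX NY NZ, MODE
  wi(c(0L, 0L, 0L)); wi(d)            # NXSTART.., MX MY MZ
  wf(grid$cell); wf(c(90, 90, 90))    # CELLA, CELLB
  wi(1:3)                             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))      # DMIN DMAX DMEAN
  wi(1L); wi(0L)                      # ISPG, NSYMBT
  wi(rep(0L, 25L))                    # EXTRA (words 26-49, MRC2014 reserves)
  wf(grid$origin)                     # ORIGIN words 50-52
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v)); wi(0L)            # RMS, NLABL
  writeBin(raw(800L), con)            # labels
  wf(v)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Voxel arithmetic

# Cartesian coordinates (n x 3) of linear (1-based) voxel indices.
.voxel_coords <- function(grid, lin_idx) {
  d <- dim(grid$values)
  i0 <- lin_idx - 1L
  ix <- i0 %% d[1L]
  iy <- (i0 %/% d[1L]) %% d[2L]
  iz <- i0 %/% (d[1L] * d[2L])
  cbind(grid$origin[1L] + ix * grid$spacing[1L],
        grid$origin[2L] + iy * grid$spacing[2L],
        grid$origin[3L] + iz * grid$spacing[3L])
}

#' Scattering mode for density synthesis and scoring
#'
#' Bundles the experiment type with its solvent background convention: X-ray
#' scoring subtracts a flat bulk-solvent level (default 0.3) from the
#' observed density, cryo-EM subtracts nothing.
#'
#' @param mode `"xray"` or `"em"`.
#' @param solvent_level flat background subtracted from observed density
#'   before fitting; forced to 0 in EM mode.
#' @param normalize if `TRUE`, maps are rescaled to unit mean positive
#'   density before the subtraction (off by default: maps are taken on their
#'   own scale).
#' @return A `scattering_mode` list.
#' @export
scattering_mode <- function(mode = c("xray", "em"), solvent_level = NULL,
                            normalize = FALSE) {
  mode <- match.arg(mode)
  if (is.null(solvent_level)) solvent_level <- if (mode == "em") 0 else 0.3
  if (mode == "em") solvent_level <- 0
  structure(list(mode = mode, solvent_level = solvent_level,
                 normalize = normalize), class = "scattering_mode")
}

#' Residue footprint: voxels used to score candidates
#'
#' Union of voxels within `rmask` of any atom of any candidate conformer
#' (each atom also claims its nearest voxel, so the footprint is never
#' empty for in-map atoms).  Ordering is deterministic (ascending linear
#' index).
#'
#' @param candidates a candidate set (see [sample_backbone()]) or a list of
#'   conformers.
#' @param grid a [density_grid()].
#' @param rmask mask radius, angstroms.
#' @return Integer vector of 1-based linear voxel indices, class
#'   `"footprint"`.
#' @export
extract_footprint <- function(candidates, grid, rmask) {
  confs <- if (!is.null(candidates$conformers)) candidates$conformers
           else candidates
  if (!length(confs)) stop("empty candidate set in extract_footprint")
  xyz <- do.call(rbind, lapply(confs, function(cf) atom_coords(cf$atoms)))
  d <- dim(grid$values)
  sp <- grid$spacing
  orig <- grid$origin
  frac <- sweep(sweep(xyz, 2L, orig), 2L, sp, `/`)   # 0-based voxel coords
  if (any(frac < -0.5) || any(frac > matrix(rep(d - 0.5, each = nrow(frac)),
                                            ncol = 3L)))
    stop("residue outside map (out-of-map)")
  mask <- array(FALSE, dim = d)
  rv <- ceiling(rmask / sp)
  for (k in seq_len(nrow(frac))) {
    ctr <- frac[k, ]
    lo <- pmax(0L, floor(ctr - rv))
    hi <- pmin(d - 1L, ceiling(ctr + rv))
    ix <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; iz <- lo[3L]:hi[3L]
    dx2 <- ((ix - ctr[1L]) * sp[1L])^2
    dy2 <- ((iy - ctr[2L]) * sp[2L])^2
    dz2 <- ((iz - ctr[3L]) * sp[3L])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rmask^2
    mask[ix + 1L, iy + 1L, iz + 1L] <- mask[ix + 1L, iy + 1L, iz + 1L] | sub
    # nearest voxel always included
    nb <- pmin(pmax(round(ctr), 0L), d - 1L)
    mask[nb[1L] + 1L, nb[2L] + 1L, nb[3L] + 1L] <- TRUE
  }
  idx <- which(mask)
  structure(idx, class = "footprint", n = length(idx))
}

# Gaussian width (variance, A^2) of an atom: B-factor spread plus a
# resolution-dependent blur (default constant 0.225 * d).
.atom_variance <- function(b, resolution, blur = 0.225) {
  b / (8 * pi^2) + (blur * resolution)^2
}

#' Calculated density of a conformer over a footprint
#'
#' Each atom contributes an isotropic 3-D Gaussian of integrated weight
#' `occupancy * amplitude` (amplitude = electron count for X-ray, tabulated
#' electron-scattering amplitude for EM) and variance
#' `B / (8 pi^2) + (blur * resolution)^2`.  Linear in occupancy, additive
#' over atoms.
#'
#' @param conformer a conformer.
#' @param grid a [density_grid()] (geometry only; values unused).
#' @param footprint a footprint from [extract_footprint()].
#' @param mode a [scattering_mode()].
#' @param resolution map resolution, angstroms (> 0).
#' @param blur resolution-blur constant.
#' @return Numeric vector of calculated density over the footprint voxels.
#' @export
density_from_conformer <- function(conformer, grid, footprint, mode,
                                   resolution, blur = 0.225) {
  if (resolution <= 0) stop("resolution must be positive")
  at <- conformer$atoms
  if (any(at$b <= 0)) stop("atoms must have positive B-factors")
  vox <- .voxel_coords(grid, as.integer(footprint))
  amp <- at$occ * .scatter_amp(at$element, mode$mode)
  v <- .atom_variance(at$b, resolution, blur)
  out <- numeric(nrow(vox))
  for (j in seq_len(nrow(at))) {
    d2 <- (vox[, 1L] - at$x[j])^2 + (vox[, 2L] - at$y[j])^2 +
      (vox[, 3L] - at$z[j])^2
    out <- out + amp[j] * (2 * pi * v[j])^(-1.5) * exp(-d2 / (2 * v[j]))
  }
  out
}

# Density matrix (voxels x candidates) for a list of conformers, with each
# conformer's occupancy forced to 1 so QP weights represent occupancies.
.candidate_densities <- function(confs, grid, footprint, mode, resolution,
                                 blur = 0.225) {
  vapply(confs, function(cf) {
    cf$atoms$occ <- 1
    density_from_conformer(cf, grid, footprint, mode, resolution, blur)
  }, numeric(length(footprint)))
}

#' Observed density target over a footprint
#'
#' Extracts the experimental density over the footprint, subtracts the
#' mode's flat solvent level and floors negative values at zero.
#'
#' @inheritParams density_from_conformer
#' @return Numeric vector over the footprint voxels.
#' @export
target_vector <- function(grid, footprint, mode) {
  v <- grid$values[as.integer(footprint)]
  if (isTRUE(mode$normalize)) {
    pos <- grid$values[grid$values > 0]
    if (length(pos) && mean(pos) > 0) v <- v / mean(pos)
  }
  pmax(v - mode$solvent_level, 0)
}

# Sub-grid covering a bounding box (used for the map-partitioning contract:
# building against a residue-centered crop equals building against the full
# map provided the crop covers footprint + rmask margin).
crop_grid <- function(grid, center, radius) {
  d <- dim(grid$values)
  lo <- pmax(0L, floor((center - radius - grid$origin) / grid$spacing))
  hi <- pmin(d - 1L, ceiling((center + radius - grid$origin) / grid$spacing))
  vals <- grid$values[(lo[1L] + 1L):(hi[1L] + 1L),
                      (lo[2L] + 1L):(hi[2L] + 1L),
                      (lo[3L] + 1L):(hi[3L] + 1L), drop = FALSE]
  density_grid(vals, spacing = grid$spacing,
               origin = grid$origin + lo * grid$spacing)
}
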