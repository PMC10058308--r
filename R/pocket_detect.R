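# Two-probe discrete-volume pocket detection on a shared global lattice.
#
# The solvent-excluded (SE) region for a probe of radius r is the morphological
# closing of the atom occupancy by a ball of radius r, minus the occupancy
# itself: cells the probe cannot sweep however it is placed without clashing.
# Pockets are SE(large probe) \ SE(small probe), split into 6-connected
# components. Computed with two Euclidean distance transforms per probe.

.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
.VDW_DEFAULT_OTHER <- 1.60

.vdw_radii <- function(elements, table = .DEFAULT_VDW,
                       default = .VDW_DEFAULT_OTHER) {
  r <- unname(table[elements])
  r[is.na(r)] <- default
  r
}

#' Construct a grid pocket from integer lattice cells
#'
#' @param cells Integer matrix (n x 3) of occupied lattice cells.
#' @param spacing Lattice spacing in Angstrom.
#' @param origin Lattice origin in Angstrom.
#' @param model_index,pocket_index 1-based indices of the pocket's model and
#'   its rank within the model.
#' @param label Pocket label; defaults to `"m<model>-<index>"`.
#' @return An object of class `grid_pocket`.
#' @export
new_grid_pocket <- function(cells, spacing, origin, model_index = 1L,
                            pocket_index = 1L, label = NULL) {
  cells <- matrix(as.integer(cells), ncol = 3)
  structure(list(
    cells = cells,
    n_cells = nrow(cells),
    spacing = spacing,
    origin = as.numeric(origin),
    model_index = as.integer(model_index),
    pocket_index = as.integer(pocket_index),
    label = if (is.null(label))
      sprintf("m%d-%d", model_index, pocket_index) else label
  ), class = "grid_pocket")
}

#' Global lattice origin for an ensemble
#'
#' The lattice shared by all models of one entry is anchored at the
#' componentwise floor of the ensemble's bounding box, so pocket cells from
#' different models are directly comparable integer triples.
#'
#' @param ensemble An `rpflex_ensemble` (or an `n x 3` coordinate matrix).
#' @param spacing Grid spacing in Angstrom.
#' @return Numeric length-3 origin in Angstrom.
#' @export
lattice_origin <- function(ensemble, spacing = 1.0) {
  xyz <- if (inherits(ensemble, "rpflex_ensemble")) {
    apply(ensemble$xyz, 2, min)
  } else if (inherits(ensemble, "rpflex_model")) {
    apply(ensemble$xyz, 2, min)
  } else apply(ensemble, 2, min)
  floor(xyz / spacing) * spacing
}

# Cell centers in Angstrom for a grid_pocket (or an integer cell matrix).
cell_centers <- function(pocket, spacing = NULL, origin = NULL) {
  if (inherits(pocket, "grid_pocket")) {
    spacing <- pocket$spacing
    origin <- pocket$origin
    pocket <- pocket$cells
  }
  sweep(pocket * spacing, 2, origin + spacing / 2, "+")
}

#' Detect pockets on one structural model
#'
#' Runs the two-probe grid method: atom occupancy from per-element van der
#' Waals spheres, solvent-excluded regions for the large and small probes by
#' morphological closing, difference split into 6-connected components, and
#' components below `min_volume` discarded. Pockets are indexed by decreasing
#' volume (ties broken on the lexicographically smallest cell).
#'
#' @param model An `rpflex_model`.
#' @param large_probe,small_probe Probe radii in Angstrom (defaults 10 and 3).
#' @param spacing Grid spacing in Angstrom (default 1.0).
#' @param min_volume Minimum pocket volume in cubic Angstrom (default 100).
#' @param origin Global lattice origin; defaults to [lattice_origin()] of this
#'   model. Pass the ensemble origin so all models share one lattice.
#' @param vdw Named per-element van der Waals radii (Angstrom).
#' @param vdw_default Radius for elements not in `vdw`.
#' @param include_ligand Include ligand (HETATM) atoms in the occupancy.
#'   Off by default so that ligand-filled sites are detected as pockets.
#' @return List of `grid_pocket` objects, labelled `"m<model>-<index>"`.
#' @export
detect_pockets <- function(model, large_probe = 10, small_probe = 3,
                           spacing = 1.0, min_volume = 100, origin = NULL,
                           vdw = .DEFAULT_VDW, vdw_default = .VDW_DEFAULT_OTHER,
                           include_ligand = FALSE) {
  stopifnot(large_probe > small_probe, small_probe > 0)
  at <- model$atoms
  keep <- at$is_heavy
  if (!include_ligand) keep <- keep & at$kind != "ligand"
  xyz <- model$xyz[keep, , drop = FALSE]
  if (nrow(xyz) < 1) stop("detection error: model has no heavy atoms")
  if (is.null(origin)) origin <- lattice_origin(xyz, spacing)

  ext <- apply(xyz, 2, function(v) diff(range(v)))
  if (any(ext < spacing) || nrow(xyz) < 4) {
    warning("degenerate geometry: structure too thin for cavity detection")
    return(list())
  }

  radii <- .vdw_radii(at$element[keep], vdw, vdw_default)
  pad <- large_probe + 2 * spacing
  lo <- floor((apply(xyz, 2, min) - radii_max(radii) - pad - origin) / spacing)
  hi <- ceiling((apply(xyz, 2, max) + radii_max(radii) + pad - origin) / spacing)
  dims <- as.integer(hi - lo + 1)
  local_origin <- origin + lo * spacing

  occ <- cpp_occupancy(xyz, radii, local_origin, dims, spacing)
  d_occ2 <- cpp_edt_sq(occ, dims, spacing)
  se_region <- function(r) {
    centers <- d_occ2 > r * r
    d_c2 <- cpp_edt_sq(centers, dims, spacing)
    (d_c2 > r * r) & !occ
  }
  mask <- se_region(large_probe) & !se_region(small_probe)
  lab <- cpp_components6(mask, dims)
  if (!any(lab > 0)) return(list())

  nx <- dims[1]; ny <- dims[2]
  idx <- which(lab > 0) - 1L
  ci <- idx %% nx
  cj <- (idx %/% nx) %% ny
  ck <- idx %/% (nx * ny)
  comp <- lab[idx + 1L]
  sizes <- table(comp)
  keep_comp <- as.integer(names(sizes))[sizes * spacing^3 >= min_volume]
  if (!length(keep_comp)) return(list())

  comps <- lapply(keep_comp, function(cc) {
    sel <- comp == cc
    cbind(ci[sel] + lo[1], cj[sel] + lo[2], ck[sel] + lo[3])
  })
  vol <- vapply(comps, nrow, integer(1))
  min_cell_key <- vapply(comps, function(m) {
    o <- order(m[, 1], m[, 2], m[, 3])
    paste(sprintf("%06d", m[o[1], ] + 5e5), collapse = "")
  }, character(1))
  ord <- order(-vol, min_cell_key)
  lapply(seq_along(ord), function(p) {
    new_grid_pocket(comps[[ord[p]]], spacing, origin,
                    model_index = model$model_index %||% 1L,
                    pocket_index = p)
  })
}

radii_max <- function(r) max(r)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect pockets on every model of an ensemble
#'
#' All models are rasterized on one shared lattice anchored at the floor of
#' the ensemble bounding box, so detected pockets can be intersected
#' voxel-by-voxel across models.
#'
#' @inheritParams detect_pockets
#' @param ensemble An `rpflex_ensemble`.
#' @param ... Passed on to [detect_pockets()].
#' @return Flat list of `grid_pocket` objects in model order, then
#'   within-model index order.
#' @export
detect_ensemble_pockets <- function(ensemble, spacing = 1.0, ...) {
  origin <- lattice_origin(ensemble, spacing)
  out <- list()
  for (m in seq_len(ensemble$n_models)) {
    out <- c(out, detect_pockets(get_model(ensemble, m), spacing = spacing,
                                 origin = origin, ...))
  }
  out
}

#' Topological metrics of a grid pocket
#'
#' Volume `Vp = |cells| h^3`, surface area `Ap` from exposed 6-neighbour faces
#' (`faces x h^2`), effective radius `reff = 3 Vp / Ap`, sphericity
#' `psi = pi^(1/3) (6 Vp)^(2/3) / Ap` and the centroid of the cell centers.
#' Face counting overestimates the area of smooth shapes by a staircase
#' factor (about 1.5x for spheres); `area_correction = TRUE` applies the 2/3
#' compensation, off by default.
#'
#' @param pocket A `grid_pocket` (or integer cell matrix).
#' @param spacing Grid spacing; taken from the pocket when available.
#' @param area_correction Multiply the face-count area by 2/3.
#' @return List of class `pocket_metrics` with `Vp`, `Ap`, `psi`, `reff`,
#'   `centroid`.
#' @export
compute_metrics <- function(pocket, spacing = NULL, area_correction = FALSE) {
  if (inherits(pocket, "grid_pocket")) {
    cells <- pocket$cells
    spacing <- pocket$spacing
    origin <- pocket$origin
  } else {
    cells <- matrix(as.integer(pocket), ncol = 3)
    if (is.null(spacing)) spacing <- 1.0
    origin <- c(0, 0, 0)
  }
  stopifnot(nrow(cells) > 0)
  Vp <- nrow(cells) * spacing^3
  faces <- cpp_exposed_faces(cells)
  Ap <- faces * spacing^2 * if (area_correction) 2 / 3 else 1
  structure(list(
    Vp = Vp,
    Ap = Ap,
    psi = pi^(1 / 3) * (6 * Vp)^(2 / 3) / Ap,
    reff = 3 * Vp / Ap,
    centroid = colMeans(sweep(cells * spacing, 2,
                              origin + spacing / 2, "+"))
  ), class = "pocket_metrics")
}

#' Closed-form pocket metrics from analytic volume and area
#'
#' @param Vp Volume in cubic Angstrom.
#' @param Ap Surface area in square Angstrom.
#' @return List with `psi` and `reff`.
#' @export
analytic_metrics <- function(Vp, Ap) {
  list(psi = pi^(1 / 3) * (6 * Vp)^(2 / 3) / Ap, reff = 3 * Vp / Ap)
}

#' Import a pocket point cloud from a dummy-atom PDB file
#'
#' Each pseudo-atom (one per occupied grid cell, as written by external cavity
#' tools or [write_pocket_pdb()]) is snapped to the nearest global lattice
#' cell; duplicates merge.
#'
#' @param path PDB file of pseudo-atoms.
#' @param model_index Model the pocket belongs to.
#' @param spacing Lattice spacing in Angstrom.
#' @param origin Global lattice origin.
#' @return A `grid_pocket`.
#' @export
import_pocket_points <- function(path, model_index = 1L, spacing = 1.0,
                                 origin = c(0, 0, 0)) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("input error: cannot read ", path, ": ",
                         conditionMessage(e)))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (nrow(xyz) < 1) stop("input error: no pseudo-atoms in ", path)
  cells <- unique(floor(sweep(xyz, 2, origin) / spacing))
  new_grid_pocket(cells, spacing, origin, model_index = model_index)
}

#' Write a pocket as a dummy-atom PDB file
#'
#' One HETATM pseudo-atom (residue `PKT`) per occupied grid cell, placed at
#' the cell center.
#'
#' @param pocket A `grid_pocket`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pocket, path) {
  ctr <- cell_centers(pocket)
  lines <- vapply(seq_len(nrow(ctr)), function(r) {
    .fmt_pdb_atom(r, "C", "PKT", "P", 1L, ctr[r, 1], ctr[r, 2], ctr[r, 3],
                  rectype = "HETATM", element = "C")
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
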