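# Deterministic synthetic inputs: analytic voxel shapes, cavity-bearing atom
# shells, perturbed multi-model ensembles and toy graphs. Every fixture is
# reproducible from its parameters and seed and carries the analytic ground
# truth it was built from.

#' Build a structural model from an atom table and coordinates
#'
#' Programmatic constructor for `rpflex_model` objects (fixtures, tests).
#' Derives element, residue kind, chemical group, heavy-atom flag and
#' residue keys from the minimal columns.
#'
#' @param atoms Data frame with at least `elety`, `resid`, `chain`, `resno`.
#' @param xyz `n x 3` coordinate matrix in Angstrom.
#' @param model_index Model index carried by the object.
#' @return An `rpflex_model`.
#' @export
as_rpflex_model <- function(atoms, xyz, model_index = 1L) {
  stopifnot(nrow(atoms) == nrow(xyz))
  at <- atoms
  at$elety <- .norm_atom_name(at$elety)
  if (is.null(at$insert)) at$insert <- ""
  if (is.null(at$element)) at$element <- .element_from_name(at$elety)
  if (is.null(at$kind)) at$kind <- .residue_kind(at$resid, "ATOM")
  at$is_heavy <- !(at$element %in% c("H", "D"))
  at$reskey <- paste0(at$chain, "/", at$resno, at$insert)
  at$res_index <- match(at$reskey, unique(at$reskey))
  if (is.null(at$group)) {
    at$group <- NA_character_
    cls <- at$kind %in% c("nucleotide", "amino_acid")
    at$group[cls] <- mapply(classify_chemical_group, at$resid[cls],
                            at$elety[cls], USE.NAMES = FALSE)
  }
  structure(list(atoms = at, xyz = as.matrix(xyz),
                 model_index = as.integer(model_index)),
            class = "rpflex_model")
}

#' Digitize an analytic solid onto the lattice
#'
#' @param kind `"sphere"` or `"box"`.
#' @param size Sphere radius, or box edge length(s), in Angstrom.
#' @param spacing Lattice spacing in Angstrom.
#' @param center Center of the solid.
#' @return A `grid_pocket` whose cells have centers inside the solid, with
#'   attribute `analytic_volume` (cubic Angstrom).
#' @export
make_voxel_shape <- function(kind = c("sphere", "box"), size, spacing = 1.0,
                             center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(all(size > spacing))
  half <- if (kind == "sphere") rep(size, 3) else rep(size, length.out = 3) / 2
  rng <- lapply(1:3, function(ax) {
    seq(floor((center[ax] - half[ax]) / spacing) - 1,
        ceiling((center[ax] + half[ax]) / spacing) + 1)
  })
  cells <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  ctr <- sweep(cells * spacing + spacing / 2, 2, center)
  inside <- if (kind == "sphere") {
    rowSums(ctr^2) < size^2
  } else {
    abs(ctr[, 1]) < half[1] & abs(ctr[, 2]) < half[2] & abs(ctr[, 3]) < half[3]
  }
  out <- new_grid_pocket(cells[inside, , drop = FALSE], spacing, c(0, 0, 0))
  attr(out, "analytic_volume") <- if (kind == "sphere")
    4 / 3 * pi * size^3 else prod(rep(size, length.out = 3))
  out
}

#' Atom shell enclosing spherical cavities of known volume
#'
#' Pseudo-atoms (carbon, van der Waals radius 1.7 A at the default tables)
#' packed on a cubic lattice fill a closed shell around each cavity center,
#' sealing the cavity against the small probe. Atoms are grouped into
#' pseudo-nucleotide residues by angular sector so that per-residue rigid
#' perturbations deform the cavity walls coherently.
#'
#' @param inner_radius Cavity radius in Angstrom.
#' @param shell_thickness Shell thickness in Angstrom (must exceed the small
#'   probe diameter to keep the cavity sealed).
#' @param atom_spacing Packing spacing of the shell atoms in Angstrom.
#' @param seed Seed for the small deterministic jitter.
#' @param centers Matrix (k x 3) of cavity centers; one cavity by default.
#' @param atoms_per_residue Number of atoms grouped into each pseudo-residue.
#' @return An `rpflex_model` with attribute `analytic_cavity_volume`.
#' @export
make_cavity_shell <- function(inner_radius = 4, shell_thickness = 6,
                              atom_spacing = 1.0, seed = 1,
                              centers = matrix(0, 1, 3),
                              atoms_per_residue = 20L) {
  stopifnot(shell_thickness >= 3) # thick enough to stay sealed
  centers <- matrix(centers, ncol = 3)
  all_xyz <- NULL
  # atom centers start one carbon vdW radius beyond the cavity surface so the
  # unoccupied cavity has the stated analytic radius
  rw <- 1.7
  inner <- inner_radius + rw
  outer <- inner + shell_thickness
  for (ci in seq_len(nrow(centers))) {
    g <- seq(-outer, outer, by = atom_spacing)
    pts <- as.matrix(expand.grid(g, g, g))
    r <- sqrt(rowSums(pts^2))
    shell <- pts[r > inner & r <= outer, , drop = FALSE]
    # deterministic ordering by angular sector, so residues are spatial patches
    theta <- acos(pmin(1, pmax(-1, shell[, 3] / sqrt(rowSums(shell^2)))))
    phi <- atan2(shell[, 2], shell[, 1])
    shell <- shell[order(round(theta, 6), round(phi, 6)), , drop = FALSE]
    all_xyz <- rbind(all_xyz, sweep(shell, 2, centers[ci, ], "+"))
  }
  n <- nrow(all_xyz)
  if (!n) stop("fixture error: unsealable geometry (no shell atoms)")
  set.seed(seed)
  all_xyz <- all_xyz + matrix(runif(3 * n, -0.05, 0.05), n, 3)
  resno <- (seq_len(n) - 1) %/% atoms_per_residue + 1
  within <- (seq_len(n) - 1) %% atoms_per_residue + 1
  atoms <- data.frame(
    elety = paste0("C", within),
    resid = c("A", "C", "G", "U")[(resno - 1) %% 4 + 1],
    chain = "A",
    resno = resno,
    stringsAsFactors = FALSE)
  out <- as_rpflex_model(atoms, all_xyz)
  attr(out, "analytic_cavity_volume") <- 4 / 3 * pi * inner_radius^3
  out
}

#' Perturbed multi-model ensemble from a template
#'
#' Model 1 is the template; models 2..n displace each residue rigidly by a
#' zero-mean Gaussian 3-vector of per-component scale `s`. The standard
#' normal draws depend only on `seed` and the problem size, so ensembles
#' built at different `s` from the same seed share displacement directions
#' and scale exactly linearly (coupled-seed monotonicity).
#'
#' @param template An `rpflex_model`.
#' @param n_models Total number of models, `>= 3`.
#' @param s Per-nucleotide displacement scale in Angstrom, `>= 0`.
#' @param seed Seed for the Gaussian draws.
#' @param entry_id Identifier for the synthetic entry.
#' @return An `rpflex_ensemble`.
#' @export
make_perturbed_ensemble <- function(template, n_models = 10, s = 1.0,
                                    seed = 1, entry_id = "SYNT") {
  stopifnot(n_models >= 3, s >= 0)
  at <- template$atoms
  n_res <- max(at$res_index)
  set.seed(seed)
  eps <- array(rnorm(n_res * 3 * (n_models - 1)), c(n_res, 3, n_models - 1))
  xyz <- array(NA_real_, c(nrow(at), 3, n_models))
  xyz[, , 1] <- template$xyz
  for (m in seq_len(n_models - 1)) {
    disp <- s * eps[, , m]
    xyz[, , m + 1] <- template$xyz + disp[at$res_index, , drop = FALSE]
  }
  chain_tab <- table(at$chain[at$kind == "nucleotide"])
  structure(list(
    entry_id = entry_id,
    atoms = at,
    xyz = xyz,
    n_models = as.integer(n_models),
    rna_chain = if (length(chain_tab)) names(chain_tab)[which.max(chain_tab)]
      else at$chain[1],
    partner_kind = if (any(at$kind == "amino_acid")) "protein"
      else if (any(at$kind == "ligand")) "ligand" else "none",
    one_model = FALSE
  ), class = "rpflex_ensemble")
}

#' Toy graphs with known metrics
#'
#' @param kind `"path"`, `"cycle"`, `"complete"` or `"random"`
#'   (Erdos-Renyi with edge probability `p`).
#' @param n Number of nodes, `>= 1`.
#' @param seed Seed (random graphs only).
#' @param p Edge probability for `kind = "random"`.
#' @return An `rpflex_network` with nodes `A/1 ... A/n`.
#' @export
make_toy_graph <- function(kind = c("path", "cycle", "complete", "random"),
                           n, seed = 1, p = 0.3) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  nodes <- paste0("A/", seq_len(n))
  edges <- switch(kind,
    path = if (n > 1) cbind(nodes[-n], nodes[-1]) else character(0),
    cycle = if (n > 2) rbind(cbind(nodes[-n], nodes[-1]),
                             c(nodes[n], nodes[1])) else
      if (n == 2) cbind(nodes[1], nodes[2]) else character(0),
    complete = if (n > 1) t(utils::combn(nodes, 2)) else character(0),
    random = {
      set.seed(seed)
      pairs <- t(utils::combn(nodes, 2))
      pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    })
  new_pocket_network(nodes, edges, model_index = 1L,
                     seq_pos = setNames(seq_len(n), nodes))
}

#' Idealized Watson-Crick G-C base pair
#'
#' Planar guanine and cytosine bases (base atoms only) at approximate
#' idealized ring geometry, oriented so the three Watson-Crick hydrogen
#' bonds (G:O6-C:N4, G:N1-C:N3, G:N2-C:O2) sit near 2.9-3.0 Angstrom.
#'
#' @return An `rpflex_model` with residues `A/1` (G) and `A/2` (C).
#' @export
make_wc_pair <- function() {
  g <- rbind(
    N1 = c(0, 0, 0), C2 = c(-0.756, -1.143, 0), N2 = c(0, -2.25, 0),
    N3 = c(-2.03, -1.44, 0), C4 = c(-2.72, -0.28, 0),
    C5 = c(-2.06, 0.92, 0), C6 = c(-0.669, 1.218, 0), O6 = c(0, 2.25, 0),
    N7 = c(-2.99, 1.94, 0), C8 = c(-4.23, 1.38, 0), N9 = c(-4.06, 0.03, 0))
  cc <- rbind(
    N3 = c(2.94, 0, 0), C2 = c(3.635, -1.204, 0), O2 = c(3.015, -2.278, 0),
    N1 = c(5.025, -1.204, 0), C6 = c(5.72, 0, 0), C5 = c(5.025, 1.204, 0),
    C4 = c(3.635, 1.204, 0), N4 = c(2.965, 2.364, 0))
  atoms <- data.frame(
    elety = c(rownames(g), rownames(cc)),
    resid = c(rep("G", nrow(g)), rep("C", nrow(cc))),
    chain = "A",
    resno = c(rep(1L, nrow(g)), rep(2L, nrow(cc))),
    stringsAsFactors = FALSE)
  as_rpflex_model(atoms, rbind(g, cc))
}
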