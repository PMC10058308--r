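# Nucleotide-averaged RMSF over the models contributing to a pocket group
# (restricted to the group's overlapping nucleotides) and over whole
# structures. No superposition is applied: NMR depositions are pre-aligned
# and coordinates are used as deposited.

#' Nucleotides lining a pocket
#'
#' Nucleotides of the RNA chain with at least one heavy atom within
#' `contact_cutoff` of any pocket cell center.
#'
#' @param pocket A `grid_pocket`.
#' @param model The `rpflex_model` the pocket was detected on.
#' @param contact_cutoff Distance cutoff in Angstrom (default 4.0, about the
#'   small-probe radius plus a heavy-atom van der Waals radius).
#' @return Character vector of residue keys (`chain/resno`), in sequence
#'   order.
#' @export
pocket_lining_nucleotides <- function(pocket, model, contact_cutoff = 4.0) {
  at <- model$atoms
  sel <- at$is_heavy & at$kind == "nucleotide"
  if (!any(sel)) return(character(0))
  d <- cpp_min_dist(model$xyz[sel, , drop = FALSE], cell_centers(pocket))
  res <- at$reskey[sel]
  hit <- unique(res[d <= contact_cutoff])
  ord <- at$res_index[match(hit, at$reskey)]
  hit[order(ord)]
}

#' Overlapping nucleotides of a pocket group
#'
#' Residues lining strictly more than half of the group's member pockets
#' (each pocket evaluated in its own model).
#'
#' @param group An `rpflex_pocket_group` with `m >= 3`.
#' @param pockets The entry's pocket list.
#' @param ensemble The `rpflex_ensemble`.
#' @param contact_cutoff Passed to [pocket_lining_nucleotides()].
#' @return Character vector of residue keys in sequence order.
#' @export
overlapping_nucleotides <- function(group, pockets, ensemble,
                                    contact_cutoff = 4.0) {
  stopifnot(group$valid)
  by_label <- setNames(pockets,
                       vapply(pockets, function(p) p$label, character(1)))
  linings <- lapply(group$members, function(l) {
    p <- by_label[[l]]
    pocket_lining_nucleotides(p, get_model(ensemble, p$model_index),
                              contact_cutoff)
  })
  counts <- table(unlist(linings))
  keep <- names(counts)[counts > group$m / 2]
  if (!length(keep)) {
    warning("group ", group$group_label,
            " has no overlapping nucleotides; unusable for RMSF")
    return(character(0))
  }
  at <- ensemble$atoms
  keep[order(at$res_index[match(keep, at$reskey)])]
}

# One representative point per residue per model.
.residue_points <- function(ensemble, reskeys, model_index,
                            representative = c("com", "C1prime")) {
  representative <- match.arg(representative)
  at <- ensemble$atoms
  xyz <- .xyz_slice(ensemble, model_index)
  sel <- at$reskey %in% reskeys &
    (if (representative == "com") at$is_heavy else at$elety == "C1'")
  if (!any(sel)) return(matrix(NA_real_, length(reskeys), 3))
  g <- at$reskey[sel]
  sums <- rowsum(xyz[sel, , drop = FALSE], g)
  pts <- sums / as.vector(table(g)[rownames(sums)])
  out <- pts[match(reskeys, rownames(pts)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.rmsf_over_models <- function(ensemble, reskeys, model_indices,
                              reference_model, representative = "com") {
  ref <- .residue_points(ensemble, reskeys, reference_model, representative)
  ok <- !is.na(ref[, 1])
  if (any(!ok))
    warning("missing representative atoms; skipping residue(s): ",
            paste(reskeys[!ok], collapse = ", "))
  reskeys <- reskeys[ok]
  ref <- ref[ok, , drop = FALSE]
  sq <- matrix(0, length(reskeys), length(model_indices))
  for (j in seq_along(model_indices)) {
    pts <- .residue_points(ensemble, reskeys, model_indices[j], representative)
    sq[, j] <- rowSums((pts - ref)^2)
  }
  per <- sqrt(rowMeans(sq))
  structure(list(
    overlapping_nucleotides = reskeys,
    per_nucleotide_rmsf = setNames(per, reskeys),
    mean_rmsf = mean(per),
    reference_model = reference_model
  ), class = "rpflex_rmsf")
}

#' Group RMSF over overlapping nucleotides
#'
#' For every overlapping nucleotide of the group, a representative point per
#' model (heavy-atom center of mass by default, `C1'` optionally); reference
#' positions come from the model of the group's first (reference) pocket.
#' Per-nucleotide RMSF is the root mean square displacement over the group's
#' m member models, and `mean_rmsf` averages over the nucleotides.
#'
#' @param group An `rpflex_pocket_group` with `m >= 3`.
#' @param ensemble The `rpflex_ensemble`.
#' @param pockets The entry's pocket list.
#' @param representative `"com"` (default) or `"C1prime"`.
#' @param contact_cutoff Passed to [overlapping_nucleotides()].
#' @return `rpflex_rmsf`: `overlapping_nucleotides`, `per_nucleotide_rmsf`,
#'   `mean_rmsf`, `reference_model`.
#' @export
group_rmsf <- function(group, ensemble, pockets,
                       representative = c("com", "C1prime"),
                       contact_cutoff = 4.0) {
  nucs <- overlapping_nucleotides(group, pockets, ensemble, contact_cutoff)
  if (!length(nucs))
    stop("group ", group$group_label, " has no overlapping nucleotides")
  by_label <- setNames(pockets,
                       vapply(pockets, function(p) p$label, character(1)))
  models <- unname(vapply(group$members, function(l)
    by_label[[l]]$model_index, integer(1)))
  .rmsf_over_models(ensemble, nucs, models, models[1],
                    match.arg(representative))
}

#' Structure RMSF over all nucleotides
#'
#' Same displacement formula over all nucleotides of the RNA chain and all
#' models of the ensemble, against a stated reference model.
#'
#' @param ensemble An `rpflex_ensemble` with at least 2 models.
#' @param reference_model_index Reference model (default 1).
#' @param representative `"com"` (default) or `"C1prime"`.
#' @return An `rpflex_rmsf`.
#' @export
structure_rmsf <- function(ensemble, reference_model_index = 1L,
                           representative = c("com", "C1prime")) {
  stopifnot(ensemble$n_models >= 2)
  at <- ensemble$atoms
  sel <- at$kind == "nucleotide" & at$chain == ensemble$rna_chain
  nucs <- unique(at$reskey[sel])
  .rmsf_over_models(ensemble, nucs, seq_len(ensemble$n_models),
                    reference_model_index, match.arg(representative))
}
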