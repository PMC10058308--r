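# Voxel-overlap similarity between pockets of one entry and the clustering of
# pockets into groups against first-model reference pockets.

.cell_keys <- function(cells) {
  stopifnot(all(abs(cells) < 512))
  (cells[, 1] + 512) + 1024 * ((cells[, 2] + 512) + 1024 * (cells[, 3] + 512))
}

.same_frame <- function(a, b) {
  isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

#' Voxel-overlap similarity between two pockets
#'
#' `P_ij = n_ij / N_i`: the fraction of reference pocket i's cells that are
#' also occupied by pocket j. Asymmetric; `P_ij N_i = P_ji N_j = n_ij`.
#'
#' @param pocket_i Reference pocket (`grid_pocket`).
#' @param pocket_j Comparison pocket on the same global lattice.
#' @return Similarity in `[0, 1]`.
#' @export
pairwise_similarity <- function(pocket_i, pocket_j) {
  if (!.same_frame(pocket_i, pocket_j))
    stop("frame error: pockets live on different lattices")
  ki <- .cell_keys(pocket_i$cells)
  kj <- .cell_keys(pocket_j$cells)
  sum(ki %in% kj) / length(ki)
}

#' Similarity matrix over all pockets of an entry
#'
#' Pockets are ordered by model, then within-model index, and labelled
#' `1 (m1-1), 2 (m1-2), 3 (m2-1), ...`. All `q^2` entries are computed; the
#' diagonal is 1 by construction.
#'
#' @param pockets List of `grid_pocket` objects from one ensemble.
#' @return Object of class `rpflex_simmat`: list with `labels`, `P` (q x q),
#'   `N` (cell counts), `n` (overlap counts) and `model_index` per pocket.
#' @export
build_matrix <- function(pockets) {
  q <- length(pockets)
  stopifnot(q >= 1)
  ord <- order(vapply(pockets, function(p) p$model_index, integer(1)),
               vapply(pockets, function(p) p$pocket_index, integer(1)))
  pockets <- pockets[ord]
  keys <- lapply(pockets, function(p) .cell_keys(p$cells))
  N <- vapply(keys, length, integer(1))
  for (p in pockets[-1]) {
    if (!.same_frame(pockets[[1]], p))
      stop("frame error: pockets live on different lattices")
  }
  n <- matrix(0L, q, q)
  for (i in seq_len(q)) {
    n[i, i] <- N[i]
    if (i < q) for (j in seq((i + 1), q)) {
      nij <- sum(keys[[i]] %in% keys[[j]])
      n[i, j] <- nij
      n[j, i] <- nij
    }
  }
  P <- n / N # divides each row i by N_i
  labels <- vapply(pockets, function(p) p$label, character(1))
  dimnames(P) <- list(labels, labels)
  structure(list(
    labels = labels,
    P = P,
    N = setNames(N, labels),
    n = n,
    model_index = vapply(pockets, function(p) p$model_index, integer(1)),
    pocket_index = vapply(pockets, function(p) p$pocket_index, integer(1))
  ), class = "rpflex_simmat")
}

#' Cluster pockets into groups against first-model references
#'
#' The pockets of the first structural model are the reference conformations.
#' Every other pocket j joins the group of reference i when `P_ij > cutoff`
#' (strict, row i of the matrix: reference i's cell count is the denominator);
#' when several references qualify, j joins the one with the largest `P_ij`
#' (ties to the lowest reference index). Pockets matching no reference become
#' leftover singleton groups. A group is valid when it has at least 3 members.
#'
#' @param matrix An `rpflex_simmat`.
#' @param cutoff Similarity cutoff (default 0.25, strict `>`).
#' @param entry_id Prefix for group labels (`"<entry>-Gk"`).
#' @return List of `rpflex_pocket_group`: `group_label`, `reference`,
#'   `members` (labels), `member_idx` (column indices), `m`, `valid`.
#' @export
group_pockets <- function(matrix, cutoff = 0.25, entry_id = "") {
  stopifnot(inherits(matrix, "rpflex_simmat"))
  q <- length(matrix$labels)
  refs <- which(matrix$model_index == min(matrix$model_index))
  if (min(matrix$model_index) != 1L || !length(refs)) {
    warning("first structural model has no pockets; all pockets are leftovers")
    refs <- integer(0)
  }
  assigned <- rep(NA_integer_, q)
  assigned[refs] <- refs
  for (j in setdiff(seq_len(q), refs)) {
    sims <- matrix$P[refs, j]
    ok <- which(sims > cutoff)
    if (length(ok)) {
      best <- ok[which.max(sims[ok])] # which.max takes the first maximum
      assigned[j] <- refs[best]
    }
  }
  groups <- list()
  k <- 0
  for (r in refs) {
    k <- k + 1
    idx <- which(assigned == r)
    groups[[k]] <- .new_group(entry_id, k, matrix$labels, idx, reference = r)
  }
  for (j in which(is.na(assigned))) {
    k <- k + 1
    groups[[k]] <- .new_group(entry_id, k, matrix$labels, j, reference = j)
  }
  groups
}

.new_group <- function(entry_id, k, labels, idx, reference) {
  structure(list(
    group_label = paste0(if (nzchar(entry_id)) paste0(entry_id, "-") else "",
                         "G", k),
    reference = labels[reference],
    members = labels[idx],
    member_idx = idx,
    m = length(idx),
    valid = length(idx) >= 3
  ), class = "rpflex_pocket_group")
}

#' Write a similarity matrix as CSV
#'
#' @param matrix An `rpflex_simmat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(matrix, path) {
  write.csv(as.data.frame(matrix$P), path, row.names = TRUE)
  invisible(path)
}
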