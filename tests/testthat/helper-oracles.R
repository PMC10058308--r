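# Independent oracles and small fixture builders shared by the suite. The
# oracles deliberately use the dumbest possible algorithm (string sets,
# Floyd-Warshall over a dense matrix, explicit scalar arithmetic) so they
# stay independent of the implementation they check.

# Fraction of pocket i's cells shared with pocket j, by string-keyed sets.
oracle_similarity <- function(cells_i, cells_j) {
  ki <- apply(cells_i, 1, paste, collapse = ",")
  kj <- apply(cells_j, 1, paste, collapse = ",")
  length(intersect(ki, kj)) / length(unique(ki))
}

oracle_pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# All-pairs shortest paths by Floyd-Warshall; metrics on the largest
# connected component.
oracle_graph_metrics <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[edges[r, 1], edges[r, 2]] <- TRUE
      adj[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  L <- sum(adj) / 2
  k <- rowSums(adj)
  # clustering: fraction of closed neighbour pairs, zero below degree 2
  C <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  comp_of <- rep(NA_integer_, n)
  cc <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp_of[i])) next
    cc <- cc + 1
    comp_of[is.finite(d[i, ])] <- cc
  }
  big <- which(comp_of == which.max(tabulate(comp_of)))
  db <- d[big, big, drop = FALSE]
  finite <- db[upper.tri(db)]
  list(k_avg = 2 * L / n, C_avg = mean(C),
       dmax = if (length(finite)) max(finite) else 0,
       d_avg = if (length(finite)) mean(finite) else 0)
}

# Minimal model with one heavy atom per residue at given coordinates.
point_residue_model <- function(xyz, resno = seq_len(nrow(xyz)),
                                resid = "G", chain = "A", elety = "C2",
                                model_index = 1L) {
  as_rpflex_model(
    data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
               stringsAsFactors = FALSE),
    xyz, model_index = model_index)
}

# Ensemble with explicit per-model coordinates for one template model.
manual_ensemble <- function(template, xyz_list, entry_id = "MAN") {
  xyz <- array(NA_real_, c(nrow(template$atoms), 3, length(xyz_list)))
  for (m in seq_along(xyz_list)) xyz[, , m] <- xyz_list[[m]]
  at <- template$atoms
  chain_tab <- table(at$chain[at$kind == "nucleotide"])
  structure(list(entry_id = entry_id, atoms = at, xyz = xyz,
                 n_models = length(xyz_list),
                 rna_chain = if (length(chain_tab))
                   names(chain_tab)[which.max(chain_tab)] else at$chain[1],
                 partner_kind = "none", one_model = length(xyz_list) == 1),
            class = "rpflex_ensemble")
}

# Hand-built pocket group object (bypasses clustering).
manual_group <- function(labels, member_idx, reference_idx = member_idx[1],
                         label = "TEST-G1") {
  structure(list(group_label = label, reference = labels[reference_idx],
                 members = labels[member_idx], member_idx = member_idx,
                 m = length(member_idx), valid = length(member_idx) >= 3),
            class = "rpflex_pocket_group")
}

random_cells <- function(n, lim = 8L) {
  unique(cbind(sample.int(lim, n, TRUE), sample.int(lim, n, TRUE),
               sample.int(lim, n, TRUE)))
}
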