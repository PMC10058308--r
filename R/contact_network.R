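# Residue contact networks over pocket-lining nucleotides, per structural
# model, and the cross-model variability of their metrics. Edges connect
# sequence-separated nucleotides whose closest heavy atoms approach within
# the contact cutoff; covalently linked sequence neighbours are excluded so
# the network reflects tertiary (non-covalent) organization.

new_pocket_network <- function(nodes, edges, model_index = 1L, seq_pos = NULL) {
  edges <- if (length(edges)) matrix(edges, ncol = 2) else
    matrix(character(0), ncol = 2)
  if (nrow(edges)) {
    # canonical unordered form, no self-edges, no duplicates
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  }
  structure(list(nodes = nodes, edges = edges,
                 model_index = as.integer(model_index),
                 seq_pos = seq_pos),
            class = "rpflex_network")
}

#' Build a pocket contact network for one model
#'
#' Nodes are the given residues; an edge joins residues u, v when their
#' sequence separation is at least `min_seq_sep` and the minimum heavy-atom
#' inter-atomic distance is strictly below `cutoff`.
#'
#' @param model An `rpflex_model`.
#' @param nodes Residue keys (`chain/resno`) to use as nodes.
#' @param cutoff Contact cutoff in Angstrom (default 8, strict `<`).
#' @param min_seq_sep Minimum sequence separation (default 2: covalent
#'   neighbours excluded).
#' @return An `rpflex_network`.
#' @export
build_network <- function(model, nodes, cutoff = 8.0, min_seq_sep = 2L) {
  at <- model$atoms
  stopifnot(all(nodes %in% at$reskey))
  if (length(nodes) < 2)
    warning("degenerate network: fewer than 2 nodes")
  seq_pos <- at$resno[match(nodes, at$reskey)]
  sel <- at$is_heavy & at$reskey %in% nodes
  node_id <- match(at$reskey[sel], nodes)
  edges <- character(0)
  if (length(nodes) >= 2 && any(sel)) {
    rmd <- cpp_res_min_dist(model$xyz[sel, , drop = FALSE], node_id, cutoff)
    keep <- abs(seq_pos[rmd$res_i] - seq_pos[rmd$res_j]) >= min_seq_sep
    if (any(keep))
      edges <- cbind(nodes[rmd$res_i[keep]], nodes[rmd$res_j[keep]])
  }
  new_pocket_network(nodes, edges,
    model_index = model$model_index %||% 1L,
    seq_pos = setNames(seq_pos, nodes))
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Metrics of a pocket network
#'
#' Average degree `<k> = 2L/N`, average local clustering coefficient `<C>`
#' (nodes of degree below 2 contribute 0), diameter `dmax` and average
#' shortest-path length `<d>`. Path-based metrics are computed on the largest
#' connected component; disconnected networks are flagged.
#'
#' @param net An `rpflex_network`.
#' @return List with `k_avg`, `C_avg`, `dmax`, `d_avg`, `N`, `L`,
#'   `connected`.
#' @export
network_metrics <- function(net) {
  N <- length(net$nodes)
  stopifnot(N >= 1)
  L <- nrow(net$edges)
  g <- .as_igraph(net)
  k_avg <- 2 * L / N
  C_avg <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(C_avg)) C_avg <- 0
  comp <- igraph::components(g)
  connected <- comp$no == 1L
  if (!connected)
    message("network on model ", net$model_index, " is disconnected (",
            comp$no, " components); path metrics use the largest")
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) < 2) {
    dmax <- 0
    d_avg <- 0
  } else {
    dmax <- igraph::diameter(sub, directed = FALSE, unconnected = FALSE)
    d_avg <- igraph::mean_distance(sub, directed = FALSE)
  }
  list(k_avg = k_avg, C_avg = C_avg, dmax = dmax, d_avg = d_avg,
       N = N, L = L, connected = connected)
}

#' Cross-model network flexibility of a pocket group
#'
#' Population (divide by m) standard deviations of the four network metrics
#' across the group's m member networks, and the combined flexibility scores
#' `Q x sigma` for each.
#'
#' @param nets List of `rpflex_network`, one per group member, `m >= 3`.
#' @param Q The group's flexibility score.
#' @return List of class `rpflex_network_flex`: `per_model` (data frame of
#'   metrics), `sigma` (named vector), `combined` (named `Q*sigma` vector).
#' @export
ensemble_network_flexibility <- function(nets, Q) {
  stopifnot(length(nets) >= 3)
  mets <- lapply(nets, network_metrics)
  per_model <- data.frame(
    model = vapply(nets, function(n) n$model_index, integer(1)),
    k_avg = vapply(mets, `[[`, numeric(1), "k_avg"),
    C_avg = vapply(mets, `[[`, numeric(1), "C_avg"),
    dmax = vapply(mets, `[[`, numeric(1), "dmax"),
    d_avg = vapply(mets, `[[`, numeric(1), "d_avg"))
  sigma <- c(sigma_k = .pop_sd(per_model$k_avg),
             sigma_C = .pop_sd(per_model$C_avg),
             sigma_dmax = .pop_sd(per_model$dmax),
             sigma_d = .pop_sd(per_model$d_avg))
  structure(list(per_model = per_model, sigma = sigma,
                 combined = setNames(Q * sigma,
                                     paste0("Q_", names(sigma)))),
            class = "rpflex_network_flex")
}

#' Contact networks for a pocket group
#'
#' By default all m networks share one node set: the nucleotides lining the
#' group's reference pocket (evaluated in the reference pocket's model), so
#' that cross-model metric differences reflect interaction changes rather
#' than node-set changes. `node_set = "per_model"` uses each member pocket's
#' own lining nucleotides instead.
#'
#' @param group An `rpflex_pocket_group` with `m >= 3`.
#' @param ensemble The `rpflex_ensemble`.
#' @param pockets The entry's pocket list.
#' @param cutoff,min_seq_sep Passed to [build_network()].
#' @param contact_cutoff Passed to [pocket_lining_nucleotides()].
#' @param node_set `"reference"` (default) or `"per_model"`.
#' @return List of `rpflex_network`, one per group member.
#' @export
group_networks <- function(group, ensemble, pockets, cutoff = 8.0,
                           min_seq_sep = 2L, contact_cutoff = 4.0,
                           node_set = c("reference", "per_model")) {
  node_set <- match.arg(node_set)
  stopifnot(group$valid)
  by_label <- setNames(pockets,
                       vapply(pockets, function(p) p$label, character(1)))
  ref_pocket <- by_label[[group$reference]]
  ref_nodes <- pocket_lining_nucleotides(
    ref_pocket, get_model(ensemble, ref_pocket$model_index), contact_cutoff)
  lapply(group$members, function(l) {
    p <- by_label[[l]]
    model <- get_model(ensemble, p$model_index)
    nodes <- if (node_set == "reference") ref_nodes else
      pocket_lining_nucleotides(p, model, contact_cutoff)
    build_network(model, nodes, cutoff = cutoff, min_seq_sep = min_seq_sep)
  })
}
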