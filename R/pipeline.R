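# End-to-end orchestration for one entry: detect pockets on every model of
# the shared lattice, build the similarity matrix, cluster into groups, then
# score, RMSF, contact-network variability and interaction profile per valid
# group. The report is fully determined by the input and the configuration.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline, named and surfaced: probe radii, grid
#' spacing, minimum pocket volume, similarity cutoff, score/topology-term
#' forms, RMSF representative point, lining and network cutoffs and the
#' hydrogen-bond/vdW distance criteria (the distance criteria themselves are
#' fixed constants of the interaction module).
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    spacing = 1.0,
    large_probe = 10.0,
    small_probe = 3.0,
    min_volume = 100.0,
    cutoff = 0.25,
    q_form = "product",
    gamma_form = "sphericity",
    area_correction = FALSE,
    representative = "com",
    contact_cutoff = 4.0,
    network_cutoff = 8.0,
    min_seq_sep = 2L,
    node_set = "reference",
    include_ligand = FALSE,
    run_interactions = TRUE
  )
}

#' Run the full pipeline on one entry
#'
#' @param x Path to a multi-model PDB file, or an `rpflex_ensemble`.
#' @param config Configuration list; missing entries fall back to
#'   [default_config()].
#' @return List of class `rpflex_report`: `entry_id`, `config`, `n_models`,
#'   `n_pockets`, `similarity` (matrix object), `groups` (each with the
#'   group's membership, flexibility result, RMSF result, network
#'   flexibility, contact summary, or an `error` field if a stage failed),
#'   and `n_valid_groups`.
#' @export
run_entry <- function(x, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  ens <- if (inherits(x, "rpflex_ensemble")) x else read_multimodel_pdb(x)
  pockets <- detect_ensemble_pockets(
    ens, spacing = cfg$spacing, large_probe = cfg$large_probe,
    small_probe = cfg$small_probe, min_volume = cfg$min_volume,
    include_ligand = cfg$include_ligand)
  if (!length(pockets)) {
    warning("no pockets detected for entry ", ens$entry_id)
    return(structure(list(entry_id = ens$entry_id, config = cfg,
                          n_models = ens$n_models, n_pockets = 0L,
                          similarity = NULL, groups = list(),
                          n_valid_groups = 0L),
                     class = "rpflex_report"))
  }
  mat <- build_matrix(pockets)
  groups <- group_pockets(mat, cutoff = cfg$cutoff, entry_id = ens$entry_id)
  out_groups <- lapply(groups, function(g) {
    res <- list(group_label = g$group_label, m = g$m, valid = g$valid,
                members = g$members, reference = g$reference)
    if (!g$valid) return(res)
    tryCatch({
      flex <- score_group(g, mat, pockets, q_form = cfg$q_form,
                          gamma_form = cfg$gamma_form,
                          area_correction = cfg$area_correction)
      rmsf <- group_rmsf(g, ens, pockets,
                         representative = cfg$representative,
                         contact_cutoff = cfg$contact_cutoff)
      nets <- group_networks(g, ens, pockets, cutoff = cfg$network_cutoff,
                             min_seq_sep = cfg$min_seq_sep,
                             contact_cutoff = cfg$contact_cutoff,
                             node_set = cfg$node_set)
      netflex <- ensemble_network_flexibility(nets, flex$Q)
      res$flexibility <- flex
      res$rmsf <- rmsf
      res$network <- netflex
      if (isTRUE(cfg$run_interactions))
        res$interactions <- group_interactions(
          g, ens, pockets, contact_cutoff = cfg$contact_cutoff)$summary
      res
    }, error = function(e) {
      res$error <- conditionMessage(e)
      res
    })
  })
  structure(list(
    entry_id = ens$entry_id,
    config = cfg,
    n_models = ens$n_models,
    n_pockets = length(pockets),
    similarity = mat,
    groups = out_groups,
    n_valid_groups = sum(vapply(groups, function(g) g$valid, logical(1)))
  ), class = "rpflex_report")
}

#' Write an entry report as JSON
#'
#' @param report An `rpflex_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  slim <- report
  slim$similarity <- if (!is.null(report$similarity)) list(
    labels = report$similarity$labels,
    P = unname(report$similarity$P),
    N = unname(report$similarity$N)) else NULL
  slim$groups <- lapply(report$groups, function(g) {
    if (!is.null(g$flexibility)) g$flexibility <- unclass(g$flexibility)
    if (!is.null(g$rmsf)) g$rmsf <- unclass(g$rmsf)
    if (!is.null(g$network)) g$network <- unclass(g$network)
    if (!is.null(g$interactions)) g$interactions <- unclass(g$interactions)
    g
  })
  jsonlite::write_json(unclass(slim), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.rpflex_report <- function(x, ...) {
  cat("rpflex entry report:", x$entry_id, "\n")
  cat("  models:", x$n_models, " pockets:", x$n_pockets,
      " groups:", length(x$groups),
      " valid groups:", x$n_valid_groups, "\n")
  for (g in x$groups) {
    if (!is.null(g$flexibility)) {
      f <- g$flexibility
      cat(sprintf(
        "  %s m=%d Q=%.3f (%s) S=%.3f Pbar=%.3f Gamma=%.3f Vg=%.0f (%s)\n",
        g$group_label, g$m, f$Q, f$flex_class, f$S, f$Pbar, f$Gamma,
        f$Vg, f$size_class))
      if (!is.null(g$rmsf))
        cat(sprintf("    mean RMSF %.2f A over %d overlapping nucleotides\n",
                    g$rmsf$mean_rmsf, length(g$rmsf$overlapping_nucleotides)))
    } else {
      cat(sprintf("  %s m=%d %s\n", g$group_label, g$m,
                  if (g$valid) paste("error:", g$error) else "invalid (m < 3)"))
    }
  }
  invisible(x)
}
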