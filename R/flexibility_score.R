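# The flexibility score Q of a pocket group and its components: the spatial
# terms S and Pbar from the group's similarity sub-matrix, the topology term
# Gamma from the member pockets' volume/area/sphericity, the rigidity /
# intermediate / flexibility classification, and the overlapping volume Vg.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Spatial variation terms of a pocket group
#'
#' For the `m x m` similarity sub-matrix of a valid group: `sigma_i` is the
#' population standard deviation (divide by m) of row i, `S` the mean of the
#' `sigma_i`, and `Pbar` the grand mean of all `m^2` entries. Larger `S`
#' means more spatial variation; larger `Pbar` means tighter overlap.
#'
#' @param sub_matrix Numeric `m x m` similarity sub-matrix, `m >= 3`.
#' @return List with `sigma_i`, `S`, `Pbar`.
#' @export
spatial_terms <- function(sub_matrix) {
  sub_matrix <- as.matrix(sub_matrix)
  m <- nrow(sub_matrix)
  if (m < 3 || ncol(sub_matrix) != m)
    stop("invalid-group error: need a square sub-matrix with m >= 3")
  sigma_i <- apply(sub_matrix, 1, .pop_sd)
  list(sigma_i = sigma_i, S = mean(sigma_i), Pbar = mean(sub_matrix))
}

#' Topology-change term of a pocket group
#'
#' `Gamma` averages, over the m member pockets, the absolute difference
#' between each pocket's sphericity and the sphericity of its "difference
#' pocket": `| psi_i - pi^(1/3) (6 |V_i - Vbar|)^(2/3) / (A_i - Abar) |`.
#' The magnitude of the volume deviation is taken before the 2/3 power so the
#' fractional power stays real; the signed area deviation is kept in the
#' denominator; terms with `|A_i - Abar| < eps` contribute `|psi_i|`.
#' `gamma_form = "literal"` drops the sphericity constant and instead uses
#' `|V_i - Vbar|^(2/3) / (6 (A_i - Abar))`.
#'
#' @param V,A,psi Numeric vectors of member volumes (cubic Angstrom), surface
#'   areas (square Angstrom) and sphericities, all length `m >= 3`.
#' @param gamma_form `"sphericity"` (default) or `"literal"`.
#' @param eps Area-degeneracy guard in square Angstrom.
#' @return `Gamma` (scalar).
#' @export
topology_term <- function(V, A, psi, gamma_form = c("sphericity", "literal"),
                          eps = 1e-9) {
  gamma_form <- match.arg(gamma_form)
  m <- length(V)
  if (m < 3 || length(A) != m || length(psi) != m)
    stop("invalid-group error: need V, A, psi of equal length m >= 3")
  dV <- abs(V - mean(V))
  dA <- A - mean(A)
  term <- numeric(m)
  for (i in seq_len(m)) {
    if (abs(dA[i]) < eps) {
      term[i] <- abs(psi[i])
    } else {
      inner <- switch(gamma_form,
        sphericity = pi^(1 / 3) * (6 * dV[i])^(2 / 3) / dA[i],
        literal = dV[i]^(2 / 3) / (6 * dA[i]))
      term[i] <- abs(psi[i] - inner)
    }
  }
  mean(term)
}

#' Flexibility score Q
#'
#' Default product form `Q = (S / Pbar) * Gamma`: the score's expanded
#' definition carries `S / Pbar` inside the sum multiplied by each pocket's
#' topology term, and larger topology change means more flexibility. The
#' quotient reading `Q = (S / Pbar) / Gamma` is available behind
#' `form = "quotient"`. Identical pockets (`S = 0`) give `Q = 0` in both
#' forms.
#'
#' @param S,Pbar,Gamma Spatial and topology terms of the group.
#' @param form `"product"` (default) or `"quotient"`.
#' @return `Q >= 0`.
#' @export
flexibility_Q <- function(S, Pbar, Gamma, form = c("product", "quotient")) {
  form <- match.arg(form)
  stopifnot(Pbar > 0)
  if (S == 0) return(0)
  if (form == "quotient") {
    if (Gamma <= 0) stop("degenerate-group error: quotient form needs Gamma > 0")
    (S / Pbar) / Gamma
  } else {
    (S / Pbar) * Gamma
  }
}

#' Flexibility class of a score
#'
#' `rigidity` for `Q < 0.30`, `intermediate` for `0.30 <= Q < 0.60`,
#' `flexibility` for `Q >= 0.60`.
#'
#' @param Q Flexibility score(s), `>= 0`.
#' @return Character vector of class labels.
#' @export
classify_flexibility <- function(Q) {
  stopifnot(all(Q >= 0))
  ifelse(Q < 0.30, "rigidity",
         ifelse(Q < 0.60, "intermediate", "flexibility"))
}

#' Overlapping volume of a pocket group
#'
#' `Vg = Vbar x Pbar`, with size classes small `(0, 500]`, medium
#' `(500, 1500]`, large `(1500, 7200]` cubic Angstrom (upper bounds
#' inclusive); values beyond 7200 warn and classify as large.
#'
#' @param Vbar Mean member volume (cubic Angstrom), `> 0`.
#' @param Pbar Mean similarity, in `(0, 1]`.
#' @return List with `Vg` and `size_class`.
#' @export
overlapping_volume <- function(Vbar, Pbar) {
  stopifnot(Vbar > 0, Pbar > 0, Pbar <= 1)
  Vg <- Vbar * Pbar
  size_class <- if (Vg <= 500) "small" else if (Vg <= 1500) "medium" else "large"
  if (Vg > 7200)
    warning("overlapping volume ", round(Vg), " beyond the large bin (7200)")
  list(Vg = Vg, size_class = size_class)
}

#' Score one pocket group
#'
#' Assembles the full flexibility result for a valid group: spatial terms
#' from the similarity sub-matrix, topology term from the member metrics,
#' `Q`, its class, and the overlapping volume.
#'
#' @param group An `rpflex_pocket_group` with `m >= 3`.
#' @param matrix The entry's `rpflex_simmat`.
#' @param pockets The entry's pocket list (as passed to [build_matrix()]).
#' @param q_form,gamma_form Passed to [flexibility_Q()] and [topology_term()].
#' @param area_correction Passed to [compute_metrics()].
#' @return List of class `rpflex_flexibility`: `group_label`, `m`, `sigma_i`,
#'   `S`, `Pbar`, `Gamma`, `Q`, `flex_class`, `Vbar`, `Abar`, `Vg`,
#'   `size_class`.
#' @export
score_group <- function(group, matrix, pockets,
                        q_form = c("product", "quotient"),
                        gamma_form = c("sphericity", "literal"),
                        area_correction = FALSE) {
  stopifnot(inherits(group, "rpflex_pocket_group"))
  if (!group$valid)
    stop("invalid-group error: group ", group$group_label, " has m = ",
         group$m, " < 3")
  idx <- group$member_idx
  sub <- matrix$P[idx, idx, drop = FALSE]
  st <- spatial_terms(sub)
  by_label <- setNames(pockets, vapply(pockets, function(p) p$label,
                                       character(1)))
  mets <- lapply(group$members, function(l)
    compute_metrics(by_label[[l]], area_correction = area_correction))
  V <- vapply(mets, function(x) x$Vp, numeric(1))
  A <- vapply(mets, function(x) x$Ap, numeric(1))
  psi <- vapply(mets, function(x) x$psi, numeric(1))
  Gamma <- topology_term(V, A, psi, gamma_form = match.arg(gamma_form))
  Q <- flexibility_Q(st$S, st$Pbar, Gamma, form = match.arg(q_form))
  ov <- overlapping_volume(mean(V), st$Pbar)
  structure(list(
    group_label = group$group_label,
    m = group$m,
    sigma_i = st$sigma_i,
    S = st$S,
    Pbar = st$Pbar,
    Gamma = Gamma,
    Q = Q,
    flex_class = classify_flexibility(Q),
    Vbar = mean(V),
    Abar = mean(A),
    Vg = ov$Vg,
    size_class = ov$size_class
  ), class = "rpflex_flexibility")
}
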