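test_that("spatial terms match direct arithmetic", {
  ones <- matrix(1, 3, 3)
  st <- spatial_terms(ones)
  expect_equal(st$sigma_i, rep(0, 3), ignore_attr = TRUE)
  expect_equal(st$S, 0)
  expect_equal(st$Pbar, 1)

  sub <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  st2 <- spatial_terms(sub)
  sd_row <- oracle_pop_sd(c(1, 0.5, 0.5)) # 0.235702...
  expect_equal(st2$sigma_i, rep(sd_row, 3), ignore_attr = TRUE)
  expect_equal(st2$S, sd_row)
  expect_equal(st2$Pbar, 2 / 3)

  # the grand mean is invariant under relabeling the pockets
  set.seed(1)
  r <- matrix(runif(25), 5, 5); diag(r) <- 1
  perm <- sample(5)
  expect_equal(spatial_terms(r)$Pbar, spatial_terms(r[perm, perm])$Pbar)
  expect_equal(sort(spatial_terms(r)$sigma_i),
               sort(spatial_terms(r[perm, perm])$sigma_i))
  expect_error(spatial_terms(matrix(1, 2, 2)), "invalid-group")
})

test_that("topology term follows the sphericity-difference form", {
  # identical pockets: every term degenerates to |psi_i|
  expect_equal(topology_term(rep(100, 3), rep(120, 3), c(0.8, 0.8, 0.8)),
               0.8)
  # independent scalar-arithmetic oracle, term by term (no degenerate A_i)
  V <- c(1000, 1150, 900); A <- c(600, 680, 550); psi <- c(0.8, 0.75, 0.85)
  oracle <- mean(abs(psi - pi^(1 / 3) * (6 * abs(V - mean(V)))^(2 / 3) /
                       (A - mean(A))))
  expect_equal(topology_term(V, A, psi), oracle)
  oracle_lit <- mean(abs(psi - abs(V - mean(V))^(2 / 3) / (6 * (A - mean(A)))))
  expect_equal(topology_term(V, A, psi, gamma_form = "literal"), oracle_lit)
  # dimensional homogeneity: V scaled by 8 and A by 4 leaves quotients alone
  expect_equal(topology_term(8 * V, 4 * A, psi), topology_term(V, A, psi))
  # member relabeling leaves Gamma unchanged
  perm <- c(2, 3, 1)
  expect_equal(topology_term(V[perm], A[perm], psi[perm]),
               topology_term(V, A, psi))
})

test_that("Q behaves in both forms and zero-variation collapses to zero", {
  expect_equal(flexibility_Q(0, 0.5, 3), 0)
  expect_equal(flexibility_Q(0, 1, 0, form = "quotient"), 0)
  expect_equal(flexibility_Q(0.3, 0.6, 2), 1) # (0.3/0.6)*2
  expect_equal(flexibility_Q(0.3, 0.6, 2, form = "quotient"), 0.25)
  expect_error(flexibility_Q(0.3, 0.6, 0, form = "quotient"),
               "degenerate-group")
})

test_that("flexibility classes use the printed boundaries", {
  expect_equal(classify_flexibility(0.09), "rigidity")
  expect_equal(classify_flexibility(0.2999), "rigidity")
  expect_equal(classify_flexibility(0.30), "intermediate")
  expect_equal(classify_flexibility(0.5999), "intermediate")
  expect_equal(classify_flexibility(0.60), "flexibility")
  expect_equal(classify_flexibility(0.84), "flexibility")
  expect_equal(classify_flexibility(c(0, 0.45, 2)),
               c("rigidity", "intermediate", "flexibility"))
})

test_that("overlapping volume bins are half-open with inclusive tops", {
  expect_equal(overlapping_volume(1000, 0.8),
               list(Vg = 800, size_class = "medium"))
  expect_equal(overlapping_volume(400, 1.0),
               list(Vg = 400, size_class = "small"))
  expect_equal(overlapping_volume(500, 1.0)$size_class, "small")
  expect_equal(overlapping_volume(1500, 1.0)$size_class, "medium")
  expect_warning(ov <- overlapping_volume(8000, 1.0), "7200")
  expect_equal(ov$size_class, "large")
})

test_that("identical pockets across models score exactly zero", {
  base <- make_voxel_shape("box", 3)$cells
  pockets <- lapply(1:4, function(m)
    new_grid_pocket(base, 1, c(0, 0, 0), model_index = m))
  mat <- build_matrix(pockets)
  gs <- group_pockets(mat, entry_id = "Z")
  res <- score_group(gs[[1]], mat, pockets)
  expect_equal(res$Q, 0)
  expect_equal(res$S, 0)
  expect_equal(res$Pbar, 1)
  expect_equal(res$flex_class, "rigidity")
  expect_equal(res$Vg, res$Vbar)
})

test_that("larger perturbation amplitude raises S and lowers Pbar", {
  sh <- make_cavity_shell(5, 6, seed = 11)
  amps <- seq(0.05, 0.75, length.out = 10)
  S <- Pbar <- rep(NA_real_, length(amps))
  for (i in seq_along(amps)) {
    ens <- make_perturbed_ensemble(sh, n_models = 5, s = amps[i], seed = 17)
    pk <- detect_ensemble_pockets(ens)
    mat <- build_matrix(pk)
    gs <- group_pockets(mat, entry_id = ens$entry_id)
    g <- gs[[which(vapply(gs, `[[`, TRUE, "valid"))[1]]]
    st <- spatial_terms(mat$P[g$member_idx, g$member_idx])
    S[i] <- st$S
    Pbar[i] <- st$Pbar
  }
  expect_gt(cor(amps, S, method = "spearman"), 0)
  expect_lt(cor(amps, Pbar, method = "spearman"), 0)
})
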