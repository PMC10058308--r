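test_that("duplicated models have zero RMSF everywhere", {
  sh <- make_cavity_shell(4, 3.5, atom_spacing = 1.5, seed = 4)
  ens <- make_perturbed_ensemble(sh, n_models = 5, s = 0, seed = 1)
  r <- structure_rmsf(ens)
  expect_equal(unname(r$per_nucleotide_rmsf),
               rep(0, length(r$per_nucleotide_rmsf)))
  expect_equal(r$mean_rmsf, 0)
})

test_that("a single displaced nucleotide follows the m = 2 closed form", {
  tpl <- point_residue_model(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                             resno = 1:3)
  d <- 1.7
  x2 <- tpl$xyz
  x2[2, ] <- x2[2, ] + c(d, 0, 0)
  ens <- manual_ensemble(tpl, list(tpl$xyz, x2))
  r <- structure_rmsf(ens, reference_model_index = 1)
  expect_equal(unname(r$per_nucleotide_rmsf["A/2"]), d / sqrt(2))
  expect_equal(unname(r$per_nucleotide_rmsf["A/1"]), 0)
})

test_that("RMSF is rigid-translation invariant and scales linearly", {
  sh <- make_cavity_shell(4, 3.5, atom_spacing = 1.5, seed = 4)
  ens <- make_perturbed_ensemble(sh, n_models = 5, s = 0.8, seed = 9)
  r0 <- structure_rmsf(ens)
  shifted <- ens
  for (m in seq_len(ens$n_models))
    shifted$xyz[, , m] <- ens$xyz[, , m] + rep(c(5, -3, 8), each = nrow(ens$atoms))
  expect_equal(structure_rmsf(shifted)$per_nucleotide_rmsf,
               r0$per_nucleotide_rmsf, tolerance = 1e-9)
  # doubling every displacement from the reference doubles the RMSF
  doubled <- ens
  for (m in seq_len(ens$n_models))
    doubled$xyz[, , m] <- ens$xyz[, , 1] + 2 * (ens$xyz[, , m] - ens$xyz[, , 1])
  expect_equal(structure_rmsf(doubled)$per_nucleotide_rmsf,
               2 * r0$per_nucleotide_rmsf, tolerance = 1e-9)
})

test_that("mean RMSF grows with the perturbation scale (coupled seeds)", {
  sh <- make_cavity_shell(4, 3.5, atom_spacing = 1.5, seed = 4)
  scales <- c(0.2, 0.5, 1.0, 1.5, 2.0)
  means <- vapply(scales, function(s)
    structure_rmsf(make_perturbed_ensemble(sh, 6, s, seed = 3))$mean_rmsf,
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pocket lining grows monotonically with the contact cutoff", {
  sh <- make_cavity_shell(4, 4, seed = 6)
  pk <- detect_pockets(sh)[[1]]
  lin <- lapply(c(3, 4, 5), function(co)
    pocket_lining_nucleotides(pk, sh, contact_cutoff = co))
  expect_true(all(lin[[1]] %in% lin[[2]]))
  expect_true(all(lin[[2]] %in% lin[[3]]))
  expect_gt(length(lin[[1]]), 0)
})

test_that("overlapping nucleotides require a strict majority of pockets", {
  # four single-cell pockets; a residue sits next to the cell in some models
  cell <- matrix(c(0L, 0L, 0L), 1, 3)
  pockets <- lapply(1:4, function(m)
    new_grid_pocket(cell, 1, c(0, 0, 0), model_index = m))
  near <- c(1.5, 0.5, 0.5) # 1 A from the cell center
  far <- c(30, 30, 30)
  tpl <- point_residue_model(rbind(near, c(0.5, 3, 0.5)), resno = 1:2)
  # residue 1 near in models 1-2 (exactly half), residue 2 near in all
  xyz_far <- tpl$xyz; xyz_far[1, ] <- far
  ens <- manual_ensemble(tpl, list(tpl$xyz, tpl$xyz, xyz_far, xyz_far))
  g <- manual_group(vapply(pockets, `[[`, "", "label"), 1:4)
  ov <- overlapping_nucleotides(g, pockets, ens)
  expect_false("A/1" %in% ov) # lines exactly m/2: excluded
  expect_true("A/2" %in% ov)  # lines all m: included
})

test_that("group RMSF references the first pocket's model", {
  cell <- matrix(c(0L, 0L, 0L), 1, 3)
  pockets <- lapply(1:3, function(m)
    new_grid_pocket(cell, 1, c(0, 0, 0), model_index = m))
  tpl <- point_residue_model(matrix(c(1.5, 0.5, 0.5), 1, 3), resno = 1)
  x2 <- tpl$xyz + rep(c(2, 0, 0), each = 1)
  x3 <- tpl$xyz + rep(c(4, 0, 0), each = 1)
  ens <- manual_ensemble(tpl, list(tpl$xyz, x2, x3))
  g <- manual_group("m1-1", 1:3,
                    label = "MAN-G1")
  g$members <- c("m1-1", "m2-1", "m3-1")
  r <- group_rmsf(g, ens, pockets)
  expect_equal(r$reference_model, 1L)
  # displacements 0, 2, 4 from model 1: rmsf = sqrt((0+4+16)/3)
  expect_equal(unname(r$per_nucleotide_rmsf), sqrt(20 / 3))
})
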