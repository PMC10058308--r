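test_that("pairwise similarity counts overlapping voxels of the reference", {
  a <- make_voxel_shape("box", 2) # 8 cells
  expect_equal(pairwise_similarity(a, a), 1)
  b <- new_grid_pocket(a$cells + 50L, 1, c(0, 0, 0), model_index = 2)
  expect_equal(pairwise_similarity(a, b), 0)
  cpart <- new_grid_pocket(a$cells[1:2, ], 1, c(0, 0, 0), model_index = 2)
  expect_equal(pairwise_similarity(a, cpart), 0.25)
  expect_equal(pairwise_similarity(cpart, a), 1) # asymmetric
  shifted <- new_grid_pocket(a$cells, 1, c(0.5, 0, 0))
  expect_error(pairwise_similarity(a, shifted), "frame error")
})

test_that("similarity matrix is reciprocal against a set-intersection oracle", {
  set.seed(42)
  for (rep in 1:5) {
    pockets <- lapply(1:6, function(i)
      new_grid_pocket(random_cells(30), 1, c(0, 0, 0),
                      model_index = (i + 1) %/% 2, pocket_index = 2 - i %% 2))
    mat <- build_matrix(pockets)
    q <- length(mat$labels)
    expect_equal(diag(mat$P), rep(1, q), ignore_attr = TRUE)
    by_label <- setNames(pockets, vapply(pockets, `[[`, "", "label"))
    for (i in seq_len(q)) for (j in seq_len(q)) {
      pi <- by_label[[mat$labels[i]]]
      pj <- by_label[[mat$labels[j]]]
      expect_equal(mat$P[i, j], oracle_similarity(pi$cells, pj$cells))
      expect_equal(mat$P[i, j] * mat$N[i], mat$P[j, i] * mat$N[j],
                   ignore_attr = TRUE)
    }
  }
})

test_that("degenerate matrices behave", {
  one <- build_matrix(list(make_voxel_shape("box", 2)))
  expect_equal(unname(one$P), matrix(1, 1, 1))
  twin <- build_matrix(list(
    make_voxel_shape("box", 2),
    new_grid_pocket(make_voxel_shape("box", 2)$cells, 1, c(0, 0, 0),
                    model_index = 2)))
  expect_equal(unname(twin$P), matrix(1, 2, 2))
})

.grouping_fixture <- function() {
  base <- make_voxel_shape("box", 2)$cells
  mk <- function(cells, mi, pi)
    new_grid_pocket(cells, 1, c(0, 0, 0), model_index = mi, pocket_index = pi)
  # model 1 carries two references; models 2-4 carry matching pockets,
  # model 4 also carries one orphan far from both references
  list(mk(base, 1, 1), mk(base + 30L, 1, 2),
       mk(rbind(base[1:6, ], c(50L, 50L, 50L), c(50L, 50L, 49L)), 2, 1),
       mk(base + 30L, 2, 2),
       mk(base, 3, 1), mk(base + 30L, 3, 2),
       mk(base + 90L, 4, 1))
}

test_that("pockets cluster to first-model references above the cutoff", {
  mat <- build_matrix(.grouping_fixture())
  gs <- group_pockets(mat, cutoff = 0.25, entry_id = "FIX")
  labs <- vapply(gs, `[[`, "", "group_label")
  m <- vapply(gs, `[[`, 1L, "m")
  valid <- vapply(gs, `[[`, TRUE, "valid")
  expect_equal(labs, c("FIX-G1", "FIX-G2", "FIX-G3"))
  expect_equal(m, c(3L, 3L, 1L))
  expect_equal(valid, c(TRUE, TRUE, FALSE))
  expect_equal(gs[[1]]$members, c("m1-1", "m2-1", "m3-1"))
  expect_equal(gs[[3]]$members, "m4-1")
  # groups partition the pocket set
  all_members <- unlist(lapply(gs, `[[`, "members"))
  expect_setequal(all_members, mat$labels)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("assignment is strict and best-match with low-index ties", {
  base <- make_voxel_shape("box", 2)$cells # the 8 cells of {-1,0}^3
  mk <- function(cells, mi, pi)
    new_grid_pocket(cells, 1, c(0, 0, 0), model_index = mi, pocket_index = pi)
  shift_x <- function(m, dx) sweep(m, 2, c(dx, 0L, 0L), "+")
  ref1 <- mk(base, 1, 1)
  ref2 <- mk(shift_x(base, 4L), 1, 2) # disjoint from ref1
  # j: 3 cells of ref1, 4 of ref2, 1 far => P(ref1,j)=0.375, P(ref2,j)=0.5
  j <- mk(rbind(base[1:3, ], shift_x(base[1:4, ], 4L), c(20L, 20L, 20L)),
          2, 1)
  # k: 3 cells of each reference, 2 far => tied at 0.375
  k <- mk(rbind(base[1:3, ], shift_x(base[1:3, ], 4L),
                c(30L, 30L, 30L), c(30L, 30L, 29L)), 2, 2)
  mat <- build_matrix(list(ref1, ref2, j, k))
  gs <- group_pockets(mat, cutoff = 0.25, entry_id = "T")
  expect_equal(gs[[2]]$members, c("m1-2", "m2-1")) # best match wins
  expect_equal(gs[[1]]$members, c("m1-1", "m2-2")) # tie goes to lowest index
  # exactly at the cutoff the pocket is NOT grouped (strict >)
  gs2 <- group_pockets(mat, cutoff = 0.5, entry_id = "T")
  expect_true("m2-1" %in% unlist(lapply(gs2[3:4], `[[`, "members")))
})

test_that("raising the cutoff never grows a group", {
  mat <- build_matrix(.grouping_fixture())
  sizes <- function(cut) {
    gs <- group_pockets(mat, cutoff = cut)
    vapply(gs[1:2], `[[`, 1L, "m")
  }
  s1 <- sizes(0.1); s2 <- sizes(0.5); s3 <- sizes(0.9)
  expect_true(all(s2 <= s1))
  expect_true(all(s3 <= s2))
})

test_that("a first model without pockets leaves only leftover groups", {
  base <- make_voxel_shape("box", 2)$cells
  ps <- list(new_grid_pocket(base, 1, c(0, 0, 0), model_index = 2),
             new_grid_pocket(base, 1, c(0, 0, 0), model_index = 3))
  mat <- build_matrix(ps)
  expect_warning(gs <- group_pockets(mat), "first structural model")
  expect_true(all(!vapply(gs, `[[`, TRUE, "valid")))
})
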