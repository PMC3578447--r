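test_that("occupancy mask of a single atom approximates its vdW sphere", {
  s <- fixture_structure(data.frame(x = 0, y = 0, z = 0))   # carbon, 1.7 A
  g <- build_occupancy(s, spacing = 0.25)
  vol <- sum(g$occupied) * g$spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * 1.7^3) / (4 / 3 * pi * 1.7^3), 0.15)
})

test_that("excluding a group removes its atoms from the masks", {
  cs <- make_cavity_shell(3.5, n_cofactor_atoms = 1)
  cof <- select_cofactor(cs$structure, "CFX")
  g_with <- build_occupancy(cs$structure, spacing = 0.5)
  g_without <- build_occupancy(cs$structure, exclude = cof, spacing = 0.5)
  expect_gt(sum(g_with$occupied), sum(g_without$occupied))
  # an empty exclusion changes nothing
  fake <- cof
  fake$atoms <- cof$atoms[0, , drop = FALSE]
  g_same <- build_occupancy(cs$structure, exclude = NULL, spacing = 0.5)
  expect_equal(sum(g_with$occupied), sum(g_same$occupied))
  expect_equal(sum(g_with$blocked), sum(g_same$blocked))
})

test_that("enclosed spherical cavity volume matches the analytic value", {
  cs <- make_cavity_shell(4.0, n_cofactor_atoms = 1)
  cof <- select_cofactor(cs$structure, "CFX")
  p <- pocket_volume(cs$structure, cof, spacing = 0.4)
  expect_false(p$open_to_solvent)
  expect_lt(abs(p$volume - cs$analytic_volume) / cs$analytic_volume, 0.10)
  expect_equal(p$volume, p$voxel_count * p$spacing^3)

  # Monte-Carlo oracle: fraction of box points that are in the empty
  # interior region (farther than vdW from every shell atom, inside it)
  set.seed(42)
  at <- cs$structure$atoms
  at <- at[at$resname != "CFX", ]
  n_mc <- 20000
  pts <- matrix(runif(3 * n_mc, -5, 5), ncol = 3)
  keep <- sqrt(rowSums(pts^2)) < cs$cavity_radius + 0.5
  xyz <- as.matrix(at[, c("x", "y", "z")])
  mind <- apply(pts, 1, function(p) min(sqrt(colSums((t(xyz) - p)^2))))
  inside <- mind >= at$vdw[1] & keep
  mc_vol <- mean(inside) * 10^3
  expect_lt(abs(mc_vol - cs$analytic_volume) / cs$analytic_volume, 0.10)
})

test_that("pocket volume is invariant under rigid transforms", {
  cs <- make_cavity_shell(4.0, n_cofactor_atoms = 1)
  cof <- select_cofactor(cs$structure, "CFX")
  v0 <- pocket_volume(cs$structure, cof, spacing = 0.4)$volume
  moved <- perturb(cs$structure, noise_sigma = 0, seed = 13)
  v1 <- pocket_volume(moved, select_cofactor(moved, "CFX"), spacing = 0.4)$volume
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("volume error shrinks as the grid refines and probe growth never adds volume", {
  cs <- make_cavity_shell(4.0, n_cofactor_atoms = 1)
  cof <- select_cofactor(cs$structure, "CFX")
  errs <- vapply(c(0.8, 0.5, 0.4), function(sp)
    abs(pocket_volume(cs$structure, cof, spacing = sp)$volume -
          cs$analytic_volume) / cs$analytic_volume, 0)
  expect_true(all(diff(errs) < 0))
  v_small <- pocket_volume(cs$structure, cof, probe = 1.4, spacing = 0.4)$volume
  v_big <- pocket_volume(cs$structure, cof, probe = 2.8, spacing = 0.4)$volume
  expect_lte(v_big, v_small)
})

test_that("a seed outside a solid block reports zero enclosed volume, open to solvent", {
  g <- expand.grid(x = seq(0, 4, 1), y = seq(0, 4, 1), z = seq(0, 4, 1))
  s <- fixture_structure(as.data.frame(g))
  grid <- build_occupancy(s, spacing = 0.5)
  p <- detect_pocket(grid, seed = c(10, 2, 2))
  expect_true(p$open_to_solvent)
  # the counted voxels never overlap occupied space
  expect_true(all(!grid$occupied[p$voxels]))
})

test_that("per-class volume aggregation uses mean and mean absolute deviation", {
  out <- aggregate_volumes(rep("X", 3), c(1, 2, 3), digits = 3)
  expect_equal(out$mean_volume, 2)
  expect_equal(out$average_deviation, 0.667)

  one <- aggregate_volumes("Y", 5)
  expect_equal(one$average_deviation, 0)

  const <- aggregate_volumes(rep("NifD-A", 3), c(1701, 1701, 1701))
  expect_equal(const$mean_volume, 1701)
  expect_equal(const$average_deviation, 0)

  set.seed(1)
  v <- runif(9, 100, 2000)
  cl <- rep(c("a", "b", "c"), each = 3)
  agg <- aggregate_volumes(cl, v)
  for (k in seq_len(3)) {
    vi <- v[cl == agg$class_label[k]]
    expect_gte(attr(agg, "mean")[k], min(vi))
    expect_lte(attr(agg, "mean")[k], max(vi))
  }
})
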