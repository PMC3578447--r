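test_that("contacts follow the distance cutoff and sequence-separation rule", {
  line <- fixture_structure(data.frame(x = c(0, 5, 10), y = 0, z = 0))
  cm <- contact_map(line, cutoff = 6, min_sep = 0)
  expect_equal(cm$contacts[[1]], c(`2` = 2L), ignore_attr = TRUE)
  expect_setequal(cm$contacts[[2]], c(1L, 3L))
  cm2 <- contact_map(line, cutoff = 6, min_sep = 2)
  expect_equal(sum(lengths(cm2$contacts)), 0L)
})

test_that("contact map equals a brute-force double loop on a random coil", {
  s <- make_planted_classes(1, 1, n_res = 50, noise_sigma = 0, seed = 33)$structures[[1]]
  cm <- contact_map(s, cutoff = 8, min_sep = 2)
  at <- s$atoms
  cb <- at[at$name == "CB", ]
  cb <- cb[order(cb$resno), ]
  for (i in 1:50) for (j in 1:50) {
    d <- sqrt(sum((cb[i, c("x", "y", "z")] - cb[j, c("x", "y", "z")])^2))
    want <- i != j && abs(i - j) > 2 && d <= 8
    expect_equal(j %in% cm$contacts[[i]], want)
  }
})

test_that("self-similarity counts residues with contacts; swap symmetry holds", {
  s <- make_planted_classes(1, 1, n_res = 40, noise_sigma = 0, seed = 3)$structures[[1]]
  cm <- contact_map(s)
  expect_equal(vscore(cm, cm), sum(lengths(cm$contacts) > 0))

  other <- make_planted_classes(1, 1, n_res = 40, noise_sigma = 0, seed = 4)$structures[[1]]
  cm2 <- contact_map(other)
  expect_equal(vscore(cm, cm2), vscore(cm2, cm), tolerance = 1e-12)

  flat <- fixture_structure(data.frame(x = (1:40) * 20, y = 0, z = 0))
  cm0 <- contact_map(flat)
  expect_equal(vscore(cm, cm0), 0)
})

test_that("mild coordinate noise keeps most of the self-similarity", {
  s <- make_planted_classes(1, 1, n_res = 60, noise_sigma = 0, seed = 10)$structures[[1]]
  cm <- contact_map(s)
  self <- vscore(cm, cm)
  for (i in 1:10) {
    noisy <- perturb(s, noise_sigma = 0.3, seed = 600 + i)
    expect_gte(vscore(cm, contact_map(noisy)), 0.8 * self)
  }
})

test_that("standardized distances are zero for duplicates and one for disjoint contact sets", {
  s <- make_planted_classes(1, 1, n_res = 40, noise_sigma = 0, seed = 12)$structures[[1]]
  sm <- distance_matrix(list(a = s, b = s))
  expect_equal(unname(sm$D["a", "b"]), 0, tolerance = 1e-12)
  expect_equal(diag(sm$D), c(a = 0, b = 0))

  # hairpin in opposite halves: every mapped contact set is disjoint
  hairpin <- function(first_half) {
    xy <- matrix(0, 20, 3)
    fold <- if (first_half) 1:10 else 11:20
    straight <- setdiff(1:20, fold)
    xy[fold, 1] <- rep(c(0, 4), each = 5)[seq_along(fold)]
    xy[fold, 2] <- rep(seq(0, 16, 4), 2)[seq_along(fold)]
    xy[straight, 1] <- 100 + 20 * seq_along(straight)
    fixture_structure(as.data.frame(xy) |> stats::setNames(c("x", "y", "z")))
  }
  sm2 <- distance_matrix(list(p = hairpin(TRUE), q = hairpin(FALSE)))
  expect_equal(unname(sm2$D["p", "q"]), 1)
  expect_true(all(sm2$D >= 0 & sm2$D <= 1))
})

test_that("complete linkage matches hand and hclust oracles with monotone heights", {
  # two leaves
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  dend2 <- complete_linkage(d2)
  expect_equal(dend2$height, 1)
  expect_equal(to_newick(dend2), "(A:0.5,B:0.5);")

  # 4x4 hand computation: {a,b} at 0.1; {c,d} at 0.2; all at 0.9
  d4 <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 0.1
  d4["c", "d"] <- d4["d", "c"] <- 0.2
  diag(d4) <- 0
  dend4 <- complete_linkage(d4)
  expect_equal(dend4$height, c(0.1, 0.2, 0.9))

  for (seed in 1:40) {
    D <- random_distance_matrix(6, seed)
    got <- complete_linkage(D)$height
    expect_equal(got, oracle_complete_linkage_heights(D), tolerance = 1e-12)
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    expect_equal(got, hc$height, tolerance = 1e-12)
    expect_true(all(diff(got) >= -1e-12))
  }
})

test_that("planted block matrices split into their blocks at mid-height", {
  n <- 6
  D <- matrix(0.9, n, n)
  D[1:3, 1:3] <- 0.1
  D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  dimnames(D) <- list(letters[1:n], letters[1:n])
  grp <- cut_dendrogram(complete_linkage(D), h = 0.5)
  expect_equal(length(unique(grp)), 2L)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
})

test_that("dendrogram heights are invariant to input label order", {
  D <- random_distance_matrix(7, 99)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  Dp <- D[perm, perm]
  expect_equal(sort(complete_linkage(D)$height),
               sort(complete_linkage(Dp)$height), tolerance = 1e-12)
  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("newick output parses back with all leaves and ultrametric depths", {
  for (seed in 1:20) {
    n <- sample(3:8, 1)
    D <- random_distance_matrix(n, 1000 + seed)
    dend <- complete_linkage(D)
    tree <- ape::read.tree(text = to_newick(dend))
    expect_equal(ape::Ntip(tree), n)
    expect_setequal(tree$tip.label, rownames(D))
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  }
})
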