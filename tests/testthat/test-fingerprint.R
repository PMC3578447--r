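test_that("alignment columns map onto reference author numbers", {
  aln <- c(AvNifD_ref = "MKVAL", q = "MKVAL")
  m <- map_to_reference(aln, "AvNifD_ref")
  expect_equal(m$col_to_ref, 1:5)

  gapped <- c(AvNifD_ref = "--MKVAL", q = "AAMKVAL")
  m2 <- map_to_reference(gapped, "AvNifD_ref")
  expect_equal(m2$col_to_ref, c(NA, NA, 1:5))
  expect_equal(unname(m2$ref_to_col["3"]), 5L)

  # hand-computed 3-row toy with author numbering offset
  toy <- c(AvNifD_ref = "AC-DE", x = "ACQDE", y = "A--DE")
  m3 <- map_to_reference(toy, "AvNifD_ref", ref_numbers = c(10L, 11L, 12L, 13L))
  expect_equal(m3$col_to_ref, c(10L, 11L, NA, 12L, 13L))

  expect_error(map_to_reference(aln, "missing"), "not found")
})

test_that("reference windows reproduce the motif rows up to case and x positions", {
  aln <- c(AvNifD_ref = reference_sequence())
  m <- map_to_reference(aln, "AvNifD_ref")
  win <- extract_windows(aln[["AvNifD_ref"]], m)
  nifa <- win[win$class_label == "NifD-A", ]
  for (i in seq_len(nrow(nifa))) {
    p <- strsplit(nifa$pattern[i], "")[[1]]
    w <- strsplit(nifa$window[i], "")[[1]]
    fixed <- p != "x"
    expect_equal(w[fixed], toupper(p[fixed]),
                 label = paste("window", nifa$anchor[i]))
  }
  expect_false(any(nifa$missing))
})

test_that("a query shorter than the reference flags windows beyond its end", {
  ref <- reference_sequence()
  short <- paste0(substr(ref, 1, 300), strrep("-", 160))
  aln <- c(AvNifD_ref = ref, q = short)
  win <- extract_windows(aln[["q"]], map_to_reference(aln, "AvNifD_ref"))
  expect_true(all(win$missing[win$start > 300]))
  expect_false(any(win$missing[win$end <= 300]))
})

test_that("pattern scoring rewards conservation and strong-group similarity", {
  expect_equal(score_pattern("GHKW", "GHKW"), 8)
  expect_equal(score_pattern("AAAA", "xxxx"), 0)
  expect_equal(score_pattern("GHKW", "AHKW"), 4)       # one uppercase miss
  expect_equal(score_pattern("IV", "lm"), 2)           # MILV strong group
  expect_equal(score_pattern("G-", "GG"), 0)           # gap = mismatch
  expect_error(score_pattern("AB", "ABC"), "length mismatch")

  # the Cys275 tetrads: CARS scores strictly higher against the V/Fe-form
  # pattern than against the Mo-form pattern
  expect_gt(score_pattern("CARS", "CARS"), score_pattern("CARS", "CxRS"))
  for (tet in c("CYRS", "CQRS", "CHRS")) expect_true(phi_pattern_check(tet))
  expect_true(phi_pattern_check("CARS"))
  expect_true(phi_pattern_check("ACTRS"))
  expect_false(phi_pattern_check("CRSX"))
})

test_that("each class row embedded in the scaffold classifies as its own class", {
  for (cl in c("NifD-A", "NifD-B", "Unc", "AnfD", "VnfD")) {
    fam <- make_motif_family(cl, 3, mutation_rate = 0, seed = 11)
    for (id in names(fam$sequences)) {
      pred <- classify(id, fam$alignment)
      expect_equal(pred$predicted_class, cl)
      expect_equal(unname(pred$predicted_cofactor),
                   unname(c("NifD-A" = "FeMo-co", "NifD-B" = "FeMo-co",
                            "Unc" = "FeMo-co", "VnfD" = "FeV-co",
                            "AnfD" = "FeFe-co")[cl]))
      expect_gt(pred$confidence, 0)
    }
  }
  ref_pred <- classify("AvNifD_ref",
                       c(AvNifD_ref = reference_sequence(),
                         pad = reference_sequence()))
  expect_equal(ref_pred$predicted_class, "NifD-A")
  expect_equal(ref_pred$predicted_cofactor, "FeMo-co")
})

test_that("diagnostic positions steer votes toward the stated classes", {
  ref <- strsplit(reference_sequence(), "")[[1]]
  vnf_like <- ref
  vnf_like[65] <- "C"; vnf_like[69] <- "L"; vnf_like[96] <- "K"
  vnf_like[276] <- "A"; vnf_like[380] <- "K"; vnf_like[428] <- "G"
  aln <- c(AvNifD_ref = reference_sequence(),
           q = paste(vnf_like, collapse = ""))
  pred <- classify("q", aln)
  expect_gt(pred$votes[["VnfD"]], pred$votes[["NifD-A"]])
  expect_gt(pred$votes[["AnfD"]], pred$votes[["NifD-A"]])
  # every rule fired on the Vnf/Anf side
  expect_true(all(grepl("VnfD|AnfD", pred$diagnostics$votes_for)))

  unc_like <- ref
  unc_like[380] <- "T"
  pred2 <- classify("q", c(AvNifD_ref = reference_sequence(),
                           q = paste(unc_like, collapse = "")))
  d380 <- pred2$diagnostics[pred2$diagnostics$position == 380, ]
  expect_equal(d380$votes_for, "Unc")
})

test_that("sequences lacking both cluster ligand positions are flagged Nif-like", {
  ref <- strsplit(reference_sequence(), "")[[1]]
  ref[275] <- "A"; ref[442] <- "A"
  aln <- c(AvNifD_ref = reference_sequence(), q = paste(ref, collapse = ""))
  pred <- classify("q", aln)
  expect_true(is.na(pred$predicted_class))
  expect_true(any(grepl("Nif-like", pred$flags)))

  ref2 <- strsplit(reference_sequence(), "")[[1]]
  ref2[275] <- "A"
  pred2 <- classify("q", c(AvNifD_ref = reference_sequence(),
                           q = paste(ref2, collapse = "")))
  expect_false(is.na(pred2$predicted_class))
  expect_true(any(grepl("ligand position missing", pred2$flags)))
})

test_that("classification is deterministic and invariant to profile row order", {
  fam <- make_motif_family("AnfD", 1, 0.03, seed = 8)
  id <- names(fam$sequences)[1]
  p1 <- classify(id, fam$alignment)
  prof <- motif_profiles()
  set.seed(5)
  p2 <- classify(id, fam$alignment, profiles = prof[sample(nrow(prof)), ])
  expect_equal(p1$predicted_class, p2$predicted_class)
  expect_equal(sort(p1$total), sort(p2$total))
})

test_that("accumulating mutations erodes the classification margin on average", {
  fam_lo <- make_motif_family("VnfD", 30, 0.01, seed = 3)
  m_low <- mean(vapply(names(fam_lo$sequences),
                       function(id) classify(id, fam_lo$alignment)$confidence, 0))
  fam_hi <- make_motif_family("VnfD", 30, 0.15, seed = 3)
  m_high <- mean(vapply(names(fam_hi$sequences),
                        function(id) classify(id, fam_hi$alignment)$confidence, 0))
  expect_gt(m_low, m_high)
})

test_that("extensions and insertions are read off the alignment", {
  ref <- "MKVALWQH"
  same <- detect_extensions(c(r = ref, q = ref), "r")$q
  expect_equal(same$c_terminal_overhang, 0L)
  expect_equal(nrow(same$internal_insertions), 0L)

  over <- detect_extensions(c(r = paste0(ref, strrep("-", 12)),
                              q = paste0(ref, strrep("A", 12))), "r")$q
  expect_equal(over$c_terminal_overhang, 12L)

  # 3-residue insertion after reference position 4
  ins <- detect_extensions(c(r = "MKVA---LWQH", q = "MKVAGGGLWQH"), "r")$q
  expect_equal(ins$internal_insertions$ref_position, 4L)
  expect_equal(ins$internal_insertions$length, 3L)

  big <- detect_extensions(
    c(r = paste0(strrep("A", 100), strrep("-", 15), strrep("A", 50)),
      q = paste0(strrep("A", 100), strrep("G", 15), strrep("A", 50))), "r")$q
  expect_equal(big$internal_insertions$ref_position, 100L)
  expect_equal(big$internal_insertions$length, 15L)
})
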