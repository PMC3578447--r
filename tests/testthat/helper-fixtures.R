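# Fixtures are built in code; no binary data ships with the package.

# build a structure straight from an atom table (geometry fixtures)
fixture_structure <- function(df, id = "fixture") {
  defaults <- list(name = "CA", element = "C", resname = "ALA", chain = "A",
                   ins = "", occupancy = 1, hetero = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$serial)) df$serial <- seq_len(nrow(df))
  if (is.null(df$resno)) df$resno <- seq_len(nrow(df))
  metcof:::.new_structure(df, id = id)
}

# n random heavy-atom points in a box, one residue each
random_point_structure <- function(n, seed, box = 20) {
  set.seed(seed)
  fixture_structure(data.frame(
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
  ))
}

# fixed-column PDB text lines for parser tests
pdb_line <- function(type, serial, name, resname, chain, resno, x, y, z,
                     element, occ = 1.0, alt = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
          element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# independent complete-linkage oracle: recomputes every inter-cluster
# distance from the original matrix at every step (no running update)
oracle_complete_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# a small two-class bundle with all three evidence lines
two_class_bundle <- function(seed = 21, mutation_rate = 0.02) {
  classes <- c("NifD-A", "VnfD")
  pc <- make_planted_classes(2, 3, n_res = 60, noise_sigma = 0.3, seed = seed)
  lab <- stats::setNames(
    classes[as.integer(sub("C([0-9]+).*", "\\1", names(pc$structures)))],
    names(pc$structures))
  structs <- pc$structures
  names(structs)[names(structs) == "C1_m3"] <- "q1"
  names(structs)[names(structs) == "C2_m3"] <- "q2"
  ref_labels <- lab[!(names(lab) %in% c("C1_m3", "C2_m3"))]
  # double-size cavity contrast between the classes
  radii <- c(4.7, 3.7)
  vols <- c()
  means <- c()
  for (i in 1:2) {
    cs <- make_cavity_shell(radii[i], n_cofactor_atoms = 1)
    v <- pocket_volume(cs$structure, select_cofactor(cs$structure, "CFX"))$volume
    vols[paste0("q", i)] <- v
    means[classes[i]] <- v * c(1.02, 0.98)[i]
  }
  fams <- lapply(seq_along(classes), function(i)
    make_motif_family(classes[i], 1, mutation_rate, seed = seed + i))
  aln <- c(stats::setNames(reference_sequence(), "AvNifD_ref"),
           stats::setNames(fams[[1]]$sequences[1], "q1"),
           stats::setNames(fams[[2]]$sequences[1], "q2"))
  list(
    truth = c(q1 = "NifD-A", q2 = "VnfD"),
    config = list(
      queries = c("q1", "q2"),
      cluster = list(structures = structs, ref_labels = ref_labels),
      volume = list(volumes = vols, class_means = means),
      fingerprint = list(alignment = aln)
    )
  )
}
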