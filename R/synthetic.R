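# Synthetic fixture generators. Everything downstream can be exercised
# without downloads: hollow shells with analytically known cavity volumes,
# perturbed structure copies with recorded ground-truth transforms, planted
# structure classes, motif-bearing sequence families, and a synthetic
# nitrogenase-like active site. All randomness flows from one seed per
# invocation, split per sub-generator.

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_123 <- stats::setNames(names(.aa_321), unname(.aa_321))

# split a seed into k reproducible sub-seeds (all < 2^31)
.split_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

# near-uniform points on a sphere of radius r (Fibonacci lattice)
.fibonacci_sphere <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = r * sin(phi) * cos(theta),
        y = r * sin(phi) * sin(theta),
        z = r * cos(phi))
}

.atoms_df <- function(xyz, name, element, resname, resno, chain = "A",
                      hetero = FALSE, serial_from = 1L) {
  n <- nrow(xyz)
  data.frame(
    serial = serial_from + seq_len(n) - 1L,
    name = rep_len(name, n), element = rep_len(element, n),
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = rep_len(resno, n), ins = rep_len("", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = rep_len(1, n), hetero = rep_len(hetero, n),
    stringsAsFactors = FALSE
  )
}

#' Hollow spherical shell with an analytically known cavity
#'
#' Pseudo-atoms (carbon radius) tile concentric spherical layers enclosing
#' a cavity of radius `cavity_radius`; the analytic inner volume
#' 4/3 pi r^3 is attached. Optional pseudo-cofactor atoms are placed at the
#' cavity center as a hetero group `"CFX"`.
#'
#' @param cavity_radius inner cavity radius in Angstrom (> 0).
#' @param shell_thickness radial wall thickness; must exceed twice the
#'   atom vdW radius so the wall cannot leak.
#' @param atom_spacing lattice spacing on each layer (Angstrom); must not
#'   exceed the atom vdW radius (leak risk otherwise).
#' @param seed RNG seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @param n_cofactor_atoms pseudo-cofactor atoms placed inside (default 0).
#' @return list: `structure` (a `metcof_structure`), `analytic_volume`
#'   (A^3), `cavity_radius`, `cofactor_spec` (`"CFX"` when present).
#' @export
make_cavity_shell <- function(cavity_radius, shell_thickness = 4.0,
                              atom_spacing = 1.0, seed = 1L,
                              n_cofactor_atoms = 0L) {
  vdw <- .vdw_default
  if (cavity_radius <= 0) stop("cavity_radius must be > 0")
  if (shell_thickness <= 2 * vdw)
    stop("shell_thickness must exceed twice the atom vdW radius (",
         2 * vdw, " A) to be leak-proof")
  if (atom_spacing > vdw)
    stop("atom_spacing ", atom_spacing, " A risks leaks; use <= ", vdw)
  r0 <- cavity_radius + vdw
  layer_step <- atom_spacing
  radii <- seq(r0, r0 + shell_thickness - 2 * vdw, by = layer_step)
  pts <- do.call(rbind, lapply(radii, function(r) {
    n <- max(12L, ceiling(4 * pi * r^2 / atom_spacing^2))
    .fibonacci_sphere(n, r)
  }))
  atoms <- .atoms_df(pts, name = "C", element = "C", resname = "SPH",
                     resno = seq_len(nrow(pts)))
  if (n_cofactor_atoms > 0L) {
    stopifnot(cavity_radius > 2.2)
    off <- .fibonacci_sphere(max(n_cofactor_atoms, 2L),
                             min(0.8, cavity_radius - 2.2))[seq_len(n_cofactor_atoms), , drop = FALSE]
    if (n_cofactor_atoms == 1L) off <- matrix(0, 1, 3)
    cof <- .atoms_df(off, name = "FE", element = "FE", resname = "CFX",
                     resno = 900L, hetero = TRUE,
                     serial_from = nrow(atoms) + 1L)
    atoms <- rbind(atoms, cof)
  }
  list(
    structure = .new_structure(atoms, id = sprintf("cavity_r%g", cavity_radius)),
    analytic_volume = 4 / 3 * pi * cavity_radius^3,
    cavity_radius = cavity_radius,
    cofactor_spec = if (n_cofactor_atoms > 0L) "CFX" else NULL
  )
}

# Rodrigues rotation matrix for axis (unit) and angle
.axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rigidly transform and noise a structure copy
#'
#' Applies a random rotation and translation, then i.i.d. Gaussian
#' coordinate noise; the ground-truth transform is attached.
#'
#' @param structure a `metcof_structure`.
#' @param noise_sigma per-axis Gaussian noise in Angstrom (default 0).
#' @param seed RNG seed.
#' @param max_translation translation components drawn uniformly from
#'   `[-max_translation, max_translation]` (default 10 A).
#' @return the perturbed `metcof_structure` with attributes
#'   `"true_rotation"` and `"true_translation"`.
#' @export
perturb <- function(structure, noise_sigma = 0, seed = 1L,
                    max_translation = 10) {
  stopifnot(inherits(structure, "metcof_structure"), noise_sigma >= 0)
  set.seed(as.integer(seed))
  R <- .axis_angle(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
  tr <- stats::runif(3, -max_translation, max_translation)
  out <- transform_structure(structure, R, tr)
  if (noise_sigma > 0) {
    n <- nrow(out$atoms)
    out$atoms$x <- out$atoms$x + stats::rnorm(n, 0, noise_sigma)
    out$atoms$y <- out$atoms$y + stats::rnorm(n, 0, noise_sigma)
    out$atoms$z <- out$atoms$z + stats::rnorm(n, 0, noise_sigma)
  }
  attr(out, "true_rotation") <- R
  attr(out, "true_translation") <- tr
  out
}

# smooth random CA trace (step 3.8 A) confined to a globule of
# protein-like density, with CB atoms pointing away from the local backbone
.random_backbone <- function(n_res, stiffness = 0.5) {
  r_max <- 3.2 * n_res^(1 / 3)   # ~134 A^3 per residue
  d <- c(1, 0, 0)
  ca <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    d <- d + stiffness * stats::rnorm(3)
    p <- ca[i - 1, ]
    rn <- sqrt(sum(p^2))
    if (rn > 0.7 * r_max) d <- d - 2 * (rn / r_max)^2 * p / rn
    d <- d / sqrt(sum(d^2))
    ca[i, ] <- ca[i - 1, ] + 3.8 * d
  }
  cb <- ca
  for (i in seq_len(n_res)) {
    lo <- max(1, i - 1); hi <- min(n_res, i + 1)
    v <- ca[i, ] - (ca[lo, ] + ca[hi, ]) / 2
    if (sum(v^2) < 1e-6) v <- stats::rnorm(3)
    cb[i, ] <- ca[i, ] + 1.5 * v / sqrt(sum(v^2))
  }
  list(ca = ca, cb = cb)
}

.backbone_structure <- function(bb, id) {
  n <- nrow(bb$ca)
  ca <- .atoms_df(bb$ca, name = "CA", element = "C", resname = "ALA",
                  resno = seq_len(n))
  cb <- .atoms_df(bb$cb, name = "CB", element = "C", resname = "ALA",
                  resno = seq_len(n), serial_from = n + 1L)
  at <- rbind(ca, cb)
  at <- at[order(at$resno, at$serial), , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  .new_structure(at, id = id)
}

#' Planted structure classes for clustering tests
#'
#' Each class gets its own random smooth CA/CB backbone; members are
#' rigidly transformed, noised copies.
#'
#' @param n_classes number of classes.
#' @param members_per_class members per class.
#' @param n_res residues per backbone (default 60).
#' @param noise_sigma member coordinate noise in Angstrom (default 0.3).
#' @param seed RNG seed.
#' @return list: `structures` (named list `C<k>_m<j>`), `labels` (named
#'   character vector of true class names `C<k>`).
#' @export
make_planted_classes <- function(n_classes = 2L, members_per_class = 3L,
                                 n_res = 60L, noise_sigma = 0.3, seed = 1L) {
  stopifnot(n_classes >= 1L, members_per_class >= 1L, n_res >= 10L)
  seeds <- .split_seed(seed, n_classes * (members_per_class + 1L))
  structures <- list()
  labels <- character()
  si <- 1L
  for (k in seq_len(n_classes)) {
    set.seed(seeds[si]); si <- si + 1L
    bb <- .random_backbone(n_res)
    proto <- .backbone_structure(bb, sprintf("C%d", k))
    for (j in seq_len(members_per_class)) {
      nm <- sprintf("C%d_m%d", k, j)
      s <- perturb(proto, noise_sigma = noise_sigma, seed = seeds[si])
      si <- si + 1L
      s$id <- nm
      structures[[nm]] <- s
      labels[nm] <- sprintf("C%d", k)
    }
  }
  list(structures = structures, labels = labels)
}

#' Synthetic A. vinelandii NifD-numbering reference sequence
#'
#' A deterministic 460-residue stand-in carrying the NifD-A motif rows at
#' their reference windows over a random background (synthetic: it is not
#' the deposited NifD sequence, but every motif and diagnostic position
#' sits at its true author number).
#'
#' @return character scalar of length-460 sequence.
#' @export
reference_sequence <- function() {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(1203L)
  s <- sample(.aa20, 460L, replace = TRUE)
  prof <- motif_profiles()
  prof <- prof[prof$class_label == "NifD-A", , drop = FALSE]
  for (i in seq_len(nrow(prof))) {
    p <- strsplit(prof$pattern[i], "")[[1]]
    for (j in seq_along(p)) {
      if (p[j] == "x") next
      s[prof$start[i] + j - 1L] <- toupper(p[j])
    }
  }
  s[276L] <- "Y"   # Mo-type tetrad environment of the Cys275 ligand
  paste(s, collapse = "")
}

#' Motif-bearing synthetic sequence family
#'
#' Members carry the class's motif rows at their reference windows over the
#' shared reference scaffold; variable (`x`) positions are drawn per member,
#' Mo-type members get a Tyr/Gln/His tetrad residue at 276 and
#' uncharacterized-class members an uncharged Thr/Leu/Met at 380. Point
#' mutations are applied at `mutation_rate` per position, reduced fivefold
#' at within-class-conserved (uppercase) positions.
#'
#' @param class_label one of `"NifD-A"`, `"NifD-B"`, `"Unc"`, `"AnfD"`,
#'   `"VnfD"`.
#' @param n_sequences family size.
#' @param mutation_rate per-position mutation probability in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return list: `sequences` (named), `alignment` (sequences plus the
#'   `AvNifD_ref` reference row; all rows equal length, no gaps), `labels`.
#' @export
make_motif_family <- function(class_label, n_sequences, mutation_rate = 0,
                              seed = 1L) {
  stopifnot(class_label %in% names(.motif_rows),
            mutation_rate >= 0, mutation_rate <= 0.5, n_sequences >= 1L)
  ref <- strsplit(reference_sequence(), "")[[1]]
  prof <- motif_profiles()
  prof <- prof[prof$class_label == class_label, , drop = FALSE]
  upper_pos <- integer()
  for (i in seq_len(nrow(prof))) {
    p <- strsplit(prof$pattern[i], "")[[1]]
    up <- p != "x" & p == toupper(p)
    upper_pos <- c(upper_pos, (prof$start[i]:prof$end[i])[up])
  }
  seeds <- .split_seed(seed, n_sequences)
  seqs <- character(n_sequences)
  for (m in seq_len(n_sequences)) {
    set.seed(seeds[m])
    s <- ref
    for (i in seq_len(nrow(prof))) {
      p <- strsplit(prof$pattern[i], "")[[1]]
      for (j in seq_along(p)) {
        pos <- prof$start[i] + j - 1L
        s[pos] <- if (p[j] == "x") sample(.aa20, 1L) else toupper(p[j])
      }
    }
    if (class_label %in% c("NifD-A", "NifD-B", "Unc"))
      s[276L] <- sample(c("Y", "Q", "H"), 1L)
    if (class_label == "Unc") s[380L] <- sample(c("T", "L", "M"), 1L)
    if (mutation_rate > 0) {
      rate <- rep(mutation_rate, length(s))
      rate[upper_pos] <- mutation_rate / 5
      hit <- which(stats::runif(length(s)) < rate)
      for (pos in hit) s[pos] <- sample(setdiff(.aa20, s[pos]), 1L)
    }
    seqs[m] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", class_label),
                         seq_len(n_sequences))
  alignment <- c(stats::setNames(reference_sequence(), "AvNifD_ref"), seqs)
  list(sequences = seqs, alignment = alignment,
       labels = stats::setNames(rep(class_label, n_sequences), names(seqs)))
}

#' Synthetic nitrogenase-like active site
#'
#' A geometric stand-in for a D-subunit active site (synthetic: built from
#' the motif windows and coordination chemistry, not from deposited
#' coordinates). A compact Mo/Fe/S pseudo-cluster with an adjacent
#' homocitrate-like group sits at the origin; the nine motif regions (in
#' A. vinelandii NifD author numbering) are placed around it with one
#' side-chain atom per residue inside the 5 A shell, Cys275 donating a
#' side-chain S and His442 a side-chain N at coordination distance; decoy
#' residues sit outside the shell.
#'
#' @param seed RNG seed (placement jitter).
#' @return list: `structure`, `cofactor_spec` (`c("ICS","HCA")`),
#'   `region_windows` (the nine windows), `anchors` (named anchor
#'   positions).
#' @export
make_synthetic_site <- function(seed = 1L) {
  set.seed(as.integer(seed))
  # pseudo-cluster: 1 Mo, 7 Fe, 9 S within ~2.5 A of the origin
  fe <- .fibonacci_sphere(7, 1.6)
  su <- .fibonacci_sphere(9, 2.2)
  mo <- matrix(c(0, 0, -2.0), 1, 3)
  clus <- rbind(mo, fe, su)
  cof <- .atoms_df(clus, name = c("MO", sprintf("FE%d", 1:7), sprintf("S%d", 1:9)),
                   element = c("MO", rep("FE", 7), rep("S", 9)),
                   resname = "ICS", resno = 500L, hetero = TRUE)
  hca <- .atoms_df(sweep(.fibonacci_sphere(6, 1.2), 2, c(0, 0, -4.2), "+"),
                   name = sprintf("O%d", 1:6), element = c("C", "C", "O", "O", "O", "O"),
                   resname = "HCA", resno = 501L, hetero = TRUE,
                   serial_from = nrow(cof) + 1L)

  prof <- motif_profiles()
  prof <- prof[prof$class_label == "NifD-A", , drop = FALSE]
  dirs <- .fibonacci_sphere(nrow(prof), 1)
  rows <- list()
  serial <- nrow(cof) + nrow(hca) + 1L
  for (i in seq_len(nrow(prof))) {
    u <- dirs[i, ]
    t1 <- c(-u[2], u[1], 0)
    if (sum(t1^2) < 1e-6) t1 <- c(1, 0, 0)
    t1 <- t1 / sqrt(sum(t1^2))
    positions <- prof$start[i]:prof$end[i]
    p <- strsplit(prof$pattern[i], "")[[1]]
    for (j in seq_along(positions)) {
      resno <- positions[j]
      aa1 <- if (p[j] == "x") "A" else toupper(p[j])
      resname <- unname(.aa_123[aa1])
      ca <- u * 6.2 + t1 * (j - (length(positions) + 1) / 2) * 2.0 +
        stats::rnorm(3, 0, 0.05)
      sc <- ca * (4.3 / sqrt(sum(ca^2)))
      sc_name <- "CB"; sc_el <- "C"; sc_d <- 4.3
      if (resno == 275L) { sc_name <- "SG"; sc_el <- "S"; sc_d <- NA }
      if (resno == 442L) { sc_name <- "NE2"; sc_el <- "N"; sc_d <- NA }
      if (resno == 275L) {
        # bond the thiolate S to the nearest Fe at 2.3 A
        fe1 <- clus[2, ]
        sc <- fe1 + 2.3 * (ca - fe1) / sqrt(sum((ca - fe1)^2))
      }
      if (resno == 442L) {
        sc <- mo[1, ] + 2.2 * (ca - mo[1, ]) / sqrt(sum((ca - mo[1, ])^2))
      }
      caat <- .atoms_df(matrix(ca, 1, 3), name = "CA", element = "C",
                        resname = resname, resno = resno, serial_from = serial)
      scat <- .atoms_df(matrix(sc, 1, 3), name = sc_name, element = sc_el,
                        resname = resname, resno = resno, serial_from = serial + 1L)
      serial <- serial + 2L
      rows[[length(rows) + 1L]] <- rbind(caat, scat)
    }
  }
  # decoys well outside the shell, between motif regions in sequence
  for (resno in c(150L, 310L, 410L)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    caat <- .atoms_df(matrix(u * 11, 1, 3), name = "CA", element = "C",
                      resname = "ALA", resno = resno, serial_from = serial)
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- caat
  }
  atoms <- rbind(cof, hca, do.call(rbind, rows))
  # polymer first, hetero groups after, as in a deposited entry
  atoms <- atoms[order(atoms$hetero, atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  anchors <- stats::setNames(prof$anchor_pos, prof$anchor)
  list(
    structure = .new_structure(atoms, id = "synthetic_site"),
    cofactor_spec = c("ICS", "HCA"),
    region_windows = prof[, c("anchor", "start", "end")],
    anchors = anchors
  )
}
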