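# Alignment-guided rigid-body superposition. CA atoms of residue pairs are
# superposed by the Kabsch least-squares rotation (proper rotation,
# det = +1) and the post-fit RMSD is reported.

# CA coordinates keyed by residue, in chain record order.
.ca_table <- function(structure, chain) {
  at <- structure$atoms
  at <- at[at$chain == chain & !at$hetero & at$name == "CA" &
             !(at$resname %in% .water_codes), , drop = FALSE]
  at[!duplicated(paste(at$resno, at$ins)), , drop = FALSE]
}

#' Pair residues of two chains through a sequence alignment
#'
#' Pairs are the aligned non-gap columns whose residues both carry a CA
#' atom. The aligned rows must reproduce the chains' extracted sequences
#' exactly (gaps removed).
#'
#' @param structA,structB `metcof_structure` objects.
#' @param chainA,chainB chain identifiers.
#' @param alignment named character vector of two aligned rows (gaps `-`),
#'   or `NULL` to pair by identical author residue numbering.
#' @return a `metcof_pairing`: data.frame `pairs` with CA coordinates of
#'   both members, and `source`.
#' @export
pair_by_alignment <- function(structA, chainA, structB, chainB,
                              alignment = NULL) {
  caA <- .ca_table(structA, chainA)
  caB <- .ca_table(structB, chainB)
  if (is.null(alignment)) {
    common <- intersect(caA$resno, caB$resno)
    ia <- match(common, caA$resno)
    ib <- match(common, caB$resno)
    src <- "numbering"
  } else {
    stopifnot(length(alignment) == 2L)
    sa <- extract_sequence(structA, chainA)$sequence
    sb <- extract_sequence(structB, chainB)$sequence
    ga <- gsub("-", "", alignment[[1]])
    gb <- gsub("-", "", alignment[[2]])
    chk <- function(aln_seq, struct_seq, who) {
      n <- min(nchar(aln_seq), nchar(struct_seq))
      a <- strsplit(aln_seq, "")[[1]]
      s <- strsplit(struct_seq, "")[[1]]
      bad <- which(a[seq_len(n)] != s[seq_len(n)] & a[seq_len(n)] != "X" &
                     s[seq_len(n)] != "X")
      if (length(bad) > 0L || nchar(aln_seq) != nchar(struct_seq))
        stop("alignment/sequence mismatch for ", who, " at position ",
             if (length(bad) > 0L) bad[1] else n + 1L)
    }
    chk(ga, sa, "first structure")
    chk(gb, sb, "second structure")
    A <- strsplit(alignment[[1]], "")[[1]]
    B <- strsplit(alignment[[2]], "")[[1]]
    posA <- cumsum(A != "-")
    posB <- cumsum(B != "-")
    both <- A != "-" & B != "-"
    # residue index within chain -> row of CA table (CA may be missing)
    seqA_res <- .residue_table(structA$atoms[structA$atoms$chain == chainA &
      !structA$atoms$hetero & !(structA$atoms$resname %in% .water_codes), ])
    seqB_res <- .residue_table(structB$atoms[structB$atoms$chain == chainB &
      !structB$atoms$hetero & !(structB$atoms$resname %in% .water_codes), ])
    ia <- match(paste(seqA_res$resno, seqA_res$ins)[posA[both]],
                paste(caA$resno, caA$ins))
    ib <- match(paste(seqB_res$resno, seqB_res$ins)[posB[both]],
                paste(caB$resno, caB$ins))
    ok <- !is.na(ia) & !is.na(ib)
    ia <- ia[ok]; ib <- ib[ok]
    src <- "sequence-alignment"
  }
  pairs <- data.frame(
    resnoA = caA$resno[ia], resnoB = caB$resno[ib],
    xA = caA$x[ia], yA = caA$y[ia], zA = caA$z[ia],
    xB = caB$x[ib], yB = caB$y[ib], zB = caB$z[ib]
  )
  structure(list(pairs = pairs, source = src), class = "metcof_pairing")
}

#' Kabsch superposition and RMSD of paired CA atoms
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' least-squares deviation of the second member onto the first, and reports
#' the CA RMSD after the fit.
#'
#' @param pairing a `metcof_pairing`, or a list with matrices `A` and `B`
#'   (n x 3 each).
#' @return list with `rotation` (3x3, applied to B-centered coordinates),
#'   `translation`, `rmsd` (Angstrom) and `n` pairs. Transformed B
#'   coordinates are `B %*% t(rotation)` + translation.
#' @export
kabsch_superpose <- function(pairing) {
  if (inherits(pairing, "metcof_pairing")) {
    A <- as.matrix(pairing$pairs[, c("xA", "yA", "zA")])
    B <- as.matrix(pairing$pairs[, c("xB", "yB", "zB")])
  } else {
    A <- pairing$A; B <- pairing$B
  }
  stopifnot(is.matrix(A), is.matrix(B), ncol(A) == 3, nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 residue pairs for superposition")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  # collinearity guard: rank of the centered coordinates must be >= 2
  if (sum(svd(A0)$d > 1e-8) < 2L || sum(svd(B0)$d > 1e-8) < 2L)
    stop("degenerate (collinear) coordinates: superposition is underdetermined")
  H <- crossprod(B0, A0)             # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)        # rotate B-frame into A-frame
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  translation <- cA - as.numeric(R %*% cB)
  list(rotation = R, translation = translation, rmsd = rmsd, n = n)
}

#' Apply a rigid transform to a structure
#'
#' @param structure a `metcof_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @return the transformed `metcof_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "metcof_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- new[, 1]
  structure$atoms$y <- new[, 2]
  structure$atoms$z <- new[, 3]
  structure
}
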