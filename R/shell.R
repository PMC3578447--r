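# Cofactor shell extraction: which residues sit within a distance cutoff of
# the active-site cluster, and how they group into contiguous sequence motif
# regions (the "sequence areas" of the D-subunit active site).

# Cell-list neighbor search. Atoms are binned into cubic cells of edge =
# cutoff; only the 27 cells around each query atom's cell are scanned.
# Returns, for each candidate atom, the minimum distance to any reference
# atom, or NA when no reference atom lies within the cutoff.
.min_dist_within <- function(cand_xyz, ref_xyz, cutoff) {
  n <- nrow(cand_xyz)
  out <- rep(NA_real_, n)
  if (n == 0L || nrow(ref_xyz) == 0L || cutoff <= 0) return(out)
  cell <- cutoff
  key_of <- function(m) {
    i <- floor(m[, 1] / cell); j <- floor(m[, 2] / cell); k <- floor(m[, 3] / cell)
    cbind(i, j, k)
  }
  rk <- key_of(ref_xyz)
  ref_map <- split(seq_len(nrow(ref_xyz)),
                   paste(rk[, 1], rk[, 2], rk[, 3], sep = ","))
  ck <- key_of(cand_xyz)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (a in seq_len(n)) {
    keys <- sprintf("%d,%d,%d", ck[a, 1] + off[, 1], ck[a, 2] + off[, 2],
                    ck[a, 3] + off[, 3])
    idx <- unlist(ref_map[keys], use.names = FALSE)
    if (is.null(idx) || length(idx) == 0L) next
    d2 <- (ref_xyz[idx, 1] - cand_xyz[a, 1])^2 +
          (ref_xyz[idx, 2] - cand_xyz[a, 2])^2 +
          (ref_xyz[idx, 3] - cand_xyz[a, 3])^2
    m <- min(d2)
    if (m <= cut2) out[a] <- sqrt(m)
  }
  out
}

#' Atoms within a distance cutoff of a reference atom group
#'
#' Returns every atom of the structure (excluding the reference group's own
#' atoms) whose center lies within `cutoff` of any reference atom center.
#' Uses a cell-list spatial grid; results are identical to brute force.
#'
#' @param structure a `metcof_structure`.
#' @param ref_atoms a `metcof_cofactor` (or any list with an `atoms`
#'   data.frame).
#' @param cutoff distance cutoff in Angstrom (> 0, or 0 for the empty set).
#' @return atom data.frame with an extra `dist` column (minimum distance to
#'   the reference group).
#' @export
atoms_within <- function(structure, ref_atoms, cutoff) {
  stopifnot(inherits(structure, "metcof_structure"), cutoff >= 0)
  ref <- ref_atoms$atoms
  if (is.null(ref) || nrow(ref) == 0L) stop("empty reference atom group")
  at <- structure$atoms
  cand <- at[!(at$serial %in% ref$serial), , drop = FALSE]
  if (cutoff == 0 || nrow(cand) == 0L) {
    cand$dist <- numeric(nrow(cand))
    return(cand[0, , drop = FALSE])
  }
  d <- .min_dist_within(as.matrix(cand[, c("x", "y", "z")]),
                        as.matrix(ref[, c("x", "y", "z")]), cutoff)
  keep <- !is.na(d)
  cand <- cand[keep, , drop = FALSE]
  cand$dist <- d[keep]
  cand
}

#' Residue shell around a cofactor
#'
#' A residue belongs to the shell iff any of its atoms lies within `cutoff`
#' of any cofactor atom. The cofactor's own residues and (by default) waters
#' are excluded; each shell residue carries its minimum atom distance.
#'
#' @param structure a `metcof_structure`.
#' @param cofactor a `metcof_cofactor` from [select_cofactor()].
#' @param cutoff shell radius in Angstrom (default 5).
#' @param include_waters keep water residues in the shell (default `FALSE`).
#' @return a `metcof_shell`: `cutoff`, `cofactor_label`, `residues`
#'   (data.frame with `chain`, `resno`, `ins`, `resname`, `one_letter`,
#'   `min_dist`), `regions` (unset until [group_motifs()]), plus internal
#'   references used by [coordination_ligands()].
#' @export
shell_residues <- function(structure, cofactor, cutoff = 5.0,
                           include_waters = FALSE) {
  stopifnot(cutoff > 0)
  near <- atoms_within(structure, cofactor, cutoff)
  cof_keys <- unique(.residue_key(cofactor$atoms))
  near <- near[!(.residue_key(near) %in% cof_keys), , drop = FALSE]
  if (!include_waters)
    near <- near[!(near$resname %in% .water_codes), , drop = FALSE]
  if (nrow(near) == 0L) {
    warning("empty shell at cutoff ", cutoff, " A")
    res <- data.frame(chain = character(), resno = integer(), ins = character(),
                      resname = character(), one_letter = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  } else {
    key <- .residue_key(near)
    md <- tapply(near$dist, key, min)
    first <- !duplicated(key)
    res <- data.frame(
      chain = near$chain[first], resno = near$resno[first],
      ins = near$ins[first], resname = near$resname[first],
      stringsAsFactors = FALSE
    )
    res$one_letter <- unname(.aa_321[res$resname])
    res$one_letter[is.na(res$one_letter)] <- "X"
    res$min_dist <- as.numeric(md[key[first]])
    res <- res[order(res$chain, res$resno, res$ins), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(
    list(cutoff = cutoff, cofactor_label = cofactor$label, residues = res,
         regions = NULL, structure = structure, cofactor = cofactor),
    class = "metcof_shell"
  )
}

#' Group shell residues into contiguous sequence motif regions
#'
#' Two shell residues of the same chain fall in the same region iff their
#' sequence separation is at most `gap`. Regions are ordered by sequence
#' position and labelled from `anchors` (a named integer vector, label ->
#' reference residue number) when an anchor falls inside the region,
#' otherwise `"R<start>-<end>"`.
#'
#' @param shell a `metcof_shell`.
#' @param gap maximum residue-number separation merged into one region
#'   (default 3).
#' @param anchors optional named integer vector of anchor positions.
#' @param ligand_resnos optional residue numbers whose regions are flagged as
#'   ligand (cofactor-coordinating) regions; default is computed with
#'   [coordination_ligands()].
#' @return the shell with `regions`: a data.frame with `chain`, `start`,
#'   `end`, `n_residues`, `label`, `is_ligand_region`.
#' @export
group_motifs <- function(shell, gap = 3L, anchors = NULL, ligand_resnos = NULL) {
  stopifnot(inherits(shell, "metcof_shell"), gap >= 0)
  res <- shell$residues
  if (nrow(res) == 0L) {
    shell$regions <- data.frame(chain = character(), start = integer(),
                                end = integer(), n_residues = integer(),
                                label = character(), is_ligand_region = logical())
    return(shell)
  }
  if (length(unique(res$chain)) > 1L)
    warning("shell spans multiple chains; regions are grouped per chain")
  if (is.null(ligand_resnos)) {
    lig <- tryCatch(coordination_ligands(shell), error = function(e) NULL)
    ligand_resnos <- if (is.null(lig)) integer() else lig$resno
  }
  out <- list()
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, , drop = FALSE]
    pos <- sort(unique(r$resno))
    brk <- c(0L, which(diff(pos) > gap), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      members <- pos[(brk[b] + 1L):brk[b + 1L]]
      s <- min(members); e <- max(members)
      lab <- sprintf("R%d-%d", s, e)
      if (!is.null(anchors)) {
        inside <- anchors >= s & anchors <= e
        if (any(inside)) lab <- paste(names(anchors)[inside], collapse = "+")
      }
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, start = s, end = e, n_residues = length(members),
        label = lab, is_ligand_region = any(members %in% ligand_resnos),
        stringsAsFactors = FALSE
      )
    }
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(regions$chain, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  shell$regions <- regions
  shell$residues$region <- NA_character_
  for (i in seq_len(nrow(regions))) {
    m <- shell$residues$chain == regions$chain[i] &
      shell$residues$resno >= regions$start[i] &
      shell$residues$resno <= regions$end[i]
    shell$residues$region[m] <- regions$label[i]
  }
  shell
}

# side-chain donor atoms: element S or N, excluding the backbone amide N
.is_sidechain_donor <- function(atoms) {
  atoms$element %in% c("S", "N") & !(atoms$name %in% c("N", "CA", "C", "O", "OXT"))
}

#' Cofactor-coordinating residues of a shell
#'
#' A residue counts as a coordination ligand when it carries a side-chain S
#' or N atom within `bond_cutoff` of a cluster metal (Fe, Mo or V) atom of
#' the cofactor. Backbone amide nitrogens never qualify.
#'
#' @param shell a `metcof_shell`.
#' @param bond_cutoff coordination bond cutoff in Angstrom (default 2.6,
#'   spanning Fe-S and Fe-N bond lengths).
#' @return data.frame of coordinating residues (subset of the shell table).
#' @export
coordination_ligands <- function(shell, bond_cutoff = 2.6) {
  stopifnot(inherits(shell, "metcof_shell"))
  cof <- shell$cofactor$atoms
  metals <- cof[cof$element %in% c("FE", "MO", "V"), , drop = FALSE]
  res <- shell$residues
  if (nrow(metals) == 0L || nrow(res) == 0L) return(res[0, , drop = FALSE])
  at <- shell$structure$atoms
  shell_keys <- paste(res$chain, res$resno, res$ins, sep = "\r")
  at <- at[.residue_key(at) %in% shell_keys, , drop = FALSE]
  at <- at[.is_sidechain_donor(at), , drop = FALSE]
  if (nrow(at) == 0L) return(res[0, , drop = FALSE])
  d <- .min_dist_within(as.matrix(at[, c("x", "y", "z")]),
                        as.matrix(metals[, c("x", "y", "z")]), bond_cutoff)
  hit_keys <- unique(.residue_key(at)[!is.na(d)])
  res[shell_keys %in% hit_keys, , drop = FALSE]
}

#' Write a shell report as TSV
#'
#' One row per shell residue: chain, number, insertion code, 3- and 1-letter
#' codes, minimum distance, region label.
#'
#' @param shell a `metcof_shell` (ideally after [group_motifs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shell_tsv <- function(shell, path) {
  res <- shell$residues
  if (is.null(res$region)) res$region <- NA_character_
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write shell motif regions as a BED-like table
#'
#' Regions over sequence coordinates, 1-based inclusive: chain, start, end,
#' label, member count, ligand flag.
#'
#' @param shell a `metcof_shell` after [group_motifs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(shell, path) {
  if (is.null(shell$regions)) stop("no regions: run group_motifs() first")
  utils::write.table(shell$regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
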