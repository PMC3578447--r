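# Structure and sequence I/O: the coordinate/residue data model shared by all
# downstream analyses. Atom records are kept in a single data.frame (one row
# per atom) in author numbering; residues and chains are derived views.

# van der Waals radii (Angstrom), Bondi-style with common metals added.
# Atoms whose element is not listed fall back to the carbon radius.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 2.00, MO = 2.10, V = 2.05, MN = 2.00, ZN = 1.39, CU = 1.40,
  NI = 1.63, CO = 2.00, MG = 1.73, `NA` = 2.27, K = 2.75, CA = 2.31
)
.vdw_default <- 1.70

.aa_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.water_codes <- c("HOH", "WAT", "DOD", "H2O")

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param override optional named numeric vector of radii (Angstrom) taking
#'   precedence over the bundled table.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, override = NULL) {
  el <- toupper(trimws(element))
  tab <- .vdw_table
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    tab[toupper(names(override))] <- override
  }
  r <- unname(tab[el])
  r[is.na(r)] <- .vdw_default
  r
}

# Guess the element symbol from a PDB atom name when the element column is
# absent or blank ("FE1" -> FE, "CA" in a polymer residue -> C alpha).
.element_from_name <- function(name, resname) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  known2 <- c("FE", "MO", "CL", "BR", "ZN", "MG", "MN", "NA", "SE", "NI", "CU", "CO")
  el <- substr(nm, 1, 1)
  is_poly <- toupper(resname) %in% names(.aa_321)
  take2 <- two %in% known2 & !(is_poly & two %in% c("CA", "CO", "NA"))
  el[take2] <- two[take2]
  el
}

# Construct the package structure object from an atom table. Internal; all
# readers and generators funnel through here so invariants live in one place.
.new_structure <- function(atoms, id = "structure", source_path = NA_character_) {
  need <- c("serial", "name", "element", "resname", "chain", "resno", "ins",
            "x", "y", "z", "occupancy", "hetero")
  stopifnot(all(need %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure contains no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  atoms$element <- toupper(atoms$element)
  atoms$vdw <- vdw_radius(atoms$element)
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, source_path = source_path),
    class = "metcof_structure"
  )
}

#' @export
print.metcof_structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("<metcof_structure> %s: %d atoms (%d hetero), chains: %s\n",
              x$id, nrow(at), sum(at$hetero),
              paste(unique(at$chain[!at$hetero]), collapse = ",")))
  invisible(x)
}

#' Read a PDB file into the package structure model
#'
#' Parses ATOM/HETATM records (first MODEL only) preserving author residue
#' numbering and insertion codes. Alternate locations are reduced to one
#' conformer per atom: the highest occupancy wins, ties broken by altloc
#' letter order.
#'
#' @param path path to a PDB file.
#' @param id identifier to attach; defaults to the file base name.
#' @return a `metcof_structure`.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not a parseable PDB file: ", path, " (", conditionMessage(e), ")")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)

  # altloc reduction: keep highest occupancy, ties by altloc letter order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(as.integer(at$eleno)), , drop = FALSE]

  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  blank <- is.na(el) | trimws(el) == ""
  el[blank] <- .element_from_name(at$elety[blank], at$resid[blank])

  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- " "

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = toupper(trimws(el)),
    resname = toupper(at$resid),
    chain = chain,
    resno = as.integer(at$resno),
    ins = ins,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  .new_structure(atoms, id = id, source_path = path)
}

#' Write a structure to PDB format
#'
#' @param structure a `metcof_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "metcof_structure"))
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(at$hetero, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = at$chain,
    insert = ifelse(at$ins == "", NA, at$ins),
    o = at$occupancy, b = rep(0, nrow(at)), elesy = at$element
  ))
  invisible(path)
}

# Unique residue table (one row per residue) in record order.
.residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    ins = atoms$ins[first], resname = atoms$resname[first],
    hetero = atoms$hetero[first], key = key[first],
    stringsAsFactors = FALSE
  )
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")

#' Select a cofactor atom group from a structure
#'
#' The selection names hetero residues by residue name (e.g. `"ICS"`,
#' `"HCA"`) and/or by `"chain:resno"` pairs (e.g. `"A:491"`). All matching
#' atoms are returned as one named group.
#'
#' @param structure a `metcof_structure`.
#' @param spec character vector of residue names and/or `"chain:resno"`.
#' @param label group label; defaults to the spec pasted together.
#' @param include_polymer set `TRUE` to allow the selection to take polymer
#'   (non-HETATM) atoms without a warning.
#' @return a `metcof_cofactor` list: `label`, `atoms` (data.frame),
#'   `selection_spec`.
#' @export
select_cofactor <- function(structure, spec, label = NULL, include_polymer = FALSE) {
  stopifnot(inherits(structure, "metcof_structure"), length(spec) >= 1)
  at <- structure$atoms
  hit <- rep(FALSE, nrow(at))
  pairs <- grepl(":", spec, fixed = TRUE)
  for (s in spec[!pairs]) hit <- hit | at$resname == toupper(s)
  for (s in spec[pairs]) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    hit <- hit | (at$chain == f[1] & at$resno == as.integer(f[2]))
  }
  if (!any(hit)) stop("cofactor not found: no atoms match selection ",
                      paste(spec, collapse = ", "))
  if (any(!at$hetero[hit]) && !include_polymer) {
    warning("cofactor selection matches polymer atoms; they are excluded ",
            "(use include_polymer = TRUE to keep them)")
    hit <- hit & at$hetero
    if (!any(hit)) stop("cofactor not found after excluding polymer atoms")
  }
  if (is.null(label)) label <- paste(spec, collapse = "+")
  structure(
    list(label = label, atoms = at[hit, , drop = FALSE],
         selection_spec = spec),
    class = "metcof_cofactor"
  )
}

#' Extract the one-letter sequence of a chain with author numbering
#'
#' Non-standard residues (including MSE) map to `"X"`. Hetero groups and
#' waters are skipped.
#'
#' @param structure a `metcof_structure`.
#' @param chain chain identifier.
#' @return list with `sequence` (string), `numbers` (integer vector of author
#'   residue numbers) and `ins` (insertion codes).
#' @export
extract_sequence <- function(structure, chain) {
  stopifnot(inherits(structure, "metcof_structure"))
  at <- structure$atoms
  at <- at[at$chain == chain & !at$hetero & !(at$resname %in% .water_codes), , drop = FALSE]
  if (nrow(at) == 0L) stop("no polymer residues in chain '", chain, "'")
  res <- .residue_table(at)
  one <- unname(.aa_321[res$resname])
  one[is.na(one)] <- "X"
  list(sequence = paste(one, collapse = ""), numbers = res$resno, ins = res$ins)
}

# Deduplicate sequence identifiers by appending _2, _3, ... to repeats.
.dedup_ids <- function(ids) {
  out <- ids
  dup <- duplicated(ids)
  if (any(dup)) {
    for (nm in unique(ids[dup])) {
      idx <- which(ids == nm)
      out[idx[-1]] <- paste0(nm, "_", seq_along(idx[-1]) + 1L)
    }
  }
  out
}

#' Read sequences from FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences (gaps preserved);
#'   duplicate identifiers are suffixed `_2`, `_3`, ...
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequences in ", path)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], ""))
  names(seqs) <- .dedup_ids(vapply(recs, function(r) attr(r, "name"), ""))
  seqs
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' Gap characters are preserved. All rows must have equal length.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"clustal"`; default sniffs the first line.
#' @return named character vector of aligned uppercase sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    aln <- read_fasta(path)
  } else {
    # single-pass Clustal block parser (handles one-block alignments,
    # conservation lines and trailing column counts)
    lines <- readLines(path)
    if (!grepl("^CLUSTAL", lines[1]))
      stop("not a Clustal alignment: ", path)
    lines <- lines[-1]
    lines <- lines[nchar(trimws(lines)) > 0 & !grepl("^\\s", lines)]
    ids <- character()
    parts <- list()
    for (ln in lines) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) < 2L || !grepl("^[A-Za-z.~-]+$", tok[2])) next
      id <- tok[1]
      if (!(id %in% ids)) { ids <- c(ids, id); parts[[id]] <- character() }
      parts[[id]] <- c(parts[[id]], tok[2])
    }
    if (length(ids) == 0L) stop("no sequences in Clustal file: ", path)
    aln <- toupper(vapply(parts[ids], paste, "", collapse = ""))
    names(aln) <- .dedup_ids(ids)
  }
  len <- nchar(aln)
  if (length(unique(len)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(len), collapse = ", "))
  aln
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      as.string = TRUE)
  invisible(path)
}
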