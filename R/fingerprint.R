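# Motif fingerprint classification of nitrogenase D-subunit sequences.
# Nine conserved sequence areas surround the active-site cluster; each
# nitrogenase class (NifD-A, NifD-B, uncharacterized, VnfD, AnfD) shows a
# distinct conservation pattern over them. Windows are expressed in
# A. vinelandii NifD author numbering. Pattern case encodes conservation:
# uppercase = conserved within the class, lowercase = strongly-similar
# group (Gonnet PAM250 strong groups, as in clustal-family tools),
# 'x' = variable.

# Strong-similarity amino-acid groups (Gonnet PAM250 score > 0.5).
.strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                    "MILV", "MILF", "HY", "FYW")

.class_cofactor <- c(
  "NifD-A" = "FeMo-co", "NifD-B" = "FeMo-co", "Unc" = "FeMo-co",
  "VnfD" = "FeV-co", "AnfD" = "FeFe-co"
)

# Per-class motif patterns. anchor_idx is the 1-based position of the
# anchor residue inside the pattern; window start = anchor - anchor_idx + 1.
.motif_rows <- list(
  "NifD-A" = list(
    G66  = list(pattern = "CxyAGskGVVwG", anchor = 66L,  anchor_idx = 5L),
    R96  = list(pattern = "SxxxRRN",      anchor = 96L,  anchor_idx = 5L),
    Q191 = list(pattern = "GvxQSLGHHla",  anchor = 191L, anchor_idx = 4L),
    N230 = list(pattern = "dyNIGGd",      anchor = 230L, anchor_idx = 3L),
    G356 = list(pattern = "vGGLRxRH",     anchor = 356L, anchor_idx = 2L),
    H383 = list(pattern = "GYEFxH",       anchor = 383L, anchor_idx = 6L),
    G424 = list(pattern = "sGiKEKf",      anchor = 424L, anchor_idx = 2L),
    C275 = list(pattern = "CxRS",         anchor = 275L, anchor_idx = 1L),
    H442 = list(pattern = "H",            anchor = 442L, anchor_idx = 1L)
  ),
  "Unc" = list(
    G66  = list(pattern = "CtyAGxxGVvxG", anchor = 66L,  anchor_idx = 5L),
    R96  = list(pattern = "R",            anchor = 96L,  anchor_idx = 1L),
    Q191 = list(pattern = "GxsQSxGHh",    anchor = 191L, anchor_idx = 4L),
    N230 = list(pattern = "iGdYNixxD",    anchor = 230L, anchor_idx = 5L),
    G356 = list(pattern = "ixxGxPrxWH",   anchor = 356L, anchor_idx = 4L),
    H383 = list(pattern = "FxH",          anchor = 383L, anchor_idx = 3L),
    G424 = list(pattern = "ixGxKEkfl",    anchor = 424L, anchor_idx = 3L),
    C275 = list(pattern = "CxRS",         anchor = 275L, anchor_idx = 1L),
    H442 = list(pattern = "H",            anchor = 442L, anchor_idx = 1L)
  ),
  "NifD-B" = list(
    G66  = list(pattern = "CxyAGxkGVv",   anchor = 66L,  anchor_idx = 5L),
    R96  = list(pattern = "sWxxRRn",      anchor = 96L,  anchor_idx = 5L),
    Q191 = list(pattern = "GVtQSxGHHiA",  anchor = 191L, anchor_idx = 4L),
    N230 = list(pattern = "lGEYNIGGD",    anchor = 230L, anchor_idx = 5L),
    G356 = list(pattern = "tGGSRxHxY",    anchor = 356L, anchor_idx = 2L),
    H383 = list(pattern = "GyeFxHR",      anchor = 383L, anchor_idx = 6L),
    G424 = list(pattern = "tGikxky",      anchor = 424L, anchor_idx = 2L),
    C275 = list(pattern = "CxRS",         anchor = 275L, anchor_idx = 1L),
    H442 = list(pattern = "H",            anchor = 442L, anchor_idx = 1L)
  ),
  "AnfD" = list(
    G66  = list(pattern = "CAyCGAKHVIG",  anchor = 66L,  anchor_idx = 5L),
    R96  = list(pattern = "TWqTKRYI",     anchor = 96L,  anchor_idx = 5L),
    Q191 = list(pattern = "GPSQSGGHHKI",  anchor = 191L, anchor_idx = 4L),
    N230 = list(pattern = "vGeYNIQGD",    anchor = 230L, anchor_idx = 5L),
    G356 = list(pattern = "lWxGGSKLWHW",  anchor = 356L, anchor_idx = 4L),
    H383 = list(pattern = "vYtKFGHQ",     anchor = 383L, anchor_idx = 7L),
    G424 = list(pattern = "ifTGxRPGE",    anchor = 424L, anchor_idx = 4L),
    C275 = list(pattern = "CARS",         anchor = 275L, anchor_idx = 1L),
    H442 = list(pattern = "H",            anchor = 442L, anchor_idx = 1L)
  ),
  "VnfD" = list(
    G66  = list(pattern = "CafCGaKLVIGG", anchor = 66L,  anchor_idx = 5L),
    R96  = list(pattern = "TWHTKRYP",     anchor = 96L,  anchor_idx = 5L),
    Q191 = list(pattern = "GVSQSKGHHxl",  anchor = 191L, anchor_idx = 4L),
    N230 = list(pattern = "IGDfNIQGD",    anchor = 230L, anchor_idx = 5L),
    G356 = list(pattern = "IWTGGPRLWHW",  anchor = 356L, anchor_idx = 4L),
    H383 = list(pattern = "MSSKFGHq",     anchor = 383L, anchor_idx = 7L),
    G424 = list(pattern = "ifTGPRVGxL",   anchor = 424L, anchor_idx = 4L),
    C275 = list(pattern = "CARS",         anchor = 275L, anchor_idx = 1L),
    H442 = list(pattern = "H",            anchor = 442L, anchor_idx = 1L)
  )
)

# Single-organism exceptions at motif positions, encoded as permitted
# alternative residues (scored as a match, never as a penalty).
.motif_alternatives <- list(
  list(class = "NifD-A", anchor = "G66",  refpos = 62L,  alt = "G"),
  list(class = "NifD-A", anchor = "R96",  refpos = 92L,  alt = "R"),
  list(class = "NifD-A", anchor = "R96",  refpos = 97L,  alt = "C"),
  list(class = "NifD-A", anchor = "G356", refpos = 356L, alt = "A"),
  list(class = "Unc",    anchor = "G356", refpos = 356L, alt = "S"),
  list(class = "Unc",    anchor = "H383", refpos = 383L, alt = "R"),
  list(class = "AnfD",   anchor = "G66",  refpos = 66L,  alt = "V")
)

# Diagnostic residue rules near the active site: position (reference
# numbering) -> residue set -> classes voted for.
.diagnostic_rules <- list(
  list(position = 65L,  map = list("A" = c("NifD-A", "NifD-B", "Unc"),
                                   "C" = c("AnfD", "VnfD"))),
  list(position = 69L,  map = list("G" = c("NifD-A", "NifD-B", "Unc"),
                                   "H" = "AnfD", "L" = "VnfD")),
  list(position = 96L,  map = list("R" = c("NifD-A", "NifD-B", "Unc"),
                                   "K" = c("AnfD", "VnfD"))),
  list(position = 276L, map = list("Y" = c("NifD-A", "NifD-B", "Unc"),
                                   "Q" = c("NifD-A", "NifD-B", "Unc"),
                                   "H" = c("NifD-A", "NifD-B", "Unc"),
                                   "A" = c("AnfD", "VnfD"))),
  list(position = 380L, map = list("E" = c("NifD-A", "NifD-B"),
                                   "Q" = c("NifD-A", "NifD-B"),
                                   "T" = "Unc", "L" = "Unc", "M" = "Unc",
                                   "K" = c("AnfD", "VnfD"),
                                   "R" = c("AnfD", "VnfD"))),
  list(position = 428L, map = list("K" = c("NifD-A", "NifD-B", "Unc"),
                                   "R" = c("NifD-A", "NifD-B", "Unc"),
                                   "G" = c("AnfD", "VnfD")))
)

#' Bundled motif profiles
#'
#' The per-class active-site motif patterns with their windows in
#' A. vinelandii NifD reference numbering.
#'
#' @return data.frame with `class_label`, `anchor`, `pattern`, `start`,
#'   `end`, `anchor_pos`.
#' @export
motif_profiles <- function() {
  rows <- list()
  for (cl in names(.motif_rows)) for (an in names(.motif_rows[[cl]])) {
    m <- .motif_rows[[cl]][[an]]
    st <- m$anchor - m$anchor_idx + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      class_label = cl, anchor = an, pattern = m$pattern,
      start = st, end = st + nchar(m$pattern) - 1L, anchor_pos = m$anchor,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Bundled diagnostic residue rules
#'
#' @return the list of diagnostic rules (position, residue -> class votes).
#' @export
diagnostic_rules <- function() .diagnostic_rules

#' Map alignment columns to reference author numbers
#'
#' @param alignment named character vector of aligned rows.
#' @param reference_id name of the reference row (A. vinelandii NifD
#'   numbering carrier).
#' @param ref_numbers author numbers of the reference's ungapped residues;
#'   default `1:n`.
#' @return a `metcof_refmap`: `col_to_ref` (per column, the reference
#'   number or NA at reference gaps) and `ref_to_col` (named lookup).
#' @export
map_to_reference <- function(alignment, reference_id, ref_numbers = NULL) {
  if (!(reference_id %in% names(alignment)))
    stop("reference '", reference_id, "' not found in alignment")
  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  nres <- sum(ref != "-")
  if (is.null(ref_numbers)) ref_numbers <- seq_len(nres)
  stopifnot(length(ref_numbers) == nres)
  col_to_ref <- rep(NA_integer_, length(ref))
  col_to_ref[ref != "-"] <- ref_numbers
  ref_to_col <- seq_along(ref)[ref != "-"]
  names(ref_to_col) <- as.character(ref_numbers)
  structure(list(col_to_ref = col_to_ref, ref_to_col = ref_to_col,
                 reference_id = reference_id),
            class = "metcof_refmap")
}

# query residue characters at the given reference positions ('-' when the
# query is gapped there or the position is beyond the reference)
.residues_at <- function(query_chars, refmap, refpos) {
  cols <- refmap$ref_to_col[as.character(refpos)]
  out <- rep("-", length(refpos))
  ok <- !is.na(cols)
  out[ok] <- query_chars[cols[ok]]
  out
}

#' Extract per-anchor motif windows of a query
#'
#' @param query aligned query string (same alignment as the map).
#' @param refmap a `metcof_refmap` from [map_to_reference()].
#' @param profiles motif profile table (default [motif_profiles()]).
#' @return the profile table with extra columns `window` (query substring
#'   over the reference window, gaps as `-`) and `missing` (window fully
#'   gapped).
#' @export
extract_windows <- function(query, refmap, profiles = motif_profiles()) {
  qc <- strsplit(toupper(query), "")[[1]]
  profiles$window <- vapply(seq_len(nrow(profiles)), function(i) {
    paste(.residues_at(qc, refmap, profiles$start[i]:profiles$end[i]),
          collapse = "")
  }, "")
  profiles$missing <- !grepl("[A-Z]", profiles$window)
  profiles
}

.in_strong_group <- function(a, b) {
  if (a == b) return(TRUE)
  any(vapply(.strong_groups, function(g)
    grepl(a, g, fixed = TRUE) && grepl(b, g, fixed = TRUE), TRUE))
}

#' Score a motif window against a class pattern
#'
#' Per position: uppercase pattern residue scores +2 on exact match and -2
#' otherwise; lowercase scores +1 when the query residue falls in the same
#' Gonnet PAM250 strong-similarity group (or matches exactly) and -1
#' otherwise; `x` contributes 0. Gaps score as mismatches. Permitted
#' alternative residues (single-organism exceptions) score as matches.
#'
#' @param window query window string.
#' @param pattern pattern string of equal length.
#' @param alternatives optional per-position list of permitted alternative
#'   residues (names are positions within the window as characters).
#' @return numeric score.
#' @export
score_pattern <- function(window, pattern, alternatives = NULL) {
  if (nchar(window) != nchar(pattern))
    stop("window/pattern length mismatch: ", nchar(window), " vs ",
         nchar(pattern))
  w <- strsplit(toupper(window), "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  s <- 0
  for (i in seq_along(p)) {
    pc <- p[i]
    if (pc == "x") next
    qc <- w[i]
    upper <- pc == toupper(pc)
    alt <- if (!is.null(alternatives)) alternatives[[as.character(i)]] else NULL
    if (qc == "-") {
      s <- s + if (upper) -2 else -1
    } else if (!is.null(alt) && qc %in% alt) {
      s <- s + if (upper) 2 else 1
    } else if (upper) {
      s <- s + if (qc == pc) 2 else -2
    } else {
      s <- s + if (.in_strong_group(qc, toupper(pc))) 1 else -1
    }
  }
  s
}

# alternatives for one (class, anchor), keyed by position within window
.window_alternatives <- function(class_label, anchor, start) {
  out <- list()
  for (a in .motif_alternatives) {
    if (a$class == class_label && a$anchor == anchor)
      out[[as.character(a$refpos - start + 1L)]] <-
        c(out[[as.character(a$refpos - start + 1L)]], a$alt)
  }
  if (length(out) == 0L) NULL else out
}

#' Classify a D-subunit sequence by its active-site motif fingerprint
#'
#' Scores the query's nine motif windows against every class row, adds
#' weighted diagnostic-position votes, and predicts the class with the
#' highest total; the class determines the inferred cofactor (NifD-A,
#' NifD-B and uncharacterized imply FeMo-co; VnfD FeV-co; AnfD FeFe-co).
#' Sequences lacking both cluster ligand positions (no Cys at 275 and no
#' His at 442) are flagged Nif-like and left unclassified.
#'
#' @param query_id name of the query row in the alignment.
#' @param alignment named character vector of aligned rows including the
#'   reference.
#' @param reference_id name of the A. vinelandii NifD-numbering reference
#'   row (default `"AvNifD_ref"`).
#' @param ref_numbers author numbers of the reference residues (default
#'   `1:n`).
#' @param profiles motif profile table (default [motif_profiles()]).
#' @param rules diagnostic rules (default [diagnostic_rules()]).
#' @param rule_weight vote weight per diagnostic rule (default 3).
#' @return a `metcof_prediction`: `query`, `scores` (motif score per
#'   class), `votes`, `total`, `predicted_class`, `predicted_cofactor`,
#'   `confidence` (margin between top two totals), `flags`, `windows`,
#'   `diagnostics`.
#' @export
classify <- function(query_id, alignment, reference_id = "AvNifD_ref",
                     ref_numbers = NULL, profiles = motif_profiles(),
                     rules = diagnostic_rules(), rule_weight = 3) {
  if (!(query_id %in% names(alignment)))
    stop("query '", query_id, "' not found in alignment")
  refmap <- map_to_reference(alignment, reference_id, ref_numbers)
  qc <- strsplit(toupper(alignment[[query_id]]), "")[[1]]
  win <- extract_windows(alignment[[query_id]], refmap, profiles)
  classes <- unique(profiles$class_label)

  scores <- stats::setNames(numeric(length(classes)), classes)
  win$score <- NA_real_
  for (i in seq_len(nrow(win))) {
    alt <- .window_alternatives(win$class_label[i], win$anchor[i], win$start[i])
    win$score[i] <- score_pattern(win$window[i], win$pattern[i], alt)
    scores[win$class_label[i]] <- scores[win$class_label[i]] + win$score[i]
  }

  votes <- stats::setNames(numeric(length(classes)), classes)
  diag_rows <- list()
  for (r in rules) {
    res <- .residues_at(qc, refmap, r$position)
    voted <- if (res %in% names(r$map)) r$map[[res]] else character()
    votes[voted] <- votes[voted] + rule_weight
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      position = r$position, residue = res,
      votes_for = paste(voted, collapse = ","), stringsAsFactors = FALSE
    )
  }
  diagnostics <- do.call(rbind, diag_rows)

  total <- scores + votes
  flags <- character()
  has_c275 <- .residues_at(qc, refmap, 275L) == "C"
  has_h442 <- .residues_at(qc, refmap, 442L) == "H"
  ord <- order(-total, names(total))
  predicted <- names(total)[ord[1]]
  confidence <- unname(total[ord[1]] - total[ord[2]])
  cofactor <- unname(.class_cofactor[predicted])
  if (!has_c275 && !has_h442) {
    flags <- c(flags, "Nif-like, unclassifiable: lacks both cluster ligand positions (Cys275, His442)")
    predicted <- NA_character_
    cofactor <- NA_character_
  } else if (!has_c275 || !has_h442) {
    flags <- c(flags, "one cluster ligand position missing")
  }
  structure(
    list(query = query_id, scores = scores, votes = votes, total = total,
         predicted_class = predicted, predicted_cofactor = cofactor,
         confidence = confidence, flags = flags, windows = win,
         diagnostics = diagnostics),
    class = "metcof_prediction"
  )
}

#' @export
print.metcof_prediction <- function(x, ...) {
  cat(sprintf("<metcof_prediction> %s -> %s (%s), margin %.1f\n", x$query,
              if (is.na(x$predicted_class)) "unclassified" else x$predicted_class,
              if (is.na(x$predicted_cofactor)) "-" else x$predicted_cofactor,
              x$confidence))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Detect C-terminal overhangs and internal insertions relative to a reference
#'
#' @param alignment named character vector of aligned rows.
#' @param reference_id name of the reference row.
#' @return named list per non-reference sequence:
#'   `c_terminal_overhang` (residue count aligned beyond the reference's
#'   last residue) and `internal_insertions` (data.frame `ref_position`,
#'   `length`: runs of reference-gap columns holding query residues,
#'   reported at the flanking reference position).
#' @export
detect_extensions <- function(alignment, reference_id) {
  if (!(reference_id %in% names(alignment)))
    stop("reference '", reference_id, "' not found in alignment")
  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  ref_cols <- which(ref != "-")
  last_ref <- max(ref_cols)
  refnum <- cumsum(ref != "-")
  out <- list()
  for (id in setdiff(names(alignment), reference_id)) {
    q <- strsplit(alignment[[id]], "")[[1]]
    overhang <- sum(q[seq_along(q) > last_ref] != "-")
    gap_run <- ref == "-" & seq_along(ref) <= last_ref
    runs <- rle(gap_run)
    ins <- list()
    pos <- 0L
    for (k in seq_along(runs$lengths)) {
      cols <- pos + seq_len(runs$lengths[k])
      pos <- pos + runs$lengths[k]
      if (!runs$values[k]) next
      len <- sum(q[cols] != "-")
      if (len > 0L)
        ins[[length(ins) + 1L]] <- data.frame(
          ref_position = refnum[cols[1]], length = len)
    }
    out[[id]] <- list(
      c_terminal_overhang = overhang,
      internal_insertions = if (length(ins)) do.call(rbind, ins)
      else data.frame(ref_position = integer(), length = integer())
    )
  }
  out
}

#' Check a sequence for the conserved NifD C-x-R-S pattern
#'
#' @param sequence amino-acid sequence (gaps ignored).
#' @return `TRUE` iff Cys-any-Arg-Ser occurs.
#' @export
phi_pattern_check <- function(sequence) {
  s <- gsub("[^A-Za-z]", "", toupper(sequence))
  grepl("C.RS", s)
}

#' Write a fingerprint report as TSV
#'
#' @param prediction a `metcof_prediction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(prediction, path) {
  win <- prediction$windows
  utils::write.table(win[, c("class_label", "anchor", "start", "end",
                             "pattern", "window", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
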