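# Contact-set structural similarity and complete-linkage clustering.
# Residue contact sets (a distance-contact surrogate for Voronoi contacts)
# are compared across aligned structure pairs by a Jaccard sum; the
# similarity is standardized into a distance matrix and agglomerated with
# the complete-link (furthest neighbor) method; trees render as Newick.

#' Residue contact map of a chain
#'
#' Two residues are in contact when their side-chain reference atoms (CB,
#' falling back to CA for glycine or missing CB) lie within `cutoff` and
#' their sequence separation exceeds `min_sep`.
#'
#' @param structure a `metcof_structure`.
#' @param chain chain identifier; default is the first polymer chain.
#' @param cutoff contact distance in Angstrom (default 8).
#' @param min_sep minimum sequence separation |i - j| strictly exceeded by
#'   contacts (default 2).
#' @return a `metcof_contactmap`: `contacts` (list of integer index sets per
#'   residue), `resno`, `cutoff`, `min_sep`.
#' @export
contact_map <- function(structure, chain = NULL, cutoff = 8.0, min_sep = 2L) {
  stopifnot(inherits(structure, "metcof_structure"), cutoff > 0)
  at <- structure$atoms
  at <- at[!at$hetero & !(at$resname %in% .water_codes), , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no polymer residues in chain '", chain, "'")
  res <- .residue_table(at)
  key <- .residue_key(at)
  pick <- function(i) {
    rows <- at[key == res$key[i], , drop = FALSE]
    cb <- rows[rows$name == "CB", , drop = FALSE]
    if (nrow(cb) == 0L) cb <- rows[rows$name == "CA", , drop = FALSE]
    if (nrow(cb) == 0L) cb <- rows[1, , drop = FALSE]
    as.numeric(cb[1, c("x", "y", "z")])
  }
  xyz <- t(vapply(seq_len(nrow(res)), pick, numeric(3)))
  dm <- as.matrix(stats::dist(xyz))
  n <- nrow(res)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  adj <- dm <= cutoff & sep > min_sep
  contacts <- lapply(seq_len(n), function(i) which(adj[i, ]))
  structure(
    list(contacts = contacts, resno = res$resno, cutoff = cutoff,
         min_sep = as.integer(min_sep)),
    class = "metcof_contactmap"
  )
}

# Resolve a pairing argument into a 2-column index matrix (A index, B index).
.pairing_index <- function(pairing, mapA, mapB) {
  if (is.null(pairing)) {
    common <- intersect(mapA$resno, mapB$resno)
    return(cbind(match(common, mapA$resno), match(common, mapB$resno)))
  }
  if (inherits(pairing, "metcof_pairing")) {
    ia <- match(pairing$pairs$resnoA, mapA$resno)
    ib <- match(pairing$pairs$resnoB, mapB$resno)
    ok <- !is.na(ia) & !is.na(ib)
    return(cbind(ia[ok], ib[ok]))
  }
  as.matrix(pairing)
}

#' Contact-set similarity score between two aligned structures
#'
#' For every aligned residue pair (i in A, j in B) the contact set of i is
#' mapped through the pairing into B numbering and compared with the
#' contact set of j by the Jaccard index; the score is the sum over aligned
#' pairs. A structure against itself under the identity pairing scores the
#' number of residues with at least one contact.
#'
#' @param mapA,mapB `metcof_contactmap` objects.
#' @param pairing a `metcof_pairing`, a 2-column index matrix, or `NULL` to
#'   pair residues with equal numbers.
#' @return numeric similarity score.
#' @export
vscore <- function(mapA, mapB, pairing = NULL) {
  idx <- .pairing_index(pairing, mapA, mapB)
  if (nrow(idx) == 0L) {
    warning("empty pairing: similarity 0")
    return(0)
  }
  a2b <- rep(NA_integer_, length(mapA$contacts))
  a2b[idx[, 1]] <- idx[, 2]
  s <- 0
  for (r in seq_len(nrow(idx))) {
    ca <- a2b[mapA$contacts[[idx[r, 1]]]]
    ca <- ca[!is.na(ca)]
    cb <- mapB$contacts[[idx[r, 2]]]
    u <- length(union(ca, cb))
    if (u > 0L) s <- s + length(intersect(ca, cb)) / u
  }
  s
}

#' Standardized contact-similarity distance matrix
#'
#' Computes all pairwise contact-set similarities and standardizes them by
#' the geometric mean of the self-scores:
#' `D(a, b) = 1 - S(a, b) / sqrt(S(a, a) * S(b, b))`, with a zero diagonal.
#'
#' @param structures named list of `metcof_structure` objects.
#' @param chains optional named/parallel vector of chain ids (default: first
#'   chain of each structure).
#' @param alignment optional named alignment (rows matching structure names)
#'   used to pair residues; default pairs by author numbering.
#' @param cutoff,min_sep passed to [contact_map()].
#' @return a `metcof_simmat`: `labels`, `S` (similarity), `D` (distance).
#' @export
distance_matrix <- function(structures, chains = NULL, alignment = NULL,
                            cutoff = 8.0, min_sep = 2L) {
  n <- length(structures)
  stopifnot(n >= 2L, !is.null(names(structures)))
  labels <- names(structures)
  if (is.null(chains)) chains <- rep(list(NULL), n)
  maps <- lapply(seq_len(n), function(i)
    contact_map(structures[[i]], chains[[i]], cutoff = cutoff, min_sep = min_sep))
  pairing_of <- function(i, j) {
    if (is.null(alignment)) return(NULL)
    rows <- alignment[c(labels[i], labels[j])]
    A <- strsplit(rows[[1]], "")[[1]]
    B <- strsplit(rows[[2]], "")[[1]]
    both <- A != "-" & B != "-"
    cbind(cumsum(A != "-")[both], cumsum(B != "-")[both])
  }
  S <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) S[i, i] <- vscore(maps[[i]], maps[[i]])
  if (any(diag(S) == 0))
    stop("self-similarity is zero for: ",
         paste(labels[diag(S) == 0], collapse = ", "))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- vscore(maps[[i]], maps[[j]], pairing_of(i, j))
    S[i, j] <- S[j, i] <- s
  }
  D <- 1 - S / sqrt(outer(diag(S), diag(S)))
  D[D < 0] <- 0
  diag(D) <- 0
  structure(list(labels = labels, S = S, D = D), class = "metcof_simmat")
}

#' Complete-linkage (furthest neighbor) hierarchical clustering
#'
#' Agglomerates a distance matrix with the complete-link rule: the distance
#' between clusters is the maximum pairwise member distance. Ties at the
#' minimal distance are broken deterministically by merging the
#' lexicographically smallest pair of cluster representative labels.
#'
#' @param D a `metcof_simmat`, or a symmetric distance matrix with zero
#'   diagonal (dimnames used as labels).
#' @return a `metcof_dendrogram`: `merge` (hclust convention), `height`,
#'   `labels`.
#' @export
complete_linkage <- function(D) {
  if (inherits(D, "metcof_simmat")) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2L)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: id (negative leaf / positive merge row), rep label,
  # member indices
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  reps <- labels
  cd <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (a in seq_along(act)) for (b in seq_along(act)) {
      if (b <= a) next
      i <- act[a]; j <- act[b]
      dij <- cd[i, j]
      key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
      if (dij < bestd - 1e-12 ||
          (abs(dij - bestd) <= 1e-12 && !is.null(bestkey) && key < bestkey)) {
        bestd <- dij; best <- c(i, j); bestkey <- key
      }
    }
    i <- best[1]; j <- best[2]
    # order merge children by representative label for a stable rendering
    if (reps[j] < reps[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- bestd
    # complete-link update: max of the two distances
    new_members <- c(members[[i]], members[[j]])
    for (k in which(active)) {
      if (k == i || k == j) next
      cd[i, k] <- cd[k, i] <- max(cd[i, k], cd[j, k])
    }
    members[[i]] <- new_members
    ids[i] <- step
    reps[i] <- min(reps[i], reps[j])
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "metcof_dendrogram")
}

#' Convert a dendrogram to a stats hclust object
#'
#' @param dend a `metcof_dendrogram`.
#' @return an object of class `hclust` (usable with [stats::cutree()],
#'   `plot()`, ...).
#' @export
as_hclust <- function(dend) {
  stopifnot(inherits(dend, "metcof_dendrogram"))
  order_leaves <- function(node) {
    if (node < 0L) return(-node)
    c(order_leaves(dend$merge[node, 1]), order_leaves(dend$merge[node, 2]))
  }
  structure(
    list(merge = dend$merge, height = dend$height,
         order = order_leaves(nrow(dend$merge)), labels = dend$labels,
         method = "complete", call = match.call(),
         dist.method = "standardized-contact"),
    class = "hclust"
  )
}

#' Cut a dendrogram into groups at a height
#'
#' @param dend a `metcof_dendrogram`.
#' @param h cut height; default is half the root height.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dend, h = NULL) {
  if (is.null(h)) h <- max(dend$height) / 2
  stats::cutree(as_hclust(dend), h = h)
}

.escape_newick <- function(x) {
  bad <- grepl("[ ,;:()\\[\\]']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Render a dendrogram as a Newick string
#'
#' Branch lengths follow the ultrametric reading of merge heights: a leaf
#' under a node of height h sits at depth h/2, so two leaves merging at
#' height 1 render as `"(A:0.5,B:0.5);"`.
#'
#' @param dend a `metcof_dendrogram`.
#' @return Newick string (with trailing `;`).
#' @export
to_newick <- function(dend) {
  stopifnot(inherits(dend, "metcof_dendrogram"))
  labs <- .escape_newick(dend$labels)
  node_h <- function(node) if (node < 0L) 0 else dend$height[node]
  render <- function(node) {
    if (node < 0L) return(labs[-node])
    h <- dend$height[node]
    kids <- dend$merge[node, ]
    parts <- vapply(kids, function(k)
      sprintf("%s:%.10g", render(k), (h - node_h(k)) / 2), "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(render(nrow(dend$merge)), ";")
}

#' Write a Newick file
#'
#' @param dend a `metcof_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  writeLines(to_newick(dend), path)
  invisible(path)
}

#' Write a distance matrix as TSV (labels in header row and first column)
#'
#' @param simmat a `metcof_simmat`.
#' @param path output path.
#' @param which `"D"` (default) or `"S"`.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(simmat, path, which = c("D", "S")) {
  which <- match.arg(which)
  m <- simmat[[which]]
  utils::write.table(cbind(label = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
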