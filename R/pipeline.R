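# Pipeline: combine the three evidence lines (structure clustering, pocket
# volume, motif fingerprint) into one per-query report. Evidence is
# combined by majority vote over the lines that could run; ties are
# reported as "ambiguous", never silently resolved.

#' Assign a class by nearest mean pocket volume
#'
#' @param volume query pocket volume (A^3) or a `metcof_pocket`.
#' @param class_means named numeric vector of class mean volumes.
#' @return list: `class` (NA on a tie), `margin` (distance to runner-up
#'   minus distance to winner), `tie`.
#' @export
volume_class <- function(volume, class_means) {
  if (inherits(volume, "metcof_pocket")) volume <- volume$volume
  stopifnot(is.numeric(volume), length(class_means) >= 1,
            !is.null(names(class_means)))
  d <- abs(class_means - volume)
  ord <- order(d, names(class_means))
  tie <- length(d) > 1L && abs(d[ord[1]] - d[ord[2]]) < 1e-9
  list(
    class = if (tie) NA_character_ else names(class_means)[ord[1]],
    margin = if (length(d) > 1L) unname(d[ord[2]] - d[ord[1]]) else Inf,
    tie = tie
  )
}

#' Assign a class by dendrogram co-clustering with labelled references
#'
#' Clusters the query together with labelled reference structures
#' (standardized contact-set distance, complete linkage), cuts the tree at
#' half the root height and reports the majority label among the
#' references sharing the query's cluster.
#'
#' @param query_id name of the query in `structures`.
#' @param structures named list of `metcof_structure` (query + references).
#' @param ref_labels named character vector of reference class labels.
#' @param alignment,cutoff,min_sep passed to [distance_matrix()].
#' @param cut_height dendrogram cut; default half the root height.
#' @return list: `class` (NA if the query clusters alone or the vote
#'   ties), `cluster_members`, `dendrogram`.
#' @export
cluster_assignment <- function(query_id, structures, ref_labels,
                               alignment = NULL, cutoff = 8.0, min_sep = 2L,
                               cut_height = NULL) {
  stopifnot(query_id %in% names(structures))
  sm <- distance_matrix(structures, alignment = alignment, cutoff = cutoff,
                        min_sep = min_sep)
  dend <- complete_linkage(sm)
  grp <- cut_dendrogram(dend, h = cut_height)
  mates <- names(grp)[grp == grp[query_id]]
  mates <- setdiff(mates, query_id)
  mates <- intersect(mates, names(ref_labels))
  cls <- NA_character_
  if (length(mates) > 0L) {
    tab <- sort(table(ref_labels[mates]), decreasing = TRUE)
    if (length(tab) == 1L || tab[1] > tab[2]) cls <- names(tab)[1]
  }
  list(class = cls, cluster_members = mates, dendrogram = dend)
}

.majority_call <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) return(list(call = NA_character_, agreement = "none"))
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(calls) == 1L)
    return(list(call = names(tab)[1], agreement = "partial"))
  if (length(tab) > 1L && tab[1] == tab[2])
    return(list(call = "ambiguous", agreement = "conflict"))
  list(call = names(tab)[1],
       agreement = if (tab[1] == length(calls)) "unanimous" else "majority")
}

#' Run the three-evidence cofactor-inference pipeline
#'
#' Executes, for each query, whichever evidence lines the configuration
#' supports — structure clustering against labelled references, pocket
#' volume against class means, and the motif fingerprint — and combines
#' them by majority vote ("ambiguous" on ties; "partial" agreement when
#' only one line ran). The configuration is an R list; a YAML/JSON file
#' path naming input files is also accepted.
#'
#' @param config list (or path to a YAML file) with optional blocks:
#'   `cluster` (`structures` named list or named paths, `ref_labels`,
#'   optional `alignment`), `volume` (`volumes` named numeric per query or
#'   `structures` + `cofactor_spec`, and `class_means` or reference volumes
#'   implied by `ref_labels`), `fingerprint` (`alignment` named vector or
#'   path, `reference_id`), and `queries` (character vector of query ids).
#' @param out_dir optional directory receiving artifacts (dendrogram
#'   Newick, volume TSV, fingerprint TSV).
#' @return a `metcof_report`: data.frame with one row per query
#'   (`query`, `cluster_call`, `volume_call`, `fingerprint_call`,
#'   `combined_call`, `agreement`, `predicted_cofactor`) with a
#'   `provenance` attribute.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$cluster$structures))
      cfg$cluster$structures <- lapply(cfg$cluster$structures, read_pdb)
    if (!is.null(cfg$volume$structures))
      cfg$volume$structures <- lapply(cfg$volume$structures, read_pdb)
    if (!is.null(cfg$fingerprint$alignment) &&
        is.character(cfg$fingerprint$alignment) &&
        length(cfg$fingerprint$alignment) == 1L &&
        file.exists(cfg$fingerprint$alignment))
      cfg$fingerprint$alignment <- read_alignment(cfg$fingerprint$alignment)
    config <- cfg
  }
  queries <- config$queries
  if (is.null(queries)) stop("config$queries must name at least one query")
  has_cluster <- !is.null(config$cluster)
  has_volume <- !is.null(config$volume)
  has_finger <- !is.null(config$fingerprint)
  if (!has_cluster && !has_volume && !has_finger)
    stop("no evidence line runnable: supply cluster, volume and/or fingerprint inputs")

  volumes <- NULL
  class_means <- NULL
  if (has_volume) {
    v <- config$volume
    volumes <- v$volumes
    if (is.null(volumes) && !is.null(v$structures)) {
      spacing <- if (is.null(v$spacing)) 0.5 else v$spacing
      probe <- if (is.null(v$probe)) 1.4 else v$probe
      volumes <- vapply(v$structures, function(s) {
        cof <- select_cofactor(s, v$cofactor_spec)
        pocket_volume(s, cof, probe = probe, spacing = spacing)$volume
      }, 0)
    }
    class_means <- v$class_means
    if (is.null(class_means) && !is.null(v$ref_labels)) {
      refs <- intersect(names(volumes), names(v$ref_labels))
      class_means <- tapply(volumes[refs], v$ref_labels[refs], mean)
      class_means <- stats::setNames(as.numeric(class_means), names(class_means))
    }
  }

  rows <- list()
  artifacts <- list()
  for (q in queries) {
    ccall <- vcall <- fcall <- NA_character_
    if (has_cluster && q %in% names(config$cluster$structures)) {
      ca <- cluster_assignment(q, config$cluster$structures,
                               config$cluster$ref_labels,
                               alignment = config$cluster$alignment)
      ccall <- ca$class
      artifacts$dendrogram <- ca$dendrogram
    }
    if (has_volume && !is.null(volumes) && q %in% names(volumes) &&
        !is.null(class_means)) {
      vcall <- volume_class(volumes[[q]], class_means)$class
    }
    if (has_finger && q %in% names(config$fingerprint$alignment)) {
      rid <- config$fingerprint$reference_id
      if (is.null(rid)) rid <- "AvNifD_ref"
      pred <- classify(q, config$fingerprint$alignment, reference_id = rid)
      fcall <- pred$predicted_class
      artifacts$fingerprints[[q]] <- pred
    }
    mc <- .majority_call(c(cluster = ccall, volume = vcall, fingerprint = fcall))
    cof <- if (!is.na(mc$call) && mc$call %in% names(.class_cofactor))
      unname(.class_cofactor[mc$call]) else NA_character_
    rows[[q]] <- data.frame(
      query = q, cluster_call = ccall, volume_call = vcall,
      fingerprint_call = fcall, combined_call = mc$call,
      agreement = mc$agreement, predicted_cofactor = cof,
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "provenance") <- list(
    package_version = as.character(utils::packageVersion("metcof")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    evidence_lines = c(cluster = has_cluster, volume = has_volume,
                       fingerprint = has_finger),
    class_means = class_means
  )
  class(report) <- c("metcof_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(artifacts$dendrogram))
      write_newick(artifacts$dendrogram, file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(volumes))
      utils::write.table(
        data.frame(id = names(volumes), volume = as.numeric(volumes)),
        file.path(out_dir, "volumes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    for (q in names(artifacts$fingerprints))
      write_fingerprint_tsv(artifacts$fingerprints[[q]],
                            file.path(out_dir, sprintf("fingerprint_%s.tsv", q)))
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
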