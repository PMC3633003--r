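# Propagated term -> gene sets (true-path rule) and the term-size filter.

ASPECT_NAMESPACE <- c(P = "biological_process", F = "molecular_function",
                      C = "cellular_component")

#' Build propagated term-to-gene sets from an ontology and annotation snapshot
#'
#' Realizes the true-path rule: each direct annotation (gene, term)
#' contributes the gene to the term and to every ancestor of the term over
#' the chosen relations. Duplicate gene-term assertions (multiple evidence
#' lines) count once. Annotations whose term cannot be resolved in this
#' ontology snapshot, resolves to an obsolete term, or lies outside the
#' requested namespace are skipped and tallied in the skip report — across
#' eras this is routine, not exceptional.
#'
#' @param graph a `go_ontology`.
#' @param annos a `go_annotations` (typically aspect-filtered to match
#'   `namespace`).
#' @param relations relation types to propagate over; default `is_a` +
#'   `part_of`.
#' @param namespace ontology namespace of the collection; annotations to
#'   terms in other namespaces are skipped.
#' @return a `gene_set_collection`: list with `sets` (named list, term id ->
#'   sorted character vector of gene ids; terms with empty sets omitted),
#'   `term_names`, `universe` (union of all sets), `namespace`, `provenance`
#'   (ontology and annotation snapshot labels) and `skip_report` (counts of
#'   unresolved / obsolete / namespace-mismatched annotations).
#' @export
build_gene_sets <- function(graph, annos, relations = c("isa", "partof"),
                            namespace = "biological_process") {
  stopifnot(inherits(graph, "go_ontology"), inherits(annos, "go_annotations"))
  namespace <- match.arg(namespace, unname(ASPECT_NAMESPACE))
  r <- annos$records
  pairs <- unique(r[, c("gene_id", "term_id")])
  skip <- c(unknown = 0L, obsolete = 0L, namespace_mismatch = 0L)

  # resolve each distinct direct term once
  direct_terms <- unique(pairs$term_id)
  resolved <- setNames(rep(NA_character_, length(direct_terms)), direct_terms)
  for (tid in direct_terms) {
    res <- resolve_term_quiet(graph, tid)
    if (res$status == "ok") {
      if (identical(graph$terms[[res$id]]$namespace, namespace))
        resolved[[tid]] <- res$id
    }
  }

  skipped_terms <- direct_terms[is.na(resolved)]
  for (tid in skipped_terms) {
    res <- resolve_term_quiet(graph, tid)
    kind <- switch(res$status, unknown = "unknown", obsolete = "obsolete",
                   "namespace_mismatch")
    skip[[kind]] <- skip[[kind]] + sum(pairs$term_id == tid)
  }

  anc <- all_ancestors(graph, relations)
  genes_by_set <- new.env(parent = emptyenv())
  kept <- !is.na(resolved[pairs$term_id])
  genes_by_direct <- split(pairs$gene_id[kept],
                           resolved[pairs$term_id[kept]])
  for (canon in names(genes_by_direct)) {
    gs <- genes_by_direct[[canon]]
    for (a in anc[[canon]]) genes_by_set[[a]] <- c(genes_by_set[[a]], gs)
  }
  ids <- sort(ls(genes_by_set))
  sets <- lapply(ids, function(id) sort(unique(genes_by_set[[id]])))
  names(sets) <- ids
  term_names <- vapply(ids, function(id) graph$terms[[id]]$name, character(1))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, term_names = term_names, universe = universe,
                 namespace = namespace,
                 provenance = c(ontology = graph$snapshot_label,
                                annotations = annos$snapshot_label),
                 skip_report = skip,
                 removed_by_size = integer(0)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "gene_set_collection [%s]: %d terms, %d genes in universe (skipped: %s)\n",
    x$namespace, length(x$sets), length(x$universe),
    paste(names(x$skip_report), x$skip_report, sep = "=", collapse = " ")))
  invisible(x)
}

#' Restrict and size-filter a gene-set collection
#'
#' Optionally intersects every set (and the universe) with `restrict_to` —
#' typically the genes actually measured on the expression platform, which
#' keeps the enrichment contingency table self-consistent — then removes
#' terms annotated to fewer than `min_size` or more than `max_size` genes.
#' Bounds are inclusive: sizes of exactly `min_size` and `max_size` survive.
#'
#' @param collection a `gene_set_collection`.
#' @param min_size,max_size inclusive size bounds (defaults 3 and 500).
#' @param restrict_to optional character vector of gene ids forming the
#'   analysis universe.
#' @return the filtered `gene_set_collection`; the ids and sizes of terms
#'   removed by the size rule are recorded in `removed_by_size` so downstream
#'   reports can distinguish "filtered" from "absent". An empty result is
#'   legal and carried with a warning.
#' @export
filter_by_size <- function(collection, min_size = 3, max_size = 500,
                           restrict_to = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"),
            min_size >= 1, max_size >= min_size)
  sets <- collection$sets
  universe <- collection$universe
  if (!is.null(restrict_to)) {
    universe <- intersect(universe, restrict_to)
    sets <- lapply(sets, intersect, restrict_to)
  }
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  removed <- sizes[!keep]
  out <- collection
  out$sets <- sets[keep]
  out$universe <- universe
  out$term_names <- collection$term_names[names(out$sets)]
  out$removed_by_size <- c(collection$removed_by_size, removed)
  if (!length(out$sets))
    warning("size filter removed every term; empty collection returned",
            call. = FALSE)
  out
}

#' Write a gene-set collection as a GMT file
#'
#' One line per term: term id, term name, then tab-separated gene ids.
#'
#' @param collection a `gene_set_collection`.
#' @param path output path, or `NULL` to return lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_gmt <- function(collection, path = NULL) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$term_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(unname(lines))
}

#' Read a GMT file into a gene-set collection
#'
#' @param source path, connection, or character vector of lines.
#' @param namespace namespace label to attach.
#' @return a `gene_set_collection` (universe = union of all sets; no
#'   provenance beyond the source name).
#' @export
read_gmt <- function(source, namespace = "biological_process") {
  lines <- read_text_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate term id in GMT: ",
                               ids[duplicated(ids)][1], call. = FALSE)
  sets <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  names(sets) <- ids
  term_names <- setNames(vapply(fields, `[`, character(1), 2), ids)
  structure(list(sets = sets, term_names = term_names,
                 universe = sort(unique(unlist(sets, use.names = FALSE))),
                 namespace = namespace,
                 provenance = c(ontology = "", annotations = ""),
                 skip_report = c(unknown = 0L, obsolete = 0L,
                                 namespace_mismatch = 0L),
                 removed_by_size = integer(0)),
            class = "gene_set_collection")
}
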