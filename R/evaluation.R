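# Snapshot series evaluation: per-snapshot enrichment trajectories for terms
# of interest, structure-vs-annotation decoupling, and top-term tracking.

#' Bundle an ontology and annotation snapshot under one label
#'
#' A snapshot is the knowledgebase at one time point: the ontology structure
#' and the annotation corpus released together (e.g. the May releases of one
#' year).
#'
#' @param label unique free-text label (e.g. `"2007"`).
#' @param graph a `go_ontology`.
#' @param annos a `go_annotations`.
#' @return a `go_snapshot` object.
#' @export
snapshot <- function(label, graph, annos) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(graph, "go_ontology"), inherits(annos, "go_annotations"))
  structure(list(label = label, graph = graph, annos = annos),
            class = "go_snapshot")
}

#' Read a snapshot manifest and load its files
#'
#' The manifest is a TSV with header columns `label`, `obo_path`, `gaf_path`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return list of `go_snapshot`, in manifest order.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "obo_path", "gaf_path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$label))
    stop("duplicate snapshot label in manifest", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    snapshot(tab$label[i],
             parse_obo(resolve(tab$obo_path[i]), snapshot_label = tab$label[i]),
             parse_gaf(resolve(tab$gaf_path[i]), snapshot_label = tab$label[i]))
  })
}

#' Default analysis settings for a snapshot series
#'
#' @param min_size,max_size inclusive term-size bounds (defaults 3, 500).
#' @param aspect annotation aspect, default `"P"` (biological process).
#' @param relations propagation relations, default `is_a` + `part_of`.
#' @param restrict_to optional measured-gene universe.
#' @param evidence_exclude optional evidence codes to drop (default keeps
#'   all, including IEA).
#' @param drop_negated drop NOT-qualified annotations (default `TRUE`).
#' @return a list of settings consumed by [run_series()].
#' @export
series_config <- function(min_size = 3, max_size = 500, aspect = "P",
                          relations = c("isa", "partof"), restrict_to = NULL,
                          evidence_exclude = NULL, drop_negated = TRUE) {
  aspect <- match.arg(aspect, c("P", "F", "C"))
  list(min_size = min_size, max_size = max_size, aspect = aspect,
       namespace = unname(ASPECT_NAMESPACE[aspect]), relations = relations,
       restrict_to = restrict_to, evidence_exclude = evidence_exclude,
       drop_negated = drop_negated)
}

#' Enrichment trajectory of terms of interest across a snapshot series
#'
#' For each snapshot: filter annotations to the configured aspect, build
#' propagated gene sets, apply the size filter, run the enrichment analysis
#' against the fixed study gene list, and record the rank, p-values and set
#' size of every requested term. The study list is computed once upstream and
#' reused across snapshots — the series evaluates the knowledgebase, not the
#' differential-expression call. Term ids are resolved per snapshot (alt_id
#' drift), and every (term, snapshot) cell is either a full record or a
#' reasoned absence; nothing is silently empty.
#'
#' @param snapshots list of `go_snapshot` with unique labels.
#' @param study_genes fixed study gene list (character vector).
#' @param terms_of_interest GO ids to track.
#' @param config settings from [series_config()].
#' @return a `trajectory_table`: data.frame with one row per (term, snapshot)
#'   — columns term_id, snapshot, status, rank, p_raw, p_adjusted, set_size —
#'   with attribute `snapshot_labels` preserving series order. Status is
#'   `tested` or an absence reason in `{filtered_by_size,
#'   absent_from_snapshot, p_equals_1, fewer_than_min_genes}` (the last two
#'   only after [track_terms()]).
#' @export
run_series <- function(snapshots, study_genes, terms_of_interest,
                       config = series_config()) {
  stopifnot(length(snapshots) >= 1L)
  labels <- vapply(snapshots, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("snapshot labels must be unique within a series", call. = FALSE)
  rows <- list()
  for (s in snapshots) {
    annos <- filter_annotations(s$annos, evidence_exclude =
                                  config$evidence_exclude,
                                drop_negated = config$drop_negated,
                                aspect = config$aspect)
    collection <- build_gene_sets(s$graph, annos,
                                  relations = config$relations,
                                  namespace = config$namespace)
    collection <- suppressWarnings(
      filter_by_size(collection, config$min_size, config$max_size,
                     config$restrict_to))
    report <- if (length(collection$sets) && length(collection$universe)) {
      if (!length(intersect(study_genes, collection$universe)))
        warning(sprintf(
          "snapshot '%s': gene sets share no genes with the study list",
          s$label), call. = FALSE)
      res <- enrich(study_genes, collection)
      resolved <- vapply(terms_of_interest, function(tid) {
        q <- resolve_term_quiet(s$graph, tid)
        if (q$status == "ok") q$id else NA_character_
      }, character(1))
      rep <- term_report(res, ifelse(is.na(resolved), terms_of_interest,
                                     resolved))
      rep$term_id <- terms_of_interest  # key rows by the requested id
      rep
    } else {
      warning(sprintf(
        "snapshot '%s': no testable gene sets; recording all-absent column",
        s$label), call. = FALSE)
      removed <- collection$removed_by_size
      data.frame(term_id = terms_of_interest,
                 status = ifelse(terms_of_interest %in% names(removed),
                                 "filtered_by_size", "absent_from_snapshot"),
                 rank = NA_integer_, p_raw = NA_real_, p_adjusted = NA_real_,
                 set_size = NA_integer_, stringsAsFactors = FALSE)
    }
    report$snapshot <- s$label
    rows[[s$label]] <- report
  }
  out <- do.call(rbind, rows)
  out <- out[, c("term_id", "snapshot", "status", "rank", "p_raw",
                 "p_adjusted", "set_size")]
  rownames(out) <- NULL
  structure(out, class = c("trajectory_table", "data.frame"),
            snapshot_labels = labels)
}

#' Freeze one knowledgebase component across a snapshot series
#'
#' The decoupling experiment: to attribute trajectory changes to structure
#' versus annotations, hold one component at a reference snapshot while the
#' other varies. `fix_annotations` pairs every snapshot's ontology with the
#' reference annotation set (only structure varies); `fix_structure` pairs
#' the reference ontology with every snapshot's annotations (only annotations
#' vary). The result feeds [run_series()] unchanged.
#'
#' @param snapshots list of `go_snapshot`.
#' @param mode `"fix_annotations"` or `"fix_structure"`.
#' @param reference_label label of the snapshot supplying the frozen
#'   component.
#' @return list of `go_snapshot` with the original labels.
#' @export
decouple <- function(snapshots, mode = c("fix_annotations", "fix_structure"),
                     reference_label) {
  mode <- match.arg(mode)
  labels <- vapply(snapshots, function(s) s$label, character(1))
  i <- match(reference_label, labels)
  if (is.na(i))
    stop("reference_label '", reference_label, "' is not in the series",
         call. = FALSE)
  ref <- snapshots[[i]]
  lapply(snapshots, function(s) {
    if (mode == "fix_annotations") snapshot(s$label, s$graph, ref$annos)
    else snapshot(s$label, ref$graph, s$annos)
  })
}

#' Top-k most significant terms of an enrichment run
#'
#' @param results an `enrichment_result`.
#' @param k how many (default 10); fewer available returns all.
#' @return character vector of term ids in rank order (ascending raw p,
#'   lexicographic term-id tie-break).
#' @export
top_terms <- function(results, k = 10) {
  stopifnot(inherits(results, "enrichment_result"), k >= 0)
  utils::head(results$term_id, k)
}

#' Apply the trajectory omission rule
#'
#' Masks trajectory cells that carry no signal: a cell whose gene set has
#' fewer than `min_genes` genes becomes an absence with reason
#' `fewer_than_min_genes`; a tested cell with p_raw exactly 1 becomes
#' `p_equals_1`. Terms absent at every snapshot after masking are dropped.
#' This is why trajectory lines can start late or end early.
#'
#' @param table a `trajectory_table`.
#' @param min_genes minimum gene-set size for a cell to count (default 3).
#' @return the masked `trajectory_table`.
#' @export
track_terms <- function(table, min_genes = 3) {
  stopifnot(inherits(table, "trajectory_table"))
  tested <- table$status == "tested"
  too_small <- tested & !is.na(table$set_size) & table$set_size < min_genes
  p_one <- tested & !too_small & !is.na(table$p_raw) & table$p_raw == 1
  table$status[too_small] <- "fewer_than_min_genes"
  table$status[p_one] <- "p_equals_1"
  mask <- too_small | p_one
  table$rank[mask] <- NA_integer_
  table$p_raw[mask] <- NA_real_
  table$p_adjusted[mask] <- NA_real_
  present <- tapply(table$status == "tested", table$term_id, any)
  keep_terms <- names(present)[present]
  out <- table[table$term_id %in% keep_terms, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table),
            snapshot_labels = attr(table, "snapshot_labels"))
}

#' Write a trajectory table as TSV
#'
#' One row per (term, snapshot); the snapshot order of the series is stored
#' in a `#snapshots:` header comment so the round-trip is lossless.
#'
#' @param table a `trajectory_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#snapshots: ",
                    paste(attr(table, "snapshot_labels"), collapse = "\t")),
             con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path TSV path.
#' @return a `trajectory_table`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labels <- character(0)
  if (length(lines) && startsWith(lines[1], "#snapshots: ")) {
    labels <- strsplit(sub("^#snapshots: ", "", lines[1]), "\t",
                       fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
  tab$term_id <- as.character(tab$term_id)
  tab$snapshot <- as.character(tab$snapshot)
  tab$status <- as.character(tab$status)
  tab$rank <- as.integer(tab$rank)
  tab$set_size <- as.integer(tab$set_size)
  structure(tab, class = c("trajectory_table", "data.frame"),
            snapshot_labels = labels)
}
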