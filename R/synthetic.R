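# Synthetic test substrate: random DAG ontologies, annotation corpora with
# snapshot growth, and two-group expression matrices with a planted
# over-expressed term. Every pipeline stage is exercisable without downloads.

#' Simulation settings for the synthetic corpus
#'
#' Defaults describe the study conditions the test suite runs under: a
#' 200-term biological-process DAG, 500 genes averaging 2 direct annotations
#' each, a planted term whose genes gain a ln-scale mean shift of 2 against
#' noise SD 0.5 in 10-vs-10 samples, and a five-point cumulative annotation
#' growth series.
#'
#' @param n_terms number of ontology terms (>= 1).
#' @param max_depth maximum DAG depth below the root.
#' @param branching mean width growth per level (controls the level-size
#'   profile of the generated DAG).
#' @param n_genes number of genes.
#' @param annotations_per_gene Poisson mean of direct annotations per gene
#'   (minimum 1 enforced).
#' @param planted_term GO-style id of the over-expressed term, or `NULL` to
#'   pick a mid-sized term automatically (see [choose_planted_term()]).
#' @param effect_size ln-scale mean shift added to case samples of planted
#'   genes (>= 0).
#' @param noise_sd ln-scale noise SD (> 0).
#' @param samples_per_group samples per group in the expression matrix.
#' @param baseline ln-scale baseline intensity.
#' @param growth_fractions non-decreasing fractions in (0, 1] defining the
#'   cumulative annotation snapshots.
#' @param seed integer random seed; all generators are deterministic in it.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_terms = 200, max_depth = 6, branching = 3,
                              n_genes = 500, annotations_per_gene = 2,
                              planted_term = NULL, effect_size = 2,
                              noise_sd = 0.5, samples_per_group = 10,
                              baseline = 6,
                              growth_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              seed = 1) {
  stopifnot(n_terms >= 1, effect_size >= 0, noise_sd > 0,
            samples_per_group >= 2, all(diff(growth_fractions) >= 0),
            all(growth_fractions > 0), growth_fractions[length(growth_fractions)] <= 1)
  structure(list(n_terms = n_terms, max_depth = max_depth,
                 branching = branching, n_genes = n_genes,
                 annotations_per_gene = annotations_per_gene,
                 planted_term = planted_term, effect_size = effect_size,
                 noise_sd = noise_sd, samples_per_group = samples_per_group,
                 baseline = baseline, growth_fractions = growth_fractions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random rooted DAG ontology
#'
#' Terms are assigned to levels 0 (a single root) through `max_depth`, with
#' level sizes growing geometrically by `branching`; every non-root term
#' receives one or two parents drawn from strictly shallower levels, so the
#' graph is acyclic by construction. All terms are in the
#' `biological_process` namespace. Byte-identical OBO serialization for a
#' fixed seed.
#'
#' @param config a `sim_config`.
#' @return a `go_ontology`.
#' @export
simulate_ontology <- function(config) {
  with_seed(config$seed, {
    n <- config$n_terms
    ids <- sprintf("GO:%07d", seq_len(n))
    levels <- integer(n)
    if (n > 1) {
      depth <- max(1L, config$max_depth)
      w <- config$branching ^ seq_len(depth)
      levels[-1] <- sort(sample(seq_len(depth), n - 1L, replace = TRUE,
                                prob = w / sum(w)))
    }
    terms <- vector("list", n)
    names(terms) <- ids
    for (i in seq_len(n)) {
      isa <- character(0); partof <- character(0)
      if (i > 1L) {
        shallower <- which(levels < levels[i])
        n_par <- min(length(shallower), sample(1:2, 1))
        par_idx <- if (length(shallower) == 1L) shallower else
          sample(shallower, n_par)
        for (p in ids[par_idx]) {
          if (stats::runif(1) < 0.8) isa <- c(isa, p) else
            partof <- c(partof, p)
        }
      }
      terms[[i]] <- list(term_id = ids[i], name = paste("synthetic term", i),
                         namespace = "biological_process",
                         isa_parents = isa, partof_parents = partof,
                         regulates_parents = character(0),
                         alt_ids = character(0), obsolete = FALSE)
    }
    graph <- structure(list(terms = terms, alt = character(0),
                            snapshot_label = sprintf("sim-seed%d", config$seed)),
                       class = "go_ontology")
    validate_ontology(graph)
    graph
  })
}

#' Generate direct gene annotations for a synthetic ontology
#'
#' Each gene receives `max(1, Poisson(annotations_per_gene))` direct
#' annotations to uniformly drawn terms; dates are uniform over a synthetic
#' decade (2003-01-01 to 2012-12-31) so date filters are exercisable;
#' evidence codes are drawn from IEA/IDA/TAS with fixed proportions
#' (0.5/0.3/0.2); aspect is `P` throughout.
#'
#' @param graph a `go_ontology`.
#' @param config a `sim_config`.
#' @return a `go_annotations`.
#' @export
simulate_annotations <- function(graph, config) {
  stopifnot(length(graph$terms) >= 1L)
  with_seed(config$seed + 1L, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    term_ids <- names(graph$terms)
    counts <- pmax(1L, stats::rpois(config$n_genes,
                                    config$annotations_per_gene))
    total <- sum(counts)
    day0 <- as.Date("2003-01-01")
    day1 <- as.Date("2012-12-31")
    dates <- day0 + sample.int(as.integer(day1 - day0) + 1L, total,
                               replace = TRUE) - 1L
    records <- data.frame(
      gene_id = rep(genes, counts),
      gene_symbol = rep(genes, counts),
      term_id = sample(term_ids, total, replace = TRUE),
      qualifier_negated = FALSE,
      evidence_code = sample(c("IEA", "IDA", "TAS"), total, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)),
      aspect = "P",
      date = as.integer(format(dates, "%Y%m%d")),
      stringsAsFactors = FALSE)
    new_annotations(records, sprintf("sim-annos-seed%d", config$seed))
  })
}

#' Pick a mid-sized term to plant signal on
#'
#' Deterministically selects the term whose propagated gene-set size is
#' closest to `target` within `[lower, upper]` (ties broken by term id); the
#' planted term must be large enough to survive the size filter and small
#' enough that its signal is specific.
#'
#' @param collection a `gene_set_collection`.
#' @param target preferred set size.
#' @param lower,upper admissible size range.
#' @return a term id.
#' @export
choose_planted_term <- function(collection, target = 25, lower = 10,
                                upper = 100) {
  sizes <- vapply(collection$sets, length, integer(1))
  cand <- sizes[sizes >= lower & sizes <= upper]
  if (!length(cand)) cand <- sizes
  ord <- order(abs(cand - target), names(cand))
  names(cand)[ord[1]]
}

#' Simulate a two-group expression matrix with a planted enriched term
#'
#' One probe per annotated gene. Control samples draw
#' `exp(baseline + Normal(0, noise_sd))`; case samples of genes in the
#' planted term's propagated set gain an additional ln-scale shift of
#' `effect_size`. Values are positive by construction, so the standard
#' pipeline (probe filter, natural log, t-test) applies unchanged.
#'
#' @param annos a `go_annotations` supplying the gene roster.
#' @param collection a `gene_set_collection` containing the planted term.
#' @param config a `sim_config`; `planted_term` must be set (use
#'   [choose_planted_term()]) and present in `collection`.
#' @return an `expr_matrix` with an identity probe-to-gene map
#'   (probe `"p_<gene>"` -> gene).
#' @export
simulate_expression <- function(annos, collection, config) {
  planted <- config$planted_term
  if (is.null(planted) || is.null(collection$sets[[planted]]))
    stop("planted term ", planted %||% "<NULL>",
         " is absent from the collection", call. = FALSE)
  with_seed(config$seed + 2L, {
    genes <- sort(unique(annos$records$gene_id))
    planted_genes <- collection$sets[[planted]]
    ns <- config$samples_per_group
    samples <- c(sprintf("case_%02d", seq_len(ns)),
                 sprintf("ctrl_%02d", seq_len(ns)))
    groups <- setNames(rep(c("case", "control"), each = ns), samples)
    lnvals <- matrix(stats::rnorm(length(genes) * 2 * ns, config$baseline,
                                  config$noise_sd),
                     nrow = length(genes),
                     dimnames = list(paste0("p_", genes), samples))
    shift_rows <- genes %in% planted_genes
    lnvals[shift_rows, groups == "case"] <-
      lnvals[shift_rows, groups == "case"] + config$effect_size
    expression_matrix(exp(lnvals), groups,
                      probe_gene_map = setNames(genes, paste0("p_", genes)))
  })
}

#' Nested cumulative subsets of an annotation corpus
#'
#' Emulates annotation growth over snapshots: for each fraction f, exactly
#' `round(f * n_records)` records, each snapshot's records a subset of the
#' next's (a fixed seed-determined record order is truncated at each size).
#' Labels are `"t1"`, `"t2"`, ...
#'
#' @param full a `go_annotations`.
#' @param config a `sim_config` with valid `growth_fractions`.
#' @return list of `go_annotations`, one per fraction, in order.
#' @export
simulate_growth <- function(full, config) {
  n <- nrow(full$records)
  with_seed(config$seed + 3L, {
    perm <- sample.int(n)
    lapply(seq_along(config$growth_fractions), function(i) {
      size <- round(config$growth_fractions[i] * n)
      idx <- sort(perm[seq_len(size)])
      new_annotations(full$records[idx, , drop = FALSE],
                      paste0("t", i))
    })
  })
}

#' Generate a complete in-memory synthetic study
#'
#' Convenience wrapper tying the generators together: one ontology, a full
#' annotation corpus, its growth series as snapshots (structure frozen,
#' annotations growing), a planted term, and the expression matrix carrying
#' its signal.
#'
#' @param config a `sim_config`.
#' @return list with elements `graph`, `annos` (full corpus), `snapshots`
#'   (list of `go_snapshot` over the growth series), `collection` (full,
#'   unfiltered), `planted_term`, `expr` (an `expr_matrix`), and `config`
#'   (with `planted_term` filled in).
#' @export
simulate_study <- function(config = simulation_config()) {
  graph <- simulate_ontology(config)
  annos <- simulate_annotations(graph, config)
  collection <- build_gene_sets(graph, annos)
  if (is.null(config$planted_term))
    config$planted_term <- choose_planted_term(collection)
  expr <- simulate_expression(annos, collection, config)
  growth <- simulate_growth(annos, config)
  snaps <- lapply(growth, function(a) snapshot(a$snapshot_label, graph, a))
  list(graph = graph, annos = annos, snapshots = snaps,
       collection = collection, planted_term = config$planted_term,
       expr = expr, config = config)
}

#' Write a synthetic corpus to disk
#'
#' Serializes a [simulate_study()] result into the file formats the rest of
#' the toolchain consumes: one OBO file, one GAF per growth snapshot, the
#' expression TSV, group labels, the probe-to-gene map, and a snapshot
#' manifest consumable by [read_manifest()].
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
simulate_corpus <- function(config = simulation_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  write_obo(study$graph, file.path(dir, "ontology.obo"))
  labels <- vapply(study$snapshots, function(s) s$label, character(1))
  gaf_paths <- sprintf("annotations_%s.gaf", labels)
  for (i in seq_along(study$snapshots))
    write_gaf(study$snapshots[[i]]$annos, file.path(dir, gaf_paths[i]))
  v <- study$expr$values
  expr_tab <- data.frame(probe_id = rownames(v), v, check.names = FALSE)
  utils::write.table(expr_tab, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(study$expr$group_labels),
               group = unname(study$expr$group_labels)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(study$expr$probe_gene_map),
               gene_id = unname(study$expr$probe_gene_map)),
    file.path(dir, "probe_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest <- data.frame(label = labels, obo_path = "ontology.obo",
                         gaf_path = gaf_paths)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(study$planted_term, file.path(dir, "planted_term.txt"))
  invisible(manifest_path)
}
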