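# Shared fixtures (built in code) and independent brute-force oracles.

# four-stanza OBO: A root; B is_a A (with an alt_id); C part_of A; D obsolete
obo_fixture <- function() c(
  "format-version: 1.2",
  "",
  "[Term]",
  "id: GO:0000001",
  "name: term A",
  "namespace: biological_process",
  "",
  "[Term]",
  "id: GO:0000002",
  "name: term B",
  "namespace: biological_process",
  "alt_id: GO:0009999",
  "is_a: GO:0000001 ! term A",
  "",
  "[Term]",
  "id: GO:0000003",
  "name: term C",
  "namespace: biological_process",
  "relationship: part_of GO:0000001 ! term A",
  "",
  "[Term]",
  "id: GO:0000004",
  "name: term D",
  "namespace: biological_process",
  "is_obsolete: true",
  "",
  "[Typedef]",
  "id: part_of",
  "name: part of")

# three GAF lines with distinct evidence codes and dates, one NOT-qualified
gaf_fixture <- function() c(
  "!gaf-version: 2.1",
  paste("UniProtKB", "P00001", "GENE1", "", "GO:0000001", "GO_REF:0000001",
        "IDA", "", "P", "gene one", "", "protein", "taxon:9606", "20050101",
        "UniProt", "", "", sep = "\t"),
  paste("UniProtKB", "P00002", "GENE2", "NOT|involved_in", "GO:0000002",
        "GO_REF:0000002", "IEA", "", "P", "gene two", "", "protein",
        "taxon:9606", "20100315", "UniProt", "", "", sep = "\t"),
  paste("UniProtKB", "P00003", "GENE3", "", "GO:0000003", "GO_REF:0000003",
        "TAS", "", "F", "gene three", "", "protein", "taxon:9606",
        "20111231", "UniProt", "", "", sep = "\t"))

# chain C is_a B is_a A plus a diamond D -> {B, C}
chain_obo <- function() c(
  "[Term]", "id: GO:0000011", "name: A", "namespace: biological_process", "",
  "[Term]", "id: GO:0000012", "name: B", "namespace: biological_process",
  "is_a: GO:0000011", "",
  "[Term]", "id: GO:0000013", "name: C", "namespace: biological_process",
  "is_a: GO:0000012", "",
  "[Term]", "id: GO:0000014", "name: D", "namespace: biological_process",
  "is_a: GO:0000012", "is_a: GO:0000013", "")

# brute-force reflexive reachability by repeated edge-following, no memoization
oracle_ancestors <- function(graph, term_id, relations = c("isa", "partof")) {
  fields <- paste0(relations, "_parents")
  walk <- function(id) {
    parents <- unlist(graph$terms[[id]][fields], use.names = FALSE)
    out <- id
    for (p in parents) out <- c(out, walk(p))
    out
  }
  sort(unique(walk(term_id)))
}

# naive gene-set construction: per annotation, walk to every reachable
# ancestor independently (the oracle build_gene_sets must reproduce)
oracle_gene_sets <- function(graph, annos, relations = c("isa", "partof"),
                             namespace = "biological_process") {
  sets <- list()
  r <- unique(annos$records[, c("gene_id", "term_id")])
  for (i in seq_len(nrow(r))) {
    tid <- r$term_id[i]
    t <- graph$terms[[tid]]
    if (is.null(t) || t$obsolete || !identical(t$namespace, namespace)) next
    for (a in oracle_ancestors(graph, tid, relations))
      sets[[a]] <- union(sets[[a]], r$gene_id[i])
  }
  lapply(sets[sort(names(sets))], sort)
}

# exhaustive hypergeometric upper tail from binomial-coefficient ratios
oracle_fisher <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# build a tiny collection directly from explicit sets
make_collection <- function(sets, universe = NULL,
                            namespace = "biological_process") {
  sets <- lapply(sets, sort)
  if (is.null(universe))
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets,
                 term_names = setNames(paste("name of", names(sets)),
                                       names(sets)),
                 universe = universe, namespace = namespace,
                 provenance = c(ontology = "test", annotations = "test"),
                 skip_report = c(unknown = 0L, obsolete = 0L,
                                 namespace_mismatch = 0L),
                 removed_by_size = integer(0)),
            class = "gene_set_collection")
}

small_config <- function(seed = 1, ...) {
  simulation_config(n_terms = 40, max_depth = 4, n_genes = 60,
                    samples_per_group = 5, seed = seed, ...)
}
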