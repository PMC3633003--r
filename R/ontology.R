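# Ontology: OBO parsing, DAG validation, ancestor closure, id resolution.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"

is_go_id <- function(x) grepl(GO_ID_PATTERN, x)

#' Parse an OBO 1.2 flat file into a validated ontology graph
#'
#' Reads `[Term]` stanzas (tags: `id`, `name`, `namespace`, `is_a`,
#' `relationship`, `alt_id`, `is_obsolete`) into a directed acyclic graph of
#' GO terms. `relationship: part_of` lines populate part_of parent edges;
#' `regulates`-family relationships are parsed and stored but excluded from
#' the default propagation relation set. Obsolete terms are retained in the
#' term map, flagged, and stripped of all parent edges. Trailing `!` comments
#' are removed; non-`[Term]` stanzas (`[Typedef]`) are skipped.
#'
#' @param source path to an OBO file (gzip transparently supported), a
#'   connection, or a character vector of lines.
#' @param snapshot_label free-text label recorded on the graph (e.g.
#'   `"2012-05"`); defaults to the file name when `source` is a path.
#' @return an object of class `go_ontology`: a list with elements `terms`
#'   (named list of term records), `alt` (named character vector mapping
#'   alt_id to canonical id) and `snapshot_label`.
#' @details Validation is strict: a parent id that is not itself a term, a
#'   cycle in the is_a/part_of/regulates edge set, a parent edge crossing
#'   namespaces, a stanza without an `id`, or an `alt_id` colliding with a
#'   canonical id or claimed by two terms, each raise an error.
#' @seealso [ancestors()], [resolve_term()], [write_obo()]
#' @export
parse_obo <- function(source, snapshot_label = NULL) {
  lines <- read_text_lines(source)
  if (is.null(snapshot_label)) {
    snapshot_label <- if (is.character(source) && length(source) == 1L &&
                          file.exists(source)) basename(source) else ""
  }
  # strip "!" comments (end-of-line), keep original line numbers for errors
  stripped <- sub("[ \t]*!.*$", "", lines)

  terms <- list()
  alt <- character(0)
  stanza_type <- NA_character_
  cur <- NULL
  cur_line <- NA_integer_

  flush_term <- function(cur, cur_line) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$term_id)) {
      stop(sprintf("OBO [Term] stanza starting at line %d has no id tag",
                   cur_line), call. = FALSE)
    }
    if (!is_go_id(cur$term_id)) {
      stop(sprintf("line %d: term id '%s' does not match the GO identifier pattern",
                   cur_line, cur$term_id), call. = FALSE)
    }
    if (!is.null(terms[[cur$term_id]])) {
      stop(sprintf("duplicate [Term] stanza for %s", cur$term_id), call. = FALSE)
    }
    if (isTRUE(cur$obsolete)) {
      cur$isa_parents <- character(0)
      cur$partof_parents <- character(0)
      cur$regulates_parents <- character(0)
    }
    terms[[cur$term_id]] <<- cur
    if (length(cur$alt_ids)) {
      for (a in cur$alt_ids) {
        if (!is.na(alt[a]) && nzchar(alt[a] %||% "") && alt[[a]] != cur$term_id)
          stop(sprintf("alt_id %s claimed by both %s and %s",
                       a, alt[[a]], cur$term_id), call. = FALSE)
        alt[[a]] <<- cur$term_id
      }
    }
    invisible(NULL)
  }

  for (i in seq_along(stripped)) {
    line <- trimws(stripped[i])
    if (!nzchar(line)) next
    if (startsWith(line, "[")) {
      flush_term(cur, cur_line)
      cur <- NULL
      stanza_type <- line
      if (identical(line, "[Term]")) {
        cur <- list(term_id = NULL, name = "", namespace = "",
                    isa_parents = character(0),
                    partof_parents = character(0),
                    regulates_parents = character(0),
                    alt_ids = character(0), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (is.null(cur)) next  # header or [Typedef] body
    m <- regmatches(line, regexec("^([A-Za-z_]+)[ \t]*:[ \t]*(.*)$", line))[[1]]
    if (length(m) != 3L) next
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "id") cur$term_id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- val
    else if (tag == "is_a") cur$isa_parents <- c(cur$isa_parents, first_token(val))
    else if (tag == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (tag == "relationship") {
      toks <- strsplit(val, "[ \t]+")[[1]]
      if (length(toks) >= 2L) {
        rel <- toks[1]; target <- toks[2]
        if (rel == "part_of")
          cur$partof_parents <- c(cur$partof_parents, target)
        else if (rel %in% c("regulates", "positively_regulates",
                            "negatively_regulates"))
          cur$regulates_parents <- c(cur$regulates_parents, target)
        # other relationship types are ignored
      }
    }
  }
  flush_term(cur, cur_line)

  graph <- structure(list(terms = terms, alt = alt,
                          snapshot_label = snapshot_label),
                     class = "go_ontology")
  validate_ontology(graph)
  graph
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

first_token <- function(x) strsplit(trimws(x), "[ \t]+")[[1]][1]

read_text_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    con <- gzfile(source, "r")  # reads plain text and gzip alike
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (is.character(source)) {
    # a character vector of lines (possibly one string with newlines)
    return(unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE))
  }
  stop("unsupported input: expected a path, connection, or character vector")
}

validate_ontology <- function(graph) {
  terms <- graph$terms
  ids <- names(terms)
  collide <- intersect(names(graph$alt), ids)
  if (length(collide))
    stop("alt_id collides with a canonical term id: ", collide[1], call. = FALSE)
  for (t in terms) {
    parents <- c(t$isa_parents, t$partof_parents, t$regulates_parents)
    missing <- setdiff(parents, ids)
    if (length(missing))
      stop(sprintf("term %s references unknown parent %s", t$term_id,
                   missing[1]), call. = FALSE)
    for (p in parents) {
      pn <- terms[[p]]$namespace
      if (nzchar(t$namespace) && nzchar(pn) && !identical(t$namespace, pn))
        stop(sprintf("cross-namespace parent edge %s (%s) -> %s (%s)",
                     t$term_id, t$namespace, p, pn), call. = FALSE)
    }
  }
  assert_acyclic(graph)
  invisible(graph)
}

# Kahn's algorithm over the full relation set; errors naming a cycle member.
assert_acyclic <- function(graph) {
  terms <- graph$terms
  ids <- names(terms)
  if (!length(ids)) return(invisible(TRUE))
  parents <- lapply(terms, function(t)
    unique(c(t$isa_parents, t$partof_parents, t$regulates_parents)))
  indeg <- vapply(parents, length, integer(1))  # edges child -> parent
  children <- new.env(parent = emptyenv())
  for (id in ids) {
    for (p in parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    cyc <- ids[indeg > 0L]
    stop("ontology edge set contains a cycle involving term ", cyc[1],
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.go_ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$obsolete, logical(1)))
  cat(sprintf("go_ontology '%s': %d terms (%d obsolete), %d alt_ids\n",
              x$snapshot_label, length(x$terms), n_obs, length(x$alt)))
  invisible(x)
}

#' Reflexive transitive ancestor closure of a term
#'
#' Returns the term itself together with every term reachable from it by
#' repeatedly following parent edges of the selected relation types. This is
#' the closure the true-path rule propagates annotations over.
#'
#' @param graph a `go_ontology`.
#' @param term_id a canonical GO id of a non-obsolete term.
#' @param relations subset of `c("isa", "partof", "regulates")`; defaults to
#'   the classical true-path pair `is_a` + `part_of`.
#' @return character vector of GO ids, each ancestor once, `term_id` included.
#' @export
ancestors <- function(graph, term_id, relations = c("isa", "partof")) {
  relations <- match.arg(relations, c("isa", "partof", "regulates"),
                         several.ok = TRUE)
  t <- graph$terms[[term_id]]
  if (is.null(t))
    stop_goeval("unknown_term", sprintf("unknown term id '%s'", term_id),
                term_id)
  if (t$obsolete)
    stop_goeval("obsolete_term",
                sprintf("term %s is obsolete in snapshot '%s'", term_id,
                        graph$snapshot_label), term_id)
  fields <- paste0(relations, "_parents")
  seen <- new.env(parent = emptyenv())
  stack <- term_id
  out <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (!is.null(seen[[v]])) next
    seen[[v]] <- TRUE
    out <- c(out, v)
    tv <- graph$terms[[v]]
    for (f in fields) stack <- c(stack, tv[[f]])
  }
  out
}

# Closure for every term at once (memoized over a topological order);
# used by gene-set construction where per-term ancestors() would be wasteful.
all_ancestors <- function(graph, relations = c("isa", "partof")) {
  fields <- paste0(relations, "_parents")
  ids <- names(graph$terms)
  parents <- lapply(graph$terms, function(t)
    unique(unlist(t[fields], use.names = FALSE)))
  # topological order: parents before children
  order <- topo_order(ids, parents)
  anc <- vector("list", length(ids))
  names(anc) <- ids
  for (id in order) {
    ps <- parents[[id]]
    anc[[id]] <- unique(c(id, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

topo_order <- function(ids, parents) {
  indeg <- vapply(parents, length, integer(1))
  children <- list()
  for (id in ids) for (p in parents[[id]])
    children[[p]] <- c(children[[p]], id)
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Resolve a (possibly historical) GO id to its canonical id
#'
#' Term ids drift across ontology releases: a merged term survives as an
#' `alt_id` of the term it was merged into. `resolve_term` maps a query id to
#' the canonical id it denotes in this snapshot.
#'
#' @param graph a `go_ontology`.
#' @param query_id GO id, canonical or alternative.
#' @return the canonical GO id (the query itself if already canonical).
#'   Unknown ids raise an "unknown term" error; ids resolving to an obsolete
#'   term raise a distinct "obsolete term" error carrying the id.
#' @export
resolve_term <- function(graph, query_id) {
  canonical <- if (!is.null(graph$terms[[query_id]])) query_id
               else if (query_id %in% names(graph$alt)) graph$alt[[query_id]]
               else NA_character_
  if (is.na(canonical))
    stop_goeval("unknown_term",
                sprintf("unknown term id '%s' in snapshot '%s'", query_id,
                        graph$snapshot_label), query_id)
  if (graph$terms[[canonical]]$obsolete)
    stop_goeval("obsolete_term",
                sprintf("term '%s' resolves to obsolete term %s", query_id,
                        canonical), canonical)
  canonical
}

# quiet resolution for bulk use: returns canonical id or a status string
resolve_term_quiet <- function(graph, query_id) {
  canonical <- if (!is.null(graph$terms[[query_id]])) query_id
               else if (query_id %in% names(graph$alt)) graph$alt[[query_id]]
               else return(list(id = NA_character_, status = "unknown"))
  if (graph$terms[[canonical]]$obsolete)
    return(list(id = canonical, status = "obsolete"))
  list(id = canonical, status = "ok")
}

stop_goeval <- function(kind, msg, term_id = NULL) {
  cond <- structure(
    class = c(paste0("goeval_", kind), "goeval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), term_id = term_id))
  stop(cond)
}

#' Serialize an ontology back to OBO 1.2 text
#'
#' Deterministic: terms and tags are written in a fixed order, so two graphs
#' with identical content serialize byte-identically.
#'
#' @param graph a `go_ontology`.
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_obo <- function(graph, path = NULL) {
  out <- c("format-version: 1.2",
           sprintf("remark: snapshot %s", graph$snapshot_label), "")
  for (id in sort(names(graph$terms))) {
    t <- graph$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    for (a in sort(t$alt_ids)) out <- c(out, paste0("alt_id: ", a))
    for (p in sort(t$isa_parents))
      out <- c(out, sprintf("is_a: %s ! %s", p, graph$terms[[p]]$name))
    for (p in sort(t$partof_parents))
      out <- c(out, sprintf("relationship: part_of %s ! %s", p,
                            graph$terms[[p]]$name))
    for (p in sort(t$regulates_parents))
      out <- c(out, sprintf("relationship: regulates %s ! %s", p,
                            graph$terms[[p]]$name))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
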