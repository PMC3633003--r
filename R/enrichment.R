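# One-sided Fisher's exact over-representation analysis with Bonferroni
# correction, deterministic ranking, and term-of-interest reporting.

#' Upper-tail hypergeometric probability (one-sided Fisher's exact test)
#'
#' Probability of observing `k` or more study genes inside a term's gene set
#' when `n` study genes are drawn without replacement from a universe of `N`
#' genes of which `K` belong to the term: P(X >= k) for X ~
#' Hypergeometric(N, K, n). Computed in log space via `lchoose`, so it is
#' stable for universes up to at least 1e5 genes.
#'
#' @param k overlap count (study genes in the term set).
#' @param K term set size.
#' @param n study set size (within the universe).
#' @param N universe size.
#' @return the tail probability in [0, 1]; `k = 0` gives exactly 1.
#' @export
fisher_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || n > N || K > N)
    stop(sprintf("invalid contingency counts k=%d K=%d n=%d N=%d", k, K, n, N),
         call. = FALSE)
  if (k == 0) return(1)
  x <- k:min(K, n)
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  p <- sum(exp(logp))
  min(max(p, 0), 1)
}

#' Over-representation analysis of a study gene list
#'
#' Tests every term in a (size-filtered) gene-set collection for
#' over-representation of the study genes by the one-sided Fisher's exact
#' test, Bonferroni-corrects over the number of terms tested, and ranks
#' results by ascending raw p-value with lexicographic term-id tie-breaking
#' so ranks are deterministic.
#'
#' @param study_genes character vector of gene ids; genes outside the
#'   collection universe are dropped before testing (and tallied).
#' @param collection a `gene_set_collection`, already size-filtered.
#' @return an `enrichment_result`: data.frame with columns term_id,
#'   term_name, k, K, n, N, p_raw, p_adjusted, rank, sorted by rank.
#'   Attributes: `m` (terms tested), `n_study_outside_universe`, and
#'   `removed_by_size` carried from the collection for status reporting.
#' @export
enrich <- function(study_genes, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets))
    stop("empty gene-set collection: nothing to test", call. = FALSE)
  if (!length(collection$universe))
    stop("empty gene universe", call. = FALSE)
  study_genes <- unique(study_genes)
  study <- intersect(study_genes, collection$universe)
  n <- length(study)
  N <- length(collection$universe)
  ids <- names(collection$sets)
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(study, s)),
              integer(1))
  m <- length(ids)
  p_raw <- vapply(seq_along(ids),
                  function(i) fisher_pvalue(k[i], K[i], n, N), numeric(1))
  res <- data.frame(term_id = ids,
                    term_name = unname(collection$term_names[ids]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_raw = p_raw,
                    p_adjusted = pmin(1, m * p_raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(res$p_raw, res$term_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(m)
  rownames(res) <- NULL
  structure(res,
            class = c("enrichment_result", "data.frame"),
            m = m,
            n_study_outside_universe = length(study_genes) - n,
            removed_by_size = collection$removed_by_size)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param m number of tests (>= 1).
#' @return `min(1, m * p_raw)`, vectorized over `p_raw`.
#' @export
adjust_bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

#' Rank and p-value report for terms of interest
#'
#' The framework's readout: for each requested term, its rank and p-values if
#' it was tested, otherwise an explicit status — `filtered_by_size` when the
#' term existed but fell outside the term-size bounds (or lost its genes to
#' the universe restriction), `absent_from_snapshot` when the term had no
#' gene set in this snapshot at all.
#'
#' @param results an `enrichment_result`.
#' @param terms_of_interest character vector of GO ids (canonical for this
#'   snapshot; resolve with [resolve_term()] first if historical ids are in
#'   play).
#' @return data.frame with columns term_id, status, rank, p_raw, p_adjusted,
#'   set_size (NA where not applicable).
#' @export
term_report <- function(results, terms_of_interest) {
  stopifnot(inherits(results, "enrichment_result"))
  removed <- attr(results, "removed_by_size")
  rows <- lapply(terms_of_interest, function(tid) {
    hit <- which(results$term_id == tid)
    if (length(hit)) {
      r <- results[hit, ]
      data.frame(term_id = tid, status = "tested", rank = r$rank,
                 p_raw = r$p_raw, p_adjusted = r$p_adjusted, set_size = r$K,
                 stringsAsFactors = FALSE)
    } else if (tid %in% names(removed)) {
      data.frame(term_id = tid, status = "filtered_by_size", rank = NA_integer_,
                 p_raw = NA_real_, p_adjusted = NA_real_,
                 set_size = unname(removed[tid]), stringsAsFactors = FALSE)
    } else {
      data.frame(term_id = tid, status = "absent_from_snapshot",
                 rank = NA_integer_, p_raw = NA_real_, p_adjusted = NA_real_,
                 set_size = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enrichment result as TSV
#'
#' @param results an `enrichment_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
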