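# Expression matrices and the DE pipeline:
# global-median probe filter -> natural log -> two-sample t -> Bonferroni.

#' Construct an expression matrix object
#'
#' @param values numeric probe-by-sample matrix with row and column names.
#' @param group_labels named character vector mapping each sample id to
#'   `"case"` or `"control"`.
#' @param probe_gene_map named character vector mapping probe id to gene id
#'   (possibly many probes to one gene); probes without a mapping may be
#'   present and are tallied when gene lists are formed.
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, group_labels, probe_gene_map = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must all be finite")
  missing <- setdiff(colnames(values), names(group_labels))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(group_labels), c("case", "control"))
  if (length(bad)) stop("group labels must be 'case'/'control', got: ",
                        paste(bad, collapse = ", "))
  structure(list(values = values,
                 group_labels = group_labels[colnames(values)],
                 probe_gene_map = probe_gene_map),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group_labels == "case"), sum(x$group_labels == "control")))
  invisible(x)
}

#' Parse a probe-by-sample expression matrix
#'
#' The `tsv` dialect expects a header row of sample ids and probe ids in the
#' first column; group labels are supplied separately. The `soft` dialect
#' reads the table section of a GEO GDS SOFT file (columns `ID_REF`,
#' `IDENTIFIER`, then one column per GSM sample) and derives group labels
#' from its `^subset` blocks via the supplied subset descriptions.
#'
#' @param source path, connection, or character vector of lines.
#' @param dialect `"tsv"` or `"soft"`.
#' @param group_labels (tsv) named character vector sample -> case/control.
#' @param case_subsets,control_subsets (soft) `!subset_description` values
#'   whose samples form the case / control groups; samples in neither are
#'   dropped.
#' @param probe_gene_map optional named character vector probe -> gene. For
#'   the soft dialect, when omitted, the `IDENTIFIER` column is used.
#' @return an `expr_matrix`.
#' @export
parse_matrix <- function(source, dialect = c("tsv", "soft"),
                         group_labels = NULL, case_subsets = NULL,
                         control_subsets = NULL, probe_gene_map = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(source)
  if (dialect == "soft")
    return(parse_matrix_soft(lines, case_subsets, control_subsets,
                             probe_gene_map))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty expression table", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  ncol_expect <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncol_expect))
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 which(widths != ncol_expect)[1] + 1L,
                 widths[widths != ncol_expect][1], ncol_expect), call. = FALSE)
  probes <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(probes))
    stop("duplicate probe id: ", probes[duplicated(probes)][1], call. = FALSE)
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric value '%s' for probe %s",
                   f[-1][which(is.na(v))[1]], f[1]), call. = FALSE)
    v
  }, numeric(length(samples)))
  m <- t(matrix(vals, nrow = length(samples),
                dimnames = list(samples, probes)))
  if (is.null(group_labels))
    stop("tsv dialect requires group_labels", call. = FALSE)
  expression_matrix(m, group_labels, probe_gene_map)
}

parse_matrix_soft <- function(lines, case_subsets, control_subsets,
                              probe_gene_map) {
  if (is.null(case_subsets) || is.null(control_subsets))
    stop("soft dialect requires case_subsets and control_subsets",
         call. = FALSE)
  # subset blocks
  subset_desc <- NA_character_
  subsets <- list()
  for (ln in lines) {
    if (grepl("^!subset_description\\s*=", ln))
      subset_desc <- trimws(sub("^!subset_description\\s*=", "", ln))
    if (grepl("^!subset_sample_id\\s*=", ln)) {
      ids <- trimws(strsplit(sub("^!subset_sample_id\\s*=", "", ln),
                             ",", fixed = TRUE)[[1]])
      subsets[[length(subsets) + 1L]] <- list(desc = subset_desc, ids = ids)
    }
  }
  labels <- character(0)
  for (s in subsets) {
    lab <- if (s$desc %in% case_subsets) "case"
           else if (s$desc %in% control_subsets) "control" else NA_character_
    if (!is.na(lab)) labels[s$ids] <- lab
  }
  if (!length(labels))
    stop("no subset matched the given case/control descriptions",
         call. = FALSE)
  begin <- which(grepl("^!dataset_table_begin", lines))
  end <- which(grepl("^!dataset_table_end", lines))
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("empty or missing SOFT data table section", call. = FALSE)
  tbl <- lines[(begin + 1L):(end - 1L)]
  fields <- strsplit(tbl, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_cols <- which(startsWith(header, "GSM"))
  body <- fields[-1]
  probes <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(probes))
    stop("duplicate probe id: ", probes[duplicated(probes)][1], call. = FALSE)
  ident <- if ("IDENTIFIER" %in% header)
    setNames(vapply(body, `[`, character(1), which(header == "IDENTIFIER")),
             probes) else NULL
  keep_samples <- header[sample_cols][header[sample_cols] %in% names(labels)]
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[sample_cols]))
    v
  }, numeric(length(sample_cols)))
  m <- t(matrix(vals, nrow = length(sample_cols),
                dimnames = list(header[sample_cols], probes)))
  # drop probes with any unparseable/missing value (GDS "null" cells)
  ok <- rowSums(!is.finite(m[, keep_samples, drop = FALSE])) == 0L
  m <- m[ok, keep_samples, drop = FALSE]
  if (!nrow(m)) stop("no probe with complete numeric values", call. = FALSE)
  if (is.null(probe_gene_map) && !is.null(ident)) probe_gene_map <- ident
  expression_matrix(m, labels, probe_gene_map)
}

#' Read a two-column probe-to-gene mapping table
#'
#' @param source path to a headerless (or headered) two-column TSV:
#'   probe id, gene id.
#' @return named character vector probe -> gene.
#' @export
read_probe_map <- function(source) {
  lines <- read_text_lines(source)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "probe_id"))
    fields <- fields[-1]
  setNames(vapply(fields, `[`, character(1), 2),
           vapply(fields, `[`, character(1), 1))
}

#' Remove low-intensity probes by the global-median rule
#'
#' Computes the median M over every value in the grid (all probes, all
#' samples) and removes probes whose maximum across samples is strictly less
#' than M; a probe whose maximum equals M is kept. Probe order is preserved.
#'
#' @param matrix an `expr_matrix`.
#' @return the filtered `expr_matrix`; removing every probe is an error.
#' @export
filter_probes <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (!nrow(v)) stop("empty expression matrix", call. = FALSE)
  M <- stats::median(v)
  keep <- apply(v, 1L, max) >= M
  if (!any(keep))
    stop("global-median probe filter removed every probe", call. = FALSE)
  out <- matrix
  out$values <- v[keep, , drop = FALSE]
  out
}

#' Natural-log transform of every expression value
#'
#' @param matrix an `expr_matrix` with strictly positive values, unless a
#'   positive `floor` is supplied to which values `<= 0` are clipped first.
#' @param floor optional positive clip value for non-positive entries.
#' @return the transformed `expr_matrix` (same dimensions).
#' @export
log_transform <- function(matrix, floor = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (any(v <= 0)) {
    if (is.null(floor)) {
      idx <- which(v <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "non-positive value at probe %s, sample %s; supply a positive floor",
        rownames(v)[idx[1]], colnames(v)[idx[2]]), call. = FALSE)
    }
    stopifnot(floor > 0)
    v[v <= 0] <- floor
  }
  out <- matrix
  out$values <- log(v)
  out
}

#' Per-probe two-sample t-test and Bonferroni-corrected DE gene list
#'
#' Runs an independent two-sided two-sample t-test per probe between case and
#' control samples (pooled-variance Student by default; Welch via
#' `var_equal = FALSE`), Bonferroni-corrects over the probes tested, and
#' calls a gene differentially expressed when any of its probes is
#' significant (best-probe rule; `aggregate = "all_probes"` requires every
#' probe of the gene to pass).
#'
#' @param matrix an `expr_matrix`, already probe-filtered and log-scaled.
#' @param alpha significance level applied to the Bonferroni-corrected
#'   p-value (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @param aggregate probe-to-gene rule, `"best_probe"` or `"all_probes"`.
#' @return a `de_result`: list with `table` (data.frame probe_id, gene_id, t,
#'   p_raw, p_bonferroni, is_de), `de_genes` (sorted character vector),
#'   `n_tests`, and `n_unmapped_probes`. A probe with zero variance in both
#'   groups and equal group means carries t = 0, p = 1.
#' @export
differential_expression <- function(matrix, alpha = 0.05, var_equal = TRUE,
                                    aggregate = c("best_probe", "all_probes")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  aggregate <- match.arg(aggregate)
  v <- matrix$values
  grp <- matrix$group_labels
  case <- v[, grp == "case", drop = FALSE]
  ctrl <- v[, grp == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (case=", n1,
         ", control=", n2, ")", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  s1 <- apply(case, 1L, stats::var); s2 <- apply(ctrl, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(v))
  } else {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  t_stat <- diff / se
  p_raw <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  # degenerate probes: zero spread in both groups
  degenerate <- se == 0
  t_stat[degenerate & diff == 0] <- 0
  p_raw[degenerate & diff == 0] <- 1
  t_stat[degenerate & diff != 0] <- sign(diff[degenerate & diff != 0]) * Inf
  p_raw[degenerate & diff != 0] <- 0

  n_tests <- nrow(v)
  p_bonf <- pmin(1, n_tests * p_raw)
  map <- matrix$probe_gene_map
  gene <- if (is.null(map)) rep(NA_character_, nrow(v)) else
    unname(map[rownames(v)])
  tab <- data.frame(probe_id = rownames(v), gene_id = gene, t = t_stat,
                    p_raw = p_raw, p_bonferroni = p_bonf,
                    is_de = p_bonf < alpha, stringsAsFactors = FALSE,
                    row.names = NULL)
  mapped <- tab[!is.na(tab$gene_id), , drop = FALSE]
  de_genes <- if (aggregate == "best_probe") {
    sort(unique(mapped$gene_id[mapped$is_de]))
  } else {
    all_pass <- tapply(mapped$is_de, mapped$gene_id, all)
    sort(names(all_pass)[all_pass])
  }
  structure(list(table = tab, de_genes = de_genes, n_tests = n_tests,
                 n_unmapped_probes = sum(is.na(gene)), alpha = alpha),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "de_result: %d probes tested, %d DE genes at Bonferroni alpha %.3g (%d unmapped probes)\n",
    x$n_tests, length(x$de_genes), x$alpha, x$n_unmapped_probes))
  invisible(x)
}

#' Write a DE result table as TSV
#'
#' @param de a `de_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_result <- function(de, path) {
  utils::write.table(de$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
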