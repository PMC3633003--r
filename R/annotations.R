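# GAF parsing and annotation filtering (evidence, qualifier, aspect, date).

#' Parse a GAF gene-association file
#'
#' Accepts GAF 1.0 (15-column) and 2.x (17-column) tab-delimited text.
#' Columns consumed (1-based): 2 gene id, 3 gene symbol, 4 qualifier,
#' 5 GO term id, 7 evidence code, 9 aspect, 14 date (YYYYMMDD). The
#' qualifier is negated iff it contains the token `NOT` (e.g.
#' `NOT|involved_in`). Lines beginning with `!` are comments.
#'
#' @param source path (gzip transparently supported), connection, or
#'   character vector of lines.
#' @param snapshot_label free-text label for this annotation snapshot.
#' @param strict if `TRUE`, any malformed line (fewer than 15 columns, bad GO
#'   id, bad date) is a hard error; otherwise such lines are dropped and
#'   collected into the parse report.
#' @return a `go_annotations` object: a list with `records` (data.frame with
#'   columns gene_id, gene_symbol, term_id, qualifier_negated, evidence_code,
#'   aspect, date), `snapshot_label`, and `parse_report` (data.frame of
#'   line/message pairs for rejected lines).
#' @export
parse_gaf <- function(source, snapshot_label = NULL, strict = FALSE) {
  lines <- read_text_lines(source)
  if (is.null(snapshot_label)) {
    snapshot_label <- if (is.character(source) && length(source) == 1L &&
                          file.exists(source)) basename(source) else ""
  }
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  bad <- list()
  note_bad <- function(i, msg) {
    if (strict) stop(sprintf("GAF line %d: %s", i, msg), call. = FALSE)
    bad[[length(bad) + 1L]] <<- data.frame(line = i, message = msg,
                                           stringsAsFactors = FALSE)
  }
  rows <- vector("list", length(body))
  for (j in seq_along(body)) {
    f <- strsplit(body[j], "\t", fixed = TRUE)[[1]]
    i <- lineno[j]
    if (length(f) < 15L) { note_bad(i, "fewer than 15 columns"); next }
    term_id <- f[5]; date_str <- f[14]
    if (!is_go_id(term_id)) {
      note_bad(i, sprintf("malformed GO id '%s'", term_id)); next
    }
    if (is.na(parse_gaf_date(date_str))) {
      note_bad(i, sprintf("malformed date '%s'", date_str)); next
    }
    rows[[j]] <- data.frame(
      gene_id = f[2], gene_symbol = f[3],
      term_id = term_id,
      qualifier_negated = "NOT" %in% strsplit(f[4], "|", fixed = TRUE)[[1]],
      evidence_code = f[7], aspect = f[9],
      date = as.integer(date_str), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows)) do.call(rbind, rows) else empty_gaf_records()
  report <- if (length(bad)) do.call(rbind, bad) else
    data.frame(line = integer(0), message = character(0))
  new_annotations(records, snapshot_label, parse_report = report)
}

empty_gaf_records <- function() {
  data.frame(gene_id = character(0), gene_symbol = character(0),
             term_id = character(0), qualifier_negated = logical(0),
             evidence_code = character(0), aspect = character(0),
             date = integer(0), stringsAsFactors = FALSE)
}

parse_gaf_date <- function(x) {
  if (!grepl("^[0-9]{8}$", x)) return(NA)
  d <- as.Date(x, format = "%Y%m%d")
  if (is.na(d)) NA else d
}

new_annotations <- function(records, snapshot_label,
                            parse_report = data.frame(line = integer(0),
                                                      message = character(0))) {
  rownames(records) <- NULL
  structure(list(records = records, snapshot_label = snapshot_label,
                 parse_report = parse_report),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf(
    "go_annotations '%s': %d records, %d genes, %d terms (%d rejected lines)\n",
    x$snapshot_label, nrow(x$records), length(unique(x$records$gene_id)),
    length(unique(x$records$term_id)), nrow(x$parse_report)))
  invisible(x)
}

#' Filter an annotation set by date, evidence, qualifier, and aspect
#'
#' Composes the filters conjunctively. The date cutoff is the reconstruction
#' device for historical annotation sets: keeping records dated on or before
#' `max_date` rebuilds the corpus as it stood at that date (ties at the
#' cutoff are included). Cumulative counts over increasing cutoffs are
#' therefore non-decreasing.
#'
#' @param annos a `go_annotations` object.
#' @param max_date optional cutoff, integer `YYYYMMDD` or anything coercible
#'   via [as.Date()]; records with `date <= max_date` are retained.
#' @param evidence_exclude optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`). The default keeps all codes, including IEA.
#' @param drop_negated drop `NOT`-qualified records (default `TRUE`): a
#'   negated annotation is evidence against set membership.
#' @param aspect optional single aspect in `{P, F, C}` to retain.
#' @return a filtered `go_annotations`; its `snapshot_label` records the
#'   cutoff when one was applied. An empty result is legal.
#' @export
filter_annotations <- function(annos, max_date = NULL,
                               evidence_exclude = NULL,
                               drop_negated = TRUE, aspect = NULL) {
  stopifnot(inherits(annos, "go_annotations"))
  r <- annos$records
  keep <- rep(TRUE, nrow(r))
  label <- annos$snapshot_label
  if (!is.null(max_date)) {
    cutoff <- as_yyyymmdd(max_date)
    keep <- keep & (r$date <= cutoff)
    label <- sprintf("%s<=%d", annos$snapshot_label, cutoff)
  }
  if (!is.null(evidence_exclude))
    keep <- keep & !(r$evidence_code %in% evidence_exclude)
  if (isTRUE(drop_negated))
    keep <- keep & !r$qualifier_negated
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("P", "F", "C"))
    keep <- keep & (r$aspect == aspect)
  }
  new_annotations(r[keep, , drop = FALSE], label, annos$parse_report)
}

as_yyyymmdd <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  if (inherits(x, "Date")) return(as.integer(format(x, "%Y%m%d")))
  if (is.character(x) && grepl("^[0-9]{8}$", x)) return(as.integer(x))
  as.integer(format(as.Date(x), "%Y%m%d"))
}

#' Write an annotation set as GAF 2.1
#'
#' Columns not modeled here (DB, taxon, assigned_by, ...) are filled with
#' fixed placeholders; the consumed columns round-trip through [parse_gaf()].
#'
#' @param annos a `go_annotations` object.
#' @param path output file path, or `NULL` to return lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_gaf <- function(annos, path = NULL) {
  r <- annos$records
  header <- c("!gaf-version: 2.1",
              sprintf("!snapshot: %s", annos$snapshot_label))
  lines <- if (nrow(r)) {
    paste("DB", r$gene_id, r$gene_symbol,
          ifelse(r$qualifier_negated, "NOT", ""),
          r$term_id, "GO_REF:0000000", r$evidence_code, "",
          r$aspect, "", "", "protein", "taxon:9606",
          sprintf("%08d", r$date), "goeval", "", "",
          sep = "\t")
  } else character(0)
  out <- c(header, lines)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
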