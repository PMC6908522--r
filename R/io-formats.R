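## External formats. All writers are deterministic: fixed ordering and
## 6-significant-digit numeric formatting, "." decimal separator, "NA" for
## missing, so the same object always produces a byte-identical file.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

#' Write an ExpressionStudy as expression + annotation TSV
#'
#' @param study an `ExpressionStudy`.
#' @param matrix_path path for the feature x sample matrix TSV (header row
#'   of sample labels, first column `feature`).
#' @param annotation_path path for the sample annotation TSV (columns
#'   `sample`, `group`, `disease_class`, `scale`).
#' @return invisibly, the two paths.
#' @export
write_expression_tsv <- function(study, matrix_path, annotation_path) {
  vals <- study$values
  lines <- c(
    paste(c("feature", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i)
      paste(c(rownames(vals)[i], fmt_num(vals[i, ])), collapse = "\t"),
      character(1))
  )
  writeLines(lines, matrix_path)
  ann <- c("sample\tgroup\tdisease_class\tscale",
           sprintf("%s\t%s\t%s\t%s", colnames(vals), unname(study$group),
                   study$disease_class, study$scale))
  writeLines(ann, annotation_path)
  invisible(c(matrix_path, annotation_path))
}

#' Read an ExpressionStudy from expression + annotation TSV files
#'
#' The matrix file has a header row of sample labels and feature labels in
#' the first column; the annotation file maps each sample to its group
#' (`control`/`case`) and optionally carries `disease_class` and `scale`.
#' Rows with unparseable cells are rejected with their line numbers.
#'
#' @param matrix_path,annotation_path file paths.
#' @param study_id study label; defaults to the matrix file stem.
#' @return an `ExpressionStudy`.
#' @export
read_expression_tsv <- function(matrix_path, annotation_path,
                                study_id = NULL) {
  raw <- readLines(matrix_path)
  if (length(raw) < 2) stop_format("'%s': no data rows", matrix_path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  nlens <- lengths(fields[-1])
  bad <- which(nlens != length(header)) + 1L
  if (length(bad))
    stop_format("'%s': malformed rows at lines %s", matrix_path,
                paste(head(bad, 5), collapse = ", "))
  feats <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(feats))
    stop_format("'%s': duplicate feature labels: %s", matrix_path,
                paste(head(unique(feats[duplicated(feats)]), 5), collapse = ", "))
  if (anyDuplicated(samples))
    stop_format("'%s': duplicate sample labels", matrix_path)
  cells <- t(vapply(fields[-1], function(f) f[-1], character(length(samples))))
  if (length(samples) == 1) cells <- matrix(cells, ncol = 1)
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = length(feats)))
  bad_rows <- which(apply(is.na(vals) & !(cells == "NA"), 1, any))
  if (length(bad_rows))
    stop_format("'%s': unparseable numeric cells at lines %s", matrix_path,
                paste(head(bad_rows + 1L, 5), collapse = ", "))
  dimnames(vals) <- list(feats, samples)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("sample", "group") %in% names(ann)))
    stop_format("'%s': annotation needs 'sample' and 'group' columns",
                annotation_path)
  missing <- setdiff(ann$sample, samples)
  if (length(missing))
    stop_format("sample not in matrix: %s", paste(missing, collapse = ", "))
  extra <- setdiff(samples, ann$sample)
  if (length(extra))
    stop_format("sample not in annotation: %s", paste(extra, collapse = ", "))
  grp <- ann$group[match(samples, ann$sample)]
  cls <- if ("disease_class" %in% names(ann)) ann$disease_class[1] else "LC"
  scl <- if ("scale" %in% names(ann)) ann$scale[1] else "raw"
  expression_study(study_id %||% sub("\\.[^.]*$", "", basename(matrix_path)),
                   cls, vals, grp, scale = scl)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene ...`.
#' Duplicate genes within a set are deduplicated; lines with fewer than
#' three fields are format errors.
#'
#' @param path GMT file path.
#' @return a named list of class `GeneSetCollection`; each element has
#'   `description` and `genes`.
#' @export
read_gmt <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "GeneSetCollection"))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop_format("'%s': GMT lines with fewer than 3 fields: %s", path,
                paste(head(short, 5), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop_format("'%s': duplicate set names: %s", path,
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_format("'%s': empty gene set '%s'", path, f[1])
    list(description = f[2], genes = genes)
  })
  names(sets) <- nm
  structure(sets, class = "GeneSetCollection")
}

#' Read a two-column probe-to-gene mapping
#'
#' Probes mapping to empty or `"NA"` symbols are dropped (their count is
#' reported in attribute `n_dropped`); duplicate probe rows with
#' conflicting symbols are an error.
#'
#' @param path two-column TSV (probe, symbol), no header required; a
#'   header line `probe<TAB>...` is skipped if present.
#' @return named character vector probe -> gene symbol.
#' @export
read_probe_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop_format("'%s': probe map needs 2 columns", path)
  if (nrow(tab) && tolower(tab[1, 1]) %in% c("probe", "probe_id")) tab <- tab[-1, , drop = FALSE]
  probe <- tab[[1]]; sym <- tab[[2]]
  drop <- is.na(sym) | sym == "" | sym == "NA"
  n_dropped <- sum(drop)
  probe <- probe[!drop]; sym <- sym[!drop]
  dup <- unique(probe[duplicated(probe)])
  if (length(dup)) {
    conflict <- vapply(dup, function(p) length(unique(sym[probe == p])) > 1,
                       logical(1))
    if (any(conflict))
      stop_format("conflicting probe mappings: %s",
                  paste(dup[conflict], collapse = ", "))
    keep <- !duplicated(probe)
    probe <- probe[keep]; sym <- sym[keep]
  }
  structure(setNames(sym, probe), n_dropped = n_dropped)
}

#' Write a gene network to SIF, GraphML or edge-list TSV
#'
#' SIF uses the dialect `geneA<TAB>co<TAB>geneB`, one undirected edge
#' written once with endpoints in lexicographic order. GraphML carries
#' the selection threshold as a graph attribute and `|r|` edge weights.
#' Re-reading an edge-TSV with [read_edge_tsv()] reproduces the edge set
#' exactly.
#'
#' @param network a `GeneNetwork`.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @return invisibly, `path`.
#' @export
write_graph_file <- function(network, path, format = c("sif", "graphml", "edge_tsv")) {
  format <- match.arg(format)
  ed <- network$edges   # 2-column character matrix, canonical order
  ord <- if (nrow(ed)) order(ed[, 1], ed[, 2]) else integer(0)
  ed <- ed[ord, , drop = FALSE]
  w <- network$weights[ord]
  if (format == "sif") {
    lines <- if (nrow(ed)) sprintf("%s\tco\t%s", ed[, 1], ed[, 2]) else character(0)
    if (!nrow(ed) && length(network$nodes))
      lines <- sprintf("%s", sort(network$nodes))   # isolated node list
    writeLines(lines, path)
  } else if (format == "edge_tsv") {
    lines <- c("from\tto\tweight",
               if (nrow(ed)) sprintf("%s\t%s\t%s", ed[, 1], ed[, 2], fmt_num(w)))
    writeLines(lines, path)
  } else {
    g <- as_igraph(network)
    igraph::graph_attr(g, "threshold") <- network$threshold %||% NA_real_
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV written by [write_graph_file()]
#'
#' @param path edge TSV path (columns from, to, weight).
#' @return a `GeneNetwork` over the edge endpoints.
#' @export
read_edge_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab))
    return(gene_network(character(0),
                        matrix(character(0), 0, 2), numeric(0), NA_real_))
  gene_network(sort(unique(c(tab$from, tab$to))),
               cbind(tab$from, tab$to), as.numeric(tab$weight), NA_real_)
}

#' Write a data frame as a deterministic results TSV
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
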