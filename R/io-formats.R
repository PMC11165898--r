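## Readers and writers for the plain-text formats the pipeline touches:
## expression/groups/biotype TSVs, GMT gene sets, miRNA-target tables,
## SIF + edge-table network exports, and sorted-key JSON reports.
## Numeric cells are written with "%.17g" so write/read round trips are
## bit-exact for doubles.

fmt_num <- function(x) sprintf("%.17g", x)

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path)
}

#' Read an expression dataset from TSV files
#'
#' The expression TSV has a `gene_id` first column and one column per sample;
#' the biotype TSV has columns `gene_id`, `biotype`; the groups TSV has
#' columns `sample_id`, `group`. Gene and sample order is preserved from the
#' expression file. Validation errors name the offending ids or cells.
#'
#' @param expr_path,biotype_path,groups_path file paths.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(expr_path, biotype_path, groups_path) {
  lines <- read_tsv_lines(expr_path)
  if (length(lines) < 2) stop("expression file has no data rows: ", expr_path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "gene_id")
    stop("expression header must start with 'gene_id': ", expr_path)
  samples <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, "", 1)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene id(s) in ", expr_path, ": ",
         paste(dup, collapse = ", "))
  values <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    if (length(cells) != length(samples))
      stop("row ", i + 1, " of ", expr_path, " has ", length(cells),
           " values, expected ", length(samples))
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v))
      stop("non-numeric cell at row ", i + 1, ", column ",
           which(is.na(v))[1] + 1, " of ", expr_path)
    values[i, ] <- v
  }

  bt <- utils::read.delim(biotype_path, header = TRUE,
                          colClasses = "character")
  if (!all(c("gene_id", "biotype") %in% names(bt)))
    stop("biotype file needs columns gene_id, biotype: ", biotype_path)
  biotype <- stats::setNames(bt$biotype, bt$gene_id)

  gr <- utils::read.delim(groups_path, header = TRUE,
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(gr)))
    stop("groups file needs columns sample_id, group: ", groups_path)
  group <- stats::setNames(gr$group, gr$sample_id)

  expression_dataset(values, biotype, group)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]; values are written with 17 significant
#' digits so the round trip is bit-exact.
#'
#' @param dataset an [expression_dataset()].
#' @param expr_path,biotype_path,groups_path output paths; a biotype or
#'   groups path of `NULL` skips that file.
#' @return Invisibly, `expr_path`.
#' @export
write_expression <- function(dataset, expr_path, biotype_path = NULL,
                             groups_path = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, expr_path)
  if (!is.null(biotype_path))
    writeLines(c("gene_id\tbiotype",
                 paste(names(dataset$biotype), dataset$biotype, sep = "\t")),
               biotype_path)
  if (!is.null(groups_path))
    writeLines(c("sample_id\tgroup",
                 paste(names(dataset$group), dataset$group, sep = "\t")),
               groups_path)
  invisible(expr_path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...` (at least three fields).
#'
#' @param path GMT file path.
#' @return A named list of sets; each element is a list with `description`
#'   and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " (need >= 3 fields): ", path)
    if (f[1] %in% names(sets))
      stop("duplicated set name '", f[1], "' at GMT line ", i)
    sets[[f[1]]] <- list(description = f[2], genes = f[-(1:2)])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors (or of lists with a `genes`
#'   element).
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to `"na"`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    genes <- if (is.list(sets[[nm]])) sets[[nm]]$genes else sets[[nm]]
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns `mirna_id`, `target_id`, `source` (a local stand-in for
#' database intersections). Duplicate (mirna, target) pairs are merged, with
#' sources concatenated by `";"`.
#'
#' @param path file path.
#' @return data.frame with columns mirna_id, target_id, source.
#' @export
read_mir_targets <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("mirna_id", "target_id", "source") %in% names(tb)))
    stop("miRNA-target file needs columns mirna_id, target_id, source: ",
         path)
  key <- paste(tb$mirna_id, tb$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    src <- vapply(split(tb$source, key), function(s)
      paste(sort(unique(s)), collapse = ";"), "")
    tb <- tb[!duplicated(key), ]
    tb$source <- src[paste(tb$mirna_id, tb$target_id, sep = "\r")]
  }
  rownames(tb) <- NULL
  tb[c("mirna_id", "target_id", "source")]
}

#' @rdname read_mir_targets
#' @param table data.frame with columns mirna_id, target_id, source.
#' @export
write_mir_targets <- function(table, path) {
  writeLines(c("mirna_id\ttarget_id\tsource",
               paste(table$mirna_id, table$target_id, table$source,
                     sep = "\t")),
             path)
  invisible(path)
}

canonical_edges <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

#' Write a network in SIF (simple interaction format)
#'
#' Lines are `idA<TAB>interaction<TAB>idB`; undirected edges are emitted once
#' with the lexicographically smaller id first, sorted, then isolated nodes
#' as bare ids.
#'
#' @param network a network object with `edges` (data.frame with columns
#'   `a`, `b`, optionally `interaction`) and `nodes` (character), e.g. from
#'   [build_network()] or [assemble_cerna_graph()].
#' @param path output path.
#' @param interaction default interaction label for edges lacking one.
#' @return Invisibly, `path`.
#' @export
write_network_sif <- function(network, path, interaction = "co_expression") {
  e <- network$edges
  lab <- if ("interaction" %in% names(e)) e$interaction
    else rep(interaction, nrow(e))
  ce <- canonical_edges(e$a, e$b)
  lines <- unique(paste(ce$a, lab, ce$b, sep = "\t"))
  lines <- sort(lines)
  isolated <- sort(setdiff(network$nodes, c(ce$a, ce$b)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a SIF file back into an edge list
#'
#' @param path SIF path.
#' @return list with `nodes` (character) and `edges` (data.frame `a`,
#'   `interaction`, `b`).
#' @export
read_sif <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(!n %in% c(1L, 3L))
  if (length(bad))
    stop("malformed SIF line ", bad[1], " in ", path)
  ed <- parts[n == 3L]
  edges <- data.frame(
    a = vapply(ed, `[[`, "", 1),
    interaction = vapply(ed, `[[`, "", 2),
    b = vapply(ed, `[[`, "", 3),
    stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b,
                         vapply(parts[n == 1L], `[[`, "", 1))))
  list(nodes = nodes, edges = edges)
}

#' Write a network edge table with correlation statistics
#'
#' TSV columns `a`, `b`, `pcc`, `p`, canonicalized (smaller id first) and
#' sorted; full numeric precision.
#'
#' @param network object with an `edges` data.frame holding columns `a`,
#'   `b`, `pcc`, `p`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(network, path) {
  e <- network$edges
  if (nrow(e)) {
    ce <- canonical_edges(e$a, e$b)
    e$a <- ce$a; e$b <- ce$b
    e <- e[order(e$a, e$b), ]
  }
  writeLines(c("a\tb\tpcc\tp",
               if (nrow(e)) paste(e$a, e$b, fmt_num(e$pcc), fmt_num(e$p),
                                  sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  tb <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  if (!all(c("a", "b", "pcc", "p") %in% names(tb)))
    stop("edge table needs columns a, b, pcc, p: ", path)
  tb
}

## recursively alphabetize list keys for schema-stable JSON
sort_keys <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else x
}

#' Write a schema-stable JSON report
#'
#' Keys are sorted recursively; numbers keep full precision; scalars are
#' unboxed. Identical inputs produce byte-identical files.
#'
#' @param results a (possibly nested) list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(results, path) {
  jsonlite::write_json(sort_keys(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
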