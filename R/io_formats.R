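#' Construct a pathway collection
#'
#' A pathway collection is an ordered set of named gene sets (KEGG-style
#' pathways): for each entry a pathway id, a free-text description, and the
#' member gene ids.  Gene ids are opaque strings; duplicates within one
#' pathway are collapsed.
#'
#' @param ids character vector of unique pathway ids.
#' @param descriptions character vector, same length as `ids`.
#' @param genes list of character vectors of member gene ids, one per
#'   pathway; each must be non-empty.
#' @return An object of class `pathway_collection` with fields `ids`,
#'   `descriptions` and `genes` (a named list keyed by pathway id).
#' @export
pathway_collection <- function(ids = character(), descriptions = character(),
                               genes = list()) {
  ids <- as.character(ids)
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(ids) || length(genes) != length(ids)) {
    stop("ids, descriptions and genes must have equal length")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- lapply(genes, as.character)
  if (length(genes) && any(lengths(genes) == 0L)) {
    stop("every pathway must have at least one member gene")
  }
  genes <- lapply(genes, unique)
  names(genes) <- ids
  structure(list(ids = ids, descriptions = descriptions, genes = genes),
            class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$ids)

#' @export
`[.pathway_collection` <- function(x, i) {
  pathway_collection(x$ids[i], x$descriptions[i], x$genes[i])
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection with", length(x), "gene set(s)\n")
  if (length(x)) {
    n <- lengths(x$genes)
    cat("  sizes:", min(n), "-", max(n), "genes\n")
    show <- utils::head(x$ids, 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read a genes-by-experiments expression matrix from TSV
#'
#' Expects a tab-separated file whose first row is a header (a label cell
#' followed by experiment ids) and whose remaining rows are a gene id
#' followed by numeric expression values.  Empty cells and the literal
#' tokens `NA`/`NaN` are read as missing; genes carrying missing values can
#' later be removed with [drop_incomplete_genes()].
#'
#' @param path path to the file.
#' @return A numeric matrix with gene ids as row names and experiment ids
#'   as column names.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[[1L]])) {
    stop("expression file has no header row: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  experiment_ids <- header[-1L]
  if (length(experiment_ids) == 0L) {
    stop("expression header contains no experiment ids")
  }
  if (anyDuplicated(experiment_ids)) {
    stop("duplicate experiment id: ",
         paste(unique(experiment_ids[duplicated(experiment_ids)]),
               collapse = ", "))
  }
  body <- fields[-1L]
  # trailing blank line from final newline is tolerated
  if (length(body) && identical(body[[length(body)]], "")) {
    body <- body[-length(body)]
  }
  n_genes <- length(body)
  values <- matrix(NA_real_, nrow = n_genes, ncol = length(experiment_ids))
  gene_ids <- character(n_genes)
  for (i in seq_len(n_genes)) {
    f <- body[[i]]
    if (length(f) != length(header)) {
      stop("ragged row at line ", i + 1L, ": expected ", length(header),
           " fields, found ", length(f))
    }
    gene_ids[i] <- f[[1L]]
    cells <- f[-1L]
    v <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(v) & !(cells %in% c("", "NA", "NaN")))
    if (length(bad)) {
      stop("non-numeric value '", cells[bad[1L]], "' at line ", i + 1L,
           " (gene ", gene_ids[i], "), column ", experiment_ids[bad[1L]])
    }
    values[i, ] <- v
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, experiment_ids)
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; values are written with 15
#' significant digits so a round trip reproduces them to well below 1e-12
#' relative error.  Missing values are written as empty cells.
#'
#' @param expr numeric matrix with gene row names and experiment column
#'   names.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  fmt <- function(v) {
    s <- sprintf("%.15g", v)
    s[is.na(v)] <- ""
    s
  }
  rows <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], fmt(expr[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("gene_id", colnames(expr)), collapse = "\t"), rows),
             con, sep = "\n")
  invisible(path)
}

# Validate the expression-matrix contract: numeric matrix, unique non-empty
# gene and experiment ids.
as_expression_matrix <- function(expr) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene row names and experiment column names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate experiment ids in expression matrix")
  if (any(!is.na(expr) & !is.finite(expr))) {
    stop("expression matrix contains non-finite values")
  }
  expr
}

#' Drop genes with any missing expression value
#'
#' @param expr expression matrix (genes x experiments).
#' @param verbose emit a message with the number of genes dropped.
#' @return The matrix restricted to complete genes.
#' @export
drop_incomplete_genes <- function(expr, verbose = TRUE) {
  expr <- as_expression_matrix(expr)
  keep <- stats::complete.cases(expr)
  if (verbose && any(!keep)) {
    message(sum(!keep), " gene(s) dropped for missing values")
  }
  expr[keep, , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  File order is
#' preserved; duplicate genes within one set are collapsed with a warning.
#'
#' @param path path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(pathway_collection())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway name: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-c(1L, 2L)])
  ndup <- sum(vapply(genes, function(g) sum(duplicated(g)), integer(1)))
  if (ndup > 0L) {
    warning(ndup, " duplicate gene id(s) collapsed within pathway(s)")
  }
  pathway_collection(ids, descriptions, genes)
}

#' Write gene sets in GMT format
#'
#' @param pathways a [pathway_collection()].
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  rows <- vapply(seq_along(pathways$ids), function(i) {
    paste(c(pathways$ids[i], pathways$descriptions[i], pathways$genes[[i]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a gene list (one id per line)
#'
#' Blank lines and lines starting with `#` are ignored; duplicates are
#' collapsed with a warning.
#'
#' @param path path to the file.
#' @return Character vector of unique gene ids, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("no gene ids found in ", path)
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicate gene id(s) collapsed in ", path)
    ids <- unique(ids)
  }
  ids
}

#' Write a gene list, one id per line
#'
#' @param genes character vector of gene ids.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(genes), con, sep = "\n")
  invisible(path)
}

#' Write a pathway screen table as TSV
#'
#' Serialises the output of [screen_pathways()].  Real statistics are
#' printed with 4 decimal places, p/q-values in scientific notation and
#' representative genes comma-joined, mirroring the screen report layout
#' (pathway, gene count, r, p, S_a, S_b, representative genes).
#'
#' @param records data frame of screen records (see [screen_pathways()]).
#' @param path output path.
#' @export
write_screen_table <- function(records, path) {
  cols <- c("pathway", "n_genes", "r", "p_value", "S_a", "S_b",
            "representative_genes", "q_value", "passed")
  missing_cols <- setdiff(c("pathway", "n_genes", "r", "p_value", "S_a", "S_b",
                            "representative_genes"), names(records))
  if (length(missing_cols)) {
    stop("screen records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"q_value" %in% names(records)) records$q_value <- NA_real_
  if (!"passed" %in% names(records)) records$passed <- NA
  f4 <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  fe <- function(v) ifelse(is.na(v), "NA", sprintf("%.4e", v))
  rows <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[i] <- paste(c(
      records$pathway[i],
      as.character(records$n_genes[i]),
      f4(records$r[i]),
      fe(records$p_value[i]),
      f4(records$S_a[i]),
      f4(records$S_b[i]),
      records$representative_genes[i],
      fe(records$q_value[i]),
      ifelse(is.na(records$passed[i]), "NA",
             ifelse(records$passed[i], "TRUE", "FALSE"))
    ), collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), rows), con, sep = "\n")
  invisible(path)
}

#' Write a coexpression network as a TSV edge list
#'
#' Columns: source, target, r, source_class, target_class.  Edges are
#' written in lexicographic order by source then target so identical
#' networks serialise byte-identically.
#'
#' @param network a `coexpression_network` (see
#'   [bipartite_pearson_network()]).
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  e <- network$edges
  cls <- stats::setNames(network$nodes$class, network$nodes$gene)
  header <- "source\ttarget\tr\tsource_class\ttarget_class"
  if (nrow(e)) {
    e <- e[order(e$source, e$target, method = "radix"), , drop = FALSE]
    rows <- paste(e$source, e$target, sprintf("%.15g", e$r),
                  cls[e$source], cls[e$target], sep = "\t")
  } else {
    rows <- character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Write an enrichment table as TSV
#'
#' @param rows data frame from [hypergeometric_enrichment()].
#' @param path output path.
#' @export
write_enrichment_table <- function(rows, path) {
  cols <- c("pathway", "hit_count", "pathway_size", "background_size",
            "p_value", "q_value", "genes")
  stopifnot(all(cols %in% names(rows)))
  fe <- function(v) ifelse(is.na(v), "NA", sprintf("%.4e", v))
  body <- paste(rows$pathway, rows$hit_count, rows$pathway_size,
                rows$background_size, fe(rows$p_value), fe(rows$q_value),
                rows$genes, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}
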