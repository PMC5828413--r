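new_coexpression_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$class == "disease"), "disease /",
      sum(x$nodes$class == "metabolic"), "metabolic ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Bipartite Pearson coexpression network
#'
#' The single-gene baseline: correlates every disease gene with every
#' metabolic (pathway) gene across experiments and keeps the pairs whose
#' Pearson r clears the threshold — `r > r_min` in `"signed"` mode,
#' `|r| > r_min` in `"absolute"` mode.  Genes appearing in both lists are
#' kept on the disease side and dropped from the metabolic side with a
#' warning, so the graph is strictly bipartite.
#'
#' @param expr expression matrix (genes x experiments).
#' @param disease character vector of disease gene ids.
#' @param metabolic character vector of metabolic/pathway gene ids.
#' @param r_min correlation threshold (default 0.6).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Object of class `coexpression_network`: `nodes` (gene, class)
#'   and `edges` (source = disease gene, target = metabolic gene, r at
#'   full precision).
#' @export
bipartite_pearson_network <- function(expr, disease, metabolic, r_min = 0.6,
                                      mode = c("signed", "absolute")) {
  expr <- as_expression_matrix(expr)
  mode <- match.arg(mode)
  d <- intersect(as.character(disease), rownames(expr))
  m <- intersect(as.character(metabolic), rownames(expr))
  overlap <- intersect(d, m)
  if (length(overlap)) {
    warning(length(overlap),
            " gene(s) in both lists kept as disease nodes only")
    m <- setdiff(m, overlap)
  }
  if (!length(d)) stop("no usable disease genes in the compendium")
  if (!length(m)) stop("no usable metabolic genes in the compendium")
  drop_const <- function(ids) {
    s <- apply(expr[ids, , drop = FALSE], 1L, stats::sd)
    if (any(s == 0)) {
      warning(sum(s == 0), " constant gene(s) excluded from the network")
    }
    ids[s > 0]
  }
  d <- drop_const(d)
  m <- drop_const(m)
  if (!length(d)) stop("no usable disease genes in the compendium")
  if (!length(m)) stop("no usable metabolic genes in the compendium")
  R <- stats::cor(t(expr[d, , drop = FALSE]), t(expr[m, , drop = FALSE]))
  hit <- if (mode == "signed") R > r_min else abs(R) > r_min
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(source = d[idx[, 1L]], target = m[idx[, 2L]],
                      r = R[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(gene = c(d, m),
                      class = c(rep("disease", length(d)),
                                rep("metabolic", length(m))),
                      stringsAsFactors = FALSE)
  new_coexpression_network(nodes, edges)
}

#' Connected components of a coexpression network
#'
#' Isolated nodes are excluded; components are returned largest first,
#' ties broken by the lexicographically smallest member gene id.
#'
#' @param net a `coexpression_network`.
#' @return List of `coexpression_network` objects, one per component.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!nrow(net$edges)) return(list())
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  cls <- stats::setNames(net$nodes$class, net$nodes$gene)
  comps <- lapply(split(names(memb), memb), function(genes) {
    e <- net$edges[net$edges$source %in% genes | net$edges$target %in% genes,
                   , drop = FALSE]
    rownames(e) <- NULL
    genes <- sort(genes, method = "radix")
    new_coexpression_network(
      data.frame(gene = genes, class = unname(cls[genes]),
                 stringsAsFactors = FALSE), e)
  })
  sizes <- vapply(comps, function(cp) nrow(cp$nodes), integer(1))
  first_id <- vapply(comps, function(cp) cp$nodes$gene[1L], character(1))
  comps <- comps[order(-sizes, first_id, method = "radix")]
  names(comps) <- NULL
  comps
}

#' Hub genes of a connected component
#'
#' The "center" of a subnetwork: every node attaining the maximum degree,
#' in ascending gene-id order.
#'
#' @param component a connected `coexpression_network` with at least 2
#'   nodes.
#' @return Character vector of hub gene ids.
#' @export
hub_nodes <- function(component) {
  stopifnot(inherits(component, "coexpression_network"))
  if (nrow(component$nodes) < 2L) {
    stop("hub extraction needs a component with at least 2 nodes")
  }
  deg <- table(c(component$edges$source, component$edges$target))
  hubs <- names(deg)[deg == max(deg)]
  sort(hubs, method = "radix")
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' For each pathway, tests over-representation of its members in the query
#' gene list relative to a background universe: the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' pathway members in `|query|` draws from `|background|`.
#' Benjamini-Hochberg q-values are computed across pathways.
#'
#' @param query character vector of gene ids, a subset of `background`.
#' @param pathways a [pathway_collection()]; members are intersected with
#'   the background.
#' @param background character vector: the gene universe.
#' @return Data frame sorted by p-value: `pathway`, `hit_count`,
#'   `pathway_size`, `background_size`, `p_value`, `q_value`, `genes`
#'   (comma-joined hits).
#' @export
hypergeometric_enrichment <- function(query, pathways, background) {
  stopifnot(inherits(pathways, "pathway_collection"))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background gene universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop(length(outside), " query gene(s) not in the background universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(seq_along(pathways$ids), function(i) {
    members <- intersect(pathways$genes[[i]], background)
    hits <- intersect(members, query)
    k <- length(members)
    x <- length(hits)
    p <- stats::phyper(x - 1, k, n_bg - k, n_q, lower.tail = FALSE)
    data.frame(pathway = pathways$ids[i], hit_count = x, pathway_size = k,
               background_size = n_bg, p_value = p,
               genes = paste(sort(hits, method = "radix"), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), hit_count = integer(),
                      pathway_size = integer(), background_size = integer(),
                      p_value = numeric(), genes = character(),
                      stringsAsFactors = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway", "hit_count", "pathway_size", "background_size",
          "p_value", "q_value", "genes")]
}
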