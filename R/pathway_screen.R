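#' Screening thresholds for the pathway coexpression screen
#'
#' A pathway passes when its first canonical correlation, first-pair
#' p-value and both variance-extracted statistics clear the thresholds:
#' `r >= r_min`, `p <= p_max`, `S_a >= sa_min`, `S_b >= sb_min`.
#'
#' @param r_min minimum first canonical correlation, in \[0, 1\].
#' @param p_max maximum Bartlett p-value, in (0, 1\].
#' @param sa_min minimum pathway-side variance extracted, in \[0, 1\].
#' @param sb_min minimum disease-side variance extracted, in \[0, 1\].
#' @param min_pathway_genes minimum number of measured pathway genes
#'   (inclusive) for a pathway to enter the screen; at least 2.
#' @return Object of class `screen_thresholds`.
#' @seealso [threshold_preset()] for the published threshold sets.
#' @export
screen_thresholds <- function(r_min = 0.5, p_max = 0.001,
                              sa_min = 0.15, sb_min = 0.15,
                              min_pathway_genes = 10L) {
  if (r_min < 0 || r_min > 1) stop("r_min must lie in [0, 1]")
  if (p_max <= 0 || p_max > 1) stop("p_max must lie in (0, 1]")
  if (sa_min < 0 || sa_min > 1 || sb_min < 0 || sb_min > 1) {
    stop("sa_min and sb_min must lie in [0, 1]")
  }
  min_pathway_genes <- as.integer(min_pathway_genes)
  if (min_pathway_genes < 2L) stop("min_pathway_genes must be at least 2")
  structure(list(r_min = r_min, p_max = p_max, sa_min = sa_min,
                 sb_min = sb_min, min_pathway_genes = min_pathway_genes),
            class = "screen_thresholds")
}

#' Named threshold presets
#'
#' `"default"` is the shipped set (0.5, 0.001, 0.15, 0.15); `"methods"` is
#' the stricter set (0.6, 1e-5, 0.3, 0.15); `"results"` is
#' (0.5, 0.001, 0.2, 0.2).
#'
#' @param name one of `"default"`, `"methods"`, `"results"`.
#' @param min_pathway_genes passed through to [screen_thresholds()].
#' @return A `screen_thresholds` object.
#' @export
threshold_preset <- function(name, min_pathway_genes = 10L) {
  presets <- list(
    default = c(0.5, 0.001, 0.15, 0.15),
    methods = c(0.6, 1e-5, 0.3, 0.15),
    results = c(0.5, 0.001, 0.2, 0.2)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  }
  v <- presets[[name]]
  screen_thresholds(v[1], v[2], v[3], v[4], min_pathway_genes)
}

#' Restrict pathways to measured genes and apply a size filter
#'
#' Each pathway's member list is intersected with the genes present in the
#' expression matrix; pathways retaining fewer than `min_genes` members are
#' removed.  The dropped pathways and per-pathway removal counts are
#' attached as attribute `"dropped"`.
#'
#' @param pathways a [pathway_collection()].
#' @param expr expression matrix (genes x experiments).
#' @param min_genes minimum surviving member count (inclusive).
#' @return Filtered `pathway_collection`, file order preserved.
#' @export
filter_pathways <- function(pathways, expr, min_genes = 10L) {
  stopifnot(inherits(pathways, "pathway_collection"))
  expr <- as_expression_matrix(expr)
  measured <- rownames(expr)
  restricted <- lapply(pathways$genes, function(g) g[g %in% measured])
  n_kept <- lengths(restricted)
  keep <- n_kept >= min_genes
  dropped <- data.frame(pathway = pathways$ids[!keep],
                        n_members = lengths(pathways$genes)[!keep],
                        n_measured = n_kept[!keep])
  out <- pathway_collection(pathways$ids[keep], pathways$descriptions[keep],
                            restricted[keep])
  attr(out, "dropped") <- dropped
  out
}

#' Number of representative genes for a screened pathway
#'
#' The representative-gene count is the pathway size scaled by the
#' pathway-side variance extracted, rounded half away from zero:
#' `round(n_genes * S_a)`.  A pathway that passed the screen always reports
#' at least one representative gene.
#'
#' @param n_genes number of pathway genes used in the analysis.
#' @param s_a pathway-side variance extracted, in \[0, 1\].
#' @param passed whether the pathway passed screening (floors the count
#'   at 1).
#' @return Integer count, at most `n_genes`.
#' @export
representative_gene_count <- function(n_genes, s_a, passed = TRUE) {
  if (n_genes < 1L) stop("n_genes must be at least 1")
  if (is.na(s_a) || s_a < 0 || s_a > 1) stop("s_a must lie in [0, 1]")
  k <- as.integer(floor(n_genes * s_a + 0.5))
  if (isTRUE(passed)) k <- max(k, 1L)
  min(k, as.integer(n_genes))
}

#' Representative genes of a canonical pair
#'
#' Selects the `k` second-set genes with largest absolute first-pair
#' canonical coefficient (or, optionally, structure loading), ordered by
#' descending magnitude; ties broken by ascending gene id.
#'
#' @param result a [compute_cca()] result whose second set is the pathway.
#' @param pathway_gene_ids gene ids aligned with the second-set columns.
#' @param k number of genes to select (`k <= q`).
#' @param use rank genes by raw canonical `"coefficients"` (default) or by
#'   structure `"loadings"`.
#' @param pair canonical pair index (default 1).
#' @return Character vector of `k` gene ids.
#' @export
select_representative_genes <- function(result, pathway_gene_ids, k,
                                        use = c("coefficients", "loadings"),
                                        pair = 1L) {
  stopifnot(inherits(result, "cca_result"))
  use <- match.arg(use)
  pathway_gene_ids <- as.character(pathway_gene_ids)
  if (length(pathway_gene_ids) != result$q) {
    stop("pathway_gene_ids must have length q = ", result$q)
  }
  if (k > result$q) stop("k = ", k, " exceeds number of pathway genes ", result$q)
  score <- if (use == "coefficients") {
    result$BB[, pair]
  } else {
    structure_loadings(result)$r_2B[pair, ]
  }
  ord <- order(-abs(score), pathway_gene_ids, method = "radix")
  pathway_gene_ids[ord][seq_len(max(k, 0L))]
}

#' Screen every pathway against a disease gene set by CCA
#'
#' The central loop: for each pathway surviving [filter_pathways()], the
#' disease-set matrix M (experiments x disease genes) and pathway matrix N
#' (experiments x pathway genes) are extracted from the compendium,
#' z-scored, and decomposed with [compute_cca()]; first-pair significance
#' comes from [canonical_pvalues()] and the variance-extracted statistics
#' from [structure_loadings()] + [variance_extracted()] (`S_a` = pathway
#' side, `S_b` = disease side).  Records are sorted by descending first
#' canonical correlation, and Benjamini-Hochberg q-values are reported
#' (but never thresholded).
#'
#' Constant-expression genes are dropped per set with a warning; a pathway
#' whose decomposition fails is recorded as a failed row (NA statistics),
#' not an abort.
#'
#' @param expr expression matrix (genes x experiments), no missing values.
#' @param pathways a [pathway_collection()].
#' @param disease character vector of disease gene ids.
#' @param thresholds a [screen_thresholds()] object or preset name.
#' @param representative_by passed to [select_representative_genes()]
#'   (`"coefficients"` or `"loadings"`).
#' @param pair canonical pair index used for r, p, S_a, S_b (default 1).
#' @return Data frame of class `pathway_screen` with columns `pathway`,
#'   `n_genes`, `r`, `p_value`, `S_a`, `S_b`, `representative_genes`
#'   (comma-joined), `q_value`, `passed` and `error`.
#' @export
screen_pathways <- function(expr, pathways, disease,
                            thresholds = screen_thresholds(),
                            representative_by = c("coefficients", "loadings"),
                            pair = 1L) {
  expr <- as_expression_matrix(expr)
  if (anyNA(expr)) {
    stop("expression matrix contains missing values; ",
         "apply drop_incomplete_genes() first")
  }
  if (is.character(thresholds)) thresholds <- threshold_preset(thresholds)
  stopifnot(inherits(thresholds, "screen_thresholds"))
  representative_by <- match.arg(representative_by)

  disease <- as.character(disease)
  present <- disease %in% rownames(expr)
  if (any(!present)) {
    warning(sum(!present), " disease gene(s) absent from the compendium")
  }
  disease_use <- disease[present]
  M0 <- t(expr[disease_use, , drop = FALSE])
  const <- apply(M0, 2L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant disease gene(s) dropped")
    M0 <- M0[, !const, drop = FALSE]
    disease_use <- disease_use[!const]
  }
  if (length(disease_use) < 2L) {
    stop("fewer than 2 usable disease genes in the compendium")
  }
  Mz <- zscore_columns(M0)

  kept <- filter_pathways(pathways, expr, thresholds$min_pathway_genes)
  n_pw <- length(kept)
  rec <- data.frame(pathway = kept$ids,
                    n_genes = NA_integer_, r = NA_real_, p_value = NA_real_,
                    S_a = NA_real_, S_b = NA_real_,
                    representative_genes = NA_character_,
                    q_value = NA_real_, passed = FALSE,
                    error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_pw)) {
    genes <- kept$genes[[i]]
    res <- tryCatch({
      N0 <- t(expr[genes, , drop = FALSE])
      constN <- apply(N0, 2L, stats::sd) == 0
      if (any(constN)) {
        warning(sum(constN), " constant gene(s) dropped from pathway ",
                kept$ids[i])
        N0 <- N0[, !constN, drop = FALSE]
        genes <- genes[!constN]
      }
      if (length(genes) < 2L) stop("fewer than 2 usable pathway genes")
      Nz <- zscore_columns(N0)
      fit <- compute_cca(Mz, Nz)
      sig <- canonical_pvalues(fit$r, fit$n_obs, fit$p, fit$q)
      ld <- structure_loadings(fit)
      s_a <- variance_extracted(ld$r_2B, pair)
      s_b <- variance_extracted(ld$r_1A, pair)
      r1 <- fit$r[pair]
      pv <- sig$p_value[pair]
      passed <- (r1 >= thresholds$r_min) && (pv <= thresholds$p_max) &&
        (s_a >= thresholds$sa_min) && (s_b >= thresholds$sb_min)
      k <- representative_gene_count(length(genes), s_a, passed)
      reps <- select_representative_genes(fit, genes, k,
                                          use = representative_by, pair = pair)
      list(n_genes = length(genes), r = r1, p_value = pv, S_a = s_a,
           S_b = s_b, reps = paste(reps, collapse = ","), passed = passed,
           error = NA_character_)
    }, error = function(e) {
      list(n_genes = NA_integer_, r = NA_real_, p_value = NA_real_,
           S_a = NA_real_, S_b = NA_real_, reps = "", passed = FALSE,
           error = conditionMessage(e))
    })
    rec$n_genes[i] <- res$n_genes
    rec$r[i] <- res$r
    rec$p_value[i] <- res$p_value
    rec$S_a[i] <- res$S_a
    rec$S_b[i] <- res$S_b
    rec$representative_genes[i] <- res$reps
    rec$passed[i] <- res$passed
    rec$error[i] <- res$error
  }
  ok <- !is.na(rec$p_value)
  rec$q_value[ok] <- stats::p.adjust(rec$p_value[ok], method = "BH")
  ord <- order(-rec$r, rec$pathway, method = "radix", na.last = TRUE)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "thresholds") <- thresholds
  attr(rec, "dropped_pathways") <- attr(kept, "dropped")
  attr(rec, "disease_genes_used") <- disease_use
  class(rec) <- c("pathway_screen", "data.frame")
  rec
}
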