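#' Simulation parameters for a synthetic expression compendium
#'
#' Describes a latent-factor generative model: every disease gene, and every
#' gene of a "linked" pathway, loads a shared standard-normal factor with
#' strength `loading_strength`; genes of unlinked pathways load one private
#' factor per pathway; background genes are pure noise.  Gaussian noise of
#' standard deviation `noise_sd` is added to every gene.
#'
#' `loading_strength` may be a vector, in which case each signal gene loads
#' that many shared (or pathway-private) factors, one strength per factor.
#'
#' @param n_experiments number of experiments (columns); at least 2.
#' @param n_disease_genes number of disease susceptibility genes.
#' @param pathway_sizes integer vector of pathway gene counts.
#' @param linked_pathways indices (1-based) into `pathway_sizes` of the
#'   pathways sharing the disease factor.
#' @param loading_strength positive factor loading(s) `w`.
#' @param noise_sd positive noise standard deviation `sigma`.
#' @param n_background_genes unstructured noise genes appended to the
#'   compendium (default 100, giving network stages realistic sparsity).
#' @param seed integer seed; generation is fully reproducible.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_experiments, n_disease_genes, pathway_sizes,
                       linked_pathways = integer(), loading_strength = 1,
                       noise_sd = 1, n_background_genes = 100L, seed = 1L) {
  n_experiments <- as.integer(n_experiments)
  n_disease_genes <- as.integer(n_disease_genes)
  pathway_sizes <- as.integer(pathway_sizes)
  linked_pathways <- as.integer(linked_pathways)
  n_background_genes <- as.integer(n_background_genes)
  if (n_experiments < 2L) stop("n_experiments must be at least 2")
  if (n_disease_genes < 1L) stop("n_disease_genes must be positive")
  if (length(pathway_sizes) && any(pathway_sizes < 1L)) {
    stop("pathway_sizes must be positive")
  }
  if (length(linked_pathways) &&
      (any(linked_pathways < 1L) ||
       any(linked_pathways > length(pathway_sizes)))) {
    stop("linked_pathways must index into pathway_sizes (1-based)")
  }
  if (any(loading_strength <= 0)) stop("loading_strength must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_background_genes < 0L) stop("n_background_genes must be non-negative")
  structure(list(n_experiments = n_experiments,
                 n_disease_genes = n_disease_genes,
                 pathway_sizes = pathway_sizes,
                 linked_pathways = unique(linked_pathways),
                 loading_strength = as.numeric(loading_strength),
                 noise_sd = as.numeric(noise_sd),
                 n_background_genes = n_background_genes,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a synthetic expression compendium with planted coexpression
#'
#' Draws, per experiment, the shared factor(s) and one private factor (set)
#' per unlinked pathway, then builds each gene as `w . f + noise`.  Pathways
#' listed in `linked_pathways` share the disease factor, planting a known
#' canonical correlation between the disease set and exactly those
#' pathways; every other pathway is internally coexpressed but independent
#' of the disease set.
#'
#' @param params a [sim_params()] object.
#' @return List of class `synthetic_compendium` with elements
#'   `expression` (genes x experiments matrix), `pathways`
#'   (a [pathway_collection()]), `disease_genes` (character vector) and
#'   `truth` (linked pathway ids/indices, the theoretical gene-gene
#'   correlation `rho_gene` between two signal genes, and the seed).
#' @examples
#' sim <- generate_compendium(sim_params(100, 10, c(5, 5),
#'                                       linked_pathways = 1, seed = 7))
#' dim(sim$expression)
#' @export
generate_compendium <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)
  n <- params$n_experiments
  w <- params$loading_strength
  sigma <- params$noise_sd
  nf <- length(w)
  n_pw <- length(params$pathway_sizes)
  pw_ids <- sprintf("PW%02d", seq_len(n_pw))

  signal_gene <- function(fac) drop(fac %*% w) + stats::rnorm(n, 0, sigma)

  f_shared <- matrix(stats::rnorm(n * nf), n, nf)
  blocks <- list()
  gene_ids <- list()
  disease_ids <- sprintf("CAD%03d", seq_len(params$n_disease_genes))
  blocks$disease <- t(vapply(seq_len(params$n_disease_genes),
                             function(i) signal_gene(f_shared), numeric(n)))
  gene_ids$disease <- disease_ids

  pw_genes <- vector("list", n_pw)
  for (i in seq_len(n_pw)) {
    fac <- if (i %in% params$linked_pathways) {
      f_shared
    } else {
      matrix(stats::rnorm(n * nf), n, nf)
    }
    size <- params$pathway_sizes[i]
    pw_genes[[i]] <- sprintf("%s_G%03d", pw_ids[i], seq_len(size))
    blocks[[pw_ids[i]]] <- t(vapply(seq_len(size), function(g) signal_gene(fac),
                                    numeric(n)))
    gene_ids[[pw_ids[i]]] <- pw_genes[[i]]
  }
  if (params$n_background_genes > 0L) {
    blocks$background <- matrix(
      stats::rnorm(n * params$n_background_genes, 0, sigma),
      nrow = params$n_background_genes, ncol = n)
    gene_ids$background <- sprintf("BG%04d", seq_len(params$n_background_genes))
  }
  expr <- do.call(rbind, blocks)
  rownames(expr) <- unlist(gene_ids, use.names = FALSE)
  colnames(expr) <- sprintf("E%04d", seq_len(n))

  pathways <- pathway_collection(
    ids = pw_ids,
    descriptions = ifelse(seq_len(n_pw) %in% params$linked_pathways,
                          "synthetic pathway (linked)",
                          "synthetic pathway (unlinked)"),
    genes = pw_genes)
  truth <- list(linked_pathways = params$linked_pathways,
                linked_pathway_ids = pw_ids[params$linked_pathways],
                rho_gene = sum(w^2) / (sum(w^2) + sigma^2),
                seed = params$seed)
  structure(list(expression = expr, pathways = pathways,
                 disease_genes = disease_ids, truth = truth,
                 params = params),
            class = "synthetic_compendium")
}

#' @export
print.synthetic_compendium <- function(x, ...) {
  cat("synthetic compendium:", nrow(x$expression), "genes x",
      ncol(x$expression), "experiments\n")
  cat("  disease genes:", length(x$disease_genes),
      "| pathways:", length(x$pathways),
      "| linked:", if (length(x$truth$linked_pathway_ids))
        paste(x$truth$linked_pathway_ids, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Theoretical correlation between two factor-sharing genes
#'
#' For genes `x = w1 f + e1`, `y = w2 f + e2` with a shared unit-variance
#' factor and independent Gaussian noise of sd `sigma`, the population
#' Pearson correlation is `w1 w2 / sqrt((w1^2 + sigma^2)(w2^2 + sigma^2))`.
#'
#' @param w1,w2 factor loadings of the two genes.
#' @param sigma positive noise standard deviation.
#' @return The population correlation.
#' @export
theoretical_gene_correlation <- function(w1, w2, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  (w1 * w2) / sqrt((w1^2 + sigma^2) * (w2^2 + sigma^2))
}

#' Theoretical first canonical correlation of the generative model
#'
#' For two sets of `p` and `q` genes all loading one shared unit-variance
#' factor with strength `w` plus noise of sd `sigma`, the population
#' canonical directions are the set means, giving first canonical
#' correlation `w^2 / sqrt((w^2 + sigma^2/p)(w^2 + sigma^2/q))`.
#'
#' @param w factor loading.
#' @param sigma positive noise standard deviation.
#' @param p,q gene counts of the two sets.
#' @return The population first canonical correlation.
#' @export
theoretical_canonical_correlation <- function(w, sigma, p, q) {
  if (sigma <= 0) stop("sigma must be positive")
  w^2 / sqrt((w^2 + sigma^2 / p) * (w^2 + sigma^2 / q))
}
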