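#' Build a pipeline configuration
#'
#' A configuration names either input files (`inputs$expression`,
#' `inputs$pathways`, `inputs$disease_genes`) or a simulation block whose
#' fields mirror [sim_params()] — exactly one of the two — plus screening
#' thresholds (explicit values or a `preset` name), network settings
#' (`r_min`, `mode`), an output directory and a seed.
#'
#' @param x a named list, or the path to a YAML file containing one.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a list or a YAML file path")
  has_inputs <- !is.null(x$inputs)
  has_sim <- !is.null(x$simulation)
  if (has_inputs == has_sim) {
    stop("config must contain exactly one of 'inputs' or 'simulation'")
  }
  if (is.null(x$output_dir)) stop("config must name an output_dir")
  if (has_inputs) {
    need <- c("expression", "pathways", "disease_genes")
    miss <- setdiff(need, names(x$inputs))
    if (length(miss)) {
      stop("config inputs must name: ", paste(miss, collapse = ", "))
    }
  } else {
    if (is.null(x$seed) && is.null(x$simulation$seed)) {
      stop("simulation runs require an explicit seed")
    }
  }
  th <- x$thresholds
  x$thresholds <- if (is.null(th)) {
    screen_thresholds()
  } else if (inherits(th, "screen_thresholds")) {
    th
  } else if (!is.null(th$preset)) {
    threshold_preset(th$preset,
                     min_pathway_genes = th$min_pathway_genes %||% 10L)
  } else {
    screen_thresholds(r_min = th$r_min %||% 0.5,
                      p_max = th$p_max %||% 0.001,
                      sa_min = th$sa_min %||% 0.15,
                      sb_min = th$sb_min %||% 0.15,
                      min_pathway_genes = th$min_pathway_genes %||% 10L)
  }
  x$network <- list(r_min = x$network$r_min %||% 0.6,
                    mode = x$network$mode %||% "signed")
  if (!x$network$mode %in% c("signed", "absolute")) {
    stop("network mode must be 'signed' or 'absolute'")
  }
  structure(x, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screen pipeline
#'
#' Chains the stages end to end: obtain the compendium (read the configured
#' input files, or generate a synthetic one), drop genes with missing
#' values, screen every pathway by CCA, build the bipartite Pearson
#' network between disease genes and the union of measured pathway genes,
#' run hypergeometric enrichment of the network-connected metabolic genes,
#' and write all artifacts into the output directory:
#' `screen_table.tsv`, `network_edges.tsv`, `enrichment.tsv` and
#' `run_log.txt` (plus `expression.tsv`, `pathways.gmt`,
#' `disease_genes.txt` for simulation runs).  Identical configuration and
#' seed produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()], a raw list, or a YAML path.
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  simulated <- !is.null(config$simulation)
  if (!simulated) {
    for (f in unlist(config$inputs[c("expression", "pathways",
                                     "disease_genes")])) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  note("pathcca pipeline run")
  note("pathcca version: ", as.character(utils::packageVersion("pathcca")))
  note("R version: ", R.version.string)
  note("")

  if (simulated) {
    sim_block <- config$simulation
    seed <- sim_block$seed %||% config$seed
    params <- sim_params(
      n_experiments = sim_block$n_experiments %||% 500L,
      n_disease_genes = sim_block$n_disease_genes %||% 20L,
      pathway_sizes = sim_block$pathway_sizes %||% rep(10L, 5L),
      linked_pathways = sim_block$linked_pathways %||% integer(),
      loading_strength = sim_block$loading_strength %||% 1,
      noise_sd = sim_block$noise_sd %||% 1,
      n_background_genes = sim_block$n_background_genes %||% 100L,
      seed = seed)
    sim <- generate_compendium(params)
    expr <- sim$expression
    pathways <- sim$pathways
    disease <- sim$disease_genes
    write_expression_matrix(expr, out("expression.tsv"))
    write_gmt(pathways, out("pathways.gmt"))
    write_gene_list(disease, out("disease_genes.txt"))
    note("mode: simulation (seed ", params$seed, ")")
    note("simulation: ", params$n_experiments, " experiments, ",
         params$n_disease_genes, " disease genes, pathways [",
         paste(params$pathway_sizes, collapse = ", "), "], linked [",
         paste(params$linked_pathways, collapse = ", "), "], w = ",
         paste(params$loading_strength, collapse = ","), ", sigma = ",
         params$noise_sd, ", background = ", params$n_background_genes)
  } else {
    expr <- read_expression_matrix(config$inputs$expression)
    pathways <- read_gmt(config$inputs$pathways)
    disease <- read_gene_list(config$inputs$disease_genes)
    note("mode: file inputs")
    note("expression: ", config$inputs$expression)
    note("pathways: ", config$inputs$pathways)
    note("disease genes: ", config$inputs$disease_genes)
  }
  n_before <- nrow(expr)
  expr <- drop_incomplete_genes(expr, verbose = FALSE)
  note("genes dropped for missing values: ", n_before - nrow(expr))
  note("compendium: ", nrow(expr), " genes x ", ncol(expr), " experiments")
  th <- config$thresholds
  note("thresholds: r_min ", th$r_min, ", p_max ", th$p_max, ", sa_min ",
       th$sa_min, ", sb_min ", th$sb_min, ", min_pathway_genes ",
       th$min_pathway_genes)

  screen <- withCallingHandlers(
    screen_pathways(expr, pathways, disease, thresholds = th),
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  dropped_pw <- attr(screen, "dropped_pathways")
  if (!is.null(dropped_pw) && nrow(dropped_pw)) {
    note("pathways excluded by size filter: ",
         paste(sprintf("%s (%d measured)", dropped_pw$pathway,
                       dropped_pw$n_measured), collapse = "; "))
  }
  failed <- screen$pathway[!is.na(screen$error)]
  if (length(failed)) {
    note("pathways with failed decompositions: ",
         paste(failed, collapse = ", "))
  }
  note("pathways screened: ", nrow(screen), "; passed: ", sum(screen$passed))
  write_screen_table(screen, out("screen_table.tsv"))

  metabolic <- unique(unlist(pathways$genes, use.names = FALSE))
  net <- withCallingHandlers(
    bipartite_pearson_network(expr, disease, metabolic,
                              r_min = config$network$r_min,
                              mode = config$network$mode),
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("network: r_min ", config$network$r_min, " (", config$network$mode,
       "), ", nrow(net$edges), " edges")
  write_edge_list(net, out("network_edges.tsv"))

  connected_metabolic <- sort(unique(net$edges$target), method = "radix")
  background <- intersect(metabolic, rownames(expr))
  enr <- hypergeometric_enrichment(connected_metabolic, pathways, background)
  note("enrichment query (connected metabolic genes): ",
       length(connected_metabolic), " of background ", length(background))
  write_enrichment_table(enr, out("enrichment.tsv"))

  con <- file(out("run_log.txt"), open = "wb")
  writeLines(log_lines, con, sep = "\n")
  close(con)

  paths <- c(screen_table = out("screen_table.tsv"),
             network_edges = out("network_edges.tsv"),
             enrichment = out("enrichment.tsv"),
             run_log = out("run_log.txt"))
  if (simulated) {
    paths <- c(paths, expression = out("expression.tsv"),
               pathways = out("pathways.gmt"),
               disease_genes = out("disease_genes.txt"))
  }
  invisible(paths)
}
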