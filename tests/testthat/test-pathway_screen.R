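test_that("threshold constructors validate and presets carry the published sets", {
  th <- screen_thresholds()
  expect_equal(c(th$r_min, th$p_max, th$sa_min, th$sb_min),
               c(0.5, 0.001, 0.15, 0.15))
  m <- threshold_preset("methods")
  expect_equal(c(m$r_min, m$p_max, m$sa_min, m$sb_min),
               c(0.6, 1e-5, 0.3, 0.15))
  r <- threshold_preset("results")
  expect_equal(c(r$r_min, r$p_max, r$sa_min, r$sb_min),
               c(0.5, 0.001, 0.2, 0.2))
  expect_error(threshold_preset("bogus"), "default, methods, results")
  expect_error(screen_thresholds(r_min = 1.2), "r_min")
  expect_error(screen_thresholds(min_pathway_genes = 1), "at least 2")
})

test_that("pathway size filter intersects with measured genes", {
  expr <- matrix(rnorm(15 * 4), 15, 4,
                 dimnames = list(paste0("g", 1:15), paste0("E", 1:4)))
  pw <- pathway_collection(
    c("big", "small"), c("", ""),
    list(c(paste0("g", 1:11), "unmeasured"), paste0("g", c(1:9, 99))))
  kept <- filter_pathways(pw, expr, min_genes = 10)
  expect_identical(kept$ids, "big")
  expect_length(kept$genes$big, 11L)
  expect_identical(attr(kept, "dropped")$pathway, "small")
  expect_identical(attr(kept, "dropped")$n_measured, 9L)

  all_kept <- filter_pathways(pw, expr, min_genes = 1)
  expect_identical(all_kept$ids, c("big", "small"))
})

test_that("representative gene count reproduces the published screen counts", {
  # seven (n_genes, S_a) -> count pairs from the published screen table
  cases <- list(c(30, 0.20, 6), c(10, 0.30, 3), c(48, 0.23, 11),
                c(17, 0.27, 5), c(17, 0.22, 4), c(25, 0.21, 5),
                c(15, 0.22, 3))
  for (cs in cases) {
    expect_identical(representative_gene_count(cs[1], cs[2]),
                     as.integer(cs[3]))
  }
  # half-away-from-zero rounding and the passing floor
  expect_identical(representative_gene_count(10, 0.05), 1L)   # 0.5 -> 1
  expect_identical(representative_gene_count(10, 0), 1L)
  expect_identical(representative_gene_count(10, 0, passed = FALSE), 0L)
  expect_identical(representative_gene_count(3, 1), 3L)
  expect_error(representative_gene_count(0, 0.5), "n_genes")
  expect_error(representative_gene_count(10, 1.5), "\\[0, 1\\]")
})

test_that("representative genes are ranked by |coefficient| with id tie-break", {
  set.seed(5)
  fit <- compute_cca(zscore_columns(matrix(rnorm(60), 20, 3)),
                     zscore_columns(matrix(rnorm(60), 20, 3)))
  fit$BB[, 1] <- c(0.1, -0.9, 0.5)
  ids <- c("gA", "gB", "gC")
  expect_identical(select_representative_genes(fit, ids, 2), c("gB", "gC"))
  expect_identical(select_representative_genes(fit, ids, 3),
                   c("gB", "gC", "gA"))
  fit$BB[, 1] <- c(0.5, -0.5, 0.5)
  expect_identical(select_representative_genes(fit, ids, 3),
                   c("gA", "gB", "gC"))
  expect_error(select_representative_genes(fit, ids, 4), "exceeds")
})

test_that("screen identifies exactly the planted pathway and its record is reproducible", {
  sim <- generate_compendium(sim_params(2000, 10, c(10, 10, 10, 10, 10),
                                        linked_pathways = 2, seed = 314))
  expr <- sim$expression
  screen <- screen_pathways(expr, sim$pathways, sim$disease_genes,
                            screen_thresholds(min_pathway_genes = 10))
  expect_s3_class(screen, "pathway_screen")
  expect_identical(nrow(screen), 5L)
  expect_identical(screen$pathway[screen$passed], "PW02")
  expect_identical(screen$pathway[1], "PW02")  # sorted by descending r
  expect_true(all(diff(screen$r) <= 0))
  expect_true(all(screen$r >= 0 & screen$r <= 1))
  expect_true(all(screen$S_a >= 0 & screen$S_a <= 1))

  # re-running the decomposition on the stored gene subset reproduces the row
  row <- screen[screen$pathway == "PW02", ]
  M <- zscore_columns(t(expr[sim$disease_genes, ]))
  N <- zscore_columns(t(expr[sim$pathways$genes$PW02, ]))
  fit <- compute_cca(M, N)
  ld <- structure_loadings(fit)
  expect_identical(row$r, fit$r[1])
  expect_identical(row$S_a, variance_extracted(ld$r_2B, 1))
  expect_identical(row$S_b, variance_extracted(ld$r_1A, 1))
  k <- representative_gene_count(row$n_genes, row$S_a)
  expect_identical(row$representative_genes,
                   paste(select_representative_genes(
                     fit, sim$pathways$genes$PW02, k), collapse = ","))
  expect_true(all(strsplit(row$representative_genes, ",")[[1]] %in%
                    sim$pathways$genes$PW02))
})

test_that("screen records are independent of pathway order and monotone in thresholds", {
  sim <- generate_compendium(sim_params(500, 8, c(10, 12, 11),
                                        linked_pathways = 1, seed = 99))
  screen <- screen_pathways(sim$expression, sim$pathways, sim$disease_genes)
  shuffled <- sim$pathways[c(3, 1, 2)]
  screen2 <- screen_pathways(sim$expression, shuffled, sim$disease_genes)
  expect_equal(screen, screen2, ignore_attr = TRUE)

  # relaxing every threshold never removes a passing pathway
  loose <- screen_pathways(sim$expression, sim$pathways, sim$disease_genes,
                           screen_thresholds(r_min = 0.1, p_max = 0.1,
                                             sa_min = 0, sb_min = 0))
  expect_true(all(screen$pathway[screen$passed] %in%
                    loose$pathway[loose$passed]))
})

test_that("all-noise compendia rarely pass the default screen", {
  n_seed <- 100L
  clean <- 0L
  for (i in seq_len(n_seed)) {
    sim <- generate_compendium(sim_params(500, 10, c(10, 10),
                                          n_background_genes = 0,
                                          seed = 30000L + i))
    screen <- screen_pathways(sim$expression, sim$pathways, sim$disease_genes)
    if (!any(screen$passed)) clean <- clean + 1L
  }
  expect_gte(clean, 95L)
})

test_that("degenerate screen inputs are handled explicitly", {
  sim <- generate_compendium(sim_params(100, 5, 10, seed = 2))
  expr <- sim$expression
  expect_error(
    suppressWarnings(screen_pathways(expr, sim$pathways, c("nope1", "nope2"))),
    "fewer than 2")
  expect_warning(
    screen_pathways(expr, sim$pathways,
                    c(sim$disease_genes, "missing_gene")),
    "absent")
  # a constant pathway gene is dropped, not fatal
  expr2 <- rbind(expr, flatgene = rep(1, ncol(expr)))
  pw2 <- pathway_collection("PW01", "",
                            list(c(sim$pathways$genes$PW01, "flatgene")))
  expect_warning(screen2 <- screen_pathways(expr2, pw2, sim$disease_genes),
                 "constant")
  expect_identical(screen2$n_genes, 10L)
})
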