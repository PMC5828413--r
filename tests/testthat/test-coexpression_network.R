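test_that("bipartite network keeps exactly the above-threshold pairs", {
  # hand-built 6 x 8 toy: m1 duplicates d1 (r = 1), m2 = -d1 (r = -1),
  # m3 tracks d2 strongly, the rest weakly correlated
  set.seed(8)
  base <- rnorm(8)
  other <- rnorm(8)
  expr <- rbind(d1 = base,
                d2 = other,
                d3 = rnorm(8),
                m1 = base,
                m2 = -base,
                m3 = other + 0.1 * rnorm(8))
  colnames(expr) <- paste0("E", 1:8)
  R <- cor(t(expr[c("d1", "d2", "d3"), ]), t(expr[c("m1", "m2", "m3"), ]))
  expected <- which(R > 0.6, arr.ind = TRUE)

  net <- bipartite_pearson_network(expr, c("d1", "d2", "d3"),
                                   c("m1", "m2", "m3"), r_min = 0.6)
  expect_identical(nrow(net$edges), nrow(expected))
  expect_equal(net$edges$r[net$edges$source == "d1" &
                             net$edges$target == "m1"], 1)
  # every stored weight reproduces the direct Pearson computation
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$r[i],
                 cor(expr[net$edges$source[i], ], expr[net$edges$target[i], ]),
                 tolerance = 1e-12)
  }
  # signed vs absolute mode on the anticorrelated pair
  expect_false(any(net$edges$target == "m2"))
  net_abs <- bipartite_pearson_network(expr, c("d1", "d2", "d3"),
                                       c("m1", "m2", "m3"), r_min = 0.6,
                                       mode = "absolute")
  expect_true(any(net_abs$edges$source == "d1" & net_abs$edges$target == "m2"))
  # edge count is non-increasing in the threshold
  for (rm in c(0, 0.3, 0.6, 0.9)) {
    n_lo <- nrow(bipartite_pearson_network(expr, c("d1", "d2", "d3"),
                                           c("m1", "m2", "m3"),
                                           r_min = rm)$edges)
    n_hi <- nrow(bipartite_pearson_network(expr, c("d1", "d2", "d3"),
                                           c("m1", "m2", "m3"),
                                           r_min = rm + 0.05)$edges)
    expect_gte(n_lo, n_hi)
  }
  expect_warning(
    bipartite_pearson_network(expr, c("d1", "d2"), c("d1", "m1")), "both")
  expect_error(
    suppressWarnings(bipartite_pearson_network(expr, "d1", "d1")), "metabolic")
})

test_that("planted strong coexpression connects the whole linked pathway", {
  sim <- generate_compendium(sim_params(2000, 10, c(8, 8),
                                        linked_pathways = 1,
                                        loading_strength = 3, noise_sd = 1,
                                        n_background_genes = 50, seed = 17))
  expect_equal(sim$truth$rho_gene, 0.9)
  metabolic <- unique(unlist(sim$pathways$genes))
  net <- bipartite_pearson_network(sim$expression, sim$disease_genes,
                                   metabolic, r_min = 0.6)
  linked <- sim$pathways$genes$PW01
  # theory: every disease/linked-gene pair has rho 0.9 >> 0.6
  for (g in linked) {
    expect_identical(sum(net$edges$target == g), 10L)
  }
  # unlinked pathway genes essentially never reach r > 0.6 at n = 2000
  expect_identical(sum(net$edges$target %in% sim$pathways$genes$PW02), 0L)
})

test_that("connected components partition the graph, largest first", {
  edges <- data.frame(source = c("a", "b", "x"), target = c("m", "m", "y"),
                      stringsAsFactors = FALSE)
  edges$r <- c(0.9, 0.8, 0.7)
  net <- structure(list(
    nodes = data.frame(gene = c("a", "b", "x", "isolated", "m", "y"),
                       class = c(rep("disease", 4), rep("metabolic", 2)),
                       stringsAsFactors = FALSE),
    edges = edges), class = "coexpression_network")
  comps <- connected_components(net)
  expect_length(comps, 2L)
  expect_identical(comps[[1]]$nodes$gene, c("a", "b", "m"))
  expect_identical(comps[[2]]$nodes$gene, c("x", "y"))
  expect_false("isolated" %in% unlist(lapply(comps, function(cp) cp$nodes$gene)))

  net$edges <- edges[0, ]
  expect_identical(connected_components(net), list())
})

test_that("hub extraction returns all maximum-degree nodes", {
  star <- structure(list(
    nodes = data.frame(gene = c("9833", "l1", "l2", "l3", "l4"),
                       class = c("disease", rep("metabolic", 4)),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = "9833", target = paste0("l", 1:4),
                       r = rep(0.9, 4), stringsAsFactors = FALSE)),
    class = "coexpression_network")
  expect_identical(hub_nodes(star), "9833")

  path <- structure(list(
    nodes = data.frame(gene = c("a", "b", "c"),
                       class = c("disease", "metabolic", "disease"),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = c("a", "c"), target = c("b", "b"),
                       r = c(0.8, 0.7), stringsAsFactors = FALSE)),
    class = "coexpression_network")
  expect_identical(hub_nodes(path), "b")

  triangle <- structure(list(
    nodes = data.frame(gene = c("a", "b", "c"), class = rep("disease", 3),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"),
                       r = rep(0.9, 3), stringsAsFactors = FALSE)),
    class = "coexpression_network")
  expect_identical(hub_nodes(triangle), c("a", "b", "c"))

  singleton <- structure(list(
    nodes = data.frame(gene = "a", class = "disease",
                       stringsAsFactors = FALSE),
    edges = star$edges[0, ]), class = "coexpression_network")
  expect_error(hub_nodes(singleton), "at least 2")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  bg <- paste0("g", 1:10)
  pw <- pathway_collection("P1", "", list(paste0("g", 1:5)))
  enr <- hypergeometric_enrichment(paste0("g", 1:3), pw, bg)
  expect_equal(enr$p_value, choose(5, 3) / choose(10, 3))
  expect_identical(enr$hit_count, 3L)
  expect_identical(enr$genes, "g1,g2,g3")

  # zero hits and saturation give p = 1
  pw2 <- pathway_collection("P2", "", list(paste0("g", 6:10)))
  expect_equal(hypergeometric_enrichment(paste0("g", 1:3), pw2, bg)$p_value, 1)
  expect_equal(hypergeometric_enrichment(bg, pw, bg)$p_value, 1)

  expect_error(hypergeometric_enrichment("zz", pw, bg), "not in the background")
  expect_error(hypergeometric_enrichment("g1", pw, character()), "empty")
})

test_that("hypergeometric p-values agree with brute-force enumeration", {
  set.seed(12)
  bg <- paste0("g", 1:12)
  for (i in 1:6) {
    k <- sample(2:8, 1)
    members <- sample(bg, k)
    nq <- sample(2:6, 1)
    query <- sample(bg, nq)
    pw <- pathway_collection("P", "", list(members))
    p_pkg <- hypergeometric_enrichment(query, pw, bg)$p_value
    x <- length(intersect(query, members))
    p_enum <- enumerate_hyper_tail(12, match(members, bg), nq, x)
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
  }
})

test_that("BH q-values are computed across pathways and rows sorted by p", {
  bg <- paste0("g", 1:20)
  pw <- pathway_collection(c("A", "B", "C"), rep("", 3),
                           list(paste0("g", 1:5), paste0("g", 6:15),
                                paste0("g", 16:18)))
  enr <- hypergeometric_enrichment(paste0("g", 1:5), pw, bg)
  expect_true(!is.unsorted(enr$p_value))
  expect_equal(enr$q_value,
               p.adjust(enr$p_value, "BH"))
  expect_true(all(enr$q_value >= enr$p_value - 1e-15))
})
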