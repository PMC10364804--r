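test_that("Jaccard index matches set arithmetic, with the empty-set convention", {
  expect_identical(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard_index(c("a"), c("b")), 0)
  expect_identical(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(z <- jaccard_index(character(0), character(0)), "empty sets")
  expect_identical(z, 0)
})

test_that("similarity matrix equals brute-force pairwise Jaccard", {
  set.seed(19)
  pool <- letters
  sets <- replicate(40, sample(pool, sample(0:8, 1)), simplify = FALSE)
  sim <- suppressWarnings(neighborhood_similarity(sets))
  J <- sim$J
  expect_true(isSymmetric(unname(J)))
  expect_true(all(J >= 0 & J <= 1))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      expect_equal(unname(J[i, j]),
                   suppressWarnings(jaccard_index(sets[[i]], sets[[j]])))
    }
  }
  # diagonal is 1 exactly for nonempty sets
  nonempty <- lengths(sets) > 0
  expect_true(all(diag(J)[nonempty] == 1))

  # permuting the input permutes rows/columns consistently
  perm <- sample(seq_along(sets))
  sim_p <- suppressWarnings(neighborhood_similarity(sets[perm]))
  expect_equal(unname(sim_p$J), unname(J[perm, perm]))

  expect_identical(sim$labels[1:3], c("nb1", "nb2", "nb3"))
  expect_error(neighborhood_similarity(sets[1]),
               class = "genehood_parameter_error")
})

test_that("identical neighborhoods give an all-ones matrix and one cluster", {
  sets <- replicate(3, c("PF1", "PF2"), simplify = FALSE)
  sim <- neighborhood_similarity(sets)
  expect_true(all(sim$J == 1))
  cl <- cluster_neighborhoods(sim, h = 0.5)
  expect_identical(unname(cl$assignment), c(1L, 1L, 1L))
})

test_that("single linkage recovers planted blocks and honors trivial cuts", {
  blockA <- replicate(10, c("PF1", "PF2", "PF3"), simplify = FALSE)
  blockB <- replicate(8, c("PF7", "PF8"), simplify = FALSE)
  sim <- neighborhood_similarity(c(blockA, blockB))
  cl <- cluster_neighborhoods(sim, h = 0.5)
  expect_identical(unname(cl$assignment), rep(c(1L, 2L), c(10L, 8L)))

  # cut above the maximum distance: one cluster
  cl1 <- cluster_neighborhoods(sim, h = 1.01)
  expect_identical(length(unique(cl1$assignment)), 1L)

  # cut at zero on all-distinct sets: all singletons
  distinct <- lapply(1:6, function(i) paste0("PF", i))
  simd <- neighborhood_similarity(distinct)
  cl0 <- cluster_neighborhoods(simd, h = 0)
  expect_identical(unname(cl0$assignment), 1:6)

  expect_error(cluster_neighborhoods(sim, h = 0.5, k = 2),
               class = "genehood_parameter_error")
  expect_error(cluster_neighborhoods(sim, k = 100),
               class = "genehood_parameter_error")

  # merge heights are non-decreasing and the tree serializes
  expect_true(!is.unsorted(cl$hclust$height))
  nwk <- cluster_tree_newick(cl)
  expect_match(nwk, ";$")
  expect_identical(lengths(regmatches(nwk, gregexpr(",", nwk))),
                   length(sim$labels) - 1L)
})

test_that("single linkage equals the MST-cut oracle on random instances", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    sets <- replicate(n, sample(letters[1:12], sample(1:6, 1)),
                      simplify = FALSE)
    sim <- neighborhood_similarity(sets)
    h <- runif(1)
    cl <- cluster_neighborhoods(sim, h = h)
    oracle <- mst_components(1 - sim$J, h)
    expect_identical(canon_partition(unname(cl$assignment)),
                     canon_partition(oracle))
  }
})

test_that("Jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(55)
  for (rep in 1:200) {
    s <- replicate(3, sample(letters[1:10], sample(1:6, 1)), simplify = FALSE)
    d <- function(i, j) 1 - jaccard_index(s[[i]], s[[j]])
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
  }
})

test_that("clustering is invariant to input permutation up to label renaming", {
  set.seed(77)
  sets <- replicate(20, sample(letters[1:8], sample(1:5, 1)), simplify = FALSE)
  sim <- neighborhood_similarity(sets)
  cl <- cluster_neighborhoods(sim, h = 0.4)
  perm <- sample(20)
  cl_p <- cluster_neighborhoods(neighborhood_similarity(sets[perm]), h = 0.4)
  a <- canon_partition(unname(cl$assignment)[perm])
  b <- canon_partition(unname(cl_p$assignment))
  expect_identical(a, b)
})

test_that("cluster annotation reports composition and featured domains", {
  spec <- fixture_spec(n_genomes = 10, genes_per_genome = 60,
                       domain_pool_size = 15, query_prevalence = 1,
                       taxon_skew = c(GenX = 10), seed = 13)
  sim_db <- simulate_genome_db(spec)
  db <- genome_db(sim_db$genes, sim_db$taxonomy)
  q <- resolve_query(db, pfam = spec$query_domain)
  nbs <- extract_neighborhoods(db, q)
  sim <- neighborhood_similarity(nbs)
  cl <- cluster_neighborhoods(sim, h = 1.01)  # one cluster of 10
  ann <- annotate_clusters(cl, db)
  expect_identical(ann$table$size, 10L)
  expect_identical(ann$table$top_genus, "GenX")
  comp <- ann$composition[["1"]]
  expect_equal(sum(comp$genus), 100)
  expect_equal(sum(comp$family), 100)
  expect_identical(unname(comp$genus["GenX"]), 100)
  # the query domain is in every neighborhood, hence always featured
  expect_match(ann$table$featured_domains, spec$query_domain)

  # boundary: present in exactly 9/10 at threshold 0.9 counts as featured
  sets <- c(replicate(9, c("PFa", "PFb"), simplify = FALSE), list("PFb"))
  s2 <- neighborhood_similarity(sets)
  cl2 <- cluster_neighborhoods(s2, h = 1.01)
  ann2 <- annotate_clusters(cl2, taxonomy = NULL, featured_threshold = 0.9)
  expect_true(grepl("PFa", ann2$table$featured_domains))
})
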