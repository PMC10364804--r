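test_that("expected count formula and its guards", {
  expect_identical(expected_lambda(10, 10, 50, 10000), 0.5)
  expect_identical(expected_lambda(10, 10, 0, 10000), 0)
  expect_identical(expected_lambda(1, 1, 100, 100), 1)
  expect_error(expected_lambda(10, 10, 200, 100),
               class = "genehood_parameter_error")
  expect_error(expected_lambda(10, 10, 5, 0),
               class = "genehood_parameter_error")
})

test_that("P score matches the direct-summation oracle and closed forms", {
  expect_identical(poisson_pscore(0, 5), 1)
  expect_equal(poisson_pscore(2, 1), 1 - 2 * exp(-1), tolerance = 1e-14)
  expect_equal(poisson_pscore(1, 0.5), 1 - exp(-0.5), tolerance = 1e-14)
  for (lam in c(0.01, 0.5, 2, 10)) {
    for (k in c(0L, 1L, 3L, 10L, 30L)) {
      expect_lt(abs(poisson_pscore(k, lam) - poisson_tail_oracle(k, lam)),
                1e-12)
    }
  }
  # the far tail stays finite (never NaN or negative) and far below any
  # reporting threshold; extreme tails underflow cleanly to 0
  far <- poisson_pscore(2e4, 1e3)
  expect_false(is.nan(far))
  expect_gte(far, 0)
  expect_lt(far, 1e-100)
  expect_gt(poisson_pscore(2000, 1e3), 0)  # representable tail is positive
  expect_error(poisson_pscore(-1, 1), class = "genehood_parameter_error")
  expect_error(poisson_pscore(1, -1), class = "genehood_parameter_error")
})

test_that("P score is monotone: non-increasing in k, non-decreasing in lambda", {
  lam_grid <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20)
  for (lam in lam_grid) {
    p <- poisson_pscore(0:50, lam)
    expect_true(all(diff(p) <= 0))
  }
  for (k in c(0L, 1L, 5L, 20L)) {
    p <- poisson_pscore(k, lam_grid)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("domain counting is per-gene presence summed over neighborhoods", {
  fake_nb <- function(multiset) {
    structure(list(domain_multiset = multiset, domain_set = names(multiset),
                   n_genes = max(1L, sum(multiset))), class = "neighborhood")
  }
  nbs <- list(fake_nb(c(PF1 = 3L)), fake_nb(c(PF2 = 1L)))
  res <- count_in_neighborhoods(nbs, "PF1")
  expect_identical(res$k, 3L)
  expect_identical(res$presence_fraction, 0.5)
  expect_identical(count_in_neighborhoods(nbs, "PFX"),
                   list(k = 0L, presence_fraction = 0))
  nbs4 <- replicate(4, fake_nb(c(PF1 = 1L)), simplify = FALSE)
  res4 <- count_in_neighborhoods(nbs4, "PF1")
  expect_identical(res4$k, 4L)
  expect_identical(res4$presence_fraction, 1)
})

test_that("multiple-testing correction matches hand-computed values", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(correct_pvalues(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(correct_pvalues(p, "benjamini_hochberg"), c(0.03, 0.03, 0.03))
  expect_identical(correct_pvalues(p, "none"), p)
  expect_error(correct_pvalues(c(0.5, 1.2)),
               class = "genehood_parameter_error")
})

test_that("enrichment recovers the planted partner and excludes k < lambda", {
  spec <- small_planted_spec(seed = 5)
  sim <- simulate_genome_db(spec)
  db <- genome_db(sim$genes, sim$taxonomy)
  fit <- neighborhood_enrich(db, pfam = spec$query_domain)

  partner <- fit$table[fit$table$domain == "PF99902", ]
  expect_identical(nrow(partner), 1L)
  expect_lt(partner$p_score, 1e-5)
  expect_gte(partner$presence_fraction, 0.5)

  # the query's own row: a member of every neighborhood, flagged
  qrow <- fit$table[fit$table$is_query, ]
  expect_identical(qrow$domain, spec$query_domain)
  expect_gte(qrow$k, fit$Nn)
  expect_identical(qrow$presence_fraction, 1)

  # exclusion rule: retained rows all satisfy k >= lambda, and every
  # candidate with k < lambda is absent from the table
  expect_true(all(fit$table$k >= fit$table$lambda))
  excluded <- fit$candidates$domain[fit$candidates$k < fit$candidates$lambda]
  expect_length(intersect(excluded, fit$table$domain), 0L)
  # a manufactured k=1 < lambda=2 case would score ~0.86; confirm such
  # candidates exist in the fixture and are dropped
  expect_gt(nrow(fit$candidates), nrow(fit$table))

  # p_corrected dominates p_score under bonferroni
  fitb <- neighborhood_enrich(db, pfam = spec$query_domain,
                              correction = "bonferroni")
  expect_true(all(fitb$table$p_corrected >= fitb$table$p_score))
  # ordering: p ascending; ties broken by k desc then accession
  expect_true(!is.unsorted(fit$table$p_score))
})

test_that("lambda uses the empirical mean neighborhood size and subset background", {
  spec <- small_planted_spec(seed = 9)
  sim <- simulate_genome_db(spec)
  db <- genome_db(sim$genes, sim$taxonomy)
  fit <- neighborhood_enrich(db, pfam = spec$query_domain)
  expect_equal(fit$Nl, mean_neighborhood_size(fit$neighborhoods))
  d <- fit$table$domain[2]
  expect_equal(fit$table$lambda[2],
               expected_lambda(fit$Nn, fit$Nl, db$Nod[[d]], db$Sd))
})

test_that("the pipeline is deterministic: identical inputs give identical tables", {
  spec <- small_planted_spec(seed = 2)
  sim <- simulate_genome_db(spec)
  db <- genome_db(sim$genes, sim$taxonomy)
  f1 <- neighborhood_enrich(db, pfam = spec$query_domain)
  f2 <- neighborhood_enrich(db, pfam = spec$query_domain)
  expect_identical(f1$table, f2$table)
  t1 <- tempfile(); t2 <- tempfile()
  write.csv(f1$table, t1, row.names = FALSE)
  write.csv(f2$table, t2, row.names = FALSE)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("a query absent from the database yields an empty, flagged result", {
  db <- genome_db(toy_gene_table(), toy_taxonomy())
  fit <- neighborhood_enrich(db, pfam = "PF55555")
  expect_identical(fit$status, "query_not_found")
  expect_identical(nrow(fit$table), 0L)
})

test_that("taxonomy report lists lineages and per-rank genome counts", {
  genes <- rbind(
    transform(toy_gene_table(), genome_id = "G1", gene_id = paste0("a", 1:3)),
    transform(toy_gene_table(), genome_id = "G2", gene_id = paste0("b", 1:3))
  )
  tax <- data.frame(genome_id = c("G1", "G2"), phylum = "P", class = "C",
                    order = "O", family = "F", genus = c("Escherichia",
                                                         "Escherichia"),
                    stringsAsFactors = FALSE)
  db <- genome_db(genes, tax)
  q <- resolve_query(db, pfam = "PF00002")
  rep <- taxonomy_report(db, q)
  expect_identical(nrow(rep$genes), 2L)
  expect_identical(unname(rep$rank_counts$genus[["Escherichia"]]), 2L)
  # counts over genera sum to the number of distinct query genomes
  expect_identical(sum(rep$rank_counts$genus),
                   length(unique(rep$genes$genome_id)))

  # missing lineages surface as the sentinel
  db2 <- suppressWarnings(genome_db(genes,
                                    tax[tax$genome_id == "G1", , drop = FALSE]))
  rep2 <- taxonomy_report(db2, resolve_query(db2, pfam = "PF00002"))
  expect_true("<missing>" %in% names(rep2$rank_counts$genus))
  expect_true(any(is.na(rep2$genes$genus)))
})
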