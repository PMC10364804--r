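# A database with two genera of controllable genome counts, query in every
# genome, so subtaxon grouping/balancing behaviour is fully predictable.
two_genus_db <- function(nA = 6, nB = 3, genes_per_genome = 30, seed = 1) {
  spec <- fixture_spec(
    n_genomes = nA + nB, genes_per_genome = genes_per_genome,
    domain_pool_size = 20, query_prevalence = 1,
    taxon_skew = stats::setNames(c(nA, nB), c("GenA", "GenB")),
    planted_genera = "GenA", seed = seed)
  sim <- simulate_genome_db(spec)
  list(db = genome_db(sim$genes, sim$taxonomy), spec = spec)
}

test_that("grouping drops small subtaxa and missing-rank neighborhoods", {
  x <- two_genus_db(nA = 6, nB = 3)
  q <- resolve_query(x$db, pfam = x$spec$query_domain)
  nbs <- extract_neighborhoods(x$db, q)
  # min_genomes = 5: only GenA (6 genomes) qualifies
  groups <- suppressMessages(group_by_subtaxon(nbs, x$db, "genus",
                                               min_genomes = 5))
  expect_length(groups, 1L)
  expect_identical(groups[[1]]$name, "GenA")
  expect_identical(groups[[1]]$n_sub, 6L)
  expect_identical(groups[[1]]$n_genomes, 6L)
  expect_identical(attr(groups, "dropped")$small_subtaxa, "GenB")

  # both qualify at min_genomes = 2
  g2 <- group_by_subtaxon(nbs, x$db, "genus", min_genomes = 2)
  expect_identical(vapply(g2, `[[`, "", "name"), c("GenA", "GenB"))
  expect_identical(vapply(g2, `[[`, 0L, "n_sub"), c(6L, 3L))

  # everything below threshold -> empty-grouping error
  expect_error(
    suppressMessages(group_by_subtaxon(nbs, x$db, "genus", min_genomes = 100)),
    class = "genehood_empty_error")

  # missing-rank genomes are dropped with a report
  db_na <- x$db
  db_na$taxonomy$genus <- NA_character_
  expect_error(
    suppressMessages(group_by_subtaxon(nbs, db_na, "genus", min_genomes = 1)),
    class = "genehood_empty_error")
})

test_that("balancing tops every subtaxon up to n_max with in-group copies", {
  x <- two_genus_db(nA = 5, nB = 2)
  q <- resolve_query(x$db, pfam = x$spec$query_domain)
  nbs <- extract_neighborhoods(x$db, q)
  groups <- group_by_subtaxon(nbs, x$db, "genus", min_genomes = 2)
  bal <- balance_subtaxa(groups, seed = 11)
  rep <- attr(bal, "report")

  expect_identical(length(bal), 10L)  # 2 groups x n_max = 5
  expect_true(all(rep$n_contributed == max(rep$n_neighborhoods)))
  expect_identical(rep$n_neighborhoods, c(5L, 2L))
  expect_identical(rep$seed, c(11L, 11L))

  # resampled entries are exact copies from the same group
  ids_b <- vapply(groups[[2]]$neighborhoods, `[[`, "", "query_gene_id")
  out_b <- bal[6:10]
  expect_true(all(vapply(out_b, `[[`, "", "query_gene_id") %in% ids_b))
  genus_of <- x$db$taxonomy$genus[match(vapply(out_b, `[[`, "", "genome_id"),
                                        x$db$taxonomy$genome_id)]
  expect_true(all(genus_of == "GenB"))

  # fixed seed -> identical draws; different seed may differ
  bal2 <- balance_subtaxa(groups, seed = 11)
  expect_identical(vapply(bal2, `[[`, "", "query_gene_id"),
                   vapply(bal, `[[`, "", "query_gene_id"))

  # equal group sizes -> identity concatenation, no draws
  xeq <- two_genus_db(nA = 4, nB = 4)
  qeq <- resolve_query(xeq$db, pfam = xeq$spec$query_domain)
  nbeq <- extract_neighborhoods(xeq$db, qeq)
  geq <- group_by_subtaxon(nbeq, xeq$db, "genus", min_genomes = 2)
  beq <- balance_subtaxa(geq, seed = 1)
  expect_identical(length(beq), length(nbeq))

  # single group -> unchanged
  b1 <- balance_subtaxa(groups[1], seed = 1)
  expect_identical(length(b1), groups[[1]]$n_sub)
})

test_that("averaged enrichment balances contributions and restricts the background", {
  x <- two_genus_db(nA = 8, nB = 3, seed = 4)
  fit <- suppressMessages(neighborhood_enrich(
    x$db, pfam = x$spec$query_domain, average_rank = "genus",
    min_genomes = 2, seed = 7))
  rep <- fit$averaging_report
  expect_identical(sort(rep$subtaxon), c("GenA", "GenB"))
  expect_true(all(rep$n_contributed == max(rep$n_neighborhoods)))
  expect_identical(fit$Nn, nrow(rep) * max(rep$n_neighborhoods))

  # with one qualifying subtaxon, averaging reduces to plain enrichment on
  # that subtaxon (background recomputed over its genomes)
  fit1 <- suppressMessages(neighborhood_enrich(
    x$db, pfam = x$spec$query_domain, average_rank = "genus",
    min_genomes = 5, seed = 7))
  sub <- subset_by_taxon(x$db, "genus", "GenA")
  plain <- neighborhood_enrich(sub, pfam = x$spec$query_domain)
  expect_identical(fit1$table, plain$table)
  expect_identical(fit1$Sd, sub$Sd)

  # determinism under a fixed seed
  fit2 <- suppressMessages(neighborhood_enrich(
    x$db, pfam = x$spec$query_domain, average_rank = "genus",
    min_genomes = 2, seed = 7))
  expect_identical(fit$table, fit2$table)
})

test_that("balancing dilutes an association private to the oversampled genus", {
  spec <- fixture_spec(
    n_genomes = 40, genes_per_genome = 120, domain_pool_size = 20,
    query_prevalence = 1,
    taxon_skew = c(GenA = 30, GenB = 10),
    planted_genera = "GenA",
    planted_partners = list(list(domain = "PF99902", prob = 0.9,
                                 max_offset = 2)),
    seed = 21)
  sim <- simulate_genome_db(spec)
  db <- genome_db(sim$genes, sim$taxonomy)
  un <- neighborhood_enrich(db, pfam = spec$query_domain)
  av <- neighborhood_enrich(db, pfam = spec$query_domain,
                            average_rank = "genus", min_genomes = 5, seed = 3)
  p_un <- un$candidates[un$candidates$domain == "PF99902", ]
  p_av <- av$candidates[av$candidates$domain == "PF99902", ]
  expect_lt(p_av$presence_fraction, p_un$presence_fraction)
})
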