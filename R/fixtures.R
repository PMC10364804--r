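#' Specify a synthetic genome-annotation database
#'
#' Defines the study conditions for the simulator: genome layout, background
#' domain frequencies, the query domain's prevalence, planted co-localized
#' partner domains, and taxon sampling skew. Every stochastic choice is
#' governed by `seed`, so a spec maps to exactly one database.
#'
#' Defaults describe the standard validation fixture: 200 single-contig
#' genomes of 1,000 genes, a 300-domain background pool with power-law
#' frequencies (about one domain per gene on average), the query domain in
#' 150 genomes, and one partner domain planted within 3 genes of the query
#' with probability 0.8.
#'
#' @param n_genomes number of genomes (one contig each).
#' @param genes_per_genome genes per genome.
#' @param mean_gene_len mean gene length in bp (gamma-distributed, min 50).
#' @param mean_intergenic mean intergenic gap in bp (geometric).
#' @param domain_pool_size number of background domains (`PF00001...`).
#' @param background_freq per-domain carry probability: a scalar, a vector of
#'   length `domain_pool_size`, or `NULL` for the default power-law spectrum
#'   `f_j` proportional to `j^-0.7` scaled to a mean of one domain per gene.
#' @param query_domain accession of the query domain (kept outside the
#'   background pool).
#' @param query_prevalence fraction of genomes carrying one query gene.
#' @param planted_partners list of partners, each
#'   `list(domain =, prob =, max_offset =)`: with probability `prob` the
#'   partner is placed within `max_offset` genes of the query gene, otherwise
#'   at a random other gene of the genome. `NULL` or `list()` gives a null
#'   database with no planted association.
#' @param planted_genera genera in which co-localization applies (`NULL` =
#'   all); elsewhere the partner is always placed at random.
#' @param taxon_skew named integer vector, genus name to genome count,
#'   summing to `n_genomes`; `NULL` splits genomes evenly over four genera.
#' @param same_strand_prob probability a gene keeps its predecessor's strand.
#' @param seed RNG seed.
#' @return object of class `fixture_spec` (a validated list).
#' @export
fixture_spec <- function(n_genomes = 200,
                         genes_per_genome = 1000,
                         mean_gene_len = 900,
                         mean_intergenic = 100,
                         domain_pool_size = 300,
                         background_freq = NULL,
                         query_domain = "PF99901",
                         query_prevalence = 0.75,
                         planted_partners = list(
                           list(domain = "PF99902", prob = 0.8, max_offset = 3)),
                         planted_genera = NULL,
                         taxon_skew = NULL,
                         same_strand_prob = 0.6,
                         seed = 1L) {
  if (n_genomes < 1 || genes_per_genome < 1) {
    gh_parameter_error("`n_genomes` and `genes_per_genome` must be >= 1")
  }
  if (is.null(background_freq)) {
    f <- seq_len(domain_pool_size)^-0.7
    background_freq <- f / sum(f)
  } else if (length(background_freq) == 1L) {
    background_freq <- rep(background_freq, domain_pool_size)
  }
  if (length(background_freq) != domain_pool_size ||
      any(background_freq < 0) || any(background_freq > 1)) {
    gh_parameter_error("`background_freq` must be probabilities of length `domain_pool_size`")
  }
  if (query_prevalence < 0 || query_prevalence > 1) {
    gh_parameter_error("`query_prevalence` must be in [0, 1]")
  }
  planted_partners <- planted_partners %||% list()
  for (pp in planted_partners) {
    if (!all(c("domain", "prob", "max_offset") %in% names(pp))) {
      gh_parameter_error("each planted partner needs `domain`, `prob`, `max_offset`")
    }
    if (pp$prob < 0 || pp$prob > 1) gh_parameter_error("partner `prob` must be in [0, 1]")
    if (pp$max_offset < 1 || genes_per_genome < 2 * pp$max_offset + 1) {
      gh_parameter_error("`genes_per_genome` too small for partner `max_offset`")
    }
  }
  if (is.null(taxon_skew)) {
    k <- min(4L, n_genomes)
    counts <- diff(floor(seq(0, n_genomes, length.out = k + 1L)))
    taxon_skew <- stats::setNames(as.integer(counts), paste0("Genus_", seq_len(k)))
  }
  if (sum(taxon_skew) != n_genomes) {
    gh_parameter_error("`taxon_skew` counts must sum to `n_genomes`")
  }
  if (same_strand_prob < 0 || same_strand_prob > 1) {
    gh_parameter_error("`same_strand_prob` must be in [0, 1]")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genes_per_genome = as.integer(genes_per_genome),
    mean_gene_len = mean_gene_len,
    mean_intergenic = mean_intergenic,
    domain_pool_size = as.integer(domain_pool_size),
    background_freq = background_freq,
    query_domain = query_domain,
    query_prevalence = query_prevalence,
    planted_partners = planted_partners,
    planted_genera = planted_genera,
    taxon_skew = taxon_skew,
    same_strand_prob = same_strand_prob,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Null-database spec for model calibration
#'
#' A smaller fixture with no planted association, used to check that observed
#' domain counts match their expectations. Background frequencies sit in
#' three well-separated tiers (0.12, 0.08, 0.002) so that every domain's
#' expected neighborhood count is either far above or far below typical
#' reporting lines, keeping Monte-Carlo noise in replicate averages small
#' relative to the quantity being checked.
#'
#' @param n_genomes,genes_per_genome,seed see [fixture_spec()].
#' @param ... further overrides passed to [fixture_spec()].
#' @return a `fixture_spec` with `planted_partners = list()`.
#' @export
null_fixture_spec <- function(n_genomes = 100, genes_per_genome = 500,
                              seed = 1L, ...) {
  fixture_spec(
    n_genomes = n_genomes, genes_per_genome = genes_per_genome,
    domain_pool_size = 100,
    background_freq = c(rep(0.12, 20), rep(0.08, 20), rep(0.002, 60)),
    query_prevalence = 0.9,
    planted_partners = list(),
    seed = seed, ...)
}

#' Simulate a genome annotation database in memory
#'
#' Lays each genome out as a single contig of non-overlapping genes with
#' gamma-distributed lengths and geometric intergenic gaps; assigns
#' background domains to genes as independent Bernoulli trials at the spec's
#' per-domain frequencies; places one query gene per query-carrying genome;
#' and plants partner domains near the query per the spec. Fully reproducible
#' from the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `genes` (data.frame in the gene-table dialect, `domains`
#'   as a list column), `taxonomy` (data.frame), and `truth` (the planted
#'   ground truth: query gene IDs, partner placements and co-localization
#'   flags).
#' @export
simulate_genome_db <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, simulate_genome_db_impl(spec))
}

simulate_genome_db_impl <- function(spec) {
  G <- spec$n_genomes
  g <- spec$genes_per_genome
  N <- G * g

  genome_ids <- sprintf("G%04d", seq_len(G))
  genus <- rep(names(spec$taxon_skew), spec$taxon_skew)
  gi <- match(genus, names(spec$taxon_skew))
  taxonomy <- data.frame(
    genome_id = genome_ids,
    phylum = paste0("Phylum_", (gi - 1L) %/% 16L + 1L),
    class  = paste0("Class_",  (gi - 1L) %/% 8L + 1L),
    order  = paste0("Order_",  (gi - 1L) %/% 4L + 1L),
    family = paste0("Family_", (gi - 1L) %/% 2L + 1L),
    genus  = genus,
    stringsAsFactors = FALSE
  )

  # coordinates: per-genome cumulative (gap, gene) layout; genes never overlap
  len <- pmax(50L, as.integer(round(stats::rgamma(N, shape = 4,
                                                  scale = spec$mean_gene_len / 4))))
  gap <- stats::rgeom(N, prob = 1 / (spec$mean_intergenic + 1))
  step <- matrix(len + gap + 1L, nrow = g, ncol = G)
  end_m <- apply(step, 2L, cumsum)
  end <- as.integer(end_m)
  start <- end - len + 1L

  # strand: Markov chain along each contig with P(keep) = same_strand_prob
  flip <- matrix(as.integer(stats::runif(N) >= spec$same_strand_prob),
                 nrow = g, ncol = G)
  flip[1L, ] <- sample(0:1, G, replace = TRUE)
  strand <- c("+", "-")[(apply(flip, 2L, cumsum) %% 2L) + 1L]

  # background domains: independent Bernoulli per (gene, domain)
  pool <- sprintf("PF%05d", seq_len(spec$domain_pool_size))
  carriers <- vector("list", spec$domain_pool_size)
  for (j in seq_len(spec$domain_pool_size)) {
    n_j <- stats::rbinom(1L, N, spec$background_freq[j])
    carriers[[j]] <- sample.int(N, n_j)
  }
  dom_gene <- unlist(carriers, use.names = FALSE)
  dom_name <- rep.int(pool, lengths(carriers))
  domains <- rep(list(character(0)), N)
  if (length(dom_gene) > 0L) {
    sp <- split(dom_name, dom_gene)
    domains[as.integer(names(sp))] <- sp
  }

  # query gene: one per query-carrying genome, away from contig ends so a
  # planted partner offset always fits
  max_off <- max(c(1L, vapply(spec$planted_partners, `[[`, 0, "max_offset")))
  if (g - 2L * max_off < 1L) {
    gh_parameter_error("`genes_per_genome` too small to place a query gene away from contig ends")
  }
  n_q <- round(spec$query_prevalence * G)
  query_genomes <- sort(sample.int(G, n_q))
  q_within <- sample.int(g - 2L * max_off, n_q, replace = TRUE) + max_off
  q_idx <- (query_genomes - 1L) * g + q_within
  for (i in seq_along(q_idx)) {
    domains[[q_idx[i]]] <- unique(c(domains[[q_idx[i]]], spec$query_domain))
  }

  gene_ids <- paste0(rep(genome_ids, each = g), "_g",
                     formatC(rep(seq_len(g), G), width = 4, flag = "0"))

  partners_truth <- list()
  for (pp in spec$planted_partners) {
    plantable <- if (is.null(spec$planted_genera)) rep(TRUE, n_q)
                 else genus[query_genomes] %in% spec$planted_genera
    coloc <- plantable & (stats::runif(n_q) < pp$prob)
    offset <- integer(n_q)
    p_within <- integer(n_q)
    off_choices <- c(-seq_len(pp$max_offset), seq_len(pp$max_offset))
    offset[coloc] <- sample(off_choices, sum(coloc), replace = TRUE)
    p_within[coloc] <- q_within[coloc] + offset[coloc]
    # non-colocalized: uniform over the genome's other genes
    n_far <- sum(!coloc)
    if (n_far > 0L) {
      rnd <- sample.int(g - 1L, n_far, replace = TRUE)
      qw <- q_within[!coloc]
      p_within[!coloc] <- ifelse(rnd >= qw, rnd + 1L, rnd)
      offset[!coloc] <- p_within[!coloc] - qw
    }
    p_idx <- (query_genomes - 1L) * g + p_within
    for (i in seq_along(p_idx)) {
      domains[[p_idx[i]]] <- unique(c(domains[[p_idx[i]]], pp$domain))
    }
    partners_truth[[pp$domain]] <- list(
      domain = pp$domain, prob = pp$prob, max_offset = pp$max_offset,
      placements = data.frame(
        genome_id = genome_ids[query_genomes],
        gene_id = gene_ids[p_idx],
        colocalized = coloc,
        offset_genes = offset,
        stringsAsFactors = FALSE
      )
    )
  }

  genes <- data.frame(
    gene_id = gene_ids,
    genome_id = rep(genome_ids, each = g),
    contig_id = "c1",
    start = start,
    end = end,
    strand = strand,
    stringsAsFactors = FALSE
  )
  genes$domains <- domains

  truth <- list(
    seed = spec$seed,
    query_domain = spec$query_domain,
    query_genomes = genome_ids[query_genomes],
    query_gene_ids = gene_ids[q_idx],
    partners = partners_truth
  )
  list(genes = genes, taxonomy = taxonomy, truth = truth)
}

#' Generate fixture files on disk
#'
#' Runs [simulate_genome_db()] and writes the gene table, taxonomy table, and
#' ground-truth record in the package's plain-text dialects. Identical specs
#' (including seed) yield byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of paths: `genes`, `taxonomy`, `truth`.
#' @export
generate_database <- function(spec, dir) {
  sim <- simulate_genome_db(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genes = file.path(dir, "genes.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                truth = file.path(dir, "truth.json"))
  out <- sim$genes
  out$domains <- vapply(out$domains, paste, "", collapse = ";")
  utils::write.table(out, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$taxonomy, paths$taxonomy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(paths)
}
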