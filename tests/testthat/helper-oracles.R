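# Shared fixtures and independent oracles. Every oracle here is written
# against the definition, not against the package's code path.

# 3-gene toy database used across modules:
#   g1 {PF00001}, g2 {}, g3 {PF00001, PF00002}, all on one contig.
toy_gene_table <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    genome_id = "G1", contig_id = "c1",
    start = c(100L, 600L, 5000L),
    end = c(400L, 900L, 5300L),
    strand = c("+", "-", "+"),
    domains = c("PF00001", "", "PF00001;PF00002"),
    stringsAsFactors = FALSE
  )
}

toy_taxonomy <- function() {
  data.frame(
    genome_id = "G1", phylum = "Proteobacteria",
    class = "Gammaproteobacteria", order = "Enterobacterales",
    family = "Enterobacteriaceae", genus = "Escherichia",
    stringsAsFactors = FALSE
  )
}

# Direct-summation oracle for the upper-tail Poisson probability:
# P(X >= k) = 1 - sum_{i < k} exp(-lambda) lambda^i / i!, terms in log space.
poisson_tail_oracle <- function(k, lambda) {
  if (k == 0L) return(1)
  i <- 0:(k - 1L)
  1 - sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# Brute-force step-up Benjamini-Hochberg adjusted values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

bonferroni_oracle <- function(p) pmin(1, length(p) * p)

# Brute-force neighborhood membership: every gene on the query's contig
# whose interval overlaps [start - r, end + r] (clamped at 1).
brute_force_members <- function(genes, query_id, radius, strand_mode = "all") {
  q <- genes[genes$gene_id == query_id, ]
  same <- genes[genes$genome_id == q$genome_id & genes$contig_id == q$contig_id, ]
  lo <- max(1, q$start - radius); hi <- q$end + radius
  hit <- same[same$end >= lo & same$start <= hi, ]
  if (strand_mode == "same") {
    hit <- hit[hit$strand == q$strand | hit$gene_id == query_id, ]
  } else if (strand_mode == "opposite") {
    hit <- hit[hit$strand != q$strand | hit$gene_id == query_id, ]
  }
  hit <- hit[order(hit$start, hit$end, hit$gene_id), ]
  hit$gene_id
}

# Minimum-spanning-tree oracle for single linkage: Prim's algorithm on the
# distance matrix, then components after deleting MST edges longer than h.
mst_components <- function(D, h) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 2L)
  wts <- numeric(n - 1L)
  best_d <- D[1L, ]; best_from <- rep(1L, n)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]
    edges[e, ] <- c(best_from[v], v); wts[e] <- best_d[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_d
    best_d[upd] <- D[v, upd]; best_from[upd] <- v
  }
  keep <- wts <= h
  # union-find over kept edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in which(keep)) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, 0L)
  match(comp, unique(comp))
}

# Canonical renumbering so two partitions can be compared up to labels.
canon_partition <- function(x) match(x, unique(x))

# Small planted database with one strongly co-localized partner, for
# module-level tests (fast).
small_planted_spec <- function(seed = 1L) {
  fixture_spec(n_genomes = 30, genes_per_genome = 150, domain_pool_size = 50,
               query_prevalence = 0.8, seed = seed)
}
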