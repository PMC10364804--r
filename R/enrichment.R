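#' Expected neighborhood count of a target domain
#'
#' Under random placement, the expected number of occurrences of a target
#' domain across the query neighborhoods is
#' \deqn{\lambda = N_n \cdot N_l \cdot N_{od} / S_d}
#' where `Nn` is the number of query neighborhoods, `Nl` the mean neighborhood
#' size in genes, `Nod` the number of database genes carrying the target
#' domain, and `Sd` the total number of genes in the database. `Nn * Nl` is
#' the total number of gene slots inspected; `Nod / Sd` the per-slot chance of
#' the target domain.
#'
#' @param Nn number of query neighborhoods (>= 1).
#' @param Nl mean neighborhood size in genes (> 0).
#' @param Nod occurrences of the target domain in the database (0 <= Nod <= Sd).
#' @param Sd total genes in the database (>= 1).
#' @return the expectation, a single non-negative number.
#' @examples
#' expected_lambda(10, 10, 50, 10000)  # 0.5
#' @export
expected_lambda <- function(Nn, Nl, Nod, Sd) {
  if (any(Sd < 1)) gh_parameter_error("`Sd` must be >= 1")
  if (any(Nn < 1)) gh_parameter_error("`Nn` must be >= 1")
  if (any(Nl <= 0)) gh_parameter_error("`Nl` must be > 0")
  if (any(Nod < 0) || any(Nod > Sd)) {
    gh_parameter_error("`Nod` must satisfy 0 <= Nod <= Sd")
  }
  Nn * Nl * Nod / Sd
}

#' Upper-tail Poisson probability score
#'
#' The probability of observing `k` or more events under a Poisson law with
#' mean `lambda`: `P(X >= k) = 1 - sum_{k' < k} exp(-lambda) lambda^k' / k'!`.
#' Computed through the Poisson survival function, which is numerically stable
#' in the far tail (no `1 - sum` cancellation), so scores remain finite and
#' accurate for `k` in the tens of thousands and `lambda` in the thousands.
#'
#' @param k observed count(s), non-negative integer(s).
#' @param lambda expected count(s), non-negative.
#' @return `P(X >= k)`, vectorized over `k` and `lambda`.
#' @examples
#' poisson_pscore(0, 3)    # 1
#' poisson_pscore(2, 1)    # 1 - 2*exp(-1)
#' @export
poisson_pscore <- function(k, lambda) {
  if (any(k < 0) || any(k != floor(k))) {
    gh_parameter_error("`k` must be non-negative integer(s)")
  }
  if (any(lambda < 0)) gh_parameter_error("`lambda` must be non-negative")
  # survival function: P(X >= k) = P(X > k - 1)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Count a domain's occurrences across neighborhoods
#'
#' `k` is per-gene presence summed over neighborhoods: a domain carried by
#' three member genes of one neighborhood contributes 3. This matches the
#' construction of the expectation, in which each of the `Nn * Nl` gene slots
#' is a trial with success probability `Nod / Sd`. The presence fraction is
#' the proportion of neighborhoods containing the domain at least once (the
#' "percentage in neighborhoods" of the results table).
#'
#' @param neighborhoods a `neighborhood_set`.
#' @param domain a Pfam accession.
#' @return list with elements `k` (integer) and `presence_fraction`.
#' @export
count_in_neighborhoods <- function(neighborhoods, domain) {
  if (length(neighborhoods) == 0L) gh_parameter_error("`neighborhoods` must be nonempty")
  per_nb <- vapply(neighborhoods, function(nb) {
    v <- nb$domain_multiset[domain]
    if (is.na(v)) 0L else as.integer(v)
  }, 0L)
  list(k = sum(per_nb),
       presence_fraction = mean(per_nb > 0L))
}

#' Adjust a vector of P scores for multiple testing
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @param method `"none"`, `"bonferroni"` (`min(1, m p)`), or
#'   `"benjamini_hochberg"` (step-up adjusted values).
#' @return adjusted probabilities, same length and order as `p`.
#' @export
correct_pvalues <- function(p, method = c("none", "bonferroni",
                                          "benjamini_hochberg")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    gh_parameter_error("`p` must be probabilities in [0, 1]")
  }
  switch(method,
         none = p,
         bonferroni = stats::p.adjust(p, method = "bonferroni"),
         benjamini_hochberg = stats::p.adjust(p, method = "BH"))
}

# Core enrichment computation over an extracted neighborhood set.
#
# Returns both the unfiltered candidate table (every domain seen in any
# neighborhood, with k, Nod, lambda, p_score, presence) and the retained
# table: domains with k >= lambda (those occurring at least as often as in a
# random neighborhood), corrected for multiple testing over the retained set
# and sorted by p_score (ties: k descending, then accession).
compute_enrichment <- function(db, neighborhoods, correction = "none",
                               query_domain = NULL, pfam_meta = NULL) {
  if (length(neighborhoods) == 0L) gh_parameter_error("`neighborhoods` must be nonempty")
  Nn <- length(neighborhoods)
  Nl <- mean_neighborhood_size(neighborhoods)
  Sd <- db$Sd

  multisets <- lapply(neighborhoods, `[[`, "domain_multiset")
  dom_all <- unlist(lapply(multisets, names), use.names = FALSE)
  cnt_all <- unlist(multisets, use.names = FALSE)
  if (length(dom_all) == 0L) {
    empty <- enrichment_row_frame(character(0))
    return(list(candidates = empty, table = empty,
                Nn = Nn, Nl = Nl, Sd = Sd, m = 0L))
  }
  k <- rowsum(as.numeric(cnt_all), dom_all, reorder = TRUE)
  domains <- rownames(k)
  k <- as.integer(k[, 1L])
  presence_n <- rowsum(as.numeric(cnt_all > 0L), dom_all, reorder = TRUE)[, 1L]

  Nod <- db$Nod[domains]
  if (anyNA(Nod)) {
    gh_parameter_error(sprintf(
      "domain '%s' occurs in the neighborhoods but not in the background database; neighborhoods and database are inconsistent",
      domains[which(is.na(Nod))[1L]]))
  }
  lambda <- expected_lambda(Nn, Nl, as.integer(Nod), Sd)
  p_score <- poisson_pscore(k, lambda)

  cand <- enrichment_row_frame(domains, pfam_meta)
  cand$k <- k
  cand$Nod <- as.integer(Nod)
  cand$lambda <- lambda
  cand$p_score <- p_score
  cand$p_corrected <- p_score
  cand$presence_fraction <- as.numeric(presence_n) / Nn
  cand$is_query <- !is.null(query_domain) & cand$domain %in% query_domain

  retained <- cand[cand$k >= cand$lambda, , drop = FALSE]
  retained$p_corrected <- correct_pvalues(retained$p_score, correction)
  ord <- order(retained$p_score, -retained$k, retained$domain)
  retained <- retained[ord, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(cand) <- NULL
  list(candidates = cand, table = retained,
       Nn = Nn, Nl = Nl, Sd = Sd, m = nrow(retained))
}

enrichment_row_frame <- function(domains, pfam_meta = NULL) {
  out <- data.frame(
    domain = domains,
    name = character(length(domains)),
    description = character(length(domains)),
    k = integer(length(domains)),
    Nod = integer(length(domains)),
    lambda = numeric(length(domains)),
    p_score = numeric(length(domains)),
    p_corrected = numeric(length(domains)),
    presence_fraction = numeric(length(domains)),
    is_query = logical(length(domains)),
    go_ids = character(length(domains)),
    go_terms = character(length(domains)),
    stringsAsFactors = FALSE
  )
  if (!is.null(pfam_meta) && length(domains) > 0L) {
    i <- match(domains, pfam_meta$accession)
    out$name <- ifelse(is.na(i), "", as.character(pfam_meta$name[i]))
    out$description <- ifelse(is.na(i), "", as.character(pfam_meta$description[i]))
  }
  out
}

#' Taxonomy report for the query genes
#'
#' Shows in which genes and genomes the query was found: one row per query
#' gene with its genome's full lineage, plus per-rank counts of distinct
#' query genomes.
#'
#' @param db a [genome_db()].
#' @param query_genes data.frame of resolved query genes.
#' @return object of class `taxonomy_report`: list with `genes` (data.frame)
#'   and `rank_counts` (named list of named integer vectors, one per rank).
#' @export
taxonomy_report <- function(db, query_genes) {
  stopifnot(inherits(db, "genome_db"))
  i <- match(query_genes$genome_id, db$taxonomy$genome_id)
  genes <- data.frame(gene_id = query_genes$gene_id,
                      genome_id = query_genes$genome_id,
                      stringsAsFactors = FALSE)
  for (r in TAXON_RANKS) genes[[r]] <- db$taxonomy[[r]][i]
  genomes <- genes[!duplicated(genes$genome_id), , drop = FALSE]
  rank_counts <- lapply(TAXON_RANKS, function(r) {
    v <- genomes[[r]]
    v[is.na(v)] <- "<missing>"
    tab <- table(v)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(rank_counts) <- TAXON_RANKS
  structure(list(genes = genes, rank_counts = rank_counts),
            class = "taxonomy_report")
}

#' @export
print.taxonomy_report <- function(x, ...) {
  cat(sprintf("<taxonomy_report> %d query genes in %d genomes\n",
              nrow(x$genes), length(unique(x$genes$genome_id))))
  gc <- x$rank_counts$genus
  gc <- sort(gc, decreasing = TRUE)
  top <- utils::head(gc, 5L)
  cat("  top genera: ",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n", sep = "")
  invisible(x)
}
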