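#' Genomic neighborhood enrichment analysis
#'
#' The package's main fitting function. Resolves the query into genes,
#' extracts each gene's genomic neighborhood (all genes within `radius_bp` on
#' the same contig), and scores every domain observed in the neighborhoods
#' with an upper-tail Poisson probability (`P` score) against its
#' whole-database frequency. Domains occurring less often than expected in a
#' random neighborhood (`k < lambda`) are excluded before multiple-testing
#' correction.
#'
#' With `average_rank` set, the subtaxon-averaging correction for uneven
#' genome sampling is applied first: neighborhoods are grouped by the query
#' genome's lineage at that rank (subtaxa with fewer than `min_genomes`
#' database genomes are dropped), every subtaxon is brought up to the largest
#' group's neighborhood count by seeded resampling with replacement, and the
#' background counts (`Nod`, `Sd`) are recomputed over the retained subtaxa's
#' genomes only.
#'
#' @param db a [genome_db()].
#' @param pfam query Pfam accession (mutually exclusive with `genes`).
#' @param genes query gene-ID vector (mutually exclusive with `pfam`).
#' @param radius_bp neighborhood half-width in bp each direction (default
#'   5000, roughly a 10-gene window at typical bacterial gene density).
#' @param strand_mode `"all"`, `"same"` or `"opposite"` (relative to the
#'   query gene; the query gene is always kept).
#' @param taxon_filter optional `c(rank = name)`; restricts the *whole*
#'   analysis (query and background) to that taxon.
#' @param average_rank optional rank for subtaxon averaging, or `NULL`.
#' @param min_genomes minimum database genomes per subtaxon (default 25).
#' @param correction `"none"`, `"bonferroni"` or `"benjamini_hochberg"`,
#'   applied over the retained (`k >= lambda`) domains.
#' @param pscore_cutoff significance threshold on the (corrected) `P` score
#'   used by [significant_domains()] and the writers (default `1e-5`).
#' @param min_presence minimum fraction of query neighborhoods a domain must
#'   appear in to be reported significant (default `0.05`).
#' @param seed RNG seed for the averaging draws (default 1; recorded in the
#'   result).
#' @param pfam_meta optional data.frame `accession`/`name`/`description`
#'   filling the name and description columns.
#' @param pfam2go optional [read_pfam2go()] map; significant output rows are
#'   annotated with GO terms.
#'
#' @return An object of class `domain_enrichment` with components
#'   \describe{
#'     \item{table}{retained domains (`k >= lambda`), corrected and sorted by
#'       `p_score` (ties: `k` descending, then accession).}
#'     \item{candidates}{every domain seen in the neighborhoods, unfiltered.}
#'     \item{Nn, Nl, Sd, m}{neighborhood count, mean neighborhood size
#'       (genes), database size (genes), number of retained tests.}
#'     \item{neighborhoods}{the (balanced, when averaging) neighborhood set.}
#'     \item{averaging_report}{per-subtaxon contribution table, or `NULL`.}
#'     \item{taxonomy}{a [taxonomy_report()] for the query genes.}
#'     \item{status}{`"ok"` or `"query_not_found"`.}
#'   }
#' @examples
#' spec <- fixture_spec(n_genomes = 12, genes_per_genome = 60, seed = 42)
#' sim <- simulate_genome_db(spec)
#' db <- genome_db(sim$genes, sim$taxonomy)
#' fit <- neighborhood_enrich(db, pfam = spec$query_domain)
#' fit
#' head(significant_domains(fit))
#' @export
neighborhood_enrich <- function(db, pfam = NULL, genes = NULL,
                                radius_bp = 5000,
                                strand_mode = c("all", "same", "opposite"),
                                taxon_filter = NULL,
                                average_rank = NULL,
                                min_genomes = 25,
                                correction = c("none", "bonferroni",
                                               "benjamini_hochberg"),
                                pscore_cutoff = 1e-5,
                                min_presence = 0.05,
                                seed = 1L,
                                pfam_meta = NULL,
                                pfam2go = NULL) {
  stopifnot(inherits(db, "genome_db"))
  strand_mode <- match.arg(strand_mode)
  correction <- match.arg(correction)
  if (!is.numeric(pscore_cutoff) || pscore_cutoff <= 0 || pscore_cutoff > 1) {
    gh_parameter_error("`pscore_cutoff` must be in (0, 1]")
  }
  if (!is.numeric(min_presence) || min_presence < 0 || min_presence > 1) {
    gh_parameter_error("`min_presence` must be in [0, 1]")
  }
  if (!is.null(average_rank)) check_rank(average_rank)

  cl <- match.call()
  if (!is.null(taxon_filter)) {
    tf <- as_taxon_filter(taxon_filter)
    db <- subset_by_taxon(db, tf$rank, tf$name)
  }

  params <- list(radius_bp = radius_bp, strand_mode = strand_mode,
                 taxon_filter = taxon_filter, average_rank = average_rank,
                 min_genomes = min_genomes, correction = correction,
                 pscore_cutoff = pscore_cutoff, min_presence = min_presence,
                 seed = as.integer(seed))

  query_genes <- resolve_query(db, pfam = pfam, genes = genes)
  if (identical(attr(query_genes, "status"), "not_found")) {
    empty <- enrichment_row_frame(character(0))
    return(structure(list(
      table = empty, candidates = empty,
      Nn = 0L, Nl = NA_real_, Sd = db$Sd, m = 0L,
      query = list(pfam = pfam, genes = genes, n_genes = 0L,
                   unmatched = character(0)),
      params = params, neighborhoods = NULL, averaging_report = NULL,
      taxonomy = NULL, status = "query_not_found", call = cl
    ), class = "domain_enrichment"))
  }

  nbs <- extract_neighborhoods(db, query_genes, radius_bp = radius_bp,
                               strand_mode = strand_mode)
  tax_rep <- taxonomy_report(db, query_genes)

  averaging_report <- NULL
  db_bg <- db
  if (!is.null(average_rank)) {
    groups <- group_by_subtaxon(nbs, db, average_rank, min_genomes)
    nbs <- balance_subtaxa(groups, seed = seed)
    averaging_report <- attr(nbs, "report")
    retained_taxa <- vapply(groups, `[[`, "", "name")
    keep_genomes <- db$taxonomy$genome_id[
      !is.na(db$taxonomy[[average_rank]]) &
        db$taxonomy[[average_rank]] %in% retained_taxa]
    db_bg <- subset_by_genomes(db, keep_genomes)
  }

  res <- compute_enrichment(db_bg, nbs, correction = correction,
                            query_domain = pfam, pfam_meta = pfam_meta)

  fit <- structure(list(
    table = res$table, candidates = res$candidates,
    Nn = res$Nn, Nl = res$Nl, Sd = res$Sd, m = res$m,
    query = list(pfam = pfam, genes = genes, n_genes = nrow(query_genes),
                 unmatched = attr(query_genes, "unmatched") %||% character(0)),
    params = params, neighborhoods = nbs,
    averaging_report = averaging_report,
    taxonomy = tax_rep, status = "ok", call = cl
  ), class = "domain_enrichment")

  if (!is.null(pfam2go)) fit <- annotate_go(fit, pfam2go)
  fit
}

#' Significant domains from an enrichment fit
#'
#' Applies the reporting convention: corrected `P` score strictly below the
#' cutoff and presence in at least `min_presence` of the query neighborhoods.
#'
#' @param object a `domain_enrichment`.
#' @param pscore_cutoff,min_presence thresholds; default to the fit's.
#' @param drop_query drop the query domain's own row (always trivially
#'   enriched)? Default `FALSE`; it stays flagged via `is_query`.
#' @return data.frame of significant rows, ordered as in `object$table`.
#' @export
significant_domains <- function(object,
                                pscore_cutoff = object$params$pscore_cutoff,
                                min_presence = object$params$min_presence,
                                drop_query = FALSE) {
  stopifnot(inherits(object, "domain_enrichment"))
  tab <- object$table
  keep <- tab$p_corrected < pscore_cutoff & tab$presence_fraction >= min_presence
  if (drop_query) keep <- keep & !tab$is_query
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.domain_enrichment <- function(x, n = 10L, ...) {
  cat("<domain_enrichment>\n")
  q <- if (!is.null(x$query$pfam)) sprintf("domain %s", x$query$pfam)
       else sprintf("gene list (%d genes)", x$query$n_genes)
  cat(sprintf("  query: %s; status: %s\n", q, x$status))
  if (x$status != "ok") return(invisible(x))
  cat(sprintf("  neighborhoods Nn = %d, mean size Nl = %.2f genes; background Sd = %d genes\n",
              x$Nn, x$Nl, x$Sd))
  if (!is.null(x$averaging_report)) {
    cat(sprintf("  subtaxon averaging at rank '%s': %d subtaxa x %d neighborhoods each (seed %d)\n",
                x$params$average_rank, nrow(x$averaging_report),
                x$averaging_report$n_contributed[1L], x$params$seed))
  }
  sig <- significant_domains(x)
  cat(sprintf("  %d candidate domains, %d retained (k >= lambda), %d significant (p < %g, presence >= %g)\n",
              nrow(x$candidates), x$m, nrow(sig),
              x$params$pscore_cutoff, x$params$min_presence))
  if (nrow(sig) > 0L) {
    show <- utils::head(sig[, c("domain", "k", "Nod", "lambda", "p_score",
                                "p_corrected", "presence_fraction", "is_query")], n)
    show$lambda <- signif(show$lambda, 4)
    show$p_score <- signif(show$p_score, 4)
    show$p_corrected <- signif(show$p_corrected, 4)
    show$presence_fraction <- round(show$presence_fraction, 4)
    print(show)
    if (nrow(sig) > n) cat(sprintf("  ... and %d more rows\n", nrow(sig) - n))
  }
  invisible(x)
}

#' @export
summary.domain_enrichment <- function(object, ...) {
  sig <- significant_domains(object)
  structure(list(
    query = object$query, status = object$status, params = object$params,
    Nn = object$Nn, Nl = object$Nl, Sd = object$Sd,
    n_candidates = nrow(object$candidates), n_retained = object$m,
    n_significant = nrow(sig), significant = sig,
    averaging_report = object$averaging_report
  ), class = "summary.domain_enrichment")
}

#' @export
print.summary.domain_enrichment <- function(x, ...) {
  q <- if (!is.null(x$query$pfam)) sprintf("domain %s", x$query$pfam)
       else sprintf("gene list (%d genes)", x$query$n_genes)
  cat(sprintf("Neighborhood enrichment of %s\n", q))
  cat(sprintf("  Nn = %d neighborhoods (Nl = %.2f genes), Sd = %d background genes\n",
              x$Nn, x$Nl, x$Sd))
  cat(sprintf("  candidates: %d; retained (k >= lambda): %d; significant: %d\n",
              x$n_candidates, x$n_retained, x$n_significant))
  if (!is.null(x$averaging_report)) {
    cat("  subtaxon contributions:\n")
    print(x$averaging_report, row.names = FALSE)
  }
  if (x$n_significant > 0L) {
    cat("  significant domains:\n")
    show <- x$significant[, c("domain", "k", "Nod", "lambda", "p_score",
                              "presence_fraction", "is_query")]
    show$lambda <- signif(show$lambda, 4)
    show$p_score <- signif(show$p_score, 4)
    show$presence_fraction <- round(show$presence_fraction, 4)
    print(utils::head(show, 20L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.domain_enrichment <- function(x, ...) x$table

#' Plot the strongest neighborhood associations
#'
#' Horizontal bars of `-log10(P score)` for the top significant domains
#' (query domain excluded), the standard at-a-glance view of an enrichment
#' result.
#'
#' @param x a `domain_enrichment`.
#' @param n number of domains to show (default 15).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.domain_enrichment <- function(x, n = 15L, ...) {
  sig <- significant_domains(x, drop_query = TRUE)
  if (nrow(sig) == 0L) {
    graphics::plot.new()
    graphics::title(main = "No significant neighborhood domains")
    return(invisible(x))
  }
  sig <- utils::head(sig, n)
  vals <- -log10(pmax(sig$p_score, .Machine$double.xmin))
  graphics::barplot(rev(vals), names.arg = rev(sig$domain), horiz = TRUE,
                    las = 1, xlab = expression(-log[10](italic(P)~score)),
                    main = "Top neighborhood domains", ...)
  invisible(x)
}
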