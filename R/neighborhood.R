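#' Resolve a query into its gene set
#'
#' A query is either a Pfam domain accession (translated to every gene whose
#' protein carries the domain) or an explicit list of gene identifiers, e.g.
#' precomputed homologs of a protein of interest.
#'
#' @param db a [genome_db()].
#' @param pfam a single Pfam accession, or `NULL`.
#' @param genes a character vector of gene IDs, or `NULL`. Exactly one of
#'   `pfam` / `genes` must be given.
#' @param taxon_filter optional `c(rank = name)` restriction (pfam mode).
#' @return data.frame of query gene rows with attributes `status`
#'   (`"ok"`/`"not_found"`) and `unmatched` (unknown gene IDs, gene-list mode).
#'   All-unknown gene lists are an error; a partially unknown list is not.
#' @export
resolve_query <- function(db, pfam = NULL, genes = NULL, taxon_filter = NULL) {
  stopifnot(inherits(db, "genome_db"))
  if (is.null(pfam) == is.null(genes)) {
    gh_parameter_error("exactly one of `pfam` or `genes` must be supplied")
  }
  if (!is.null(pfam)) {
    res <- genes_with_domain(db, pfam, taxon_filter = taxon_filter)
    attr(res, "unmatched") <- character(0)
    return(res)
  }
  genes <- as.character(genes)
  if (length(genes) == 0L) gh_parameter_error("`genes` must be a nonempty gene-ID vector")
  idx <- db$gene_index[genes]
  unmatched <- genes[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    gh_empty_error(sprintf("none of the %d supplied gene IDs are in the database",
                           length(genes)))
  }
  res <- db$genes[sort(unname(idx)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "status") <- "ok"
  attr(res, "unmatched") <- unmatched
  res
}

#' Extract the genomic neighborhood of one gene
#'
#' The neighborhood is every gene on the query gene's contig whose
#' `[start, end]` interval overlaps the window
#' `[query_start - radius_bp, query_end + radius_bp]` (any overlap suffices;
#' the window is anchored on the gene body, and clamped at position 1). The
#' query gene is always a member.
#'
#' @param db a [genome_db()].
#' @param gene_id a gene identifier present in `db`.
#' @param radius_bp window half-width in base pairs on each side (default
#'   5000, which in typical bacterial gene density corresponds to roughly a
#'   10-gene neighborhood).
#' @param strand_mode `"all"` keeps every overlapping gene; `"same"` keeps
#'   only neighbors on the query's strand; `"opposite"` only the other strand.
#'   The query gene is kept in every mode.
#' @return object of class `neighborhood`: list with `query_gene_id`,
#'   `genome_id`, `contig_id`, `member_genes` (data.frame ordered by start),
#'   `domain_multiset` (named integer, per-gene presence counts),
#'   `domain_set`, `n_genes`.
#' @export
extract_neighborhood <- function(db, gene_id, radius_bp = 5000,
                                 strand_mode = c("all", "same", "opposite")) {
  stopifnot(inherits(db, "genome_db"))
  strand_mode <- match.arg(strand_mode)
  if (!is.numeric(radius_bp) || length(radius_bp) != 1L || radius_bp <= 0) {
    gh_parameter_error("`radius_bp` must be a single positive number")
  }
  row <- db$gene_index[[gene_id]]
  if (is.null(row) || is.na(row)) {
    gh_parameter_error(sprintf("gene '%s' is not in the database", gene_id))
  }
  build_neighborhood(db, row, radius_bp, strand_mode)
}

# Internal fast path working on a row index.
build_neighborhood <- function(db, row, radius_bp, strand_mode) {
  g <- db$genes
  contig_rows <- db$contig_index[[db$contig_key[row]]]
  win_lo <- max(1L, g$start[row] - radius_bp)
  win_hi <- g$end[row] + radius_bp
  s <- g$start[contig_rows]; e <- g$end[contig_rows]
  keep <- e >= win_lo & s <= win_hi
  members <- contig_rows[keep]
  if (strand_mode != "all") {
    same <- g$strand[members] == g$strand[row]
    keep2 <- if (strand_mode == "same") same else !same
    keep2[members == row] <- TRUE  # query always kept
    members <- members[keep2]
  }
  members <- members[order(g$start[members], g$end[members], g$gene_id[members])]
  member_genes <- g[members, , drop = FALSE]
  rownames(member_genes) <- NULL
  doms <- unlist(member_genes$domains, use.names = FALSE)
  multiset <- if (length(doms) > 0L) {
    tab <- table(doms)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  structure(list(
    query_gene_id = g$gene_id[row],
    genome_id = g$genome_id[row],
    contig_id = g$contig_id[row],
    member_genes = member_genes,
    domain_multiset = multiset,
    domain_set = names(multiset),
    n_genes = nrow(member_genes)
  ), class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> query %s (%s / %s): %d genes, %d distinct domains\n",
              x$query_gene_id, x$genome_id, x$contig_id, x$n_genes,
              length(x$domain_set)))
  invisible(x)
}

#' Extract neighborhoods for a set of query genes
#'
#' One neighborhood per query gene, in input order. Neighborhoods of nearby
#' query genes may share member genes; they are deliberately kept as separate
#' entries, never merged.
#'
#' @param db a [genome_db()].
#' @param genes data.frame of query gene rows (from [resolve_query()]) or a
#'   character vector of gene IDs.
#' @inheritParams extract_neighborhood
#' @return list of `neighborhood` objects (class `neighborhood_set`).
#' @export
extract_neighborhoods <- function(db, genes, radius_bp = 5000,
                                  strand_mode = c("all", "same", "opposite")) {
  stopifnot(inherits(db, "genome_db"))
  strand_mode <- match.arg(strand_mode)
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  if (length(ids) == 0L) gh_parameter_error("`genes` must be nonempty")
  rows <- db$gene_index[ids]
  if (anyNA(rows)) {
    gh_parameter_error(sprintf("gene '%s' is not in the database",
                               ids[which(is.na(rows))[1L]]))
  }
  out <- lapply(unname(rows), build_neighborhood, db = db,
                radius_bp = radius_bp, strand_mode = strand_mode)
  structure(out, class = c("neighborhood_set", "list"))
}

#' @export
print.neighborhood_set <- function(x, ...) {
  ng <- vapply(x, `[[`, 0L, "n_genes")
  cat(sprintf("<neighborhood_set> %d neighborhoods; genes per neighborhood: mean %.2f (range %d-%d)\n",
              length(x), mean(ng), min(ng), max(ng)))
  invisible(x)
}

#' Mean neighborhood size in genes
#'
#' The empirical mean number of genes per neighborhood, `Nl`. Together with
#' the neighborhood count `Nn` it sets the number of gene slots `Nn * Nl`
#' against which the expected domain count is computed.
#'
#' @param neighborhoods a `neighborhood_set` or list of `neighborhood`s.
#' @return a single number.
#' @export
mean_neighborhood_size <- function(neighborhoods) {
  if (length(neighborhoods) == 0L) {
    gh_parameter_error("`neighborhoods` must be nonempty")
  }
  mean(vapply(neighborhoods, `[[`, 0L, "n_genes"))
}

#' Serialize neighborhoods to a long-format table
#'
#' @param neighborhoods a `neighborhood_set`.
#' @return data.frame with one row per (neighborhood, member gene):
#'   `query_gene_id`, `genome_id`, `contig_id`, `member_gene_id`, `domains`
#'   (semicolon-separated).
#' @export
neighborhoods_as_table <- function(neighborhoods) {
  rows <- lapply(neighborhoods, function(nb) {
    data.frame(
      query_gene_id = nb$query_gene_id,
      genome_id = nb$genome_id,
      contig_id = nb$contig_id,
      member_gene_id = nb$member_genes$gene_id,
      domains = vapply(nb$member_genes$domains, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
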