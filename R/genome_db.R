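#' Build an indexed genome annotation database
#'
#' Assembles a validated, indexed database from a gene annotation table and an
#' optional taxonomy table. The database caches the two global quantities the
#' enrichment model needs: `Sd`, the total number of genes, and `Nod`, the
#' per-domain count of genes carrying each domain (per-gene presence: repeated
#' hits of one domain within one protein count once, so `Nod <= Sd` always
#' holds).
#'
#' @param genes data.frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand` and `domains`. `domains` may be a list column of
#'   character vectors of Pfam accessions, or a character column of
#'   semicolon/comma-separated accessions (empty string = unannotated gene).
#'   Coordinates are 1-based inclusive; `strand` is `"+"` or `"-"`.
#' @param taxonomy optional data.frame with columns `genome_id`, `phylum`,
#'   `class`, `order`, `family`, `genus`. Missing ranks are `NA`. Genomes
#'   present in `genes` but absent here receive an all-`NA` lineage with a
#'   warning.
#'
#' @return An object of class `genome_db`: a list with elements `genes`
#'   (sorted by genome, contig, start), `taxonomy`, `Sd`, `Nod` (named integer
#'   vector), and internal position/domain indexes.
#' @examples
#' g <- data.frame(
#'   gene_id = c("g1", "g2", "g3"), genome_id = "G1", contig_id = "c1",
#'   start = c(100, 600, 1200), end = c(400, 900, 1500), strand = "+",
#'   domains = c("PF00001", "", "PF00001;PF00002")
#' )
#' db <- genome_db(g)
#' db$Sd      # 3
#' db$Nod     # PF00001 = 2, PF00002 = 1
#' @export
genome_db <- function(genes, taxonomy = NULL) {
  required <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand",
                "domains")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    gh_schema_error(sprintf("gene table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) == 0L) {
    gh_empty_error("gene table has no rows: refusing to build an empty database")
  }

  genes$gene_id   <- as.character(genes$gene_id)
  genes$genome_id <- as.character(genes$genome_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$start     <- as.integer(genes$start)
  genes$end       <- as.integer(genes$end)
  genes$strand    <- as.character(genes$strand)

  if (!is.list(genes$domains)) {
    genes$domains <- parse_domain_strings(as.character(genes$domains))
  } else {
    # collapse duplicate (gene, domain) pairs to set semantics
    genes$domains <- lapply(genes$domains, function(d) {
      d <- as.character(d)
      unique(d[!is.na(d) & nzchar(d)])
    })
  }

  bad_coord <- which(is.na(genes$start) | is.na(genes$end) |
                     genes$start > genes$end | genes$start < 1L)
  if (length(bad_coord) > 0L) {
    gh_integrity_error(sprintf(
      "%d gene row(s) with invalid coordinates (need 1 <= start <= end), e.g. gene_id %s",
      length(bad_coord), genes$gene_id[bad_coord[1L]]))
  }
  bad_strand <- which(!genes$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    gh_integrity_error(sprintf(
      "%d gene row(s) with unknown strand (need '+' or '-'), e.g. gene_id %s",
      length(bad_strand), genes$gene_id[bad_strand[1L]]))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    gh_integrity_error(sprintf(
      "duplicate gene_id(s): %s%s", paste(utils::head(dup, 5L), collapse = ", "),
      if (length(dup) > 5L) sprintf(" (and %d more)", length(dup) - 5L) else ""))
  }

  ord <- order(genes$genome_id, genes$contig_id, genes$start, genes$end,
               genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL

  taxonomy <- normalize_taxonomy(taxonomy, unique(genes$genome_id),
                                 warn_absent = !is.null(taxonomy))

  db <- structure(list(genes = genes, taxonomy = taxonomy), class = "genome_db")
  rebuild_indexes(db)
}

# Split "PF1;PF2" / "PF1,PF2" strings into per-gene accession sets.
parse_domain_strings <- function(x) {
  x[is.na(x)] <- ""
  parts <- strsplit(x, "[;,]")
  lapply(parts, function(d) {
    d <- trimws(d)
    unique(d[nzchar(d)])
  })
}

normalize_taxonomy <- function(taxonomy, genome_ids, warn_absent = TRUE) {
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(genome_id = character(0), stringsAsFactors = FALSE)
    for (r in TAXON_RANKS) taxonomy[[r]] <- character(0)
  }
  needed <- c("genome_id", TAXON_RANKS)
  missing_cols <- setdiff(needed, names(taxonomy))
  if (length(missing_cols) > 0L) {
    gh_schema_error(sprintf("taxonomy table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  taxonomy <- taxonomy[, needed, drop = FALSE]
  taxonomy$genome_id <- as.character(taxonomy$genome_id)
  for (r in TAXON_RANKS) {
    v <- as.character(taxonomy[[r]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    taxonomy[[r]] <- v
  }
  dup <- unique(taxonomy$genome_id[duplicated(taxonomy$genome_id)])
  if (length(dup) > 0L) {
    gh_integrity_error(sprintf("duplicate taxonomy rows for genome_id(s): %s",
                               paste(utils::head(dup, 5L), collapse = ", ")))
  }
  absent <- setdiff(genome_ids, taxonomy$genome_id)
  if (length(absent) > 0L) {
    if (warn_absent) {
      warning(sprintf(
        "%d genome(s) in the gene table have no taxonomy row; assigned all-missing lineages (e.g. %s)",
        length(absent), absent[1L]), call. = FALSE)
    }
    filler <- data.frame(genome_id = absent, stringsAsFactors = FALSE)
    for (r in TAXON_RANKS) filler[[r]] <- NA_character_
    taxonomy <- rbind(taxonomy, filler)
  }
  taxonomy <- taxonomy[order(taxonomy$genome_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  taxonomy
}

rebuild_indexes <- function(db) {
  genes <- db$genes
  db$Sd <- nrow(genes)

  n_dom <- lengths(genes$domains)
  all_dom <- unlist(genes$domains, use.names = FALSE)
  gene_of_dom <- rep.int(seq_len(nrow(genes)), n_dom)
  if (length(all_dom) > 0L) {
    tab <- table(all_dom)
    db$Nod <- stats::setNames(as.integer(tab), names(tab))
    db$domain_index <- split(gene_of_dom, all_dom)
  } else {
    db$Nod <- stats::setNames(integer(0), character(0))
    db$domain_index <- list()
  }

  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  db$contig_index <- split(seq_len(nrow(genes)), key)
  db$contig_key <- key
  db$gene_index <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  db
}

#' Read a gene annotation table from TSV
#'
#' Expects a header row and columns `gene_id`, `genome_id`, `contig_id`,
#' `start`, `end`, `strand`, `domains`, with `domains` a
#' semicolon- (or comma-) separated list of Pfam accessions, possibly empty.
#'
#' @param path path to a tab-separated file.
#' @param taxonomy_path optional path to a taxonomy TSV, passed to
#'   [read_taxonomy()].
#' @return a [genome_db()] object.
#' @export
read_gene_table <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) gh_parameter_error(sprintf("file not found: %s", path))
  genes <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "",
                             na.strings = NULL, check.names = FALSE)
  if (nrow(genes) == 0L) {
    gh_empty_error(sprintf("gene table %s contains a header but no rows", path))
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  genome_db(genes, taxonomy)
}

#' Read a genome taxonomy table from TSV
#'
#' Columns: `genome_id`, `phylum`, `class`, `order`, `family`, `genus`;
#' blank rank cells become explicit missing values.
#'
#' @param path path to a tab-separated file with a header row.
#' @return data.frame of lineages, one row per genome.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) gh_parameter_error(sprintf("file not found: %s", path))
  raw <- readLines(path)
  if (length(raw) < 1L) gh_schema_error(sprintf("taxonomy file %s is empty", path))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols != ncols[1L])
  if (length(bad) > 0L) {
    gh_schema_error(sprintf("taxonomy file %s: malformed row at line %d (%d fields, expected %d)",
                            path, bad[1L], ncols[bad[1L]], ncols[1L]))
  }
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = c("", "NA"), check.names = FALSE)
  tax
}

#' Write a database back to the gene-table / taxonomy TSV dialect
#'
#' @param db a `genome_db`.
#' @param genes_path,taxonomy_path output file paths (`NULL` skips one).
#' @return invisibly, the paths written.
#' @export
write_gene_table <- function(db, genes_path, taxonomy_path = NULL) {
  stopifnot(inherits(db, "genome_db"))
  g <- db$genes
  out <- data.frame(
    gene_id = g$gene_id, genome_id = g$genome_id, contig_id = g$contig_id,
    start = g$start, end = g$end, strand = g$strand,
    domains = vapply(g$domains, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path)) {
    tax <- db$taxonomy
    tax[is.na(tax)] <- ""
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(genes_path, taxonomy_path))
}

#' Genes carrying a given domain
#'
#' @param db a `genome_db`.
#' @param domain a Pfam accession, e.g. `"PF00001"`.
#' @param taxon_filter optional `c(rank = name)` length-1 named character
#'   vector (or `list(rank =, name =)`) restricting to genomes whose lineage
#'   matches at that rank.
#' @return the matching rows of `db$genes` in (genome, contig, start) order,
#'   with attribute `status` set to `"ok"` or `"not_found"` (a query domain
#'   absent from the database is a status, not an error).
#' @export
genes_with_domain <- function(db, domain, taxon_filter = NULL) {
  stopifnot(inherits(db, "genome_db"))
  if (!is.character(domain) || length(domain) != 1L || !nzchar(domain)) {
    gh_parameter_error("`domain` must be a single non-empty accession string")
  }
  idx <- db$domain_index[[domain]]
  if (is.null(idx)) {
    res <- db$genes[0L, , drop = FALSE]
    attr(res, "status") <- "not_found"
    return(res)
  }
  idx <- sort(idx)
  res <- db$genes[idx, , drop = FALSE]
  if (!is.null(taxon_filter)) {
    tf <- as_taxon_filter(taxon_filter)
    keep_genomes <- db$taxonomy$genome_id[
      !is.na(db$taxonomy[[tf$rank]]) & db$taxonomy[[tf$rank]] == tf$name]
    res <- res[res$genome_id %in% keep_genomes, , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "status") <- if (nrow(res) > 0L) "ok" else "not_found"
  res
}

as_taxon_filter <- function(x) {
  if (is.list(x)) {
    rank <- x$rank; name <- x$name
  } else if (!is.null(names(x)) && length(x) == 1L) {
    rank <- names(x); name <- unname(x)
  } else if (length(x) == 2L) {
    rank <- x[[1L]]; name <- x[[2L]]
  } else {
    gh_parameter_error("`taxon_filter` must be c(rank = name) or list(rank=, name=)")
  }
  list(rank = check_rank(rank), name = as.character(name))
}

#' Restrict a database to one taxon
#'
#' Keeps only genomes whose lineage matches `name` at `rank` and recomputes
#' `Sd`, `Nod` and all indexes over the subset.
#'
#' @inheritParams genes_with_domain
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @param name taxon name (exact string match; missing ranks never match).
#' @return a new `genome_db`.
#' @export
subset_by_taxon <- function(db, rank, name) {
  stopifnot(inherits(db, "genome_db"))
  rank <- check_rank(rank)
  keep_genomes <- db$taxonomy$genome_id[
    !is.na(db$taxonomy[[rank]]) & db$taxonomy[[rank]] == name]
  keep <- db$genes$genome_id %in% keep_genomes
  if (!any(keep)) {
    gh_empty_error(sprintf("no genomes with %s == '%s' in the database", rank, name))
  }
  subset_by_genomes(db, keep_genomes)
}

# Internal: restrict to an explicit genome set (used by taxon subsetting and
# by the averaging step's background recomputation).
subset_by_genomes <- function(db, genome_ids) {
  keep <- db$genes$genome_id %in% genome_ids
  genes <- db$genes[keep, , drop = FALSE]
  rownames(genes) <- NULL
  taxonomy <- db$taxonomy[db$taxonomy$genome_id %in% genome_ids, , drop = FALSE]
  rownames(taxonomy) <- NULL
  out <- structure(list(genes = genes, taxonomy = taxonomy), class = "genome_db")
  rebuild_indexes(out)
}

#' @export
print.genome_db <- function(x, ...) {
  cat(sprintf("<genome_db> %d genes, %d genomes, %d contigs, %d distinct domains\n",
              x$Sd, length(unique(x$genes$genome_id)),
              length(x$contig_index), length(x$Nod)))
  n_tax <- sum(!is.na(x$taxonomy$genus))
  cat(sprintf("  taxonomy: %d genomes, %d with genus assigned\n",
              nrow(x$taxonomy), n_tax))
  invisible(x)
}
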