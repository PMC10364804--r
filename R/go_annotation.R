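#' Read a pfam2go mapping file
#'
#' Parses the GeneOntology `external2go` line format, e.g.
#' `Pfam:PF00255 GSHPx > GO:glutathione peroxidase activity ; GO:0004602`.
#' Comment lines starting with `!` are skipped; malformed lines are skipped
#' with a count reported via `message()`.
#'
#' @param path path to a pfam2go file.
#' @return object of class `pfam2go`: data.frame with columns `pfam`,
#'   `pfam_name`, `go_id`, `go_name`; one row per (domain, term) pair. A
#'   domain may map to zero or many terms.
#' @export
read_pfam2go <- function(path) {
  if (!file.exists(path)) gh_parameter_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  pat <- "^Pfam:(PF\\d+)\\s+(\\S+)\\s*>\\s*GO:(.*?)\\s*;\\s*(GO:\\d{7})\\s*$"
  ok <- grepl(pat, lines)
  if (sum(!ok) > 0L) {
    message(sprintf("pfam2go: skipped %d malformed line(s)", sum(!ok)))
  }
  if (!any(ok)) gh_schema_error(sprintf("no parsable pfam2go lines in %s", path))
  m <- regmatches(lines[ok], regexec(pat, lines[ok]))
  out <- data.frame(
    pfam = vapply(m, `[`, "", 2L),
    pfam_name = vapply(m, `[`, "", 3L),
    go_id = vapply(m, `[`, "", 5L),
    go_name = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("pfam2go", "data.frame"))
}

#' Attach GO terms to enrichment results
#'
#' Fills the `go_ids` / `go_terms` columns of a result table from a
#' [read_pfam2go()] map. Annotation is a pure decoration: no row is added,
#' removed, or reordered, and P scores are untouched, so
#' `annotate_go(annotate_go(x, map), map)` equals `annotate_go(x, map)`.
#'
#' @param x a `domain_enrichment` fit or a plain results data.frame with a
#'   `domain` column.
#' @param map a `pfam2go` object.
#' @return `x` with `go_ids`/`go_terms` filled (semicolon-separated) where a
#'   mapping exists, empty strings otherwise.
#' @export
annotate_go <- function(x, map) {
  stopifnot(inherits(map, "pfam2go"))
  if (inherits(x, "domain_enrichment")) {
    x$table <- annotate_go(x$table, map)
    x$candidates <- annotate_go(x$candidates, map)
    return(x)
  }
  if (!is.data.frame(x) || !"domain" %in% names(x)) {
    gh_parameter_error("`x` must be a domain_enrichment or a data.frame with a `domain` column")
  }
  by_dom_ids <- split(map$go_id, map$pfam)
  by_dom_names <- split(map$go_name, map$pfam)
  hit <- x$domain %in% names(by_dom_ids)
  x$go_ids <- ifelse(hit,
    vapply(x$domain, function(d) paste(unique(by_dom_ids[[d]]), collapse = ";"), ""),
    "")
  x$go_terms <- ifelse(hit,
    vapply(x$domain, function(d) paste(unique(by_dom_names[[d]]), collapse = ";"), ""),
    "")
  x
}
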