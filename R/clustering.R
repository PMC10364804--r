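#' Jaccard index of two domain sets
#'
#' `|A intersect B| / |A union B|`, the similarity between two neighborhoods'
#' domain compositions. Two empty sets are defined as maximally dissimilar
#' (`0`, with a warning): neighborhoods with no annotated domains carry no
#' evidence of similarity, and 0/0 must not silently become 1.
#'
#' @param A,B character vectors (treated as sets).
#' @return a number in `[0, 1]`.
#' @examples
#' jaccard_index(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard_index <- function(A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  u <- length(union(A, B))
  if (u == 0L) {
    warning("Jaccard index of two empty sets defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(A, B)) / u
}

#' Pairwise neighborhood similarity matrix
#'
#' Computes the Jaccard index between every pair of neighborhoods' domain
#' *sets* (presence, not multiset). Label order equals input order; labels
#' are the query gene IDs, made unique when neighborhoods repeat (e.g. after
#' subtaxon balancing).
#'
#' @param x a `neighborhood_set`, or a plain list of character vectors
#'   (domain sets).
#' @param labels optional character labels, recycled checks apply.
#' @return object of class `neighborhood_similarity`: list with `J`
#'   (symmetric matrix, unit diagonal for nonempty sets), `labels`, `sets`
#'   and `genome_ids` (`NA` when unknown).
#' @export
neighborhood_similarity <- function(x, labels = NULL) {
  if (length(x) < 2L) {
    gh_parameter_error("need at least 2 neighborhoods to compare")
  }
  if (inherits(x, "neighborhood_set") ||
      (is.list(x) && all(vapply(x, inherits, TRUE, "neighborhood")))) {
    sets <- lapply(x, `[[`, "domain_set")
    genome_ids <- vapply(x, `[[`, "", "genome_id")
    if (is.null(labels)) labels <- vapply(x, `[[`, "", "query_gene_id")
  } else {
    sets <- lapply(x, function(s) unique(as.character(s)))
    genome_ids <- rep(NA_character_, length(x))
    if (is.null(labels)) labels <- paste0("nb", seq_along(x))
  }
  labels <- make.unique(as.character(labels))

  n <- length(sets)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) {
    warning(sprintf("%d neighborhood(s) have empty domain sets; their similarities are 0",
                    sum(sizes == 0L)), call. = FALSE)
  }
  all_dom <- unique(unlist(sets, use.names = FALSE))
  if (length(all_dom) == 0L) {
    J <- matrix(0, n, n, dimnames = list(labels, labels))
  } else {
    M <- matrix(0L, n, length(all_dom))
    idx <- lapply(sets, match, table = all_dom)
    for (i in seq_len(n)) M[i, idx[[i]]] <- 1L
    inter <- tcrossprod(M)
    un <- outer(sizes, sizes, `+`) - inter
    J <- ifelse(un == 0, 0, inter / un)
    dimnames(J) <- list(labels, labels)
  }
  structure(list(J = J, labels = labels, sets = sets, genome_ids = genome_ids),
            class = "neighborhood_similarity")
}

#' @export
print.neighborhood_similarity <- function(x, ...) {
  off <- x$J[upper.tri(x$J)]
  cat(sprintf("<neighborhood_similarity> %d neighborhoods; off-diagonal Jaccard: mean %.3f (range %.3f-%.3f)\n",
              length(x$labels), mean(off), min(off), max(off)))
  invisible(x)
}

#' Single-linkage clustering of neighborhoods
#'
#' Agglomerative clustering on Jaccard distance `d = 1 - J` with single
#' (minimum) linkage, which merges the two clusters with the smallest
#' inter-cluster pairwise distance at each step (equivalently: cutting the
#' minimum spanning tree of the distance graph). Cut the tree either at a
#' distance threshold `h` or into `k` clusters.
#'
#' @param sim a [neighborhood_similarity()] object.
#' @param h distance threshold in `[0, 1]`; clusters are the components
#'   joined at distance `<= h`.
#' @param k target number of clusters. Exactly one of `h`/`k` must be given.
#' @return object of class `neighborhood_clusters`: list with `assignment`
#'   (named integer vector, cluster IDs numbered by order of first
#'   appearance), `hclust` (the merge tree), `sim`, and the cut used.
#' @export
cluster_neighborhoods <- function(sim, h = NULL, k = NULL) {
  stopifnot(inherits(sim, "neighborhood_similarity"))
  if (is.null(h) == is.null(k)) {
    gh_parameter_error("supply exactly one of `h` (distance cut) or `k` (cluster count)")
  }
  if (!is.null(h) && (!is.numeric(h) || length(h) != 1L || h < 0)) {
    gh_parameter_error("`h` must be a single non-negative distance")
  }
  n <- length(sim$labels)
  if (!is.null(k) && (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)) {
    gh_parameter_error(sprintf("`k` must be an integer in [1, %d]", n))
  }
  d <- stats::as.dist(1 - sim$J)
  hc <- stats::hclust(d, method = "single")
  raw <- if (!is.null(h)) stats::cutree(hc, h = h) else stats::cutree(hc, k = k)
  # renumber by first appearance so labels are deterministic in input order
  assignment <- match(raw, unique(raw))
  names(assignment) <- sim$labels
  structure(list(assignment = assignment, hclust = hc, sim = sim,
                 h = h, k = k),
            class = "neighborhood_clusters")
}

#' @export
print.neighborhood_clusters <- function(x, ...) {
  sizes <- table(x$assignment)
  cut_desc <- if (!is.null(x$h)) sprintf("distance cut h = %g", x$h)
              else sprintf("k = %d", x$k)
  cat(sprintf("<neighborhood_clusters> %d neighborhoods in %d cluster(s) (%s)\n",
              length(x$assignment), length(sizes), cut_desc))
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap of the similarity matrix ordered by the cluster tree
#'
#' @param x a `neighborhood_clusters`.
#' @param ... passed to [graphics::image()].
#' @export
plot.neighborhood_clusters <- function(x, ...) {
  ord <- x$hclust$order
  J <- x$sim$J[ord, ord]
  n <- nrow(J)
  graphics::image(seq_len(n), seq_len(n), J[, n:1, drop = FALSE],
                  zlim = c(0, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = "Neighborhood similarity (Jaccard)", ...)
  graphics::box()
  invisible(x)
}

#' Annotate clusters with taxonomy and featured domains
#'
#' For each cluster: its size, the percentage composition at genus and family
#' rank (from the neighborhoods' source genomes), and the "featured" domains
#' present in at least `featured_threshold` of the cluster's neighborhoods.
#'
#' @param clusters a [cluster_neighborhoods()] result.
#' @param taxonomy a taxonomy data.frame (e.g. `db$taxonomy`), or a
#'   [genome_db()]; optional when the neighborhoods carry no genome IDs.
#' @param featured_threshold presence fraction for a domain to be featured
#'   (default 0.9).
#' @return object of class `cluster_annotation`: list with `table`
#'   (data.frame: `cluster_id`, `size`, `top_genus`, `featured_domains`) and
#'   `composition` (per-cluster named percentage vectors for genus and
#'   family, each summing to 100).
#' @export
annotate_clusters <- function(clusters, taxonomy = NULL,
                              featured_threshold = 0.9) {
  stopifnot(inherits(clusters, "neighborhood_clusters"))
  if (inherits(taxonomy, "genome_db")) taxonomy <- taxonomy$taxonomy
  sim <- clusters$sim
  asg <- clusters$assignment
  ids <- sort(unique(asg))

  lineage_of <- function(genomes, rank) {
    if (is.null(taxonomy)) return(rep("<missing>", length(genomes)))
    v <- taxonomy[[rank]][match(genomes, taxonomy$genome_id)]
    v[is.na(v)] <- "<missing>"
    v
  }

  composition <- list()
  rows <- lapply(ids, function(cid) {
    members <- which(asg == cid)
    sets <- sim$sets[members]
    genomes <- sim$genome_ids[members]
    comp <- lapply(c(genus = "genus", family = "family"), function(r) {
      tab <- table(lineage_of(genomes, r))
      100 * as.vector(tab) / sum(tab) -> pct
      stats::setNames(pct, names(tab))
    })
    composition[[as.character(cid)]] <<- comp
    dom_tab <- table(unlist(lapply(sets, unique), use.names = FALSE))
    featured <- names(dom_tab)[dom_tab / length(members) >= featured_threshold]
    top_g <- names(sort(comp$genus, decreasing = TRUE))[1L] %||% "<missing>"
    data.frame(cluster_id = cid, size = length(members), top_genus = top_g,
               featured_domains = paste(sort(featured), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, composition = composition,
                 featured_threshold = featured_threshold),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("<cluster_annotation> %d cluster(s); featured threshold %.0f%%\n",
              nrow(x$table), 100 * x$featured_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize a merge tree to a Newick-like nested string
#'
#' @param clusters a `neighborhood_clusters` (or an `hclust`).
#' @return a single string: nested parentheses with merge heights as branch
#'   annotations, terminated by `";"`.
#' @export
cluster_tree_newick <- function(clusters) {
  hc <- if (inherits(clusters, "neighborhood_clusters")) clusters$hclust
        else clusters
  stopifnot(inherits(hc, "hclust"))
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  rec <- function(node) {
    if (node < 0L) return(lab[-node])
    sprintf("(%s,%s):%g", rec(hc$merge[node, 1L]), rec(hc$merge[node, 2L]),
            hc$height[node])
  }
  paste0(rec(nrow(hc$merge)), ";")
}
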