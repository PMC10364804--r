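#' Partition neighborhoods by subtaxon
#'
#' Groups a neighborhood set by the query gene's genome lineage at the chosen
#' rank, in preparation for the sampling-bias correction. Subtaxa represented
#' by fewer than `min_genomes` genomes *in the database* (not neighborhood
#' count) are dropped, as are neighborhoods from genomes with a missing rank;
#' both removals are reported via `message()` and recorded on the result.
#'
#' @param neighborhoods a `neighborhood_set`.
#' @param db the [genome_db()] the neighborhoods came from (supplies lineages
#'   and per-subtaxon genome counts).
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @param min_genomes minimum database genome count for a subtaxon to take
#'   part (default 25).
#' @return object of class `subtaxon_groups`: a list of groups, each a list
#'   with `rank`, `name`, `neighborhoods`, `n_sub` (neighborhood count) and
#'   `n_genomes` (database genome count); attribute `dropped` records what
#'   was excluded.
#' @export
group_by_subtaxon <- function(neighborhoods, db, rank, min_genomes = 25) {
  stopifnot(inherits(db, "genome_db"))
  rank <- check_rank(rank)
  if (length(neighborhoods) == 0L) gh_parameter_error("`neighborhoods` must be nonempty")

  lineage <- db$taxonomy[[rank]][match(
    vapply(neighborhoods, `[[`, "", "genome_id"), db$taxonomy$genome_id)]

  n_missing <- sum(is.na(lineage))
  if (n_missing > 0L) {
    message(sprintf("dropping %d neighborhood(s) from genomes with missing %s",
                    n_missing, rank))
  }

  genome_counts <- table(db$taxonomy[[rank]])
  keepable <- names(genome_counts)[genome_counts >= min_genomes]
  too_small <- setdiff(unique(lineage[!is.na(lineage)]), keepable)
  if (length(too_small) > 0L) {
    message(sprintf("dropping %d subtaxon(a) with fewer than %d genomes: %s",
                    length(too_small), min_genomes,
                    paste(utils::head(too_small, 5L), collapse = ", ")))
  }

  keep <- !is.na(lineage) & lineage %in% keepable
  if (!any(keep)) {
    gh_empty_error(sprintf(
      "no neighborhoods remain after grouping at rank '%s' with min_genomes = %d",
      rank, min_genomes))
  }
  idx_by_name <- split(which(keep), lineage[keep])
  groups <- lapply(names(idx_by_name), function(nm) {
    list(rank = rank, name = nm,
         neighborhoods = neighborhoods[idx_by_name[[nm]]],
         n_sub = length(idx_by_name[[nm]]),
         n_genomes = as.integer(genome_counts[[nm]]))
  })
  structure(groups, class = c("subtaxon_groups", "list"),
            dropped = list(missing_rank = n_missing, small_subtaxa = too_small))
}

#' @export
print.subtaxon_groups <- function(x, ...) {
  cat(sprintf("<subtaxon_groups> %d group(s) at rank '%s'\n",
              length(x), x[[1L]]$rank))
  for (g in x) {
    cat(sprintf("  %s: %d neighborhoods, %d genomes\n",
                g$name, g$n_sub, g$n_genomes))
  }
  invisible(x)
}

#' Equalize subtaxon contributions by resampling neighborhoods
#'
#' Identifies the subtaxon with the largest neighborhood count (`n_max`) and,
#' for every other subtaxon `i`, draws `n_max - n_sub_i` additional
#' neighborhoods from that subtaxon with replacement, so every subtaxon
#' contributes exactly `n_max` entries. Resampled entries are exact copies of
#' existing neighborhoods from the same subtaxon.
#'
#' @param groups a `subtaxon_groups` object.
#' @param seed RNG seed for the draws (logged in the report).
#' @return a `neighborhood_set` of length `n_groups * n_max`, with attribute
#'   `report`: a data.frame with columns `rank`, `subtaxon`, `n_genomes`,
#'   `n_neighborhoods`, `n_contributed`, `seed`.
#' @export
balance_subtaxa <- function(groups, seed = 1L) {
  if (length(groups) == 0L) gh_parameter_error("`groups` must be nonempty")
  n_sub <- vapply(groups, `[[`, 0L, "n_sub")
  if (any(n_sub < 1L)) gh_parameter_error("every group must hold at least one neighborhood")
  n_max <- max(n_sub)
  out <- with_seed(seed, {
    lapply(groups, function(g) {
      extra <- n_max - g$n_sub
      if (extra > 0L) {
        draws <- sample.int(g$n_sub, extra, replace = TRUE)
        c(g$neighborhoods, g$neighborhoods[draws])
      } else {
        g$neighborhoods
      }
    })
  })
  report <- data.frame(
    rank = vapply(groups, `[[`, "", "rank"),
    subtaxon = vapply(groups, `[[`, "", "name"),
    n_genomes = vapply(groups, `[[`, 0L, "n_genomes"),
    n_neighborhoods = n_sub,
    n_contributed = rep.int(n_max, length(groups)),
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  structure(unlist(out, recursive = FALSE),
            class = c("neighborhood_set", "list"), report = report)
}
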