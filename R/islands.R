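#' Fraction of mesenchymal cells per epithelial island
#'
#' Aggregates manual per-cell epithelial/mesenchymal calls into per-island
#' percentages and a condition summary.  Islands with fewer than
#' `min_cells` scored cells are excluded (default 5); the summary is the
#' mean and standard error over the included islands, with the island as
#' the experimental unit.
#'
#' @param annotations list of `IslandAnnotation` (see [read_annotations()])
#' @param min_cells minimum scored cells for an island to count (default 5)
#' @return list with `per_island` (data.frame `island_id`, `n_cells`,
#'   `n_mesenchymal`, `percent_mesenchymal`, `included`) and `summary`
#'   (data.frame `mean`, `sem`, `n_islands` over included islands)
#' @export
mesenchymal_fraction <- function(annotations, min_cells = 5) {
  if (length(annotations) == 0) stop("no annotations supplied")
  per <- do.call(rbind, lapply(annotations, function(a) {
    n <- length(a$cell_classes)
    m <- sum(a$cell_classes == "mesenchymal")
    data.frame(island_id = a$island_id, n_cells = n, n_mesenchymal = m,
               percent_mesenchymal = 100 * m / n,
               included = n >= min_cells, stringsAsFactors = FALSE)
  }))
  inc <- per[per$included, , drop = FALSE]
  if (nrow(inc) == 0) stop("all islands excluded by the min_cells rule")
  s <- summarize(inc$percent_mesenchymal)
  list(per_island = per,
       summary = data.frame(mean = s$mean, sem = s$sem,
                            n_islands = s$n))
}

#' Fraction of island perimeter bounded by mesenchymal cells
#'
#' Per island, the percentage of total perimeter length contributed by
#' segments classed mesenchymal; summarized as mean and SEM over islands.
#'
#' @param annotations list of `IslandAnnotation` carrying
#'   `perimeter_segments`
#' @return list with `per_island` (data.frame `island_id`,
#'   `total_length_um`, `mesenchymal_length_um`, `percent_mesenchymal`) and
#'   `summary` (`mean`, `sem`, `n_islands`)
#' @export
perimeter_fraction <- function(annotations) {
  if (length(annotations) == 0) stop("no annotations supplied")
  missing_seg <- vapply(annotations,
                        function(a) is.null(a$perimeter_segments),
                        logical(1))
  if (any(missing_seg))
    stop(sprintf("island '%s' has no perimeter segments",
                 annotations[[which(missing_seg)[1]]]$island_id))
  per <- do.call(rbind, lapply(annotations, function(a) {
    segs <- a$perimeter_segments
    tot <- sum(segs$length_um)
    mes <- sum(segs$length_um[segs$class == "mesenchymal"])
    data.frame(island_id = a$island_id, total_length_um = tot,
               mesenchymal_length_um = mes,
               percent_mesenchymal = 100 * mes / tot,
               stringsAsFactors = FALSE)
  }))
  s <- summarize(per$percent_mesenchymal)
  list(per_island = per,
       summary = data.frame(mean = s$mean, sem = s$sem, n_islands = s$n))
}
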