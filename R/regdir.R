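# Motif-stratified direction-of-regulation analysis: do peaks of a given
# motif class sit near genes that go up or down, and how does that depend
# on distance to the TSS?

#' Direction-of-regulation fractions per peak class
#'
#' Each peak votes once through its assigned gene's DE direction (`up`,
#' `down`, or `non-DE` when the gene was not selected). Both a peak-level
#' table (genes with several peaks counted once per peak) and a gene-level
#' table (each gene once per class) are returned, distinguished by the
#' `level` column. Fractions sum to 1 within each class and level.
#'
#' @param assignments Output of [nearest_tss()] (`name`, `gene_id`, ...).
#' @param de_selected Output of [select_de()] (`gene_id`, `direction`).
#' @param classes Tibble `name`, `motif_class` (e.g. [partition_by_motif()]).
#' @return Tibble `level`, `motif_class`, `direction`, `n`, `fraction`.
#'   Empty classes are dropped with a warning.
#' @export
direction_fractions <- function(assignments, de_selected, classes) {
  assert_columns(assignments, c("name", "gene_id"), "assignments")
  assert_columns(classes, c("name", "motif_class"), "classes")
  df <- inner_join(as_tibble(assignments), as_tibble(classes), by = "name") |>
    filter(!is.na(.data$gene_id)) |>
    left_join(as_tibble(de_selected)[, c("gene_id", "direction")], by = "gene_id") |>
    mutate(direction = if_else(is.na(.data$direction), "non-DE", .data$direction))

  empty <- setdiff(unique(classes$motif_class), unique(df$motif_class))
  if (length(empty)) {
    warn(sprintf("peak class(es) with no assigned genes omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  lev <- c("up", "down", "non-DE")
  tab_of <- function(d, level) {
    d |>
      count(.data$motif_class, .data$direction) |>
      tidyr::complete(motif_class = unique(d$motif_class), direction = lev,
                      fill = list(n = 0L)) |>
      group_by(.data$motif_class) |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup() |>
      mutate(level = level, .before = 1)
  }
  bind_rows(
    tab_of(df, "peak"),
    tab_of(distinct(df, .data$motif_class, .data$gene_id, .data$direction), "gene")
  )
}

#' Smoothed peak-density curves vs distance to TSS, by class and direction
#'
#' For every (motif class, DE direction) the signed summit-to-TSS distances
#' are smoothed with a Gaussian kernel of the given bandwidth and evaluated
#' on a regular grid over `[-halfspan, halfspan]`. Curves are scaled to
#' counts (each peak contributes a unit-mass kernel), so the integral of a
#' curve approximates the class/direction peak count.
#'
#' @param assignments Output of [nearest_tss()] (`distance` used).
#' @param de_selected Output of [select_de()].
#' @param classes Tibble `name`, `motif_class`.
#' @param halfspan Grid half-span in bp (default 30000).
#' @param bandwidth Gaussian kernel SD in bp (default 2000; must be > 0).
#' @param n_grid Number of grid points (default 200).
#' @return Tibble `motif_class`, `direction`, `x`, `density`, `n`.
#' @export
distance_direction_curve <- function(assignments, de_selected, classes,
                                     halfspan = 30000, bandwidth = 2000,
                                     n_grid = 200L) {
  assert_scalar_number(bandwidth, "bandwidth", positive = TRUE)
  df <- inner_join(as_tibble(assignments), as_tibble(classes), by = "name") |>
    filter(!is.na(.data$gene_id)) |>
    left_join(as_tibble(de_selected)[, c("gene_id", "direction")], by = "gene_id") |>
    mutate(direction = if_else(is.na(.data$direction), "non-DE", .data$direction))
  grid <- seq(-halfspan, halfspan, length.out = n_grid)
  df |>
    group_by(.data$motif_class, .data$direction) |>
    summarise(
      x = list(grid),
      density = list(vapply(grid, function(g) sum(dnorm(g, .data$distance, bandwidth)), 0)),
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::unnest(c("x", "density"))
}
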