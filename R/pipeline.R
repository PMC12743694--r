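# End-to-end orchestration: scenario preparation -> resistance ensemble ->
# pairwise circuit solves (both scenarios, same focal nodes) -> consensus and
# percent change -> change detection -> hexagonal prioritisation of
# reforestation offsets, landscape-wide and riparian.

#' Analysis run configuration
#'
#' @param resistance_levels Per-class resistance levels;
#'   [default_resistance_levels()].
#' @param n_focal Number of focal nodes (default 50).
#' @param buffer_width Fixed focal buffer ring width in metres, or `NULL` to
#'   derive it as `buffer_fraction` of the maximum extent length.
#' @param buffer_fraction Ring width as a fraction of the maximum extent
#'   length (default 0.2).
#' @param rho_threshold Spearman near-duplicate threshold (default 0.99).
#' @param percentile Current-density percentile for candidate filtering
#'   (default 20).
#' @param distances Dispersal distance thresholds in metres, ascending
#'   (default 500, 1000, 2000).
#' @param lost_forest_area Forest area removed by the project in m^2, or
#'   `NULL` to measure it from the scenarios.
#' @param elevation_threshold Tree-line threshold in metres (default 3600).
#' @param cell_area Hexagon area in m^2 (default 1e5 = 10 ha).
#' @param seed Integer seed for focal-node placement.
#' @return A validated `run_config` list.
#' @export
run_config <- function(resistance_levels = default_resistance_levels(),
                       n_focal = 50, buffer_width = NULL,
                       buffer_fraction = 0.2, rho_threshold = 0.99,
                       percentile = 20, distances = c(500, 1000, 2000),
                       lost_forest_area = NULL, elevation_threshold = 3600,
                       cell_area = 1e5, seed = 1) {
  if (any(diff(distances) <= 0) || any(distances <= 0))
    stop("distances must be positive and sorted ascending")
  if (n_focal < 2) stop("n_focal must be >= 2")
  structure(list(resistance_levels = resistance_levels, n_focal = n_focal,
                 buffer_width = buffer_width, buffer_fraction = buffer_fraction,
                 rho_threshold = rho_threshold, percentile = percentile,
                 distances = distances, lost_forest_area = lost_forest_area,
                 elevation_threshold = elevation_threshold,
                 cell_area = cell_area, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#'   (unknown keys are rejected).
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(run_config, y)
}

resolved_buffer <- function(lc, config) {
  if (!is.null(config$buffer_width)) return(config$buffer_width)
  b <- raster_extent(lc)
  config$buffer_fraction * max(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"])
}

# Solve the full ensemble for one scenario. Profiles whose resistances agree
# on every class present in the raster rasterise to identical surfaces, so
# the linear solve is shared within each such group and the resulting map is
# attributed to every member profile.
ensemble_current_maps <- function(lc, profiles, focal) {
  present <- sort(unique(lc$values[!is.na(lc$values)]))
  sig <- apply(profiles[, names(lc_classes())[present], drop = FALSE], 1,
               paste, collapse = "|")
  maps <- vector("list", nrow(profiles))
  for (s in unique(sig)) {
    members <- which(sig == s)
    surface <- build_resistance_surface(lc, profiles[members[1], ])
    net <- build_network(surface)
    cm <- cumulative_current(net, focal)
    for (m in members) {
      mm <- cm
      mm$profile_id <- profiles$profile_id[m]
      maps[[m]] <- mm
    }
  }
  maps
}

#' Before/after connectivity impact assessment
#'
#' Prepares the before-construction scenario (tree-line mask on the date-2
#' land cover) and the after-construction scenario (footprint burned to
#' unsuitable), runs the full resistance ensemble through the pairwise
#' circuit solver with one shared set of focal nodes, reduces each scenario
#' to a rank-correlation-filtered consensus, and maps the percent change in
#' current density.
#'
#' @param landscape List with `landcover_2019`, `landcover_2000`,
#'   `elevation`, `footprint`, `rivers` (as from [generate_landscape()] or a
#'   [pinch_fixture()] adapted via `before`/`after`).
#' @param config A [run_config()].
#' @return An `impact_result`: scenario land covers, per-scenario retained
#'   profile ids, consensus maps, the change map, focal nodes, the study
#'   extent polygon and a run report.
#' @export
run_impact <- function(landscape, config = run_config()) {
  if (!is.null(landscape$before)) {
    before <- landscape$before
    after <- if (!is.null(landscape$after)) landscape$after
             else burn_footprint(before, landscape$footprint)
  } else {
    before <- apply_elevation_mask(landscape$landcover_2019,
                                   landscape$elevation,
                                   config$elevation_threshold)
    after <- burn_footprint(before, landscape$footprint)
  }
  buffer <- resolved_buffer(before, config)
  extent <- inset_extent(before, buffer)
  focal <- sample_focal_nodes(extent, buffer, config$n_focal,
                              before, config$seed)
  profiles <- enumerate_profiles(config$resistance_levels)
  maps_before <- ensemble_current_maps(before, profiles, focal)
  maps_after <- ensemble_current_maps(after, profiles, focal)
  ded_b <- spearman_dedup(maps_before, config$rho_threshold)
  ded_a <- spearman_dedup(maps_after, config$rho_threshold)
  cons_b <- sum_consensus(ded_b$retained, ded_b$retained_ids)
  cons_a <- sum_consensus(ded_a$retained, ded_a$retained_ids)
  change <- percent_change(cons_b, cons_a)
  cls <- lc_classes()
  lost <- (sum(before$values == cls[["forest"]], na.rm = TRUE) -
             sum(after$values == cls[["forest"]], na.rm = TRUE)) *
    before$cell_size^2
  structure(list(
    before = before, after = after, footprint = landscape$footprint,
    consensus_before = cons_b, consensus_after = cons_a, change = change,
    focal = focal, extent = extent, profiles = profiles,
    retained_before = ded_b$retained_ids, retained_after = ded_a$retained_ids,
    lost_forest_area = lost,
    report = list(
      seed = config$seed, buffer_width = buffer,
      n_profiles = nrow(profiles),
      n_retained_before = length(ded_b$retained_ids),
      n_retained_after = length(ded_a$retained_ids),
      n_pairs = maps_before[[1]]$n_pairs,
      n_skipped_pairs = maps_before[[1]]$n_skipped,
      lost_forest_area = lost,
      change_summary = summary(change$values[!is.na(change$values)]))),
    class = "impact_result")
}

#' Reforestation offset prioritisation
#'
#' Detects 2000 -> 2019 deforestation on the prepared (tree-line-masked)
#' land covers, tessellates the study area into 10-ha hexagons, classifies
#' them, filters deforested candidates by after-construction current
#' density, scores each candidate's varIIC at every dispersal distance, and
#' ranks both the landscape-wide and the riparian candidate sets.
#'
#' @param landscape As in [run_impact()]; needs both land-cover dates (or a
#'   fixture's `before`/`after` used as the two dates) and `rivers`.
#' @param impact The matching `impact_result`.
#' @param config A [run_config()].
#' @return An `offset_result`: hex grid, classifications, candidates,
#'   patches, scores, landscape-wide and riparian `priority_ranking`s and a
#'   report.
#' @export
run_offset <- function(landscape, impact, config = run_config()) {
  if (!is.null(landscape$landcover_2000)) {
    t1 <- apply_elevation_mask(landscape$landcover_2000, landscape$elevation,
                               config$elevation_threshold)
    t2 <- impact$before
  } else {
    t1 <- landscape$before
    t2 <- landscape$after
  }
  change_lc <- detect_deforestation(t1, t2)
  hexes <- build_hexgrid(impact$extent, config$cell_area)
  statuses <- classify_hexes(hexes, change_lc)
  def_ids <- statuses$id[statuses$status == "deforested"]
  if (!length(def_ids))
    stop("no deforested hexagonal cells: nothing to prioritise ",
         "(deforested pixels: ",
         sum(change_lc$values == change_classes()[["deforested"]], na.rm = TRUE),
         ")")
  mean_cur <- hex_mean_current(hexes, impact$consensus_after, def_ids)
  filt <- percentile_filter(mean_cur, config$percentile)
  if (!length(filt$ids))
    stop("no candidates above the ", config$percentile,
         "th current-density percentile (threshold ",
         signif(filt$threshold, 4), ", ", length(def_ids),
         " deforested cells)")
  patches <- merge_forest_patches(hexes, statuses, impact$consensus_after)
  if (!length(patches)) stop("no forested patches: degenerate landscape")
  A_L <- polygon_area(impact$extent)
  cand_idx <- match(filt$ids, hexes$cells$id)
  cand_attr <- hex_sum_current(hexes, impact$consensus_after, filt$ids) /
    config$cell_area
  candidates <- data.frame(id = filt$ids, attribute = cand_attr,
                           mean_current = mean_cur[as.character(filt$ids)])
  geoms <- hexes$vertices[cand_idx]
  scores <- score_candidates(candidates, geoms, patches,
                             config$distances, A_L)
  lost <- if (!is.null(config$lost_forest_area)) config$lost_forest_area
          else impact$lost_forest_area
  ranking <- rank_candidates(scores, lost, config$cell_area)
  rip <- riparian_subset(hexes, landscape$rivers, filt$ids)
  rip_ids <- filt$ids[rip]
  riparian_ranking <- NULL
  if (length(rip_ids)) {
    rip_scores <- scores[scores$id %in% rip_ids, , drop = FALSE]
    riparian_ranking <- rank_candidates(rip_scores, lost, config$cell_area)
  }
  structure(list(
    hexes = hexes, statuses = statuses, change_landcover = change_lc,
    candidates = candidates, candidate_geometries = geoms,
    patches = patches, scores = scores, A_L = A_L,
    ranking = ranking, riparian_ids = rip_ids,
    riparian_ranking = riparian_ranking,
    report = list(
      n_hexes = nrow(hexes$cells),
      n_deforested = length(def_ids),
      n_candidates = length(filt$ids),
      percentile_threshold = filt$threshold,
      n_riparian = length(rip_ids),
      n_patches = length(patches),
      lost_forest_area = lost,
      n_select = ranking$n_select)),
    class = "offset_result")
}
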