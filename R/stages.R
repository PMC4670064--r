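#' Invasion-stage classification from paired model predictions
#'
#' Classifies points by the quadrant of their (regional, global) predicted
#' suitability pair relative to a threshold `tau`, after the
#' stabilization/colonization/adaptation/sink framework for invasion
#' stages:
#' \itemize{
#'   \item both `>= tau`: stabilizing (quasi-equilibrium);
#'   \item regional `< tau <=` global: colonization potential;
#'   \item global `< tau <=` regional: regional adaptation;
#'   \item both `< tau`: sink.
#' }
#' "High" means `>= tau`, so the four categories partition the unit
#' square. The regional model is fitted on invaded-range occurrences only;
#' the global model on native plus invasive occurrences.
#'
#' @param p_regional,p_global predicted probabilities in `[0, 1]`
#'   (vectors, recycled to a common length).
#' @param tau threshold between low and high suitability (default 0.5).
#' @return Factor with levels `stabilizing`, `colonization`, `adaptation`,
#'   `sink`.
#' @export
classify_stage <- function(p_regional, p_global, tau = 0.5) {
  n <- max(length(p_regional), length(p_global))
  p_regional <- rep_len(p_regional, n)
  p_global <- rep_len(p_global, n)
  ok <- is.na(p_regional) | (p_regional >= 0 & p_regional <= 1)
  ok2 <- is.na(p_global) | (p_global >= 0 & p_global <= 1)
  if (!all(ok) || !all(ok2)) stop_named("probabilities must be in [0, 1]")
  hi_r <- p_regional >= tau
  hi_g <- p_global >= tau
  out <- rep(NA_character_, n)
  out[hi_r & hi_g] <- "stabilizing"
  out[!hi_r & hi_g] <- "colonization"
  out[hi_r & !hi_g] <- "adaptation"
  out[!hi_r & !hi_g] <- "sink"
  factor(out, levels = stage_levels())
}

#' @export
stage_levels <- function() {
  c("stabilizing", "colonization", "adaptation", "sink")
}

#' Invasion-stage map from regional and global suitability rasters
#'
#' Cellwise [classify_stage()] over two aligned suitability rasters.
#' Nodata in either raster propagates. Stage codes in the output raster:
#' 1 stabilizing, 2 colonization, 3 adaptation, 4 sink.
#'
#' @param regional,global_ aligned [raster_grid()]s of predicted
#'   suitability.
#' @param tau threshold (default 0.5).
#' @return List: `raster` (integer-coded `raster_grid`), `counts` (named
#'   category counts over valid cells), `legend`, `tau`.
#' @export
classify_stage_raster <- function(regional, global_, tau = 0.5) {
  stopifnot(is_raster_grid(regional), is_raster_grid(global_))
  if (!same_geometry(regional, global_)) {
    stop_named("regional and global rasters are not aligned")
  }
  pr <- as.vector(regional$values)
  pg <- as.vector(global_$values)
  valid <- !is.na(pr) & !is.na(pg)
  stage <- rep(NA_integer_, length(pr))
  stage[valid] <- as.integer(classify_stage(pr[valid], pg[valid], tau))
  out <- regional
  out$values[] <- as.numeric(stage)
  counts <- table(factor(stage_levels()[stage[valid]],
                         levels = stage_levels()))
  list(raster = out, counts = counts,
       legend = stats::setNames(1:4, stage_levels()), tau = tau)
}
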