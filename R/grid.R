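#' Build the agromanagement parameter grid
#'
#' Expands a factor specification into the full Cartesian product of
#' agromanagement combinations (planting density, seed brand, relative
#' maturity, applied nitrogen, planting-date percentile). The order is
#' deterministic and density-major: planting density varies slowest, then
#' seed brand, relative maturity, nitrogen, and finally the planting-date
#' percentile, which varies fastest.
#'
#' With the default factor levels the grid has 288 combinations.
#'
#' @param grid_spec a named list with elements `planting_density`,
#'   `seed_brand`, `relative_maturity`, `nitrogen_applied` and
#'   `planting_date_percentile`, each a vector of levels. Defaults to the
#'   grid in [default_config()].
#' @return a data.frame with one row per combination, a `combo_id` column
#'   (1-based, in grid order) and one column per factor.
#' @examples
#' nrow(build_parameter_grid())  # 288
#' @export
build_parameter_grid <- function(grid_spec = default_config()$grid) {
  required <- c("planting_density", "seed_brand", "relative_maturity",
                "nitrogen_applied", "planting_date_percentile")
  missing <- setdiff(required, names(grid_spec))
  if (length(missing) > 0L) {
    stop("grid_spec is missing factor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in required) {
    if (length(grid_spec[[f]]) < 1L) {
      stop("grid factor '", f, "' must have at least one level", call. = FALSE)
    }
  }
  # expand.grid varies the first factor fastest; list factors fastest-first
  # so that planting_density ends up varying slowest (density-major order).
  g <- expand.grid(
    planting_date_percentile = grid_spec$planting_date_percentile,
    nitrogen_applied = grid_spec$nitrogen_applied,
    relative_maturity = grid_spec$relative_maturity,
    seed_brand = grid_spec$seed_brand,
    planting_density = grid_spec$planting_density,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, rev(names(g))]
  g <- cbind(combo_id = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  g
}
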