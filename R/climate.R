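#' Climate predictor stack for one stage
#'
#' The four climatic layers used throughout: mean-maximum and mean-minimum
#' sea surface temperature (degrees C) and mean-maximum and mean-minimum
#' surface insolation (W m^-2), all on one shared grid. `sst_max >= sst_min`
#' and `ins_max >= ins_min` must hold wherever both members are defined.
#'
#' @param stage_id Stage identifier token.
#' @param sst_max,sst_min,ins_max,ins_min [lat_lon_grid()] layers on a
#'   common grid.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(stage_id, sst_max, sst_min, ins_max, ins_min) {
  layers <- list(sst_max = sst_max, sst_min = sst_min,
                 ins_max = ins_max, ins_min = ins_min)
  for (nm in names(layers)) {
    stopifnot(is_grid(layers[[nm]]))
    stop_if_not_conformable(layers[[nm]], sst_max, paste("climate layers", nm))
  }
  chk <- function(a, b, lab) {
    both <- !is.na(a$values) & !is.na(b$values)
    if (any(a$values[both] < b$values[both] - 1e-9))
      stop("climate_stack: ", lab, " violated for stage ", stage_id)
  }
  chk(sst_max, sst_min, "sst_max >= sst_min")
  chk(ins_max, ins_min, "ins_max >= ins_min")
  structure(c(list(stage_id = stage_id), layers), class = "climate_stack")
}

climate_layer_names <- function() c("sst_max", "sst_min", "ins_max", "ins_min")

#' Regrid a climate stack onto a working grid and gap-fill over the mask
#'
#' Each layer is bilinearly interpolated onto the mask's grid
#' ([bilinear_regrid()]); mask cells left undefined because the interpolation
#' stencil touched missing (land) coarse cells are filled by iterated 3 x 3
#' focal means ([focal_fill()]).
#'
#' @param climate A [climate_stack()] at native resolution.
#' @param mask A `shallow_mask` grid on the working grid.
#' @return A [climate_stack()] on the working grid, fully defined on mask cells.
#' @export
regrid_climate <- function(climate, mask) {
  layers <- lapply(climate_layer_names(), function(nm) {
    focal_fill(bilinear_regrid(climate[[nm]], mask), mask)
  })
  names(layers) <- climate_layer_names()
  # gap filling can nudge members past each other near coasts; restore order
  swap <- which(!is.na(layers$sst_max$values) & !is.na(layers$sst_min$values) &
                  layers$sst_max$values < layers$sst_min$values)
  if (length(swap)) {
    mid <- (layers$sst_max$values[swap] + layers$sst_min$values[swap]) / 2
    layers$sst_max$values[swap] <- mid
    layers$sst_min$values[swap] <- mid
  }
  swap <- which(!is.na(layers$ins_max$values) & !is.na(layers$ins_min$values) &
                  layers$ins_max$values < layers$ins_min$values)
  if (length(swap)) {
    mid <- (layers$ins_max$values[swap] + layers$ins_min$values[swap]) / 2
    layers$ins_max$values[swap] <- mid
    layers$ins_min$values[swap] <- mid
  }
  climate_stack(climate$stage_id, layers$sst_max, layers$sst_min,
                layers$ins_max, layers$ins_min)
}

#' Raw predictor matrix at cells
#'
#' @param climate A [climate_stack()].
#' @param cells Data frame with `row`, `col` on the stack's grid.
#' @return Numeric matrix with one column per climate layer.
#' @export
climate_values_at <- function(climate, cells) {
  out <- vapply(climate_layer_names(),
                function(nm) grid_values_at(climate[[nm]], cells),
                numeric(nrow(as.data.frame(cells))))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, climate_layer_names()))
  out
}
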