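#' Packaged bed-net geometry
#'
#' Rectangular-box geometry of a packaged long-lasting insecticidal net
#' (LLIN).  The default 190 x 180 x 150 cm corresponds to the packaged
#' dimensions of the polyethylene nets assessed by the package's damage
#' pipeline.  A net has five assessable panels: two long sides
#' (length x height), two short sides (width x height) and the roof
#' (width x length).
#'
#' @param length_cm,width_cm,height_cm positive panel dimensions in cm.
#' @return An object of class `net_geometry`: a list with the three
#'   dimensions and the five side identifiers.
#' @examples
#' g <- net_geometry()
#' panel_size("roof", g)
#' @export
net_geometry <- function(length_cm = 190, width_cm = 180, height_cm = 150) {
  if (any(c(length_cm, width_cm, height_cm) <= 0))
    stop("all net dimensions must be positive")
  structure(
    list(length_cm = length_cm, width_cm = width_cm, height_cm = height_cm,
         sides = c("long1", "long2", "short1", "short2", "roof")),
    class = "net_geometry")
}

#' Panel dimensions for a net side
#'
#' @param side a side identifier (`"long1"`, `"short2"`, `"roof"`, ...) or a
#'   bare side type (`"long"`, `"short"`, `"roof"`).
#' @param geometry a [net_geometry()].
#' @return Named numeric vector `c(width_cm=, height_cm=)` of the panel; for
#'   the roof, "height" is the net length and "width" the net width.
#' @export
panel_size <- function(side, geometry = net_geometry()) {
  switch(side_type(side),
    long  = c(width_cm = geometry$length_cm, height_cm = geometry$height_cm),
    short = c(width_cm = geometry$width_cm,  height_cm = geometry$height_cm),
    roof  = c(width_cm = geometry$width_cm,  height_cm = geometry$length_cm))
}

#' @rdname panel_size
#' @export
side_type <- function(side) {
  type <- sub("[0-9]+$", "", side)
  if (!all(type %in% c("long", "short", "roof")))
    stop("unknown side: ", paste(unique(side[!type %in% c("long", "short", "roof")]), collapse = ", "))
  type
}

# Relative panel areas; used to distribute holes across sides.
.panel_areas <- function(geometry) {
  vapply(geometry$sides, function(s) prod(panel_size(s, geometry)), numeric(1))
}
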