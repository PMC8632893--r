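#' Chebyshev (chessboard) distance
#'
#' The model's single distance convention: the number of king moves between
#' two cells, `max(|x1 - x2|, |y1 - y2|)`. All radii (movement, material
#' search, tree adjacency, tool-use-location census, displacement reporting)
#' use this metric, consistent with the Moore 8-neighbour geometry of
#' movement and discard.
#'
#' @param x1,y1,x2,y2 Cell coordinates (vectorised).
#' @param euclidean If `TRUE`, return Euclidean distances instead (offered
#'   for sensitivity reporting; never used by the model rules).
#' @return Numeric vector of distances in cells.
#' @examples
#' chebyshev_distance(0, 0, 2, 3)  # 3
#' @export
chebyshev_distance <- function(x1, y1, x2, y2, euclidean = FALSE) {
  if (euclidean) return(sqrt((x1 - x2)^2 + (y1 - y2)^2))
  pmax(abs(x1 - x2), abs(y1 - y2))
}

# distance from each point to its nearest source, vectorised over points
nearest_source_distance <- function(x, y, sources) {
  if (length(x) == 0) return(numeric(0))
  if (nrow(sources) == 0) return(rep(Inf, length(x)))
  dx <- abs(outer(x, sources$x, "-"))
  dy <- abs(outer(y, sources$y, "-"))
  apply(pmax(dx, dy), 1, min)
}
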