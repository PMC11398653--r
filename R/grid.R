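#' Hexagonal detector array
#'
#' Builds a triangular lattice of detector sites clipped to a unit-scale
#' hexagonal domain (circumradius 1, flat-topped). The lattice pitch is solved
#' numerically so the number of retained sites is as close as possible to
#' `target_sites`; each site hosts one intensity detector and one change
#' detector, in that block order.
#'
#' @param target_sites Requested number of sites (>= 1). The achieved count is
#'   returned in the object and is deterministic for a given target.
#' @return An object of class `detector_array` with elements `positions`
#'   (n x 2 matrix), `n_sites`, and `type` (length `2n`, `"intensity"` then
#'   `"change"`, matching the ordering used by the encoders).
#' @examples
#' arr <- make_hexagonal_grid(7)
#' arr$n_sites
#' @export
make_hexagonal_grid <- function(target_sites) {
  stopifnot(is.numeric(target_sites), length(target_sites) == 1L,
            target_sites >= 1)
  target_sites <- as.integer(round(target_sites))
  if (target_sites == 1L) {
    pos <- matrix(0, 1, 2)
  } else {
    count_for <- function(pitch) nrow(.hex_lattice(pitch))
    # bracket the pitch: smaller pitch -> more sites (~ area/pitch^2)
    pitches <- exp(seq(log(2.6 / sqrt(target_sites)),
                       log(0.9 / sqrt(target_sites)), length.out = 400))
    counts <- vapply(pitches, count_for, integer(1))
    best <- which.min(abs(counts - target_sites))
    # among equally good counts prefer the largest pitch (most regular fill)
    best <- which(counts == counts[best])[1L]
    pos <- .hex_lattice(pitches[best])
  }
  structure(list(positions = pos, n_sites = nrow(pos),
                 type = rep(c("intensity", "change"), each = nrow(pos))),
            class = "detector_array")
}

# triangular lattice points inside a flat-topped hexagon of circumradius 1,
# centered at the origin
.hex_lattice <- function(pitch) {
  r <- ceiling(1.2 / pitch)
  ij <- expand.grid(i = -r:r, j = -r:r)
  x <- (ij$i + ij$j / 2) * pitch
  y <- ij$j * sqrt(3) / 2 * pitch
  keep <- .in_hexagon(x, y)
  cbind(x = x[keep], y = y[keep])
}

.in_hexagon <- function(x, y, R = 1) {
  tol <- 1e-9
  q <- abs(x) * sqrt(3) / 2 + abs(y) / 2
  (abs(y) <= R * sqrt(3) / 2 + tol) & (q <= R * sqrt(3) / 2 + tol)
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf("detector array: %d sites (%d neurons) on a unit hexagon\n",
              x$n_sites, 2L * x$n_sites))
  invisible(x)
}
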