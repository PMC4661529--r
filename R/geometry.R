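#' Microtubule geometry descriptor
#'
#' Bundles the quantities needed for the back-of-envelope capacity math:
#' how much microtubule surface a cell offers, and how many bait copies
#' that surface can anchor.
#'
#' @param n_microtubules Number of microtubules in the cell.
#' @param mean_length Mean microtubule length in micrometres.
#' @param diameter Microtubule outer diameter in nanometres. Microtubules
#'   are cylinders of about 25 nm diameter, hence the default.
#' @param bait_footprint Interacting surface area required by one bait
#'   molecule, in square nanometres.
#'
#' @return A tibble of class `mt_geometry` with one row and the four fields.
#' @examples
#' g <- mt_geometry(250, 10)
#' mt_surface_area(g)
#' @export
mt_geometry <- function(n_microtubules, mean_length, diameter = 25,
                        bait_footprint = 10) {
  for (v in c(n_microtubules, mean_length, diameter, bait_footprint)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("all geometry fields must be single strictly positive numbers",
           call. = FALSE)
    }
  }
  tibble::new_tibble(
    tibble::tibble(
      n_microtubules = n_microtubules,
      mean_length    = mean_length,
      diameter       = diameter,
      bait_footprint = bait_footprint
    ),
    class = "mt_geometry"
  )
}

#' Lateral surface area of the microtubule network
#'
#' Treats each microtubule as a cylinder and returns the total lateral
#' (side) area `n * pi * d * L`, converting the diameter from nm to um.
#'
#' @param geometry A [mt_geometry()] object (or any data frame with columns
#'   `n_microtubules`, `mean_length`, `diameter`).
#' @return Total surface area in square micrometres.
#' @examples
#' mt_surface_area(mt_geometry(1, 1))  # ~0.0785 um^2
#' @export
mt_surface_area <- function(geometry) {
  stopifnot(is.data.frame(geometry))
  with(geometry, {
    if (any(c(n_microtubules, mean_length, diameter) <= 0)) {
      stop("geometry fields must be strictly positive", call. = FALSE)
    }
    n_microtubules * pi * (diameter * 1e-3) * mean_length
  })
}

#' Bait binding capacity of a surface
#'
#' Number of bait copies that fit on a surface, given the interacting
#' footprint one copy requires: `floor(area_nm2 / footprint)`. A network
#' of about 70 um^2 with a 10 nm^2 footprint anchors 7e6 copies, which is
#' why the microtubule platform is effectively unsaturable for most baits.
#'
#' @param surface_area Surface area in square micrometres.
#' @param footprint Per-copy footprint in square nanometres.
#' @return Integer count of bait copies (as a double to avoid 32-bit overflow).
#' @examples
#' binding_capacity(70, 10)  # 7e6
#' @export
binding_capacity <- function(surface_area, footprint) {
  if (!is.numeric(surface_area) || surface_area <= 0) {
    stop("surface_area must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(footprint) || footprint <= 0) {
    stop("footprint must be strictly positive", call. = FALSE)
  }
  q <- surface_area * 1e6 / footprint  # 1 um^2 = 1e6 nm^2
  floor(q + 1e-9 * abs(q))             # guard the floor against float error
}
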