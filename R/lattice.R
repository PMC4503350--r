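#' 3D cubic lattice for the tumor cellular automaton
#'
#' Creates an empty cubic lattice of `side^3` sites together with the
#' growth-factor region geometry. Cells can divide without the self-growth
#' hallmark only inside a central sub-box covering `boundary_fraction` of
#' each dimension; with the default 0.95 that is \eqn{0.95^3 \approx 85.7\%}
#' of the grid volume. The per-side exclusion width is discretized as
#' `growth_margin = max(1, round(side * (1 - boundary_fraction) / 2))` when
#' `boundary_fraction < 1`, else 0.
#'
#' Coordinates are 0-based integer triples; there are no periodic boundaries.
#'
#' @param side number of sites per dimension (integer, at least 3).
#' @param boundary_fraction fraction of each dimension covered by the
#'   growth-factor region, in (0, 1].
#' @param neighborhood `"moore"` (26 neighbors, the default) or
#'   `"von_neumann"` (6 neighbors).
#' @return an object of class `ca_lattice` with fields `side`,
#'   `growth_margin`, `neighborhood` and `occupancy` (integer vector of
#'   length `side^3`; 0 denotes an empty site).
#' @examples
#' lat <- make_lattice(50)
#' lat$side^3            # 125000 sites
#' lat$growth_margin     # 1
#' @export
make_lattice <- function(side, boundary_fraction = 0.95,
                         neighborhood = c("moore", "von_neumann")) {
  neighborhood <- match.arg(neighborhood)
  if (!is.numeric(side) || length(side) != 1L || side != as.integer(side) ||
      side < 3)
    stop("`side` must be a single integer >= 3")
  side <- as.integer(side)
  margin <- growth_margin_for(side, boundary_fraction)
  if (margin >= side / 2)
    stop("growth margin must be smaller than side/2")
  structure(
    list(side = side,
         boundary_fraction = boundary_fraction,
         growth_margin = margin,
         neighborhood = neighborhood,
         occupancy = integer(side^3)),
    class = "ca_lattice")
}

#' Discretized growth-region margin for a given lattice side
#'
#' @param side sites per dimension.
#' @param boundary_fraction fraction of each dimension inside the
#'   growth-factor region, in (0, 1].
#' @return integer per-side exclusion width.
#' @export
growth_margin_for <- function(side, boundary_fraction) {
  if (!is.numeric(boundary_fraction) || length(boundary_fraction) != 1L ||
      boundary_fraction <= 0 || boundary_fraction > 1)
    stop("`boundary_fraction` must be in (0, 1]")
  if (boundary_fraction == 1) return(0L)
  as.integer(max(1, round(side * (1 - boundary_fraction) / 2)))
}

#' @export
print.ca_lattice <- function(x, ...) {
  cat(sprintf("<ca_lattice> %d^3 = %d sites, %d occupied, growth margin %d (%s)\n",
              x$side, x$side^3, sum(x$occupancy != 0L), x$growth_margin,
              x$neighborhood))
  invisible(x)
}

check_site <- function(lattice, site) {
  site <- as.integer(site)
  if (length(site) != 3L || anyNA(site) ||
      any(site < 0L) || any(site >= lattice$side))
    stop("site must be a 0-based integer triple within the lattice bounds")
  site
}

#' Linear index of a 0-based site coordinate (internal layout: x fastest)
#' @param side sites per dimension.
#' @param site 0-based integer triple, or an n x 3 matrix of triples.
#' @return 0-based linear index (or vector thereof).
#' @export
site_index <- function(side, site) {
  if (is.matrix(site))
    return(site[, 1] + side * (site[, 2] + side * site[, 3]))
  site[1] + side * (site[2] + side * site[3])
}

#' 0-based coordinates of linear site indices
#' @param side sites per dimension.
#' @param idx 0-based linear indices.
#' @return an n x 3 integer matrix of coordinates.
#' @export
site_coords <- function(side, idx) {
  cbind(x = idx %% side,
        y = (idx %/% side) %% side,
        z = idx %/% (side * side))
}

#' Neighborhood of a lattice site
#'
#' Returns the in-bounds sites at Chebyshev distance 1 (Moore, up to 26) or
#' at Manhattan distance 1 (von Neumann, up to 6), clipped at the lattice
#' edges — no wrapping.
#'
#' @param lattice a `ca_lattice`.
#' @param site 0-based integer triple.
#' @return an n x 3 integer matrix of neighbor coordinates.
#' @examples
#' lat <- make_lattice(3, boundary_fraction = 1)
#' nrow(neighbors(lat, c(1, 1, 1)))  # 26
#' nrow(neighbors(lat, c(0, 0, 0)))  # 7
#' @export
neighbors <- function(lattice, site) {
  site <- check_site(lattice, site)
  idx <- cpp_neighbor_sites(lattice$side, site_index(lattice$side, site),
                            lattice$neighborhood == "moore")
  site_coords(lattice$side, idx)
}

#' Empty sites in the neighborhood of a site
#'
#' Subset of [neighbors()] whose occupancy is empty. A cell with a fully
#' occupied neighborhood cannot perform a mitotic division (unless it has
#' the ignore-growth-inhibit hallmark and wins a competition).
#'
#' @inheritParams neighbors
#' @return an n x 3 integer matrix (possibly 0 rows).
#' @export
empty_neighbors <- function(lattice, site) {
  nb <- neighbors(lattice, site)
  nb[lattice$occupancy[site_index(lattice$side, nb) + 1L] == 0L, , drop = FALSE]
}

#' Place or remove an occupant on a lattice (bookkeeping helper)
#'
#' @param lattice a `ca_lattice`.
#' @param site 0-based integer triple.
#' @param id positive cell identity, or 0 to clear the site.
#' @return the modified lattice.
#' @export
lattice_occupy <- function(lattice, site, id) {
  site <- check_site(lattice, site)
  lattice$occupancy[site_index(lattice$side, site) + 1L] <- as.integer(id)
  lattice
}

#' Is a site inside the growth-factor region?
#'
#' Outside this central sub-box growth signals are too faint to prompt
#' mitosis unless the cell has acquired the self-growth hallmark.
#'
#' @inheritParams neighbors
#' @return logical.
#' @export
in_growth_region <- function(lattice, site) {
  site <- check_site(lattice, site)
  m <- lattice$growth_margin
  all(site >= m & site <= lattice$side - 1L - m)
}

#' Continuum volume fraction of the growth-factor region
#'
#' The cube of the per-dimension fraction: 0.95 per dimension gives
#' 0.857375, i.e. 85.7% of the grid volume.
#'
#' @param boundary_fraction per-dimension fraction in (0, 1].
#' @return `boundary_fraction^3`.
#' @examples
#' growth_region_volume_fraction(0.95)  # 0.857375
#' @export
growth_region_volume_fraction <- function(boundary_fraction) {
  if (!is.numeric(boundary_fraction) || length(boundary_fraction) != 1L ||
      boundary_fraction <= 0 || boundary_fraction > 1)
    stop("`boundary_fraction` must be in (0, 1]")
  boundary_fraction^3
}

#' All 0-based linear indices of sites inside the growth-factor region
#' @param side sites per dimension.
#' @param margin per-side exclusion width.
#' @return integer vector of 0-based linear indices.
#' @export
growth_region_sites <- function(side, margin) {
  r <- margin:(side - 1L - margin)
  g <- expand.grid(x = r, y = r, z = r)
  as.integer(g$x + side * (g$y + side * g$z))
}
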