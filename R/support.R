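# Data-support mask for derived products.
#
# Occurrence-probability estimates far from any sampled location are pure
# extrapolation: a penalized spline's unpenalized (linear) directions can
# grow without bound there, and a normalised density would concentrate its
# mass in such unsampled corners. Derived products are therefore restricted
# to the sampled domain: a fixed fine occupancy lattice is recorded at fit
# time, dilated by a support radius, and product-grid cells outside the
# dilated set are excluded (given zero density / no contribution). Because
# the dilated lattice is fixed, the supported region does not depend on
# the product grid's resolution.

#' Build the training-data occupancy lattice
#'
#' @param east,north training sample coordinates, metres.
#' @param nbins lattice resolution per axis.
#' @return list of class `bw_support`: bounding box and logical occupancy
#'   matrix.
#' @export
support_build <- function(east, north, nbins = 200L) {
  e0 <- min(east); e1 <- max(east); n0 <- min(north); n1 <- max(north)
  ie <- pmin(pmax(ceiling((east - e0) / max(e1 - e0, 1) * nbins), 1L), nbins)
  in_ <- pmin(pmax(ceiling((north - n0) / max(n1 - n0, 1) * nbins), 1L), nbins)
  occ <- matrix(FALSE, nbins, nbins)
  occ[cbind(ie, in_)] <- TRUE
  structure(list(e0 = e0, e1 = e1, n0 = n0, n1 = n1, nbins = nbins,
                 occ = occ),
            class = "bw_support")
}

# Dilate the occupancy lattice by a radius (metres): a lattice cell is
# supported if any occupied cell lies within the radius.
.support_dilate <- function(support, radius_m) {
  nb <- support$nbins
  he <- (support$e1 - support$e0) / nb   # bin sizes
  hn <- (support$n1 - support$n0) / nb
  re <- ceiling(radius_m / max(he, 1))
  rn <- ceiling(radius_m / max(hn, 1))
  off <- expand.grid(de = -re:re, dn = -rn:rn)
  off <- off[(off$de * he)^2 + (off$dn * hn)^2 <= radius_m^2, , drop = FALSE]
  idx <- which(support$occ, arr.ind = TRUE)
  out <- matrix(FALSE, nb, nb)
  for (k in seq_len(nrow(off))) {
    ie <- idx[, 1] + off$de[k]
    in_ <- idx[, 2] + off$dn[k]
    ok <- ie >= 1 & ie <= nb & in_ >= 1 & in_ <= nb
    out[cbind(ie[ok], in_[ok])] <- TRUE
  }
  out
}

# Look points up in a dilated lattice; points outside the bounding box
# (expanded by the radius) are unsupported.
.support_lookup <- function(support, dil, east, north) {
  nb <- support$nbins
  ie <- ceiling((east - support$e0) / max(support$e1 - support$e0, 1) * nb)
  in_ <- ceiling((north - support$n0) / max(support$n1 - support$n0, 1) * nb)
  ok <- ie >= 1 & ie <= nb & in_ >= 1 & in_ <= nb
  res <- logical(length(east))
  res[ok] <- dil[cbind(ie[ok], in_[ok])]
  res
}

#' Supported-cell mask for a set of spatial locations
#'
#' @param model a fitted `bw_gam` (carries the occupancy lattice).
#' @param east,north locations to classify, metres.
#' @param support_km support radius in kilometres; `NULL` disables masking
#'   (everything supported).
#' @return logical vector.
#' @export
support_mask <- function(model, east, north, support_km = 80) {
  if (is.null(support_km) || is.null(model$support))
    return(rep(TRUE, length(east)))
  dil <- .support_dilate(model$support, support_km * 1000)
  .support_lookup(model$support, dil, east, north)
}

#' Supported area fraction of product-grid cells
#'
#' For each cell of a regular east/north product grid, the fraction of the
#' fixed fine support lattice covered by the dilated sampled region. Using
#' area fractions (rather than a yes/no test at the cell centre) makes
#' integrals over the supported domain stable under product-grid
#' refinement: every resolution integrates the same fine indicator.
#'
#' @param model a fitted `bw_gam`.
#' @param east_axis,north_axis cell-centre axes (uniform spacing).
#' @param support_km support radius, km; `NULL` disables (all ones).
#' @return numeric matrix (length(east_axis) x length(north_axis)) in
#'   `[0, 1]`.
#' @export
support_fraction <- function(model, east_axis, north_axis, support_km = 80) {
  ne <- length(east_axis); nn <- length(north_axis)
  if (is.null(support_km) || is.null(model$support))
    return(matrix(1, ne, nn))
  sp <- model$support
  dil <- .support_dilate(sp, support_km * 1000)
  nb <- sp$nbins
  he <- (sp$e1 - sp$e0) / nb
  hn <- (sp$n1 - sp$n0) / nb
  de <- if (ne > 1) east_axis[2] - east_axis[1] else he
  dn <- if (nn > 1) north_axis[2] - north_axis[1] else hn
  # integer lattice positions whose centres fall inside each cell
  pos <- function(centre, half, h, x0) {
    lo <- ceiling((centre - half - x0) / h + 0.5)
    hi <- floor((centre + half - x0) / h + 0.5)
    if (hi < lo) lo <- hi <- round((centre - x0) / h + 0.5)  # tiny cell
    lo:hi
  }
  w <- matrix(0, ne, nn)
  for (i in seq_len(ne)) {
    ie <- pos(east_axis[i], de / 2, he, sp$e0)
    oke <- ie[ie >= 1 & ie <= nb]
    for (j in seq_len(nn)) {
      in_ <- pos(north_axis[j], dn / 2, hn, sp$n0)
      okn <- in_[in_ >= 1 & in_ <= nb]
      hits <- if (length(oke) && length(okn)) sum(dil[oke, okn]) else 0
      w[i, j] <- hits / (length(ie) * length(in_))
    }
  }
  w
}
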