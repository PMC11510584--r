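# Sparse hemispherical transmit/receive geometry.
#
# The published system fixes the counts (64 modules x 4 receive corner elements
# = 256 PCI channels, plus 4 dedicated ICD receivers) and the scaffold radius;
# the exact module layout was chosen by the designers from transmit
# simulations and is not recoverable. Placement here is seeded quasi-uniform
# (blue-noise) rejection sampling on the hemisphere with a minimum angular gap,
# which preserves the sparse, grating-lobe-suppressing character of the array.
#
# Coordinates: right-handed Cartesian, origin at the geometric focus, +z along
# the hemisphere pole ("axial"); the x-y plane is "lateral". All metres.

#' Build a sparse hemispherical receiver geometry
#'
#' Places `n_modules` transducer modules quasi-uniformly on the upper
#' hemisphere of radius `hemisphere_diameter/2`, projects the four corner
#' receive elements of each module (8 x 8 element grid, `module_pitch`
#' spacing, corners at +/-3.5 pitch) back onto the sphere to form the PCI
#' receiver set, and drops four dedicated wideband (ICD) receivers into the
#' largest gaps between modules.
#'
#' @param seed Integer seed; the layout is deterministic given
#'   `(seed, n_modules, module_pitch, min_gap)`.
#' @param n_modules Number of transducer modules (64 in the physical array).
#' @param module_pitch Inter-element spacing within a module, m.
#' @param min_gap Minimum angular spacing between module centres, rad.
#' @param constants A [system_constants()] object (radius, sound speed).
#' @param max_tries Rejection-sampling budget before placement is declared
#'   infeasible.
#'
#' @return An object of class `array_geometry`: list with
#'   `pci_receiver_positions` (4*n_modules x 3), `icd_receiver_positions`
#'   (4 x 3), `module_centres` (n_modules x 3), `geometric_focus` (origin),
#'   `radius`, and the placement parameters.
#' @examples
#' geom <- build_array_geometry(seed = 7)
#' nrow(geom$pci_receiver_positions)  # 256
#' @export
build_array_geometry <- function(seed,
                                 n_modules = 64,
                                 module_pitch = 2.5e-3,
                                 min_gap = 0.14,
                                 constants = system_constants(),
                                 max_tries = 20000L) {
  stopifnot(n_modules >= 1, module_pitch > 0, min_gap >= 0)
  radius <- constants$hemisphere_diameter / 2

  centres <- withr_seed(seed, {
    pts <- matrix(NA_real_, n_modules, 3)
    n_placed <- 0L
    tries <- 0L
    # keep module centres off the rim so the projected corners stay on the cap
    cos_pol_min <- sin(0.1)
    while (n_placed < n_modules && tries < max_tries) {
      tries <- tries + 1L
      u <- stats::runif(1, cos_pol_min, 1)  # cos(polar angle)
      ph <- stats::runif(1, 0, 2 * pi)
      s <- sqrt(1 - u^2)
      p <- c(s * cos(ph), s * sin(ph), u)
      ok <- TRUE
      if (n_placed > 0L) {
        cosang <- pts[seq_len(n_placed), , drop = FALSE] %*% p
        ok <- all(acos(pmin(1, pmax(-1, cosang))) > min_gap)
      }
      if (ok) {
        n_placed <- n_placed + 1L
        pts[n_placed, ] <- p
      }
    }
    if (n_placed < n_modules) {
      stop(sprintf(paste0("module placement failed: placed %d of %d modules ",
                          "with min_gap %.3f rad in %d tries"),
                   n_placed, n_modules, min_gap, max_tries))
    }
    pts
  })

  corner_off <- 3.5 * module_pitch  # corner elements of the 8x8 grid
  pci <- matrix(NA_real_, 4L * n_modules, 3)
  for (i in seq_len(n_modules)) {
    nrm <- centres[i, ]
    basis <- tangent_basis(nrm)
    corners <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * corner_off
    for (j in 1:4) {
      p <- nrm * radius + corners[j, 1] * basis$t1 + corners[j, 2] * basis$t2
      pci[(i - 1L) * 4L + j, ] <- p / sqrt(sum(p^2)) * radius
    }
  }

  icd_dirs <- place_in_gaps(centres, n_pick = 4L, seed = seed)
  geom <- structure(list(
    pci_receiver_positions = pci * 1,
    icd_receiver_positions = icd_dirs * radius,
    module_centres = centres * radius,
    geometric_focus = c(0, 0, 0),
    radius = radius,
    seed = as.integer(seed),
    n_modules = as.integer(n_modules),
    module_pitch = module_pitch,
    min_gap = min_gap
  ), class = "array_geometry")
  geom
}

# orthonormal tangent basis at a unit normal
tangent_basis <- function(nrm) {
  a <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a - sum(a * nrm) * nrm
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

# pick n_pick unit directions on the upper hemisphere maximising the minimum
# angular distance to the module centres (deterministic candidate grid)
place_in_gaps <- function(centres, n_pick, seed) {
  cand <- withr_seed(seed + 101L, {
    u <- stats::runif(4000, sin(0.05), 1)
    ph <- stats::runif(4000, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    cbind(s * cos(ph), s * sin(ph), u)
  })
  picked <- matrix(NA_real_, n_pick, 3)
  occupied <- centres
  for (k in seq_len(n_pick)) {
    ang <- acos(pmin(pmax(cand %*% t(occupied), -1), 1))
    score <- apply(ang, 1, min)
    best <- which.max(score)
    picked[k, ] <- cand[best, ]
    occupied <- rbind(occupied, cand[best, ])
  }
  picked
}

#' One-way propagation delay between two points
#'
#' @param source,receiver 3-vectors or n x 3 matrices of Cartesian
#'   coordinates, m.
#' @param sound_speed Uniform sound speed, m/s.
#' @return Delay(s) in seconds: Euclidean distance / sound_speed.
#' @examples
#' propagation_delay(c(0, 0, 0), c(0, 0, 0.1255), 1482)  # ~84.68 us
#' @export
propagation_delay <- function(source, receiver, sound_speed = 1482) {
  stopifnot(sound_speed > 0)
  s <- matrix(source, ncol = 3)
  r <- matrix(receiver, ncol = 3)
  if (nrow(s) == 1 && nrow(r) > 1) s <- s[rep(1, nrow(r)), , drop = FALSE]
  if (nrow(r) == 1 && nrow(s) > 1) r <- r[rep(1, nrow(s)), , drop = FALSE]
  sqrt(rowSums((s - r)^2)) / sound_speed
}

#' Serialize / read an array geometry as JSON
#'
#' Positions are stored in metres together with the seed and placement
#' parameters so a layout can be reproduced or inspected outside R.
#'
#' @param geometry An `array_geometry` object.
#' @param path Output (input) file path.
#' @return `write_geometry_json` returns `path` invisibly;
#'   `read_geometry_json` returns an `array_geometry`.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "array_geometry"))
  obj <- unclass(geometry)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("pci_receiver_positions", "icd_receiver_positions", "module_centres")) {
    obj[[f]] <- matrix(unlist(obj[[f]]), ncol = 3,
                       nrow = length(unlist(obj[[f]])) / 3)
  }
  obj$geometric_focus <- as.numeric(obj$geometric_focus)
  structure(obj, class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("array_geometry: %d modules, %d PCI + %d ICD receivers, radius %.4f m (seed %d)\n",
              x$n_modules, nrow(x$pci_receiver_positions),
              nrow(x$icd_receiver_positions), x$radius, x$seed))
  invisible(x)
}

# run expr with a locally-set RNG seed, restoring global state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic fan-out of a master seed into stage-specific child seeds
child_seeds <- function(master_seed, n) {
  withr_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
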