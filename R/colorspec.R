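# Reflectance-spectrum processing, avian tetrahedral color space, and
# color-volume overlap.

#' Reflectance spectrum container
#'
#' @param wavelengths strictly ascending grid in nm.
#' @param reflectance percent reflectance relative to a white standard
#'   (negatives allowed before smoothing).
#' @export
reflectance_spectrum <- function(wavelengths, reflectance) {
  stopifnot(length(wavelengths) == length(reflectance),
            all(is.finite(wavelengths)), all(is.finite(reflectance)))
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly ascending")
  }
  structure(list(wl = as.numeric(wavelengths),
                 refl = as.numeric(reflectance)),
            class = "reflectance_spectrum")
}

#' Read spectra from CSV (first column wavelength, one column per specimen)
#' @param path CSV path.
#' @return named list of [reflectance_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- df[[1]]
  out <- lapply(df[-1], function(col) reflectance_spectrum(wl, col))
  names(out) <- names(df)[-1]
  out
}

#' Write spectra to CSV
#' @param spectra named list of spectra sharing one grid.
#' @param path output path.
#' @export
write_spectra <- function(spectra, path) {
  wl <- spectra[[1]]$wl
  for (s in spectra) stopifnot(identical(s$wl, wl))
  df <- data.frame(wl = wl, lapply(spectra, function(s) s$refl),
                   check.names = FALSE)
  names(df) <- c("wl", names(spectra))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' LOESS-smooth a reflectance spectrum
#'
#' Local quadratic regression with tricube weights evaluated on the input
#' grid (default span 0.25, the standard choice for removing spectrometer
#' noise). Negative smoothed reflectance is clipped to zero.
#'
#' @param spec a [reflectance_spectrum()].
#' @param span loess span, 0 < span <= 1.
#' @return a smoothed [reflectance_spectrum()] with attribute `n_clipped`.
#' @export
smooth_spectrum <- function(spec, span = 0.25) {
  stopifnot(inherits(spec, "reflectance_spectrum"), span > 0, span <= 1)
  n <- length(spec$wl)
  if (n < 10) stop("need at least 10 points to smooth")
  if (span * n < 4) {
    stop("span too small: needs span >= ", signif(4 / n, 2),
         " for local quadratic fits")
  }
  fit <- stats::loess(refl ~ wl, data = data.frame(wl = spec$wl,
                                                   refl = spec$refl),
                      span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = data.frame(wl = spec$wl))
  n_clipped <- sum(sm < 0)
  sm[sm < 0] <- 0
  out <- reflectance_spectrum(spec$wl, sm)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Dual-window hue extraction
#'
#' Wavelength of peak reflectance within each window (default UV/blue
#' 300-500 nm and red beyond 600 nm). A peak landing on a window boundary
#' shared with the grid edge is flagged as a non-peak (NA with flag).
#'
#' @param spec a smoothed [reflectance_spectrum()].
#' @param windows list of c(lo, hi) windows in nm; NA hi means grid max.
#' @return data.frame with window bounds, peak wavelength and a
#'   `boundary` flag.
#' @export
hue_peaks <- function(spec, windows = list(c(300, 500), c(600, NA))) {
  stopifnot(inherits(spec, "reflectance_spectrum"))
  out <- do.call(rbind, lapply(windows, function(wdw) {
    lo <- wdw[1]; hi <- if (is.na(wdw[2])) max(spec$wl) else wdw[2]
    if (lo < min(spec$wl) || hi > max(spec$wl)) {
      stop("window [", lo, ", ", hi, "] outside the spectrum grid")
    }
    sel <- spec$wl >= lo & spec$wl <= hi
    i <- which.max(spec$refl[sel])
    pk <- spec$wl[sel][i]
    boundary <- i == 1L || i == sum(sel)
    data.frame(lo = lo, hi = hi,
               peak = if (boundary) NA_real_ else pk,
               argmax = pk, boundary = boundary)
  }))
  out
}

#' Tetrachromat visual model
#'
#' Cone spectral sensitivities on a wavelength grid plus an illuminant;
#' each sensitivity integrates to 1 over the grid. The default is an
#' idealized avian UV-sensitive tetrachromat: Gaussian sensitivities
#' peaking at 372, 456, 544 and 609 nm (SD 40 nm) with a flat illuminant
#' over 300-700 nm.
#'
#' @param wl wavelength grid (nm).
#' @param sens 4-column matrix (u, s, m, l) of nonnegative sensitivities;
#'   NULL builds the idealized default.
#' @param illuminant illuminant spectrum on the grid (default flat).
#' @export
visual_model <- function(wl = 300:700, sens = NULL, illuminant = NULL) {
  if (is.null(sens)) {
    peaks <- c(u = 372, s = 456, m = 544, l = 609)
    sens <- vapply(peaks, function(p) exp(-((wl - p)^2) / (2 * 40^2)),
                   numeric(length(wl)))
  }
  stopifnot(ncol(sens) == 4, nrow(sens) == length(wl), all(sens >= 0))
  if (is.null(illuminant)) illuminant <- rep(1, length(wl))
  # normalize: each cone integrates to 1 (trapezoid) under the illuminant
  for (j in 1:4) {
    z <- trapz(wl, sens[, j] * illuminant)
    if (z <= 0) stop("cone ", j, " has zero integral")
    sens[, j] <- sens[, j] / z
  }
  colnames(sens) <- c("u", "s", "m", "l")
  structure(list(wl = wl, sens = sens, illuminant = illuminant),
            class = "visual_model")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Relative cone quantum catches
#'
#' Q_i = integral of R(lambda) I(lambda) S_i(lambda) over the visual range
#' (trapezoid rule), normalized to the 3-simplex. Reflectance outside the
#' visual-model grid (e.g. beyond 700 nm) does not contribute.
#'
#' @param spec a [reflectance_spectrum()].
#' @param vm a [visual_model()].
#' @return named numeric usml vector summing to 1.
#' @export
quantum_catches <- function(spec, vm = visual_model()) {
  refl <- stats::approx(spec$wl, spec$refl, xout = vm$wl, rule = 2)$y
  Q <- vapply(1:4, function(j) trapz(vm$wl, refl * vm$illuminant * vm$sens[, j]),
              numeric(1))
  if (sum(Q) <= 0) stop("black spectrum: total quantum catch is zero")
  stats::setNames(Q / sum(Q), c("u", "s", "m", "l"))
}

#' Map quantum catches to tetrahedral color space
#'
#' Standard tetrahedral construction: the achromatic point (equal catches)
#' sits at the origin and the four unit-stimulation vertices lie at
#' distance 0.75. Returns Cartesian coordinates, hue angles (azimuth
#' h_theta, elevation h_phi), chroma r_vec, the maximum chroma r_max along
#' the hue direction (exact ray-face intersection), and r_achieved =
#' r_vec / r_max.
#'
#' @param usml numeric vector (u, s, m, l) on the simplex (tolerance 1e-9).
#' @return list of class `color_point`.
#' @export
tetra_point <- function(usml) {
  if (abs(sum(usml) - 1) > 1e-9 || any(usml < -1e-12)) {
    stop("usml must lie on the 3-simplex")
  }
  u <- usml[1]; s <- usml[2]; m <- usml[3]; l <- usml[4]
  x <- ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2)
  y <- (-1 + 3 * m + u) / (2 * sqrt(2))
  z <- u - 1 / 4
  r_vec <- sqrt(x^2 + y^2 + z^2)
  h_theta <- atan2(y, x)
  h_phi <- if (r_vec > 0) asin(z / r_vec) else 0
  r_max <- if (r_vec > 0) {
    ray_tetra_boundary(c(x, y, z) / r_vec)
  } else NA_real_
  r_ach <- if (r_vec > 0) r_vec / r_max else 0
  structure(list(usml = stats::setNames(as.numeric(usml), c("u", "s", "m", "l")),
                 X = unname(x), Y = unname(y), Z = unname(z),
                 h_theta = unname(h_theta), h_phi = unname(h_phi),
                 r_vec = unname(r_vec), r_max = unname(r_max),
                 r_achieved = unname(r_ach)),
            class = "color_point")
}

# distance from the origin to the tetrahedron boundary along unit vector v
ray_tetra_boundary <- function(v) {
  V <- rbind(c(0, 0, 3 / 4),
             c(-sqrt(3 / 2) / 2, -1 / (2 * sqrt(2)), -1 / 4),
             c(0, 1 / sqrt(2), -1 / 4),
             c(sqrt(3 / 2) / 2, -1 / (2 * sqrt(2)), -1 / 4))
  faces <- utils::combn(4, 3)
  tmin <- Inf
  for (f in seq_len(ncol(faces))) {
    tri <- V[faces[, f], ]
    nrm <- crossprod3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    c0 <- sum(nrm * tri[1, ])
    # orient outward (origin is interior: n.x = c0 with c0 same sign as outward)
    if (c0 < 0) { nrm <- -nrm; c0 <- -c0 }
    den <- sum(nrm * v)
    if (den > 1e-12) tmin <- min(tmin, c0 / den)
  }
  tmin
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Full spectrum-to-color-point pipeline
#'
#' Smooths, computes quantum catches and maps into the tetrahedron.
#'
#' @param spec a [reflectance_spectrum()].
#' @param vm a [visual_model()].
#' @param span loess span (NULL skips smoothing).
#' @export
spectrum_to_color <- function(spec, vm = visual_model(), span = 0.25) {
  if (!is.null(span)) spec <- smooth_spectrum(spec, span)
  tetra_point(quantum_catches(spec, vm))
}

# ---- 3-D convex hulls -----------------------------------------------------

# Incremental quickhull. Returns list(vertices = index vector,
# faces = 3-column matrix of point indices, oriented outward).
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) return(NULL)
  # initial simplex: extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) return(NULL)
  d2line <- apply(pts, 1, function(p) {
    v <- crossprod3(p - pts[i1, ], pts[i2, ] - pts[i1, ]); sum(v^2)
  })
  i3 <- which.max(d2line)
  if (d2line[i3] < 1e-24) return(NULL)
  nrm <- crossprod3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(as.numeric(pts %*% nrm) - sum(nrm * pts[i1, ])) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] < 1e-12) return(NULL)  # coplanar set
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  mkface <- function(a, b, c) {
    nrm <- crossprod3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    if (sum(nrm * (centroid - pts[a, ])) > 0) { tmp <- b; b <- c; c <- tmp; nrm <- -nrm }
    list(v = c(a, b, c), n = nrm, off = sum(nrm * pts[a, ]))
  }
  faces <- list(mkface(i1, i2, i3), mkface(i1, i2, i4),
                mkface(i1, i3, i4), mkface(i2, i3, i4))
  eps <- 1e-10 * max(abs(pts))
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  repeat {
    if (!length(remaining)) break
    # farthest point outside any face
    best_d <- eps; best_p <- 0L
    for (p in remaining) {
      for (f in faces) {
        d <- sum(f$n * pts[p, ]) - f$off
        dn <- d / sqrt(sum(f$n^2))
        if (dn > best_d) { best_d <- dn; best_p <- p }
      }
    }
    if (best_p == 0L) break
    p <- best_p
    vis <- vapply(faces, function(f) sum(f$n * pts[p, ]) - f$off > eps * sqrt(sum(f$n^2)),
                  logical(1))
    # horizon: edges of visible faces shared with an invisible face
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    counts <- new.env()
    for (f in faces[vis]) {
      v <- f$v
      for (e in list(c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))) {
        k <- edge_key(e[1], e[2])
        cur <- if (!is.null(counts[[k]])) counts[[k]] else list(0L, e)
        counts[[k]] <- list(cur[[1]] + 1L, e)
      }
    }
    horizon <- list()
    for (k in ls(counts)) {
      if (counts[[k]][[1]] == 1L) horizon[[length(horizon) + 1L]] <- counts[[k]][[2]]
    }
    inner_centroid <- centroid
    faces <- faces[!vis]
    for (e in horizon) {
      nf <- mkface(e[1], e[2], p)
      faces[[length(faces) + 1L]] <- nf
    }
    remaining <- setdiff(remaining, p)
    # drop points now inside all faces
    inside <- vapply(remaining, function(q) {
      all(vapply(faces, function(f) sum(f$n * pts[q, ]) - f$off <= eps * sqrt(sum(f$n^2)),
                 logical(1)))
    }, logical(1))
    remaining <- remaining[!inside]
  }
  verts <- sort(unique(unlist(lapply(faces, `[[`, "v"))))
  list(vertices = verts,
       faces = do.call(rbind, lapply(faces, `[[`, "v")),
       normals = do.call(rbind, lapply(faces, `[[`, "n")),
       offsets = vapply(faces, `[[`, numeric(1), "off"),
       points = pts)
}

hull_volume <- function(hull) {
  if (is.null(hull)) return(0)
  ref <- colMeans(hull$points[hull$vertices, , drop = FALSE])
  vol <- 0
  for (f in seq_len(nrow(hull$faces))) {
    tri <- hull$points[hull$faces[f, ], ]
    vol <- vol + abs(det(rbind(tri[1, ] - ref, tri[2, ] - ref, tri[3, ] - ref))) / 6
  }
  vol
}

point_in_hull <- function(hull, p, tol = 1e-9) {
  d <- as.numeric(hull$normals %*% p) - hull$offsets
  all(d <= tol * sqrt(rowSums(hull$normals^2)) + tol)
}

#' Color-volume overlap between two point sets
#'
#' Convex-hull volumes for each set and a seeded Monte-Carlo estimate of
#' the intersection volume (points sampled in the intersection of the two
#' bounding boxes and tested against both hulls' half-spaces; documented
#' tolerance about 1% at the default sample size). Degenerate (coplanar)
#' sets yield zero volume with a flag.
#'
#' @param pointsA,pointsB matrices (>= 4 rows x 3 columns) of XYZ color
#'   coordinates.
#' @param n_mc Monte-Carlo sample size.
#' @param rng_seed integer seed.
#' @return list of class `volume_overlap`: vol_A, vol_B, vol_intersection,
#'   frac_smaller (intersection / smaller volume), frac_union
#'   (intersection / union), degenerate flag.
#' @export
color_volume_overlap <- function(pointsA, pointsB, n_mc = 1e6L,
                                 rng_seed = 1L) {
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  stopifnot(ncol(pointsA) == 3, ncol(pointsB) == 3)
  hA <- convex_hull_3d(pointsA)
  hB <- convex_hull_3d(pointsB)
  vA <- hull_volume(hA); vB <- hull_volume(hB)
  degenerate <- is.null(hA) || is.null(hB)
  vI <- 0
  if (!degenerate && vA > 0 && vB > 0) {
    lo <- pmax(apply(pointsA, 2, min), apply(pointsB, 2, min))
    hi <- pmin(apply(pointsA, 2, max), apply(pointsB, 2, max))
    if (all(hi > lo)) {
      old <- .Random.seed_store()
      set.seed(rng_seed)
      m <- as.integer(n_mc)
      X <- cbind(stats::runif(m, lo[1], hi[1]),
                 stats::runif(m, lo[2], hi[2]),
                 stats::runif(m, lo[3], hi[3]))
      .Random.seed_restore(old)
      dA <- X %*% t(hA$normals)
      inA <- rowSums(sweep(dA, 2, hA$offsets) > 0) == 0
      dB <- X %*% t(hB$normals)
      inB <- rowSums(sweep(dB, 2, hB$offsets) > 0) == 0
      vI <- prod(hi - lo) * mean(inA & inB)
    }
  }
  vI <- min(vI, vA, vB)
  structure(list(vol_A = vA, vol_B = vB, vol_intersection = vI,
                 frac_smaller = if (min(vA, vB) > 0) vI / min(vA, vB) else NA_real_,
                 frac_union = if (vA + vB - vI > 0) vI / (vA + vB - vI) else NA_real_,
                 degenerate = degenerate),
            class = "volume_overlap")
}

#' @export
print.volume_overlap <- function(x, ...) {
  cat(sprintf("color volumes: A = %.4g, B = %.4g, intersection = %.4g\n",
              x$vol_A, x$vol_B, x$vol_intersection))
  cat(sprintf("overlap: %.3f of smaller, %.3f of union%s\n",
              x$frac_smaller, x$frac_union,
              if (x$degenerate) " (degenerate set)" else ""))
  invisible(x)
}
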