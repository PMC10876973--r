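# Ensemble EEG power from single-neuron contributions: coherence
# superposition of spectra, signed neuron counts on a cortical mesh, mean
# pairwise dipole correlation under a Gaussian coupling kernel, and the
# total power sigma_N^2.

#' Gaussian dipole-coupling kernel
#'
#' Dipole correlation between neurons separated by distance `d` mm:
#' `rho(d) = rho_max * exp(-d^2 / sigma2)`, multiplied on a mesh by the
#' cosine of the angle between the local surface normals (apical axes).
#'
#' @param rho_max maximal dipole correlation in `[0, 1]`.
#' @param sigma2 spatial scale, mm^2 (subthreshold-correlation estimates
#'   put sigma at roughly 5-13 mm).
#' @return object of class `coupling_kernel`.
#' @export
coupling_kernel <- function(rho_max = 0.1, sigma2 = 64) {
  stop_if_not_scalar(rho_max, "rho_max", lower = 0, upper = 1)
  stop_if_not_scalar(sigma2, "sigma2")
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  structure(list(rho_max = rho_max, sigma2 = sigma2),
            class = "coupling_kernel")
}

#' Ensemble spectrum by coherence superposition
#'
#' Power spectral density of the sum of `n` signals:
#' `S_N(f) = sum_i S_i(f) + 2 sum_{i<j} gamma_ij(f) sqrt(S_i S_j)`,
#' where `gamma_ij` is the (real) coherence between signals i and j.
#'
#' @param spectra list of [new_spectrum()] objects on a common grid.
#' @param gamma coherence: a scalar, an `n x n` matrix, or a function of
#'   frequency returning an `n x n` matrix; magnitudes must not exceed 1.
#' @return a [new_spectrum()]; negative totals (inconsistent coherence) are
#'   an error.
#' @export
ensemble_spectrum <- function(spectra, gamma = 0) {
  stopifnot(length(spectra) >= 1)
  spectra <- lapply(spectra, as_spectrum)
  f <- spectra[[1]]$freq
  for (s in spectra)
    if (length(s$freq) != length(f) || any(abs(s$freq - f) > 1e-9))
      stop("spectra must share a common frequency grid", call. = FALSE)
  n <- length(spectra)
  P <- vapply(spectra, function(s) s$power, numeric(length(f)))  # nf x n
  amp <- sqrt(P)
  total <- rowSums(P)
  if (!is.function(gamma)) {
    G <- if (length(gamma) == 1) matrix(gamma, n, n) else as.matrix(gamma)
    if (any(abs(G) > 1 + 1e-12)) stop("|gamma| must be <= 1", call. = FALSE)
    diag(G) <- 0
    cross <- rowSums((amp %*% G) * amp)  # = sum_{i != j} gamma_ij a_i a_j
    total <- total + cross
  } else {
    for (k in seq_along(f)) {
      G <- gamma(f[k])
      if (any(abs(G) > 1 + 1e-12)) stop("|gamma| must be <= 1", call. = FALSE)
      diag(G) <- 0
      total[k] <- total[k] + sum((amp[k, ] %*% G) * amp[k, ])
    }
  }
  if (any(total < -1e-9 * max(abs(total))))
    stop("coherence yields negative total power (inconsistent gamma)",
         call. = FALSE)
  new_spectrum(f, pmax(total, 0))
}

# --- signed neuron counts ---------------------------------------------------

# Squared distance from point x to the closest point of triangle (v1,v2,v3).
point_tri_dist2 <- function(x, v1, v2, v3) {
  # Ericson's real-time collision detection closest-point construction
  ab <- v2 - v1; ac <- v3 - v1; ap <- x - v1
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sum((x - v1)^2))
  bp <- x - v2; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sum((x - v2)^2))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(sum((x - (v1 + v * ab))^2))
  }
  cp <- x - v3; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sum((x - v3)^2))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(sum((x - (v1 + w * ac))^2))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sum((x - (v2 + w * (v3 - v2)))^2))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sum((x - (v1 + ab * v + ac * w))^2)
}

# Fraction of triangle (v1,v2,v3) inside the ball of radius r at x, by
# adaptive subdivision: triangles fully inside/outside are resolved exactly
# (balls are convex), boundary triangles split until the unresolved area is
# below `tol` times the running estimate, with a depth cap.
tri_ball_fraction <- function(x, v1, v2, v3, r, tol = 1e-3, max_depth = 12) {
  r2 <- r^2
  tri_area <- function(a, b, cc) {
    cr <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
            (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
            (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    sqrt(sum(cr^2)) / 2
  }
  total <- tri_area(v1, v2, v3)
  inside <- 0
  queue <- list(list(v = list(v1, v2, v3), area = total, depth = 0))
  while (length(queue)) {
    nd <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    a <- nd$v[[1]]; b <- nd$v[[2]]; cc <- nd$v[[3]]
    din <- c(sum((a - x)^2), sum((b - x)^2), sum((cc - x)^2))
    if (max(din) <= r2) { inside <- inside + nd$area; next }
    if (point_tri_dist2(x, a, b, cc) >= r2) next
    if (nd$depth >= max_depth) {
      ctr <- (a + b + cc) / 3
      if (sum((ctr - x)^2) <= r2) inside <- inside + nd$area
      next
    }
    # unresolved-area stopping rule
    pending <- nd$area + sum(vapply(queue, function(q) q$area, 0))
    if (pending <= tol * max(inside, total * 1e-6) && nd$depth > 2) {
      ctr <- (a + b + cc) / 3
      if (sum((ctr - x)^2) <= r2) inside <- inside + nd$area
      next
    }
    ab <- (a + b) / 2; bc <- (b + cc) / 2; ca <- (cc + a) / 2
    qa <- nd$area / 4; dp <- nd$depth + 1
    queue <- c(queue,
               list(list(v = list(a, ab, ca), area = qa, depth = dp),
                    list(v = list(ab, b, bc), area = qa, depth = dp),
                    list(v = list(ca, bc, cc), area = qa, depth = dp),
                    list(v = list(ab, bc, ca), area = qa, depth = dp)))
  }
  inside / total
}

#' Signed number of neurons within a radius of a surface point
#'
#' Evaluates `nu_i(r) = sum_j mu A_j f_j(r, x_i) (N_j . N_i)`, where
#' `f_j` is the fraction of mesh face j inside the ball of radius r centred
#' at `x_i`, and the normal dot product signs the count (anti-aligned patches
#' contribute negatively; on closed surfaces `nu` may decrease with r).
#'
#' @param mesh a [cortical_mesh()].
#' @param x surface point (3-vector), mm.
#' @param r radius or vector of radii, mm (>= 0).
#' @param face_i index of the face whose normal defines `N_i`; defaults to
#'   the face nearest to `x`.
#' @param tol relative refinement tolerance of the face-ball intersection.
#' @return numeric vector, one signed count per radius.
#' @export
signed_neuron_count <- function(mesh, x, r, face_i = NULL, tol = 1e-3) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  x <- as.numeric(x)
  if (is.null(face_i)) {
    cen <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
            mesh$vertices[mesh$faces[, 3], ]) / 3
    face_i <- which.min(rowSums(sweep(cen, 2, x)^2))
  }
  Ni <- mesh$normals[face_i, ]
  cosf <- as.vector(mesh$normals %*% Ni)
  vapply(r, function(rk) {
    if (rk == 0) return(0)
    # faces that can intersect the ball (vertex distance prefilter)
    vd2 <- rowSums(sweep(mesh$vertices, 2, x)^2)
    near <- which(vd2[mesh$faces[, 1]] < (rk + max_edge(mesh))^2 |
                  vd2[mesh$faces[, 2]] < (rk + max_edge(mesh))^2 |
                  vd2[mesh$faces[, 3]] < (rk + max_edge(mesh))^2)
    tot <- 0
    for (j in near) {
      fr <- tri_ball_fraction(x, mesh$vertices[mesh$faces[j, 1], ],
                              mesh$vertices[mesh$faces[j, 2], ],
                              mesh$vertices[mesh$faces[j, 3], ], rk, tol = tol)
      if (fr > 0) tot <- tot + mesh$mu * mesh$areas[j] * fr * cosf[j]
    }
    tot
  }, numeric(1))
}

max_edge <- function(mesh) {
  if (!is.null(mesh$.max_edge)) return(mesh$.max_edge)
  e1 <- sqrt(rowSums((mesh$vertices[mesh$faces[, 1], ] -
                      mesh$vertices[mesh$faces[, 2], ])^2))
  max(e1)
}

# Uniformly subdivide all faces into micro-triangles of edge <= h and
# return their centroids, signed areas and normals (shared across sample
# points when estimating nu-bar).
micro_mesh <- function(mesh, h) {
  cen_list <- list(); area_list <- list(); norm_list <- list()
  for (j in seq_len(nrow(mesh$faces))) {
    v1 <- mesh$vertices[mesh$faces[j, 1], ]
    v2 <- mesh$vertices[mesh$faces[j, 2], ]
    v3 <- mesh$vertices[mesh$faces[j, 3], ]
    edge <- max(sqrt(sum((v2 - v1)^2)), sqrt(sum((v3 - v2)^2)),
                sqrt(sum((v1 - v3)^2)))
    k <- max(1L, ceiling(edge / h))
    # split into k^2 congruent sub-triangles on the barycentric grid:
    # "up" triangles at (i, j), i + j <= k - 1, centroid offsets
    # ((3i+1)/(3k), (3j+1)/(3k)); "down" triangles at i + j <= k - 2 with
    # offsets ((3i+2)/(3k), (3j+2)/(3k))
    ij <- expand.grid(i = 0:(k - 1), j = 0:(k - 1))
    up <- ij[ij$i + ij$j <= k - 1, , drop = FALSE]
    dn <- ij[ij$i + ij$j <= k - 2, , drop = FALSE]
    a <- c((3 * up$i + 1), (3 * dn$i + 2)) / (3 * k)
    b <- c((3 * up$j + 1), (3 * dn$j + 2)) / (3 * k)
    cen <- outer(1 - a - b, v1) + outer(a, v2) + outer(b, v3)
    cen_list[[j]] <- cen
    area_list[[j]] <- rep(mesh$areas[j] / k^2, length(a))
    norm_list[[j]] <- matrix(mesh$normals[j, ], length(a), 3, byrow = TRUE)
  }
  list(centroids = do.call(rbind, cen_list),
       areas = unlist(area_list),
       normals = do.call(rbind, norm_list))
}

#' Mean pairwise dipole correlation over a mesh
#'
#' Monte-Carlo estimate of the cortex-wide mean pairwise correlation:
#' `rho_bar = (1/(N-1)) * integral rho_max exp(-r^2/sigma^2) d nu_bar(r)`,
#' where `nu_bar(r)` is the signed neuron count within radius r averaged
#' over `k` area-weighted random surface points, and N = mu x total area.
#' The Stieltjes integral is evaluated by the trapezoid rule on an r-grid
#' out to 5 sigma.
#'
#' @param mesh a [cortical_mesh()].
#' @param kernel a [coupling_kernel()].
#' @param k_samples number of sampled surface points (default 2000).
#' @param n_r radii in the integration grid (default 60).
#' @param h micro-triangle edge used to accumulate `nu_bar`; defaults to
#'   `sigma / 10`.
#' @param point_filter optional predicate `function(xyz)` returning TRUE for
#'   admissible sample points (e.g. to restrict to the interior of an open
#'   mesh, away from boundary truncation).
#' @param rng_seed integer seed.
#' @return list with `rho_bar`, `nu_bar` (data frame r / nu), `N`.
#' @export
mean_pairwise_correlation <- function(mesh, kernel, k_samples = 2000,
                                      n_r = 60, h = NULL, point_filter = NULL,
                                      rng_seed = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(kernel, "coupling_kernel"))
  sigma <- sqrt(kernel$sigma2)
  if (is.null(h)) h <- sigma / 10
  r_max <- 5 * sigma
  r_grid <- seq(0, r_max, length.out = n_r + 1)
  mm <- micro_mesh(mesh, h)
  N <- mesh$mu * sum(mesh$areas)
  admissible <- seq_len(nrow(mm$centroids))
  if (!is.null(point_filter)) {
    keep <- apply(mm$centroids, 1, point_filter)
    if (!any(keep)) stop("point_filter admits no sample points", call. = FALSE)
    admissible <- which(keep)
  }
  with_seed(rng_seed, {
    # area-weighted sample points: random micro-triangle centroids
    pick <- admissible[sample.int(length(admissible), k_samples,
                                  replace = TRUE,
                                  prob = mm$areas[admissible])]
    acc <- numeric(length(r_grid))
    for (s in seq_len(k_samples)) {
      x <- mm$centroids[pick[s], ]
      Ni <- mm$normals[pick[s], ]
      d <- sqrt(colSums((t(mm$centroids) - x)^2))
      w <- mesh$mu * mm$areas * as.vector(mm$normals %*% Ni)
      ord <- findInterval(d, r_grid)                 # 0 .. n_r+1
      keep <- ord <= n_r
      nu <- cumsum(unname(tapply(w[keep], factor(ord[keep],
                                                 levels = 0:n_r), sum,
                                 default = 0)))
      acc <- acc + nu
    }
    nu_bar <- acc / k_samples
    # subtract the self term (the sampled neuron itself is not a pair)
    g <- kernel$rho_max * exp(-((r_grid[-1] + r_grid[-length(r_grid)]) / 2)^2 /
                                kernel$sigma2)
    rho_bar <- sum(g * diff(nu_bar)) / (N - 1)
    list(rho_bar = rho_bar,
         nu_bar = data.frame(r = r_grid, nu = nu_bar), N = N)
  })
}

#' Total ensemble EEG power
#'
#' `sigma_N^2 = N sigma_0^2 + N (N - 1) rho_bar sigma_0^2`: the mean power
#' of the sum of N signals of mean power `sigma_0^2` and mean pairwise
#' correlation `rho_bar`.
#'
#' @param N neuron count (default 16e9, the human cortex).
#' @param sigma0_sq mean single-neuron EEG power, uV^2.
#' @param rho_bar mean pairwise correlation, `|rho_bar| <= 1`.
#' @return total power, uV^2.
#' @export
ensemble_power <- function(N = 16e9, sigma0_sq, rho_bar = 0) {
  stopifnot(N >= 1, sigma0_sq >= 0, abs(rho_bar) <= 1)
  N * sigma0_sq + N * (N - 1) * rho_bar * sigma0_sq
}
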