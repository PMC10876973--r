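# Spherical embedding of a presynaptic population by spike-train
# correlation, optimality-index perturbation, and synapse assignment:
# the machinery that maps correlated presynaptic activity onto geometrically
# aligned synapse positions, the prerequisite for dipole coherence.

#' Embed a correlated population on the unit sphere
#'
#' Projects units onto the sphere so that strongly correlated pairs sit at
#' small angular distances. The embedding contract is checked rather than a
#' particular algorithm guaranteed: the Spearman rank correlation between
#' pairwise correlation and pairwise angular distance must be negative
#' (below -0.3 on typical inputs). The implementation uses classical
#' multidimensional scaling of `1 - corr` into three dimensions followed by
#' radial projection onto the sphere.
#'
#' @param corr symmetric correlation matrix with unit diagonal (e.g. an
#'   [sttc_matrix()]).
#' @param rng_seed seed (used only to resolve degenerate points at the
#'   origin); the embedding is deterministic given the seed.
#' @return object of class `sphere_embedding`: `points` (n x 3 unit vectors)
#'   and `contract_rho` (the achieved rank correlation).
#' @export
embed_on_sphere <- function(corr, rng_seed = NULL) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  n <- nrow(corr)
  d <- 1 - corr
  xy <- suppressWarnings(stats::cmdscale(d, k = 3))
  if (ncol(xy) < 3) xy <- cbind(xy, matrix(0, n, 3 - ncol(xy)))
  pts <- normalize_rows(xy, jitter_seed = rng_seed)
  emb <- structure(list(points = pts, contract_rho = NA_real_),
                   class = "sphere_embedding")
  emb$contract_rho <- embedding_contract_rho(emb, corr)
  emb
}

# Spearman rank correlation between source correlations and embedded
# angular distances (lower triangle).
embedding_contract_rho <- function(emb, corr) {
  ang <- angular_distance_matrix(emb$points)
  lt <- lower.tri(corr)
  suppressWarnings(stats::cor(corr[lt], ang[lt], method = "spearman"))
}

angular_distance_matrix <- function(pts) {
  g <- tcrossprod(pts)
  acos(pmin(pmax(g, -1), 1))
}

#' Perturb a spherical embedding by an optimality index
#'
#' Each point is displaced along a uniformly random great-circle bearing by
#' an angular distance `theta = arccos(1 - 2 alpha (1 - X))` with
#' `alpha ~ Uniform(0, 1)`. `X = 1` leaves the embedding untouched; `X = 0`
#' re-scatters the points uniformly over the sphere (the cosine of the
#' displacement is then uniform on `[-1, 1]`).
#'
#' @param emb a `sphere_embedding` (or any n x 3 matrix of unit vectors).
#' @param X optimality index in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return a `sphere_embedding` with perturbed points.
#' @export
perturb_embedding <- function(emb, X, rng_seed = NULL) {
  pts <- if (inherits(emb, "sphere_embedding")) emb$points else as.matrix(emb)
  stop_if_not_scalar(X, "X", lower = 0, upper = 1)
  if (X == 1)
    return(structure(list(points = pts, contract_rho = NA_real_),
                     class = "sphere_embedding"))
  n <- nrow(pts)
  with_seed(rng_seed, {
    alpha <- stats::runif(n)
    theta <- acos(pmin(pmax(1 - 2 * alpha * (1 - X), -1), 1))
    # random unit tangent at each point
    r <- runif_sphere(n)
    tang <- r - pts * rowSums(r * pts)
    tang <- normalize_rows(tang, jitter_seed = child_seed(rng_seed, 1))
    newp <- pts * cos(theta) + tang * sin(theta)
    structure(list(points = normalize_rows(newp), contract_rho = NA_real_),
              class = "sphere_embedding")
  })
}

#' Assign synapses to embedded presynaptic units
#'
#' Iterative greedy assignment: (1) a synapse (dendrite segment) is chosen
#' randomly with replacement with probability proportional to its weight
#' (surface-area proxy); (2) the presynaptic unit closest on the spherical
#' embedding is selected and the connection formed. The loop runs until
#' every synapse is mapped; ties in angular distance break to the lowest
#' unit index.
#'
#' @param emb a `sphere_embedding`.
#' @param layout a [synapse_layout()].
#' @param weights per-synapse selection weights (default equal).
#' @param rng_seed integer seed.
#' @return integer vector: presynaptic unit index per synapse.
#' @export
assign_synapses <- function(emb, layout, weights = NULL, rng_seed = NULL) {
  stopifnot(inherits(emb, "sphere_embedding"),
            inherits(layout, "synapse_layout"))
  if (nrow(emb$points) == 0) stop("empty embedding", call. = FALSE)
  n_syn <- nrow(layout$directions)
  if (is.null(weights)) weights <- rep(1, n_syn)
  stopifnot(length(weights) == n_syn, all(weights > 0))
  # nearest unit per synapse: maximal cosine, ties to the lowest index
  cosine <- tcrossprod(layout$directions, emb$points)
  nearest <- apply(cosine, 1, function(row) which(row >= max(row) - 1e-12)[1])
  mapping <- rep(NA_integer_, n_syn)
  with_seed(rng_seed, {
    remaining <- n_syn
    while (remaining > 0) {
      i <- sample.int(n_syn, 1, prob = weights)
      if (is.na(mapping[i])) {
        mapping[i] <- nearest[i]
        remaining <- remaining - 1
      }
    }
  })
  mapping
}
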