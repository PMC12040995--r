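# Per-host position indices: individual strength, normalized nested rank,
# the specialization index d', and eigenvector centrality on the unipartite
# projection of the host-parasite network.

#' Individual (species) strength of each host
#'
#' Strength of host i is the sum over parasite species of the dependency of
#' that species on the host, `sum_j a_ij / A_j`: a host's aggregate relevance
#' for the whole parasite community. Strengths over all hosts sum exactly to
#' the number of parasite species.
#'
#' @param mat interaction matrix (counts).
#' @return named numeric vector of strengths, one per host row.
#' @export
individual_strength <- function(mat) {
  mat <- interaction_matrix(mat)
  A_j <- colSums(mat)
  rowSums(sweep(unclass(mat), 2L, A_j, "/"))
}

#' Normalized nested rank of each host
#'
#' Rank of the host row in the matrix re-arranged for maximal nestedness,
#' normalized to [0, 1]: 0 = most generalist (first row of the nested
#' arrangement), 1 = most specialized. The arrangement orders hosts by
#' decreasing number of parasite species (binary degree), breaking ties by
#' decreasing total parasite count and then by input order, so ranks are
#' distinct and deterministic.
#'
#' @param mat interaction matrix.
#' @param method ordering used for the nested arrangement; only
#'   `"degree_sort"` is implemented.
#' @return named numeric vector of normalized ranks in [0, 1].
#' @export
nested_rank <- function(mat, method = c("degree_sort")) {
  method <- match.arg(method)
  mat <- interaction_matrix(mat)
  S <- nrow(mat)
  if (S < 2L) stop("nested rank is undefined for a single host", call. = FALSE)
  deg <- rowSums(mat > 0)
  tot <- rowSums(mat)
  ord <- order(-deg, -tot)  # stable: ties keep input order
  r <- integer(S)
  r[ord] <- seq_len(S)
  out <- (r - 1) / (S - 1)
  names(out) <- rownames(mat)
  out
}

#' Specialization index d' of each host
#'
#' Kullback-Leibler divergence of a host's interaction frequencies
#' `p_ij = a_ij / A_i` from the parasite marginal distribution
#' `q_j = A_j / m`, normalized by its range: `d'_i = d_i / ln(m / A_i)`,
#' clamped to [0, 1]. A host whose parasite counts are proportional to the
#' community marginals scores 0 (neutral configuration); a host
#' monopolizing one parasite's individuals scores towards 1. The
#' normalization uses the real-valued relaxation of the range (minimum 0,
#' maximum `ln(m / A_i)`); the integer-constrained extremes of the original
#' formulation are approximated from above, which an exhaustive-allocation
#' oracle bounds in the test suite.
#'
#' @param mat interaction matrix (counts).
#' @return named numeric vector of d' values in [0, 1].
#' @export
specialization_dprime <- function(mat) {
  mat <- interaction_matrix(mat)
  A_i <- rowSums(mat)
  A_j <- colSums(mat)
  m <- sum(mat)
  q <- A_j / m
  d <- vapply(seq_len(nrow(mat)), function(i) {
    a <- unclass(mat)[i, ]
    j <- a > 0
    p <- a[j] / A_i[i]
    sum(p * log(p / q[j]))
  }, numeric(1))
  dmax <- log(m / A_i)
  out <- ifelse(dmax <= 0, 0, d / dmax)
  out <- pmin(pmax(out, 0), 1)
  names(out) <- rownames(mat)
  out
}

#' Project a bipartite network to a unipartite host-host network
#'
#' Two hosts are linked when they share at least one parasite species.
#' Methods: `"sum"` (default) weights an edge by
#' `sum over shared species j of (a_gj + a_hj)`; `"binary"` by the number of
#' shared species; `"newman"` by `sum over shared j of 1 / (n_j - 1)` where
#' `n_j` is the number of hosts carrying species j (species carried by a
#' single host contribute nothing).
#'
#' @param mat interaction matrix.
#' @param method projection weighting.
#' @return symmetric hosts-by-hosts weight matrix with zero diagonal.
#' @export
project_unipartite <- function(mat, method = c("sum", "binary", "newman")) {
  method <- match.arg(method)
  # lighter validation than interaction_matrix: projection is well defined
  # even with unused (all-zero) parasite columns
  mat <- unclass(as.matrix(mat))
  if (!is.numeric(mat) || any(mat < 0) || nrow(mat) < 2L) {
    stop("need a non-negative matrix with at least 2 host rows", call. = FALSE)
  }
  B <- (mat > 0) * 1
  W <- switch(method,
    sum = mat %*% t(B) + B %*% t(mat),
    binary = B %*% t(B),
    newman = {
      nj <- colSums(B)
      w <- ifelse(nj > 1, 1 / (nj - 1), 0)
      B %*% (t(B) * w)
    }
  )
  diag(W) <- 0
  dimnames(W) <- list(rownames(mat), rownames(mat))
  W
}

#' Eigenvector centrality of a weighted undirected graph
#'
#' Principal eigenvector of the symmetric non-negative adjacency matrix,
#' computed by power iteration (uniform start, convergence tolerance 1e-12,
#' at most 10,000 iterations) and rescaled so the maximum centrality is 1.
#' On a disconnected graph, components not carrying the principal eigenvalue
#' decay to (numerically) zero centrality.
#'
#' @param W symmetric non-negative weight matrix (zero diagonal).
#' @param tol convergence tolerance on the normalized vector.
#' @param max_iter iteration cap.
#' @return named numeric vector with maximum 1.
#' @export
eigenvector_centrality <- function(W, tol = 1e-12, max_iter = 10000L) {
  W <- as.matrix(W)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    stop("projection matrix must be symmetric", call. = FALSE)
  }
  if (any(W < 0)) stop("projection weights must be non-negative", call. = FALSE)
  if (all(W == 0)) {
    stop(paste("all projection weights are zero: no two hosts share a",
               "parasite species, so eigenvector centrality is undefined;",
               "consider the binary projection or checking the input matrix"),
         call. = FALSE)
  }
  n <- nrow(W)
  # power-iterate on W + cI: same eigenvectors, but the principal
  # eigenvalue is strictly dominant even for bipartite-spectrum graphs
  shift <- max(rowSums(W))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(W %*% v) + shift * v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) break
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- pmax(v, 0)
  out <- v / max(v)
  names(out) <- rownames(W)
  out
}

#' Per-host position table for one network
#'
#' Assembles the four position indices (strength, normalized nested rank,
#' d', eigenvector centrality on the unipartite projection) with the host
#' metadata of a bundle.
#'
#' @param bundle a [network_bundle()].
#' @param projection projection method passed to [project_unipartite()].
#' @return data.frame with columns host_id, sex, strength, nested_rank,
#'   dprime, evcent.
#' @export
position_table <- function(bundle, projection = "sum") {
  stopifnot(inherits(bundle, "network_bundle"))
  mat <- bundle$matrix
  W <- project_unipartite(mat, method = projection)
  ev <- if (all(W == 0)) {
    warning("no shared parasites in ", bundle$id,
            ": eigenvector centrality set to NA")
    rep(NA_real_, nrow(mat))
  } else {
    eigenvector_centrality(W)
  }
  data.frame(
    host_id = bundle$hosts$host_id,
    sex = bundle$hosts$sex,
    strength = unname(individual_strength(mat)),
    nested_rank = unname(nested_rank(mat)),
    dprime = unname(specialization_dprime(mat)),
    evcent = unname(ev),
    stringsAsFactors = FALSE
  )
}
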