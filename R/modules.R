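# Weighted bipartite module detection (Barber modularity maximized by
# label propagation with restarts and greedy merging), within-module degree
# z and participation coefficient c, and role classification by per-network
# 95th-percentile thresholds.

barber_Q <- function(mat, row_lab, col_lab) {
  m <- sum(mat)
  labs <- union(row_lab, col_lab)
  q <- 0
  for (l in labs) {
    ri <- row_lab == l
    cj <- col_lab == l
    E <- if (any(ri) && any(cj)) sum(mat[ri, cj, drop = FALSE]) else 0
    R <- sum(rowSums(mat)[ri])
    C <- sum(colSums(mat)[cj])
    q <- q + E / m - (R * C) / m^2
  }
  q
}

#' Detect modules in a weighted bipartite network
#'
#' Maximizes Barber's bipartite modularity
#' `Q = (1/m) sum_ij (a_ij - A_i A_j / m) * delta(module_i, module_j)`
#' by weighted label propagation: each side repeatedly adopts the label with
#' the largest modularity contribution until Q stops improving, followed by
#' a greedy module-merging pass; the best partition over `n_restarts`
#' random initializations is returned. If no partition beats the
#' single-module baseline (Q = 0), the single module is returned, so the
#' reported Q is never negative.
#'
#' @param mat interaction matrix (counts; weights used directly).
#' @param seed RNG seed (restart initializations and tie-breaks are
#'   deterministic given the seed).
#' @param n_restarts number of random restarts.
#' @return object of class `module_partition`: list with `host_module` and
#'   `parasite_module` (named integer vectors), `Q`, `n_modules`, `seed`.
#' @export
detect_modules <- function(mat, seed = 1L, n_restarts = 10L) {
  mat <- unclass(as.matrix(mat))
  R <- nrow(mat)
  C <- ncol(mat)
  m <- sum(mat)
  Ai <- rowSums(mat)
  Aj <- colSums(mat)

  best_col_labels <- function(row_lab) {
    # score of assigning column j to row-label t:
    #   sum_{i: g_i = t} a_ij - A_j * (sum_{i: g_i = t} A_i) / m
    S <- rowsum(mat, row_lab)              # label x C sums
    At <- rowsum(Ai, row_lab)[, 1L]
    labs <- as.integer(rownames(S))
    score <- S - outer(At / m, Aj)         # label x C
    pick <- apply(score, 2L, which.max)
    labs[pick]
  }
  best_row_labels <- function(col_lab) {
    S <- t(rowsum(t(mat), col_lab))        # R x label
    At <- rowsum(Aj, col_lab)[, 1L]
    labs <- as.integer(colnames(S))
    score <- S - outer(Ai, At / m)
    pick <- apply(score, 1L, which.max)
    labs[pick]
  }
  greedy_merge <- function(row_lab, col_lab) {
    repeat {
      labs <- sort(union(row_lab, col_lab))
      k <- length(labs)
      if (k < 2L) break
      Rl <- vapply(labs, function(l) sum(Ai[row_lab == l]), numeric(1))
      Cl <- vapply(labs, function(l) sum(Aj[col_lab == l]), numeric(1))
      best_gain <- 1e-12
      best_pair <- NULL
      for (a in seq_len(k - 1L)) {
        for (b in seq(a + 1L, k)) {
          s <- labs[a]; t <- labs[b]
          cross <- sum(mat[row_lab == s, col_lab == t, drop = FALSE]) +
            sum(mat[row_lab == t, col_lab == s, drop = FALSE])
          gain <- cross / m - (Rl[a] * Cl[b] + Rl[b] * Cl[a]) / m^2
          if (gain > best_gain) {
            best_gain <- gain
            best_pair <- c(s, t)
          }
        }
      }
      if (is.null(best_pair)) break
      row_lab[row_lab == best_pair[2L]] <- best_pair[1L]
      col_lab[col_lab == best_pair[2L]] <- best_pair[1L]
    }
    list(row = row_lab, col = col_lab)
  }

  best <- list(Q = -Inf)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      row_lab <- sample.int(R)
      col_lab <- best_col_labels(row_lab)
      Q_old <- -Inf
      for (it in seq_len(200L)) {
        row_lab <- best_row_labels(col_lab)
        col_lab <- best_col_labels(row_lab)
        Q <- barber_Q(mat, row_lab, col_lab)
        if (Q <= Q_old + 1e-12) break
        Q_old <- Q
      }
      mg <- greedy_merge(row_lab, col_lab)
      Q <- barber_Q(mat, mg$row, mg$col)
      if (Q > best$Q) best <- list(Q = Q, row = mg$row, col = mg$col)
    }
  })

  if (best$Q < 0) {
    best <- list(Q = 0, row = rep(1L, R), col = rep(1L, C))
  }
  labs <- sort(union(best$row, best$col))
  host_module <- match(best$row, labs)
  parasite_module <- match(best$col, labs)
  names(host_module) <- rownames(mat)
  names(parasite_module) <- colnames(mat)
  structure(
    list(host_module = host_module, parasite_module = parasite_module,
         Q = best$Q, n_modules = length(labs), seed = as.integer(seed)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d module(s), Q = %.4f (seed %d)\n",
              x$n_modules, x$Q, x$seed))
  invisible(x)
}

#' Within-module degree z and participation coefficient c of hosts
#'
#' With binary degrees by default: `k_it` is the number of parasite species
#' of module t that host i carries; `z_i` standardizes the host's links into
#' its own module against the hosts of that module
#' (`z_i = (k_i,s(i) - mean) / sd`, 0 when the module's sd is 0); the
#' participation coefficient `c_i = 1 - sum_t (k_it / k_i)^2` measures how
#' evenly the host's links spread over modules.
#'
#' @param mat interaction matrix.
#' @param partition a [detect_modules()] result.
#' @param weighted use interaction counts instead of binary degrees.
#' @return list with numeric vectors `z` and `c` (named by host).
#' @export
cz_values <- function(mat, partition, weighted = FALSE) {
  mat <- unclass(as.matrix(mat))
  B <- if (weighted) mat else (mat > 0) * 1
  cmod <- partition$parasite_module
  hmod <- partition$host_module
  stopifnot(length(cmod) == ncol(mat), length(hmod) == nrow(mat))
  mods <- sort(unique(c(hmod, cmod)))
  # k[i, t]: links of host i into module t
  K <- vapply(mods, function(t) {
    sel <- cmod == t
    if (!any(sel)) return(numeric(nrow(B)))
    rowSums(B[, sel, drop = FALSE])
  }, numeric(nrow(B)))
  K <- matrix(K, nrow = nrow(B))
  ki <- rowSums(K)
  cc <- 1 - rowSums((K / ki)^2)
  k_own <- K[cbind(seq_len(nrow(B)), match(hmod, mods))]
  z <- numeric(nrow(B))
  for (s in unique(hmod)) {
    idx <- hmod == s
    mu <- mean(k_own[idx])
    sdev <- stats::sd(k_own[idx])
    z[idx] <- if (is.na(sdev) || sdev == 0) 0 else (k_own[idx] - mu) / sdev
  }
  names(z) <- rownames(mat)
  names(cc) <- rownames(mat)
  list(z = z, c = cc)
}

#' Classify host roles from z and c
#'
#' Thresholds are the empirical 95th percentiles (linear interpolation) of
#' the network's own z and c distributions, computed separately per network
#' and pooled over all hosts; "high" means strictly greater than the
#' threshold. Roles: low z / low c = peripheral; low z / high c =
#' connector; high z / low c = module hub; high z / high c = network hub.
#' Classic fixed thresholds (z = 2.5, c = 0.62) can be supplied instead via
#' `z_crit` / `c_crit`.
#'
#' @param z,c numeric vectors from [cz_values()].
#' @param prob percentile level (default 95).
#' @param z_crit,c_crit optional fixed thresholds overriding the percentile
#'   rule.
#' @return data.frame with host_id, z, c, role; thresholds attached as
#'   attributes `z_crit`, `c_crit`.
#' @export
classify_roles <- function(z, c, prob = 95, z_crit = NULL, c_crit = NULL) {
  stopifnot(length(z) == length(c), length(z) >= 1L)
  if (is.null(z_crit)) z_crit <- percentile(z, prob / 100)
  if (is.null(c_crit)) c_crit <- percentile(c, prob / 100)
  hi_z <- z > z_crit
  hi_c <- c > c_crit
  role <- ifelse(hi_z & hi_c, "network_hub",
          ifelse(hi_z, "module_hub",
          ifelse(hi_c, "connector", "peripheral")))
  out <- data.frame(
    host_id = names(z) %||% as.character(seq_along(z)),
    z = unname(z), c = unname(c), role = role,
    stringsAsFactors = FALSE
  )
  attr(out, "z_crit") <- z_crit
  attr(out, "c_crit") <- c_crit
  out
}

#' Per-sex proportions of hosts in each network role
#'
#' @param role_table a [classify_roles()] data.frame.
#' @param hosts host metadata with `host_id` and `sex`.
#' @return data.frame with sex, role, n, proportion; proportions sum to 1
#'   within each sex (all four roles always present).
#' @export
role_proportions_by_sex <- function(role_table, hosts) {
  sex <- hosts$sex[match(role_table$host_id, hosts$host_id)]
  if (anyNA(sex)) stop("role table hosts missing from metadata", call. = FALSE)
  roles <- c("peripheral", "connector", "module_hub", "network_hub")
  out <- expand.grid(sex = sort(unique(sex)), role = roles,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$n <- mapply(function(s, r) sum(sex == s & role_table$role == r),
                  out$sex, out$role)
  tot <- tapply(out$n, out$sex, sum)
  out$proportion <- out$n / as.numeric(tot[out$sex])
  rownames(out) <- NULL
  out
}
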