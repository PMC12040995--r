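# Within-network female-male comparisons: negative-binomial and Poisson
# infestation models, distance-based MANOVA on the four position indices,
# and univariate permutation ANOVAs. Permutation p-values use the
# (1 + b) / (1 + nperm) convention. No multiplicity adjustment is applied
# anywhere in the package.

sex_factor <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F'/'M'", call. = FALSE)
  factor(sex, levels = c("F", "M"))
}

check_two_sexes <- function(sex, min_n = 2L) {
  tab <- table(sex_factor(sex))
  if (length(tab) != 2L || any(tab < min_n)) {
    stop("need at least ", min_n, " hosts of each sex", call. = FALSE)
  }
}

group_summary <- function(values, sex) {
  f <- mean_se(values[sex == "F"])
  m <- mean_se(values[sex == "M"])
  c(mean_F = unname(f["mean"]), se_F = unname(f["se"]),
    mean_M = unname(m["mean"]), se_M = unname(m["se"]))
}

new_sex_test <- function(test, statistic, p, index = NA_character_,
                         nperm = NA_integer_, group_means = NULL, extra = list()) {
  out <- c(list(test = test, index = index, statistic = statistic, p = p,
                nperm = nperm, group_means = group_means), extra)
  class(out) <- "sex_test_result"
  out
}

#' @export
print.sex_test_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g%s\n",
              x$test, if (is.na(x$index)) "" else paste0(" [", x$index, "]"),
              x$statistic, x$p,
              if (is.na(x$nperm)) "" else sprintf(" (%d permutations)", x$nperm)))
  invisible(x)
}

#' Negative-binomial regression of parasite counts on host sex
#'
#' NB2 log-link maximum-likelihood fit of per-host total parasite counts on
#' sex (dispersion estimated by ML); reports the Wald z and p for the sex
#' (male vs female) coefficient.
#'
#' @param counts per-host total parasite counts (non-negative integers).
#' @param sex per-host sex ("F"/"M").
#' @return `sex_test_result` with `statistic` = Wald z, plus `coef` (log
#'   mean ratio M/F) and `theta` (dispersion) in the result.
#' @export
nb_regression_counts <- function(counts, sex) {
  if (!is_count_vector(counts)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  sex <- sex_factor(sex)
  check_two_sexes(sex)
  gm <- group_summary(counts, sex)
  if (length(unique(counts)) == 1L) {
    # degenerate: no variation, the sex effect is exactly zero
    return(new_sex_test("nb_counts", statistic = 0, p = 1,
                        group_means = gm,
                        extra = list(coef = 0, theta = Inf)))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ sex)),
    error = function(e) {
      stop("negative-binomial fit failed to converge: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  sm <- summary(fit)$coefficients
  new_sex_test("nb_counts", statistic = sm["sexM", "z value"],
               p = sm["sexM", "Pr(>|z|)"], group_means = gm,
               extra = list(coef = sm["sexM", "Estimate"], theta = fit$theta))
}

#' Poisson regression of parasite species richness on host sex
#'
#' @param richness per-host parasite species counts.
#' @param sex per-host sex ("F"/"M").
#' @return `sex_test_result` with the Wald z for the sex coefficient.
#' @export
poisson_richness <- function(richness, sex) {
  if (!is_count_vector(richness)) {
    stop("richness must be non-negative integers", call. = FALSE)
  }
  sex <- sex_factor(sex)
  check_two_sexes(sex)
  gm <- group_summary(richness, sex)
  if (length(unique(richness)) == 1L) {
    return(new_sex_test("pois_richness", statistic = 0, p = 1,
                        group_means = gm, extra = list(coef = 0)))
  }
  fit <- stats::glm(richness ~ sex, family = stats::poisson())
  sm <- summary(fit)$coefficients
  new_sex_test("pois_richness", statistic = sm["sexM", "z value"],
               p = sm["sexM", "Pr(>|z|)"], group_means = gm,
               extra = list(coef = sm["sexM", "Estimate"]))
}

# squared Euclidean distances between rows
dist2 <- function(X) {
  D <- as.matrix(stats::dist(X))
  D^2
}

#' Distance-based MANOVA (PERMANOVA) of position indices on host sex
#'
#' One-way distance-based decomposition on the Euclidean (Pythagorean)
#' distance matrix of the (optionally standardized) index columns:
#' `SST = (1/N) sum_{i<j} d_ij^2`,
#' `SSW = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo-F = ((SST - SSW)/(g - 1)) / (SSW/(N - g))`; the p-value comes
#' from `nperm` random permutations of the sex labels, with
#' `p = (1 + #{F* >= F}) / (1 + nperm)`.
#'
#' @param X hosts-by-indices numeric matrix (e.g. the four position
#'   indices); a single column gives the classical univariate ANOVA F.
#' @param sex per-host sex ("F"/"M").
#' @param nperm number of label permutations (default 10000).
#' @param standardize center and scale the columns to unit variance before
#'   computing distances (default TRUE; zero-variance columns are dropped
#'   from the distance with a warning).
#' @param seed RNG seed for the permutations.
#' @return `sex_test_result` with `statistic` = pseudo-F.
#' @export
db_manova <- function(X, sex, nperm = 10000L, standardize = TRUE, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("index columns must be finite", call. = FALSE)
  sex <- sex_factor(sex)
  check_two_sexes(sex)
  v <- apply(X, 2L, stats::var)
  if (all(v == 0)) stop("zero total variance in the index columns", call. = FALSE)
  if (standardize) {
    if (any(v == 0)) {
      warning("dropping zero-variance column(s) before standardization")
      X <- X[, v > 0, drop = FALSE]
    }
    X <- scale(X)
  }
  D2 <- dist2(X)
  N <- nrow(X)
  u <- as.numeric(sex == "F")
  nF <- sum(u)
  nM <- N - nF
  T2 <- sum(D2)                      # = 2 * sum_{i<j} d^2
  SST <- T2 / (2 * N)
  ssw_of <- function(uvec) {
    qF <- drop(crossprod(uvec, D2 %*% uvec))
    qM <- T2 - 2 * sum(D2 %*% uvec) + qF
    qF / (2 * nF) + qM / (2 * nM)
  }
  SSW <- ssw_of(u)
  g <- 2L
  Fobs <- ((SST - SSW) / (g - 1)) / (SSW / (N - g))
  Fperm <- with_seed(seed, {
    U <- vapply(seq_len(nperm), function(b) {
      uu <- numeric(N)
      uu[sample.int(N, nF)] <- 1
      uu
    }, numeric(N))
    DU <- D2 %*% U
    qF <- colSums(U * DU)
    qM <- T2 - 2 * colSums(DU) + qF
    SSWp <- qF / (2 * nF) + qM / (2 * nM)
    ((SST - SSWp) / (g - 1)) / (SSWp / (N - g))
  })
  p <- (1 + sum(Fperm >= Fobs)) / (1 + nperm)
  new_sex_test("db_manova", statistic = Fobs, p = p,
               nperm = as.integer(nperm))
}

#' Univariate permutation ANOVA of one index on host sex
#'
#' Observed one-way ANOVA F with a null distribution from full
#' randomization of the sex labels (equivalent, for this one-factor design,
#' to residual randomization under the intercept-only reduced model);
#' `p = (1 + #{F* >= F}) / (1 + nperm)`. Per-sex means and standard errors
#' are reported alongside.
#'
#' @param values numeric index values per host.
#' @param sex per-host sex ("F"/"M").
#' @param nperm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param index optional index name carried into the result.
#' @return `sex_test_result` with `statistic` = F.
#' @export
perm_anova_univariate <- function(values, sex, nperm = 10000L, seed = 1L,
                                  index = NA_character_) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  sex <- sex_factor(sex)
  check_two_sexes(sex)
  if (stats::var(values) == 0) {
    stop("values are constant: the ANOVA F is undefined", call. = FALSE)
  }
  N <- length(values)
  nF <- sum(sex == "F")
  nM <- N - nF
  gmean <- mean(values)
  SST <- sum((values - gmean)^2)
  f_from_sumF <- function(sF) {
    mF <- sF / nF
    mM <- (sum(values) - sF) / nM
    SSB <- nF * (mF - gmean)^2 + nM * (mM - gmean)^2
    SSW <- SST - SSB
    (SSB / 1) / (SSW / (N - 2))
  }
  Fobs <- f_from_sumF(sum(values[sex == "F"]))
  Fperm <- with_seed(seed, {
    vapply(seq_len(nperm), function(b) {
      f_from_sumF(sum(values[sample.int(N, nF)]))
    }, numeric(1))
  })
  p <- (1 + sum(Fperm >= Fobs)) / (1 + nperm)
  new_sex_test("perm_anova", statistic = Fobs, p = p, index = index,
               nperm = as.integer(nperm),
               group_means = group_summary(values, sex))
}

#' All within-network sex comparisons for one bundle
#'
#' Runs the negative-binomial count model, the Poisson richness model, the
#' distance-based MANOVA on the four position indices, and a univariate
#' permutation ANOVA per index.
#'
#' @param bundle a [network_bundle()].
#' @param positions its [position_table()] (computed if missing).
#' @param nperm permutations for the MANOVA / ANOVAs.
#' @param standardize passed to [db_manova()].
#' @param seed RNG seed.
#' @return data.frame with one row per test: test, index, statistic, p,
#'   mean_F, se_F, mean_M, se_M.
#' @export
sex_tests_for_bundle <- function(bundle, positions = NULL, nperm = 10000L,
                                 standardize = TRUE, seed = 1L) {
  if (is.null(positions)) positions <- position_table(bundle)
  sex <- bundle$hosts$sex
  counts <- rowSums(bundle$matrix)
  richness <- rowSums(bundle$matrix > 0)
  idx_cols <- c("nested_rank", "dprime", "strength", "evcent")
  res <- list(
    nb_regression_counts(counts, sex),
    poisson_richness(richness, sex),
    db_manova(as.matrix(positions[idx_cols]), sex, nperm = nperm,
              standardize = standardize, seed = seed)
  )
  for (k in seq_along(idx_cols)) {
    res[[length(res) + 1L]] <- perm_anova_univariate(
      positions[[idx_cols[k]]], sex, nperm = nperm,
      seed = derive_seed(seed, k), index = idx_cols[k]
    )
  }
  rows <- lapply(res, function(r) {
    gm <- r$group_means %||% rep(NA_real_, 4L)
    data.frame(test = r$test, index = r$index, statistic = r$statistic,
               p = r$p, mean_F = gm[[1]], se_F = gm[[2]],
               mean_M = gm[[3]], se_M = gm[[4]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
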