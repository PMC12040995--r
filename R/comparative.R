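# Across-network inference: log mean-ratio sex-difference predictors, beta
# GLMMs on role proportions, and Brownian-motion PGLS with all-subsets AIC
# model selection against a host phylogeny.

#' Sex-difference predictor from per-sex index means
#'
#' Natural logarithm of the larger of the male-to-female and
#' female-to-male mean ratios: always non-negative, zero when the means are
#' equal, and symmetric in its arguments.
#'
#' @param mean_f,mean_m strictly positive per-sex means of an index.
#' @return `ln(max(mean_m / mean_f, mean_f / mean_m))`.
#' @export
sex_difference_predictor <- function(mean_f, mean_m) {
  if (any(!is.finite(c(mean_f, mean_m))) || any(c(mean_f, mean_m) <= 0)) {
    stop(paste("per-sex means must be strictly positive for the log mean",
               "ratio; consider offsetting the index if it can reach 0"),
         call. = FALSE)
  }
  abs(log(mean_m / mean_f))
}

#' Read a phylogenetic tree from a Newick file
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree with unique tip labels.
#' @export
read_newick <- function(path) {
  # ape warns (and returns NULL) on some malformed input instead of
  # erroring; both routes are turned into one parse error here
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) {
    stop("failed to parse Newick file '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (is.null(tree)) stop("failed to parse Newick file '", path, "'", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels must be unique", call. = FALSE)
  }
  tree
}

#' Brownian-motion covariance matrix from a tree
#'
#' `C_ij` is the shared root-to-tip path length of tips i and j; the
#' diagonal holds root-to-tip distances. With `unit_branches = TRUE` every
#' edge length is set to 1 first (the convention used when sister tips are
#' inserted for species occurring in two regions). Non-ultrametric trees
#' are flagged with a warning only.
#'
#' @param tree an `ape::phylo` tree with branch lengths (or none, if
#'   `unit_branches`).
#' @param unit_branches set all edge lengths to 1 before computing C.
#' @return list with `tips` (labels) and `C` (symmetric PSD matrix).
#' @export
phylo_covariance <- function(tree, unit_branches = FALSE) {
  if (unit_branches || is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  C <- ape::vcv(tree)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) {
    stop("phylogenetic covariance is not positive semi-definite", call. = FALSE)
  }
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("tree is not ultrametric; Brownian covariance diagonals differ")
  }
  list(tips = rownames(C), C = C)
}

#' Split a tip into a unit-length cherry
#'
#' Replaces one tip by a cherry of two unit-length tips, the device used to
#' enter the same host species from two regions as sister taxa.
#'
#' @param tree an `ape::phylo` tree.
#' @param tip tip label to split.
#' @param new_labels two labels for the daughter tips.
#' @return the modified tree.
#' @export
tip_to_cherry <- function(tree, tip, new_labels) {
  stopifnot(length(new_labels) == 2L)
  where <- which(tree$tip.label == tip)
  if (!length(where)) stop("tip '", tip, "' not found", call. = FALSE)
  cherry <- ape::read.tree(text = sprintf("(%s:1,%s:1);", new_labels[1L],
                                          new_labels[2L]))
  ape::bind.tree(tree, cherry, where = where)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `y ~ N(X beta, sigma^2 C)` by GLS:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, with the ML variance
#' `sigma^2 = RSS_gls / n`, the exact multivariate-normal log-likelihood,
#' and `AIC = -2 logL + 2 (p + 2)` (p slopes, counting the intercept and
#' sigma^2). R^2 is `1 - RSS_gls / TSS_gls` against the GLS intercept-only
#' model, and the whole-model F tests all slopes jointly.
#'
#' @param y response vector (one value per tip-aligned row).
#' @param X data.frame/matrix of predictor columns (no intercept column; an
#'   intercept is added). May have zero columns for the intercept-only model.
#' @param C phylogenetic covariance matrix aligned to `y` (or a
#'   [phylo_covariance()] result).
#' @return object of class `pgls_fit`: coefficients with se/t/p, `sigma2`,
#'   `logLik`, `AIC`, `r_squared`, `F`, `p_model`, `n`, `df_residual`.
#' @export
pgls_fit <- function(y, X, C) {
  if (is.list(C) && !is.matrix(C)) C <- C$C
  y <- as.numeric(y)
  n <- length(y)
  Xm <- if (is.null(X) || (is.data.frame(X) && ncol(X) == 0L)) {
    matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    as.matrix(X)
  }
  p <- ncol(Xm)
  Xd <- cbind(`(Intercept)` = 1, Xm)
  if (n <= p + 1L) stop("need n > p + 1 observations", call. = FALSE)
  if (qr(Xd)$rank < ncol(Xd)) {
    stop("collinear predictors: ", paste(colnames(Xd), collapse = ", "),
         call. = FALSE)
  }
  U <- tryCatch(chol(C), error = function(e) {
    stop(paste("singular phylogenetic covariance; consider jittering",
               "zero-length branches"), call. = FALSE)
  })
  # whiten: solve U' w = v
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, Xd, transpose = TRUE)
  colnames(wX) <- colnames(Xd)
  fit <- stats::lm.fit(wX, wy)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(U)))
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  aic <- -2 * logL + 2 * (p + 2)
  # intercept-only reference for R^2 and the whole-model F
  w1 <- backsolve(U, rep(1, n), transpose = TRUE)
  fit0 <- stats::lm.fit(matrix(w1, ncol = 1L), wy)
  tss <- sum(fit0$residuals^2)
  df_res <- n - p - 1L
  sigma2_resid <- rss / df_res
  XtX_inv <- chol2inv(chol(crossprod(wX)))
  se <- sqrt(diag(XtX_inv) * sigma2_resid)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  if (p > 0L) {
    Fmod <- ((tss - rss) / p) / (rss / df_res)
    p_model <- stats::pf(Fmod, p, df_res, lower.tail = FALSE)
    r2 <- 1 - rss / tss
  } else {
    Fmod <- NA_real_
    p_model <- NA_real_
    r2 <- 0
  }
  structure(list(
    coefficients = beta, se = se, t = tval, p_coef = pval,
    sigma2 = sigma2_ml, logLik = logL, AIC = aic, r_squared = r2,
    F = Fmod, p_model = p_model, n = n, df_residual = df_res,
    predictors = colnames(Xm) %||% character(0)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d): logLik = %.3f, AIC = %.3f, R2 = %.3f\n",
              x$n, x$logLik, x$AIC, x$r_squared))
  tab <- cbind(Estimate = x$coefficients, SE = x$se, t = x$t, p = x$p_coef)
  print(round(tab, 4))
  if (!is.na(x$F)) {
    cat(sprintf("whole-model F = %.3f, p = %.4g\n", x$F, x$p_model))
  }
  invisible(x)
}

#' All-subsets PGLS with AIC selection
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model), ranks them by AIC, and returns the minimum-AIC
#' fit; ties are broken in favour of fewer predictors, then
#' lexicographically.
#'
#' @param y response vector.
#' @param predictors data.frame of candidate predictor columns (typically
#'   dNR, dSS, dEC, dDP).
#' @param C phylogenetic covariance aligned to `y`.
#' @return list with `ranking` (data.frame: subset, k, logLik, AIC, dAIC)
#'   and `best` (the winning [pgls_fit()]).
#' @export
all_subsets_pgls <- function(y, predictors, C) {
  predictors <- as.data.frame(predictors)
  vars <- names(predictors)
  if (!length(vars)) stop("need at least one candidate predictor", call. = FALSE)
  subsets <- list(character(0))
  for (k in seq_along(vars)) {
    subsets <- c(subsets, utils::combn(vars, k, simplify = FALSE))
  }
  fits <- lapply(subsets, function(s) {
    pgls_fit(y, predictors[s], C)
  })
  lab <- vapply(subsets, function(s) {
    if (!length(s)) "(intercept)" else paste(s, collapse = " + ")
  }, character(1))
  ranking <- data.frame(
    subset = lab,
    k = lengths(subsets),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE
  )
  ord <- order(ranking$AIC, ranking$k, ranking$subset)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$dAIC <- ranking$AIC - ranking$AIC[1L]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = fits[[ord[1L]]],
       best_subset = subsets[[ord[1L]]])
}

#' Beta GLMM of role proportions on sex with a species random intercept
#'
#' Proportions are nudged off the boundary by exactly +/- `adjust` (added
#' to 0s, subtracted from 1s) and modelled with a logit-link beta
#' likelihood, constant precision phi, and a Gaussian species random
#' intercept, fitted by Laplace-approximate ML (glmmTMB). If the random
#' intercept collapses to zero variance the model is refitted as
#' fixed-effects beta regression and flagged.
#'
#' @param data data.frame with columns `proportion`, `sex`, `species`, and
#'   (if `include_role`) `role`.
#' @param include_role add `role` as a fixed effect (pooling the four
#'   roles) rather than modelling one role's proportions alone.
#' @param adjust boundary adjustment (default 1e-7).
#' @return list with `coef` (sex effect on the logit scale), `z`, `p`,
#'   `phi`, `sigma_b`, `logLik`, `collapsed` (logical), and the fitted
#'   model object.
#' @export
beta_glmm_roles <- function(data, include_role = FALSE, adjust = 1e-7) {
  stopifnot(all(c("proportion", "sex", "species") %in% names(data)))
  if (length(unique(data$species)) < 2L) {
    stop("need at least 2 species for the random intercept", call. = FALSE)
  }
  y <- data$proportion
  if (any(y < 0 | y > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  y[y == 0] <- adjust
  y[y == 1] <- 1 - adjust
  df <- data
  df$y <- y
  df$sex <- sex_factor(df$sex)
  form <- if (include_role) y ~ sex + role + (1 | species) else y ~ sex + (1 | species)
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(form, data = df,
                                      family = glmmTMB::beta_family())),
    error = function(e) stop("beta GLMM failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  vc <- glmmTMB::VarCorr(fit)$cond$species
  sigma_b <- sqrt(as.numeric(vc[1L, 1L]))
  collapsed <- FALSE
  if (!is.finite(sigma_b) || sigma_b < 1e-4) {
    form0 <- if (include_role) y ~ sex + role else y ~ sex
    fit <- suppressWarnings(glmmTMB::glmmTMB(form0, data = df,
                                             family = glmmTMB::beta_family()))
    sigma_b <- 0
    collapsed <- TRUE
  }
  sm <- summary(fit)$coefficients$cond
  list(coef = sm["sexM", "Estimate"], z = sm["sexM", "z value"],
       p = sm["sexM", "Pr(>|z|)"], phi = stats::sigma(fit),
       sigma_b = sigma_b, logLik = as.numeric(stats::logLik(fit)),
       collapsed = collapsed, fit = fit)
}

#' Assemble the comparative table linking sex differences to structure
#'
#' One row per network: the four log mean-ratio predictors (dNR for nested
#' rank, dSS for strength, dEC for eigenvector centrality, dDP for d') and
#' the structure responses (Z-standardized NODF and H2' by default, raw
#' values optionally). Indices whose per-sex mean is zero yield NA
#' predictors with a warning (the log ratio is undefined there).
#'
#' @param bundles list of network bundles.
#' @param positions list of matching [position_table()] data.frames.
#' @param structures list of matching [structure_with_nulls()] results.
#' @param response_scale `"zscore"` (default) or `"raw"`.
#' @return data.frame with id, species, region, parasite_group, tip, dNR,
#'   dSS, dEC, dDP, nodf, h2.
#' @export
comparative_table <- function(bundles, positions, structures,
                              response_scale = c("zscore", "raw")) {
  response_scale <- match.arg(response_scale)
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    pos <- positions[[i]]
    st <- structures[[i]]
    sx <- pos$sex
    pred <- function(col) {
      mf <- mean(pos[[col]][sx == "F"])
      mm <- mean(pos[[col]][sx == "M"])
      if (!is.finite(mf) || !is.finite(mm) || mf <= 0 || mm <= 0) {
        warning("zero or non-finite per-sex mean of ", col, " in ", b$id,
                ": predictor set to NA")
        return(NA_real_)
      }
      sex_difference_predictor(mf, mm)
    }
    data.frame(
      id = b$id,
      species = b$hosts$species[1L],
      region = b$hosts$region[1L],
      parasite_group = b$parasite_group,
      tip = paste(gsub(" ", "_", b$hosts$species[1L]), b$hosts$region[1L],
                  sep = "_"),
      dNR = pred("nested_rank"),
      dSS = pred("strength"),
      dEC = pred("evcent"),
      dDP = pred("dprime"),
      nodf = if (response_scale == "zscore") st$z_nodf else st$nodf_raw,
      h2 = if (response_scale == "zscore") st$z_h2 else st$h2_raw,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
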