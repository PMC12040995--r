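test_that("sex-difference predictor is a symmetric log mean ratio", {
  expect_equal(sex_difference_predictor(0.4, 0.4), 0)
  expect_equal(sex_difference_predictor(0.2, 0.4), log(2))
  expect_equal(sex_difference_predictor(0.4, 0.2), log(2))
  expect_error(sex_difference_predictor(0, 0.4), "positive")
  set.seed(115)
  for (k in 1:50) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5)
    expect_equal(sex_difference_predictor(a, b),
                 sex_difference_predictor(b, a))
    expect_gte(sex_difference_predictor(a, b), 0)
  }
})

test_that("phylogenetic covariance matches path arithmetic", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  pc <- phylo_covariance(star)
  expect_equal(unname(pc$C), diag(3))
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # unit branches make this tree non-ultrametric, which is flagged
  expect_warning(pc <- phylo_covariance(tr, unit_branches = TRUE),
                 "ultrametric")
  expect_equal(pc$C["A", "B"], 1)
  expect_equal(pc$C["A", "C"], 0)
  expect_equal(unname(diag(pc$C)), c(2, 2, 1))
  # non-ultrametric branch lengths only warn
  expect_warning(phylo_covariance(ape::read.tree(text = "((A:1,B:3):1,C:2);")),
                 "ultrametric")
})

test_that("newick reading validates input and cherry splitting works", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  writeLines("((A:1,B:1", path)
  expect_error(read_newick(path), "parse")
  tr2 <- tip_to_cherry(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
                       "A", c("A_x", "A_y"))
  expect_true(all(c("A_x", "A_y", "B", "C") %in% tr2$tip.label))
  pc <- suppressWarnings(phylo_covariance(tr2, unit_branches = TRUE))
  # the new sisters share all but their terminal unit branches
  expect_equal(pc$C["A_x", "A_y"], pc$C["A_x", "A_x"] - 1)
})

test_that("PGLS with identity covariance reproduces OLS exactly", {
  set.seed(125)
  n <- 25L
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X$a + rnorm(n)
  f <- pgls_fit(y, X, diag(n))
  ols <- stats::lm(y ~ a + b, data = X)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(f$logLik, as.numeric(stats::logLik(ols)), tolerance = 1e-8)
  # exact linear response: perfect fit
  f2 <- pgls_fit(1 + 3 * X$a, X["a"], diag(n))
  expect_equal(f2$r_squared, 1)
  expect_lt(abs(f2$sigma2), 1e-20)
  expect_error(pgls_fit(y, data.frame(a = X$a, a2 = X$a), diag(n)),
               "collinear")
})

test_that("PGLS agrees with the gls/corBrownian oracle on a real tree", {
  skip_if_not_installed("nlme")
  set.seed(135)
  tree <- ape::rphylo(20L, 1, 0)
  C <- ape::vcv(tree)
  x <- rnorm(20L)
  y <- drop(chol(C) %*% rnorm(20L)) + 0.5 * x
  names(y) <- names(x) <- rownames(C)
  f <- pgls_fit(y, data.frame(x = x), C)
  d <- data.frame(y = y, x = x, sp = rownames(C))
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(phy = tree, form = ~sp),
                   method = "ML")
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("all-subsets selection ranks by AIC with parsimony tie-breaks", {
  set.seed(145)
  n <- 30L
  X <- data.frame(a = rnorm(n))
  y <- rnorm(n) + 2 * X$a
  sel <- all_subsets_pgls(y, X, diag(n))
  expect_equal(nrow(sel$ranking), 2L)
  expect_equal(sel$best_subset, "a")
  X4 <- data.frame(dNR = rnorm(n), dSS = rnorm(n), dEC = rnorm(n),
                   dDP = rnorm(n))
  sel4 <- all_subsets_pgls(y2 <- rnorm(n), X4, diag(n))
  expect_equal(nrow(sel4$ranking), 16L)
  expect_equal(sel4$ranking$dAIC[1], 0)
  expect_true(!is.unsorted(sel4$ranking$AIC))
  # AIC ranking invariant to rescaling y (up to a constant shift)
  sel4b <- all_subsets_pgls(10 * y2, X4, diag(n))
  expect_equal(order(sel4$ranking$subset[order(sel4$ranking$AIC)]),
               order(sel4b$ranking$subset[order(sel4b$ranking$AIC)]))
})

test_that("null responses mostly select the intercept-only model", {
  set.seed(155)
  n <- 25L
  wins <- replicate(100, {
    X <- data.frame(dNR = rnorm(n), dSS = rnorm(n))
    sel <- all_subsets_pgls(rnorm(n), X, diag(n))
    length(sel$best_subset) == 0L
  })
  expect_gt(mean(wins), 0.5)
})

test_that("PGLS recovers a Brownian slope of 2", {
  set.seed(165)
  tree <- ape::rphylo(100L, 1, 0)
  C <- ape::vcv(tree)
  U <- chol(C)
  slopes <- replicate(100, {
    x <- rnorm(100L)
    y <- 2 * x + drop(t(U) %*% rnorm(100L))
    pgls_fit(y, data.frame(x = x), C)$coefficients[["x"]]
  })
  expect_lt(abs(mean(slopes) - 2), 0.05)
})

test_that("beta GLMM matches the fixed-effects ML oracle when variance collapses", {
  # proportions with no real species effect: the random intercept collapses
  # and the fit must equal plain beta-regression ML (own optimizer oracle)
  set.seed(175)
  nsp <- 12L
  df <- data.frame(
    species = rep(sprintf("sp%02d", 1:nsp), each = 2L),
    sex = rep(c("F", "M"), nsp),
    stringsAsFactors = FALSE
  )
  mu <- plogis(-1 + 0.6 * (df$sex == "M"))
  phi <- 25
  df$proportion <- rbeta(nrow(df), mu * phi, (1 - mu) * phi)
  fit <- beta_glmm_roles(df)
  # independent ML oracle for logit-link beta regression
  nll <- function(par) {
    eta <- par[1] + par[2] * (df$sex == "M")
    mu <- plogis(eta)
    ph <- exp(par[3])
    -sum(dbeta(df$proportion, mu * ph, (1 - mu) * ph, log = TRUE))
  }
  opt <- optim(c(0, 0, log(10)), nll, method = "BFGS")
  if (fit$collapsed) {
    expect_equal(fit$coef, opt$par[2], tolerance = 1e-4)
    expect_equal(log(fit$phi), opt$par[3], tolerance = 1e-3)
  } else {
    # near-zero variance: estimates still agree closely with fixed-effects ML
    expect_equal(fit$coef, opt$par[2], tolerance = 0.05)
  }
})

test_that("beta GLMM recovers a known sex shift and respects nesting", {
  set.seed(185)
  nsp <- 20L
  shifts <- replicate(60, {
    b <- rnorm(nsp, 0, 0.5)
    df <- data.frame(
      species = rep(sprintf("sp%02d", 1:nsp), each = 2L),
      sex = rep(c("F", "M"), nsp), stringsAsFactors = FALSE
    )
    mu <- plogis(-0.5 + 0.8 * (df$sex == "M") + rep(b, each = 2L))
    df$proportion <- rbeta(nrow(df), mu * 30, (1 - mu) * 30)
    beta_glmm_roles(df)$coef
  })
  expect_lt(abs(mean(shifts) - 0.8), 0.1)
  # identical proportions across sexes -> no effect
  df <- data.frame(species = rep(sprintf("sp%02d", 1:10), each = 2L),
                   sex = rep(c("F", "M"), 10),
                   proportion = rep(seq(0.2, 0.65, by = 0.05), each = 2L),
                   stringsAsFactors = FALSE)
  fit0 <- beta_glmm_roles(df)
  expect_lt(abs(fit0$coef), 1e-4)
  expect_gt(fit0$p, 0.95)
})

test_that("comparative table joins predictors and responses per network", {
  cfg <- simulation_config(n_species = 2L, hosts_per_sex = 21L,
                           regions = "Siberia", groups = "flea", seed = 19L)
  coll <- simulate_collection(cfg)
  pos <- lapply(coll$bundles, position_table)
  st <- lapply(seq_along(coll$bundles), function(i) {
    structure_with_nulls(coll$bundles[[i]], n_null = 20L, seed = i)
  })
  tab <- comparative_table(coll$bundles, pos, st)
  expect_equal(nrow(tab), length(coll$bundles))
  expect_true(all(tab$dNR >= 0, na.rm = TRUE))
  expect_true(all(c("dNR", "dSS", "dEC", "dDP", "nodf", "h2") %in% names(tab)))
  raw <- comparative_table(coll$bundles, pos, st, response_scale = "raw")
  expect_equal(raw$nodf, vapply(st, `[[`, numeric(1), "nodf_raw"))
})
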