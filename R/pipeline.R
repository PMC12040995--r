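# End-to-end orchestration: assemble networks (from files or the synthetic
# generator), compute per-host positions, null-standardized structure,
# module roles, within-network sex tests, and the across-network
# comparative models; write per-stage CSVs plus a JSON summary.

#' Pipeline configuration
#'
#' Defaults follow the survey-analysis conventions this pipeline encodes:
#' at least 20 parasitized individuals per sex, 1000 null matrices, 10,000
#' permutations, 95th-percentile role thresholds.
#'
#' @param records path to a long-format record CSV (ignored when
#'   `simulate` is given).
#' @param tree path to a Newick tree (optional; comparative stage is
#'   skipped without one).
#' @param simulate optional [simulation_config()]: generate the data
#'   instead of reading files.
#' @param min_per_sex cohort selection threshold (default 20).
#' @param n_null null matrices per network (default 1000).
#' @param nperm permutations for the MANOVA / ANOVAs (default 10000).
#' @param percentile role-threshold percentile (default 95).
#' @param standardize_db_manova standardize index columns before the
#'   distance (default TRUE).
#' @param response_scale `"zscore"` or `"raw"` structure responses for the
#'   comparative stage.
#' @param seed master seed; every per-network stream is derived from it.
#' @param outdir output directory (default: no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(records = NULL, tree = NULL, simulate = NULL,
                            min_per_sex = 20L, n_null = 1000L,
                            nperm = 10000L, percentile = 95,
                            standardize_db_manova = TRUE,
                            response_scale = c("zscore", "raw"),
                            seed = 1L, outdir = NULL) {
  response_scale <- match.arg(response_scale)
  cfg <- list(records = records, tree = tree, simulate = simulate,
              min_per_sex = as.integer(min_per_sex),
              n_null = as.integer(n_null), nperm = as.integer(nperm),
              percentile = percentile,
              standardize_db_manova = isTRUE(standardize_db_manova),
              response_scale = response_scale, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulate:`
#' block holds [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline
#'
#' Stages: network assembly -> position indices -> null-standardized
#' structure -> module roles -> within-network sex tests -> across-network
#' comparative models (role-proportion beta GLMM per parasite group,
#' all-subsets PGLS of each structure response on the four sex-difference
#' predictors). The comparative stage is skipped with a warning when no
#' tree is available. With `outdir` set, per-stage CSVs and a JSON summary
#' are written; reruns with the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return list with `bundles`, `positions`, `structures`, `roles`,
#'   `role_proportions`, `sex_tests`, `comparative` (or NULL), `tables`
#'   (Tables-1-to-5-shaped summaries), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- stage 1: data -------------------------------------------------------
  if (!is.null(config$simulate)) {
    log_stage("simulate", "generating synthetic collection")
    coll <- simulate_collection(config$simulate)
    recs <- NULL
    bundles <- coll$bundles
    tree <- coll$tree
    # the generator builds valid bundles directly, but the cohort rule is
    # still enforced so config$min_per_sex applies uniformly
    keepers <- vapply(bundles, function(b) {
      min(table(factor(b$hosts$sex, c("F", "M")))) >= config$min_per_sex
    }, logical(1))
    bundles <- bundles[keepers]
  } else {
    if (is.null(config$records)) stop("config needs records or simulate",
                                      call. = FALSE)
    log_stage("build", paste("reading", config$records))
    recs <- read_records(config$records)
    bundles <- build_networks(recs, min_per_sex = config$min_per_sex)
    tree <- if (!is.null(config$tree)) read_newick(config$tree) else NULL
  }
  if (!length(bundles)) stop("no network passed the cohort selection rule",
                             call. = FALSE)
  log_stage("build", sprintf("%d networks", length(bundles)))

  positions <- vector("list", length(bundles))
  structures <- vector("list", length(bundles))
  roles <- vector("list", length(bundles))
  partitions <- vector("list", length(bundles))
  props <- vector("list", length(bundles))
  sex_tests <- vector("list", length(bundles))

  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    sd_i <- derive_seed(config$seed, i)
    positions[[i]] <- position_table(b)
    structures[[i]] <- structure_with_nulls(b, n_null = config$n_null,
                                            seed = derive_seed(sd_i, 1L))
    part <- detect_modules(b$matrix, seed = derive_seed(sd_i, 2L))
    partitions[[i]] <- part
    cz <- cz_values(b$matrix, part)
    rt <- classify_roles(cz$z, cz$c, prob = config$percentile)
    crit <- c(attr(rt, "z_crit"), attr(rt, "c_crit"))
    rt <- data.frame(host_id = rt$host_id, sex = b$hosts$sex, z = rt$z,
                     c = rt$c, role = rt$role, stringsAsFactors = FALSE)
    attr(rt, "z_crit") <- crit[1L]
    attr(rt, "c_crit") <- crit[2L]
    roles[[i]] <- rt
    pr <- role_proportions_by_sex(rt, b$hosts)
    pr <- cbind(id = b$id, species = b$hosts$species[1L],
                region = b$hosts$region[1L],
                parasite_group = b$parasite_group, pr,
                stringsAsFactors = FALSE)
    props[[i]] <- pr
    st <- sex_tests_for_bundle(b, positions[[i]], nperm = config$nperm,
                               standardize = config$standardize_db_manova,
                               seed = derive_seed(sd_i, 3L))
    st <- cbind(id = b$id, species = b$hosts$species[1L],
                region = b$hosts$region[1L],
                parasite_group = b$parasite_group, st,
                stringsAsFactors = FALSE)
    sex_tests[[i]] <- st
    log_stage("network", sprintf("%s done (Q = %.3f)", b$id, part$Q))
  }
  sex_tests <- do.call(rbind, sex_tests)
  props <- do.call(rbind, props)

  # --- comparative stage ---------------------------------------------------
  comparative <- NULL
  if (is.null(tree)) {
    warning("no phylogenetic tree supplied: comparative stage skipped")
  } else {
    log_stage("comparative", "fitting beta GLMMs and PGLS models")
    comp_tab <- comparative_table(bundles, positions, structures,
                                  response_scale = config$response_scale)
    # species present in more than one region become unit-length sister
    # tips; all branch lengths are then set to 1
    sp_regions <- unique(comp_tab[c("species", "region")])
    wt <- tree
    for (sp in unique(sp_regions$species)) {
      tip <- gsub(" ", "_", sp)
      rgs <- sp_regions$region[sp_regions$species == sp]
      if (length(rgs) > 1L) {
        labs <- paste(tip, rgs[1:2], sep = "_")
        wt <- tip_to_cherry(wt, tip, labs)
        if (length(rgs) > 2L) {
          for (r in rgs[-(1:2)]) {
            wt <- tip_to_cherry(wt, labs[1L],
                                c(labs[1L], paste(tip, r, sep = "_")))
            wt$tip.label[wt$tip.label == labs[1L]] <- labs[1L]
          }
        }
      } else {
        wt$tip.label[wt$tip.label == tip] <- paste(tip, rgs, sep = "_")
      }
    }
    pc <- suppressWarnings(phylo_covariance(wt, unit_branches = TRUE))
    comparative <- list(table = comp_tab, glmm = list(), pgls = list())
    for (gp in unique(comp_tab$parasite_group)) {
      sub <- comp_tab[comp_tab$parasite_group == gp, , drop = FALSE]
      # beta GLMM on role proportions for this group
      psub <- props[props$parasite_group == gp, , drop = FALSE]
      comparative$glmm[[gp]] <- tryCatch(
        beta_glmm_roles(psub, include_role = TRUE),
        error = function(e) {
          warning("beta GLMM skipped for ", gp, ": ", conditionMessage(e))
          NULL
        }
      )
      ok <- stats::complete.cases(sub[c("dNR", "dSS", "dEC", "dDP")]) &
        is.finite(sub$nodf) & is.finite(sub$h2)
      sub <- sub[ok, , drop = FALSE]
      if (nrow(sub) < 7L) {
        warning("too few networks for PGLS in group ", gp)
        next
      }
      missing_tips <- setdiff(sub$tip, pc$tips)
      if (length(missing_tips)) {
        stop("species missing from the tree: ",
             paste(missing_tips, collapse = ", "), call. = FALSE)
      }
      Csub <- pc$C[sub$tip, sub$tip]
      preds <- sub[c("dNR", "dSS", "dEC", "dDP")]
      for (resp in c("nodf", "h2")) {
        comparative$pgls[[paste(gp, resp, sep = "_")]] <-
          all_subsets_pgls(sub[[resp]], preds, Csub)
      }
    }
    comparative$structure_correlation <- structure_correlation(
      comp_tab$nodf, comp_tab$h2
    )
  }

  tables <- summarize_tables(sex_tests, comparative)
  result <- list(bundles = bundles, positions = positions,
                 structures = structures, roles = roles,
                 partitions = partitions, role_proportions = props,
                 sex_tests = sex_tests, comparative = comparative,
                 tables = tables, config = config)
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  invisible(result)
}

# Tables shaped like the report tables: per-network db-MANOVA (1-2),
# per-index significant contrasts with means +/- SE (3-4), best PGLS
# models (5).
summarize_tables <- function(sex_tests, comparative) {
  t12 <- sex_tests[sex_tests$test == "db_manova",
                   c("parasite_group", "region", "species", "statistic", "p")]
  names(t12)[4L] <- "pseudo_F"
  rownames(t12) <- NULL
  t34 <- sex_tests[sex_tests$test == "perm_anova",
                   c("parasite_group", "region", "species", "index",
                     "mean_F", "se_F", "mean_M", "se_M", "statistic", "p")]
  names(t34)[9L] <- "F"
  rownames(t34) <- NULL
  t5 <- NULL
  if (!is.null(comparative)) {
    rows <- lapply(names(comparative$pgls), function(nm) {
      best <- comparative$pgls[[nm]]$best
      k <- length(best$predictors)
      eq <- if (k) {
        paste(sprintf("%+.3g*%s", best$coefficients[-1L], best$predictors),
              collapse = " ")
      } else "(intercept)"
      slope_stats <- function(v) {
        if (!k) return(NA_character_)
        paste(sprintf("%.3g", v[-1L]), collapse = ", ")
      }
      data.frame(
        model = nm, equation = eq,
        t = slope_stats(best$t), p_c = slope_stats(best$p_coef),
        R2 = best$r_squared, F = best$F, p_m = best$p_model,
        AIC = best$AIC, stringsAsFactors = FALSE
      )
    })
    t5 <- do.call(rbind, rows)
  }
  list(db_manova = t12, perm_anova = t34, pgls_best = t5)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  pos <- do.call(rbind, lapply(seq_along(result$bundles), function(i) {
    cbind(id = result$bundles[[i]]$id, result$positions[[i]],
          stringsAsFactors = FALSE)
  }))
  wcsv(pos, "positions.csv")
  st <- do.call(rbind, lapply(result$structures, function(s) {
    data.frame(id = s$id, nodf_raw = s$nodf_raw, z_nodf = s$z_nodf,
               h2_raw = s$h2_raw, z_h2 = s$z_h2, n_null = s$n_null,
               seed = s$seed, stringsAsFactors = FALSE)
  }))
  wcsv(st, "structure.csv")
  rl <- do.call(rbind, lapply(seq_along(result$bundles), function(i) {
    cbind(id = result$bundles[[i]]$id, result$roles[[i]],
          stringsAsFactors = FALSE)
  }))
  wcsv(rl, "roles.csv")
  wcsv(result$role_proportions, "role_proportions.csv")
  mods <- lapply(seq_along(result$bundles), function(i) {
    p <- result$partitions[[i]]
    list(id = result$bundles[[i]]$id, Q = p$Q, n_modules = p$n_modules,
         seed = p$seed, host_module = as.list(p$host_module),
         parasite_module = as.list(p$parasite_module))
  })
  jsonlite::write_json(mods, file.path(outdir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wcsv(result$sex_tests, "sex_tests.csv")
  wcsv(result$tables$db_manova, "table_db_manova.csv")
  wcsv(result$tables$perm_anova, "table_perm_anova.csv")
  if (!is.null(result$comparative)) {
    wcsv(result$comparative$table, "comparative_table.csv")
    if (!is.null(result$tables$pgls_best)) {
      wcsv(result$tables$pgls_best, "table_pgls_best.csv")
    }
    rank <- do.call(rbind, lapply(names(result$comparative$pgls), function(nm) {
      cbind(model = nm, result$comparative$pgls[[nm]]$ranking,
            stringsAsFactors = FALSE)
    }))
    if (!is.null(rank)) wcsv(rank, "pgls_ranking.csv")
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("ectonet")),
    n_networks = length(result$bundles),
    network_ids = vapply(result$bundles, `[[`, character(1), "id"),
    settings = result$config[c("min_per_sex", "n_null", "nperm",
                               "percentile", "standardize_db_manova",
                               "response_scale", "seed")],
    db_manova_significant = sum(result$tables$db_manova$p < 0.05),
    structure_correlation = if (!is.null(result$comparative)) {
      result$comparative$structure_correlation
    } else NULL
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
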