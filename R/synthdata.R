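# Synthetic host-parasite survey generator. Emulates the structure of
# multi-species, two-region ectoparasite surveys: overdispersed
# (negative-binomial) per-host parasite loads allocated over a geometric
# rank-abundance parasite pool, with optional male bias in total abundance
# and in parasite-community composition, and a Yule tree over host species.

#' Simulation configuration
#'
#' Defaults emulate a field survey of small-mammal ectoparasites: cohorts
#' of 30 captured-and-parasitized individuals per sex (comfortably above
#' the >= 20 selection rule), 15 parasite species with a geometric
#' rank-abundance profile, mean load 5 parasites per host with
#' negative-binomial dispersion 1 (strongly overdispersed, as typical of
#' flea and mite burdens), and no sex effects unless requested.
#'
#' @param n_species number of host species.
#' @param hosts_per_sex parasitized individuals per sex and network.
#' @param n_parasites parasite species pool size per network.
#' @param nb_mean mean parasite load per host (females).
#' @param nb_dispersion negative-binomial size (gamma-shape) parameter.
#' @param male_abundance_mult multiplier on male mean load (1 = no bias).
#' @param male_composition_shift Dirichlet divergence of per-sex parasite
#'   preferences (0 = sexes share the composition exactly).
#' @param parasite_prevalence_decay geometric rank-abundance ratio in
#'   (0, 1); smaller = steeper few-common/many-rare profile.
#' @param regions region labels; each species is simulated in every region.
#' @param groups parasite-group labels.
#' @param abundance_mult_range,composition_shift_range optional 2-vectors:
#'   per-species effect sizes are drawn uniformly from these ranges in
#'   [simulate_collection()] (defaults: degenerate at the scalar values).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 21L,
                              hosts_per_sex = 30L,
                              n_parasites = 15L,
                              nb_mean = 5,
                              nb_dispersion = 1,
                              male_abundance_mult = 1,
                              male_composition_shift = 0,
                              parasite_prevalence_decay = 0.7,
                              regions = c("Siberia", "Slovakia"),
                              groups = c("flea", "mite"),
                              abundance_mult_range = NULL,
                              composition_shift_range = NULL,
                              seed = 1L) {
  stopifnot(n_species >= 1L, hosts_per_sex >= 1L, n_parasites >= 1L,
            nb_mean > 0, nb_dispersion > 0, male_abundance_mult > 0,
            male_composition_shift >= 0,
            parasite_prevalence_decay > 0, parasite_prevalence_decay < 1)
  cfg <- list(
    n_species = as.integer(n_species),
    hosts_per_sex = as.integer(hosts_per_sex),
    n_parasites = as.integer(n_parasites),
    nb_mean = nb_mean,
    nb_dispersion = nb_dispersion,
    male_abundance_mult = male_abundance_mult,
    male_composition_shift = male_composition_shift,
    parasite_prevalence_decay = parasite_prevalence_decay,
    regions = regions,
    groups = groups,
    abundance_mult_range = abundance_mult_range %||%
      rep(male_abundance_mult, 2L),
    composition_shift_range = composition_shift_range %||%
      rep(male_composition_shift, 2L),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# positive (zero-truncated by rejection) NB loads, n at a time
sample_parasitized_loads <- function(n, mu, size, max_tries = 10000L) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  if (p0 > 0.95) {
    stop(sprintf(
      "infeasible config: P(load = 0) = %.3f; raise nb_mean or dispersion",
      p0), call. = FALSE)
  }
  out <- integer(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    draw <- stats::rnbinom(2L * n, mu = mu, size = size)
    out <- c(out, draw[draw > 0])
    tries <- tries + 1L
  }
  if (length(out) < n) stop("could not draw enough parasitized hosts",
                            call. = FALSE)
  out[seq_len(n)]
}

#' Simulate one individual-based host-parasite network
#'
#' Per host, a total parasite load is drawn from a negative binomial with
#' mean `nb_mean` (times `male_abundance_mult` for males) and dispersion
#' `nb_dispersion`; unparasitized draws are redrawn so exactly
#' `hosts_per_sex` parasitized individuals per sex enter the network (the
#' assembly rule drops unparasitized hosts anyway). Each load is allocated
#' over the parasite pool by a multinomial whose baseline probabilities
#' follow a geometric rank-abundance vector; when
#' `male_composition_shift > 0` each sex uses its own Dirichlet perturbation
#' of that baseline, with divergence increasing in the shift.
#'
#' @param config a [simulation_config()].
#' @param species_label host species name.
#' @param region,group labels for the bundle id.
#' @param seed RNG seed for this network.
#' @param male_abundance_mult,male_composition_shift optional per-network
#'   overrides of the config effect sizes.
#' @return list with `bundle` (a [network_bundle()]) and `truth` (the
#'   effect sizes and per-sex composition actually used).
#' @export
simulate_network <- function(config, species_label = "sp1",
                             region = "Siberia", group = "flea", seed = 1L,
                             male_abundance_mult = NULL,
                             male_composition_shift = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  mult <- male_abundance_mult %||% config$male_abundance_mult
  shift <- male_composition_shift %||% config$male_composition_shift
  K <- config$n_parasites
  n <- config$hosts_per_sex
  base_p <- config$parasite_prevalence_decay^(seq_len(K) - 1)
  base_p <- base_p / sum(base_p)
  with_seed(seed, {
    probs <- list(F = base_p, M = base_p)
    if (shift > 0) {
      for (s in c("F", "M")) {
        g <- stats::rgamma(K, shape = base_p / shift)
        if (sum(g) == 0) g <- base_p
        probs[[s]] <- g / sum(g)
      }
    }
    mk_side <- function(sexlab, mu) {
      loads <- sample_parasitized_loads(n, mu, config$nb_dispersion)
      mat <- vapply(loads, function(L) {
        as.numeric(stats::rmultinom(1L, L, probs[[sexlab]]))
      }, numeric(K))
      t(mat)
    }
    mat <- rbind(mk_side("F", config$nb_mean),
                 mk_side("M", config$nb_mean * mult))
    sex <- rep(c("F", "M"), each = n)
    # a multinomial draw can still land a host on zero... impossible: loads > 0
    keep_col <- colSums(mat) > 0
    mat <- mat[, keep_col, drop = FALSE]
    colnames(mat) <- paste0(group, "_sp", which(keep_col))
    host_id <- sprintf("%s_%s_%s_h%03d", gsub(" ", "_", species_label),
                       region, group, seq_len(2L * n))
    rownames(mat) <- host_id
    hosts <- data.frame(
      host_id = host_id, species = species_label, region = region,
      site = paste0(region, "_site1"), sex = sex, stringsAsFactors = FALSE
    )
    bundle <- network_bundle(mat, hosts, parasite_group = group)
    truth <- list(species = species_label, region = region, group = group,
                  male_abundance_mult = mult,
                  male_composition_shift = shift,
                  probs_F = probs$F, probs_M = probs$M, seed = seed)
    list(bundle = bundle, truth = truth)
  })
}

#' Simulate a full multi-species collection with a host phylogeny
#'
#' One network per species x region x parasite group, per-species effect
#' sizes drawn uniformly from the configured ranges, and a Yule
#' (pure-birth) tree over the species labels.
#'
#' @param config a [simulation_config()] with `n_species >= 2`.
#' @return list with `bundles`, `tree` (`ape::phylo`), and `truth` (one
#'   record per network plus per-species effect sizes).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"), config$n_species >= 2L)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  with_seed(config$seed, {
    tree <- ape::rphylo(config$n_species, birth = 1, death = 0)
    tree$tip.label <- species
    mults <- stats::runif(config$n_species, config$abundance_mult_range[1L],
                          config$abundance_mult_range[2L])
    shifts <- stats::runif(config$n_species,
                           config$composition_shift_range[1L],
                           config$composition_shift_range[2L])
  })
  bundles <- list()
  truth <- list(species_effects = data.frame(
    species = species, male_abundance_mult = mults,
    male_composition_shift = shifts, stringsAsFactors = FALSE
  ), networks = list())
  k <- 0L
  for (i in seq_along(species)) {
    for (rg in config$regions) {
      for (gp in config$groups) {
        k <- k + 1L
        sim <- simulate_network(
          config, species_label = species[i], region = rg, group = gp,
          seed = derive_seed(config$seed, k),
          male_abundance_mult = mults[i],
          male_composition_shift = shifts[i]
        )
        bundles[[k]] <- sim$bundle
        truth$networks[[k]] <- sim$truth
      }
    }
  }
  list(bundles = bundles, tree = tree, truth = truth)
}

#' Write a simulated collection to disk
#'
#' Writes the long-format record CSV, the Newick tree, and a JSON truth
#' file (the effect sizes used) side by side.
#'
#' @param collection a [simulate_collection()] result.
#' @param dir output directory.
#' @return named paths, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- file.path(dir, "records.csv")
  treefile <- file.path(dir, "tree.nwk")
  truthfile <- file.path(dir, "truth.json")
  write_records(collection$bundles, records)
  ape::write.tree(collection$tree, treefile)
  jsonlite::write_json(
    list(species_effects = collection$truth$species_effects,
         networks = lapply(collection$truth$networks, function(t) {
           t[c("species", "region", "group", "male_abundance_mult",
               "male_composition_shift", "seed")]
         })),
    truthfile, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(records = records, tree = treefile, truth = truthfile))
}
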