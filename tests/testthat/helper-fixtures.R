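# Shared fixture builders: everything is generated in code at test time.

# random valid interaction matrix (no empty rows/columns)
random_count_matrix <- function(R = 6L, C = 5L, lambda = 1.2) {
  repeat {
    m <- matrix(stats::rpois(R * C, lambda), R, C)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("h", seq_len(R)), paste0("p", seq_len(C)))
  m
}

# toy bundle with known composition
toy_bundle <- function(nF = 3L, nM = 3L, C = 3L, seed = 1L) {
  n <- nF + nM
  m <- ectonet::with_seed(seed, {
    mm <- random_count_matrix(n, C)
    mm
  })
  hosts <- data.frame(
    host_id = rownames(m), species = "toy_sp", region = "toyland",
    site = "s1", sex = rep(c("F", "M"), c(nF, nM)),
    stringsAsFactors = FALSE
  )
  network_bundle(m, hosts, parasite_group = "flea")
}

# planted two-block bipartite matrix (within-block density dw, between db)
planted_blocks <- function(rows_per_block = 8L, cols_per_block = 6L,
                           dw = 0.8, db = 0.05) {
  blk <- function(r, c, d) matrix(stats::rbinom(r * c, 1L, d), r, c)
  repeat {
    M <- rbind(
      cbind(blk(rows_per_block, cols_per_block, dw),
            blk(rows_per_block, cols_per_block, db)),
      cbind(blk(rows_per_block, cols_per_block, db),
            blk(rows_per_block, cols_per_block, dw))
    )
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) break
  }
  dimnames(M) <- list(paste0("h", seq_len(2L * rows_per_block)),
                      paste0("p", seq_len(2L * cols_per_block)))
  M
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  # small self-contained ARI for the no-mclust case
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sidx <- sum(comb2(tab))
  sa <- sum(comb2(rowSums(tab)))
  sb <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sa * sb / n
  (sidx - expected) / ((sa + sb) / 2 - expected)
}

# long-format records for a small two-species survey
demo_records_file <- function(path, min_hosts = 21L, seed = 3L) {
  cfg <- simulation_config(n_species = 2L, hosts_per_sex = min_hosts,
                           regions = "Siberia", groups = "flea", seed = seed)
  coll <- simulate_collection(cfg)
  write_records(coll$bundles, path)
  coll
}
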