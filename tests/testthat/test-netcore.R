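test_that("interaction matrix invariants are enforced", {
  expect_error(interaction_matrix(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(interaction_matrix(matrix(c(1, 0.5, 2, 3), 2)), "non-negative")
  expect_error(interaction_matrix(matrix(1:3, 1)), "at least 2 host rows")
  expect_error(interaction_matrix(rbind(c(1, 0), c(0, 0))), "all-zero host row")
  expect_error(interaction_matrix(rbind(c(1, 0), c(1, 0))), "all-zero parasite")
  m <- interaction_matrix(rbind(c(2, 0), c(1, 1)))
  expect_s3_class(m, "interaction_matrix")
})

test_that("marginals are exact hand sums", {
  mm <- marginals(rbind(c(2, 0), c(1, 1)))
  expect_equal(unname(mm$A_i), c(2, 2))
  expect_equal(unname(mm$A_j), c(3, 1))
  expect_equal(mm$m, 4)
  expect_equal(mm$L, 3)
  expect_equal(mm$connectance, 0.75)
  expect_equal(marginals(matrix(5, 1, 1))$connectance, 1)
  expect_equal(marginals(diag(3))$L, 3)
  expect_equal(marginals(diag(3))$connectance, 1 / 3)
})

test_that("marginal identities hold on random matrices", {
  set.seed(101)
  for (k in 1:1000) {
    m <- random_count_matrix(sample(2:7, 1), sample(2:6, 1))
    mm <- marginals(m)
    expect_identical(sum(mm$A_i), mm$m)
    expect_identical(sum(mm$A_j), mm$m)
    expect_gte(mm$L, max(dim(m)))
  }
})

test_that("binarization maps positives to 1 and is idempotent", {
  expect_equal(unname(to_binary(rbind(c(2, 0), c(1, 1)))),
               rbind(c(1, 0), c(1, 1)))
  m <- random_count_matrix()
  expect_equal(to_binary(to_binary(m)), to_binary(m))
  expect_true(all(to_binary(m + 1) == 1))
})

test_that("record parsing maps sexes, drops zeros, sums duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "host_id,species,region,site,sex,group,parasite,count",
    "h1,vole,Siberia,s1,female,flea,fleaA,2",
    "h2,vole,Siberia,s1,M,flea,fleaA,1",
    "h2,vole,Siberia,s1,M,flea,fleaB,1"
  ), path)
  got <- read_records(path)
  expect_equal(nrow(got$records), 2L)
  expect_equal(got$records$sex, c("F", "M"))
  expect_equal(nrow(got$triples), 3L)

  writeLines(c(
    "host_id,species,region,site,sex,group,parasite,count",
    "h1,vole,Siberia,s1,F,flea,fleaA,2",
    "h1,vole,Siberia,s1,F,flea,fleaB,0"
  ), path)
  expect_warning(got <- read_records(path), "zero-count")
  expect_equal(nrow(got$triples), 1L)

  writeLines(c(
    "host_id,species,region,site,sex,group,parasite,count",
    "h1,vole,Siberia,s1,F,flea,fleaA,2",
    "h1,vole,Siberia,s1,F,flea,fleaA,3"
  ), path)
  expect_warning(got <- read_records(path), "summed")
  expect_equal(got$triples$count, 5)

  writeLines(c(
    "host_id,species,region,site,sex,group,parasite,count",
    "h1,vole,Siberia,s1,X,flea,fleaA,2"
  ), path)
  expect_error(read_records(path), "sex")
  writeLines(c(
    "host_id,species,region,site,sex,group,parasite,count",
    "h1,vole,Siberia,s1,F,flea,fleaA,-2"
  ), path)
  expect_error(read_records(path), "count")
  writeLines(c("host_id,species,region,sex", "h1,vole,Siberia,F"), path)
  expect_error(read_records(path), "missing required column")
})

test_that("cohort assembly applies the per-sex threshold to parasitized hosts", {
  mk <- function(nF, nM, zeroF = 0L) {
    n <- nF + nM
    hid <- sprintf("h%02d", seq_len(n))
    rec <- data.frame(host_id = hid, species = "vole", region = "Siberia",
                      site = "s1", sex = rep(c("F", "M"), c(nF, nM)),
                      stringsAsFactors = FALSE)
    # every host gets one interaction except the first `zeroF` females
    keep <- if (zeroF > 0L) hid[-seq_len(zeroF)] else hid
    tr <- data.frame(host_id = keep, group = "flea",
                     parasite = rep(c("fleaA", "fleaB"), length.out = length(keep)),
                     count = 1, stringsAsFactors = FALSE)
    list(rec = rec, tr = tr)
  }
  x <- mk(25, 25)
  expect_length(build_networks(x$rec, x$tr, min_per_sex = 20), 1L)
  x <- mk(19, 40)
  expect_message(out <- build_networks(x$rec, x$tr, min_per_sex = 20),
                 "dropping")
  expect_length(out, 0L)
  # 21 F + 21 M but 2 F unparasitized -> 19 parasitized F -> dropped
  x <- mk(21, 21, zeroF = 2L)
  expect_message(out <- build_networks(x$rec, x$tr, min_per_sex = 20),
                 "dropping")
  expect_length(out, 0L)
})

test_that("write/read round-trip reproduces identical bundles", {
  cfg <- simulation_config(n_species = 2L, hosts_per_sex = 21L,
                           regions = "Siberia", groups = c("flea", "mite"),
                           seed = 9L)
  coll <- simulate_collection(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(coll$bundles, path)
  back <- build_networks(read_records(path), min_per_sex = 20)
  expect_length(back, length(coll$bundles))
  ids <- vapply(back, `[[`, character(1), "id")
  for (b in coll$bundles) {
    b2 <- back[[match(b$id, ids)]]
    # host order is preserved exactly; column order up to permutation
    expect_equal(b2$hosts, b$hosts)
    expect_setequal(colnames(b2$matrix), colnames(b$matrix))
    expect_equal(unclass(b2$matrix)[, colnames(b$matrix)], unclass(b$matrix))
    expect_identical(b2$parasite_group, b$parasite_group)
  }
  # bundles assembled from a record stream are a fixed point of the
  # write/read round trip: a second pass is bit-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_records(back, path2)
  back2 <- build_networks(read_records(path2), min_per_sex = 20)
  expect_identical(lapply(back2, unclass), lapply(back, unclass))
})

test_that("built bundles always satisfy the matrix and threshold invariants", {
  set.seed(77)
  for (k in 1:5) {
    cfg <- simulation_config(n_species = 2L, hosts_per_sex = 20L + k,
                             regions = "Siberia", groups = "flea",
                             seed = 70L + k)
    for (b in simulate_collection(cfg)$bundles) {
      expect_true(all(rowSums(b$matrix) > 0))
      expect_true(all(colSums(b$matrix) > 0))
      expect_gte(min(table(b$hosts$sex)), 20L)
    }
  }
})
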