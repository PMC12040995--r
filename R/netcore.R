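# Data model, I/O and cohort assembly for individual-based bipartite networks.
#
# A network couples host individuals (rows) to parasite species (columns);
# entries are counts of parasite individuals recorded on a host. Networks are
# assembled per (host species, region, parasite group), keeping only hosts
# parasitized by at least one species of the focal group, and only cohorts
# with at least `min_per_sex` parasitized individuals of each sex.

#' Validate and construct an interaction matrix
#'
#' An interaction matrix holds non-negative integer counts of parasite
#' individuals (columns: parasite species) on host individuals (rows). After
#' construction it contains no all-zero row or column, has at least two host
#' rows and one parasite column, and a positive grand total.
#'
#' @param counts numeric matrix of non-negative integers with row names
#'   (host ids) and column names (parasite species).
#' @return the validated matrix (numeric storage), with class
#'   `interaction_matrix` prepended.
#' @export
interaction_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || !all(is.finite(counts))) {
    stop("interaction matrix must be numeric and finite", call. = FALSE)
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("interaction matrix entries must be non-negative integers", call. = FALSE)
  }
  counts <- round(counts)
  if (nrow(counts) < 2L) {
    stop("an interaction matrix needs at least 2 host rows", call. = FALSE)
  }
  if (ncol(counts) < 1L) {
    stop("an interaction matrix needs at least 1 parasite column", call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("interaction matrix has an all-zero host row", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("interaction matrix has an all-zero parasite column", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("h", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("p", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("host ids (row names) must be unique", call. = FALSE)
  }
  class(counts) <- c("interaction_matrix", class(counts))
  counts
}

#' Marginal totals of an interaction matrix
#'
#' @param mat interaction matrix (counts).
#' @return a list with `A_i` (row totals: parasites per host), `A_j` (column
#'   totals: each parasite species' total individuals), `m` (grand total),
#'   `L` (number of non-zero cells) and `connectance` (`L / (rows * cols)`).
#' @export
marginals <- function(mat) {
  mat <- unclass(as.matrix(mat))
  storage.mode(mat) <- "double"
  out <- list(
    A_i = rowSums(mat),
    A_j = colSums(mat),
    m = sum(mat),
    L = sum(mat > 0),
    connectance = sum(mat > 0) / length(mat)
  )
  class(out) <- "marginals"
  out
}

#' Binarize an interaction matrix
#'
#' @param mat numeric matrix.
#' @return 0/1 matrix of the same shape (1 where `mat > 0`).
#' @export
to_binary <- function(mat) {
  mat <- unclass(as.matrix(mat))
  b <- (mat > 0) * 1
  dimnames(b) <- dimnames(mat)
  b
}

#' Construct a network bundle
#'
#' A bundle ties an interaction matrix to the host metadata aligned to its
#' rows and to a parasite-group tag.
#'
#' @param mat interaction matrix (or coercible counts).
#' @param hosts data.frame with columns `host_id`, `species`, `region`,
#'   `site`, `sex`, one row per matrix row, in row order.
#' @param parasite_group character tag, e.g. `"flea"` or `"mite"`.
#' @param id bundle id; default `"species|region|group"`.
#' @return object of class `network_bundle`.
#' @export
network_bundle <- function(mat, hosts, parasite_group, id = NULL) {
  mat <- interaction_matrix(mat)
  hosts <- as.data.frame(hosts, stringsAsFactors = FALSE)
  req <- c("host_id", "species", "region", "site", "sex")
  if (!all(req %in% names(hosts))) {
    stop("hosts must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(hosts) != nrow(mat) || !identical(hosts$host_id, rownames(mat))) {
    stop("host records must align 1:1 with matrix rows", call. = FALSE)
  }
  if (!all(hosts$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (length(unique(hosts$species)) != 1L || length(unique(hosts$region)) != 1L) {
    stop("all hosts in a bundle must share species and region", call. = FALSE)
  }
  if (is.null(id)) {
    id <- paste(hosts$species[1L], hosts$region[1L], parasite_group, sep = "|")
  }
  structure(
    list(matrix = mat, hosts = hosts, parasite_group = parasite_group, id = id),
    class = "network_bundle"
  )
}

#' @export
print.network_bundle <- function(x, ...) {
  cat(sprintf(
    "network_bundle %s: %d hosts x %d parasite species, %d interactions (F=%d, M=%d)\n",
    x$id, nrow(x$matrix), ncol(x$matrix), sum(x$matrix),
    sum(x$hosts$sex == "F"), sum(x$hosts$sex == "M")
  ))
  invisible(x)
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("F", "FEMALE"), "F", ifelse(s %in% c("M", "MALE"), "M", NA))
  out
}

#' Read a long-format host-parasite record file
#'
#' Expected columns: `host_id`, `species`, `region`, `site`, `sex`,
#' `parasite`, `count`, plus an optional `group` column tagging each record's
#' parasite group (defaults to `"all"`). Sex accepts F/M/female/male in any
#' case. Zero-count rows are dropped with a warning; duplicated
#' (host, group, parasite) rows are summed with a warning.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param format `"long"` (default) or `"wide"` (five metadata columns then
#'   one column per parasite species).
#' @param group parasite-group tag used for wide input (which carries none).
#' @return a list with `records` (one row per host) and `triples`
#'   (host_id, group, parasite, count with count >= 1).
#' @export
read_records <- function(path, dialect = c("csv", "tsv"),
                         format = c("long", "wide"), group = "all") {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  sep <- if (dialect == "csv") "," else "\t"
  # read everything as character ("F" would otherwise become logical FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  meta_cols <- c("host_id", "species", "region", "site", "sex")
  if (format == "wide") {
    missing <- setdiff(meta_cols, names(df))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    pcols <- setdiff(names(df), meta_cols)
    if (!length(pcols)) stop("wide input has no parasite columns", call. = FALSE)
    long <- do.call(rbind, lapply(pcols, function(p) {
      data.frame(df[meta_cols], parasite = p, count = df[[p]],
                 stringsAsFactors = FALSE)
    }))
    long$group <- group
    df <- long
  }
  required <- c(meta_cols, "parasite", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$group)) df$group <- group
  df$host_id <- as.character(df$host_id)
  df$sex <- normalize_sex(df$sex)
  if (anyNA(df$sex)) {
    bad <- which(is.na(df$sex))
    stop("invalid sex value at data line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(!is.finite(cnt) | cnt < 0 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad)) {
    stop("negative or non-integer count at data line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  df$count <- round(cnt)

  # host records, deduplicated; metadata must be consistent per host
  rec <- unique(df[meta_cols])
  if (anyDuplicated(rec$host_id)) {
    dup <- unique(rec$host_id[duplicated(rec$host_id)])
    stop("conflicting metadata for host_id(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  rownames(rec) <- NULL

  zero <- df$count == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count record(s) dropped")
    df <- df[!zero, , drop = FALSE]
  }
  key <- paste(df$host_id, df$group, df$parasite, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicated (host, parasite) records summed")
    agg <- rowsum(df$count, key, reorder = FALSE)
    first <- !duplicated(key)
    tr <- df[first, c("host_id", "group", "parasite"), drop = FALSE]
    tr$count <- as.numeric(agg[match(unique(key), rownames(agg))])
  } else {
    tr <- df[, c("host_id", "group", "parasite", "count"), drop = FALSE]
  }
  rownames(tr) <- NULL
  list(records = rec, triples = tr)
}

#' Assemble per-cohort networks from records and interaction triples
#'
#' One bundle is built for each (host species, region, parasite group).
#' Hosts carrying no parasite of the focal group are excluded from that
#' network; cohorts with fewer than `min_per_sex` parasitized individuals of
#' either sex are dropped (with a message). All-zero parasite columns never
#' arise because triples carry counts >= 1.
#'
#' @param records host record data.frame (see [read_records()]).
#' @param triples long-format interactions (host_id, group, parasite, count).
#' @param min_per_sex minimum number of parasitized individuals of each sex
#'   for a cohort to be retained (default 20).
#' @return list of [network_bundle()] objects (possibly empty).
#' @export
build_networks <- function(records, triples, min_per_sex = 20L) {
  if (is.list(records) && !is.data.frame(records) &&
      all(c("records", "triples") %in% names(records))) {
    triples <- records$triples
    records <- records$records
  }
  unknown <- setdiff(unique(triples$host_id), records$host_id)
  if (length(unknown)) {
    stop("triples reference unknown host_id(s): ",
         paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  meta <- records[match(triples$host_id, records$host_id), c("species", "region")]
  combos <- unique(data.frame(
    species = meta$species, region = meta$region, group = triples$group,
    stringsAsFactors = FALSE
  ))
  bundles <- list()
  for (k in seq_len(nrow(combos))) {
    sp <- combos$species[k]; rg <- combos$region[k]; gp <- combos$group[k]
    sel <- meta$species == sp & meta$region == rg & triples$group == gp
    tr <- triples[sel, , drop = FALSE]
    # parasitized hosts only, in record order
    hid <- records$host_id[records$species == sp & records$region == rg &
                             records$host_id %in% tr$host_id]
    rec <- records[match(hid, records$host_id), , drop = FALSE]
    rownames(rec) <- NULL
    nf <- sum(rec$sex == "F"); nm <- sum(rec$sex == "M")
    if (nf < min_per_sex || nm < min_per_sex) {
      message(sprintf("dropping %s|%s|%s: %d F / %d M parasitized (< %d)",
                      sp, rg, gp, nf, nm, min_per_sex))
      next
    }
    pid <- unique(tr$parasite)
    mat <- matrix(0, length(hid), length(pid), dimnames = list(hid, pid))
    idx <- cbind(match(tr$host_id, hid), match(tr$parasite, pid))
    mat[idx] <- mat[idx] + tr$count
    bundles[[length(bundles) + 1L]] <-
      network_bundle(mat, rec, parasite_group = gp)
  }
  if (!length(bundles)) message("no cohort satisfied the selection rule")
  bundles
}

#' Write bundles back to the long record format
#'
#' Cells are emitted row-major (host blocks in row order), so reading the
#' file back with [read_records()] + [build_networks()] preserves host
#' order exactly and reproduces bundles identically whenever the bundle
#' was itself assembled from a record stream (parasite columns are ordered
#' by first appearance in the stream, which row-major writing makes a
#' fixed point of the round trip).
#'
#' @param bundles list of network bundles.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_records <- function(bundles, path) {
  if (inherits(bundles, "network_bundle")) bundles <- list(bundles)
  rows <- lapply(bundles, function(b) {
    idx <- which(b$matrix > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    h <- b$hosts[idx[, "row"], , drop = FALSE]
    data.frame(
      host_id = h$host_id, species = h$species, region = h$region,
      site = h$site, sex = h$sex, group = b$parasite_group,
      parasite = colnames(b$matrix)[idx[, "col"]],
      count = b$matrix[idx], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # preserve first-appearance order of hosts within each bundle
  ord <- order(match(out$group, unique(out$group)))
  out <- out[ord, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize bundles to a directory of CSV matrices plus a JSON manifest
#'
#' @param bundles list of network bundles.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bundles <- function(bundles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    stem <- gsub("[^A-Za-z0-9_.-]", "_", b$id)
    mfile <- file.path(dir, paste0(stem, "_matrix.csv"))
    hfile <- file.path(dir, paste0(stem, "_hosts.csv"))
    utils::write.csv(as.data.frame(unclass(b$matrix)), mfile)
    utils::write.csv(b$hosts, hfile, row.names = FALSE)
    list(id = b$id, parasite_group = b$parasite_group,
         matrix = basename(mfile), hosts = basename(hfile),
         n_hosts = nrow(b$matrix), n_parasites = ncol(b$matrix))
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
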