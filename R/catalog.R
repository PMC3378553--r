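#' Load a curated Rab gene catalog
#'
#' Reads the tab-separated catalog of Rab GTPase genes and Rab-interacting
#' genes. Each row is one gene with a role (`rab`, `gef`, `gap`, `effector`
#' or `general_machinery`) and a semicolon-separated list of Rab-cluster
#' memberships. A Rab cluster is a Rab (all its isoforms) together with its
#' known GEFs, GAPs and effectors, treated as a gene set. The six
#' general-machinery genes (the GDIs, the Rab escort proteins and the
#' geranylgeranyl-transferase subunits) serve every Rab and carry no cluster
#' membership.
#'
#' The catalog bundled with the package (`rab_catalog.tsv` under
#' `extdata`) lists 284 genes: 61 Rabs, 23 GEFs, 20 GAPs, 174 effectors and
#' 6 general-machinery genes. Cluster membership is exact for the Rab27
#' cluster; interactors whose cluster placement is not public are synthetic
#' placeholders with `SYN`-prefixed symbols, and per-cluster counts by role
#' match the curated family description.
#'
#' @param path Path to a catalog TSV with header columns
#'   `symbol`, `role`, `clusters`.
#' @return A data frame of class `rab_catalog` with columns `symbol`,
#'   `role` and `clusters` (a list column of character vectors).
#' @examples
#' cat_path <- system.file("extdata", "rab_catalog.tsv", package = "rabscreen")
#' catalog <- load_catalog(cat_path)
#' nrow(catalog)           # 284
#' table(catalog$role)
#' @export
load_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("symbol", "role", "clusters")
  if (!all(required %in% names(df)))
    stop_rs("catalog file must have columns %s", paste(required, collapse = ", "))
  if (nrow(df) == 0) stop_rs("catalog has no entries: %s", path)
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup))
    stop_rs("duplicate symbol in catalog: %s", paste(unique(dup), collapse = ", "))
  roles <- c("rab", "gef", "gap", "effector", "general_machinery")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad))
    stop_rs("unknown role(s) in catalog: %s", paste(bad, collapse = ", "))
  cl <- strsplit(df$clusters, ";", fixed = TRUE)
  cl <- lapply(cl, function(x) x[nzchar(x)])
  one <- lengths(cl[df$role == "rab"])
  if (any(one != 1))
    stop_rs("rab gene(s) without exactly one cluster: %s",
            paste(df$symbol[df$role == "rab"][one != 1], collapse = ", "))
  if (any(lengths(cl[df$role == "general_machinery"]) != 0))
    stop_rs("general_machinery genes must not carry cluster memberships")
  out <- data.frame(symbol = df$symbol, role = df$role, stringsAsFactors = FALSE)
  out$clusters <- cl
  class(out) <- c("rab_catalog", "data.frame")
  out
}

#' List the Rab cluster names of a catalog
#' @param catalog A `rab_catalog`.
#' @return Character vector of cluster names, in order of first appearance.
#' @export
cluster_names <- function(catalog) {
  stopifnot(inherits(catalog, "rab_catalog"))
  unique(unlist(catalog$clusters, use.names = FALSE))
}

#' Members of one Rab cluster
#' @param catalog A `rab_catalog`.
#' @param rab Cluster name, e.g. `"RAB27"`.
#' @return Data frame with columns `symbol` and `role` for all member genes.
#' @export
cluster_members <- function(catalog, rab) {
  stopifnot(inherits(catalog, "rab_catalog"))
  if (!rab %in% cluster_names(catalog))
    stop_rs("unknown cluster: %s", rab)
  keep <- vapply(catalog$clusters, function(x) rab %in% x, TRUE)
  data.frame(symbol = catalog$symbol[keep], role = catalog$role[keep],
             stringsAsFactors = FALSE)
}

#' Per-role member counts for one Rab cluster
#'
#' Counts isoforms, GEFs, GAPs and effectors of a cluster.
#' General-machinery genes are common to all Rabs and never counted.
#'
#' @inheritParams cluster_members
#' @return Named integer vector `c(isoforms, gefs, gaps, effectors)`.
#' @examples
#' catalog <- load_catalog(system.file("extdata", "rab_catalog.tsv",
#'                                     package = "rabscreen"))
#' cluster_summary(catalog, "RAB27")  # 2 1 1 12
#' @export
cluster_summary <- function(catalog, rab) {
  m <- cluster_members(catalog, rab)
  counts <- table(factor(m$role, levels = c("rab", "gef", "gap", "effector")))
  stats::setNames(as.integer(counts), c("isoforms", "gefs", "gaps", "effectors"))
}

#' Restrict a catalog to the genes measurable on a platform
#'
#' Microarray platforms miss some catalog genes. Restriction keeps every
#' catalog entry but flags which are measurable, and records `N`, the number
#' of catalog genes present, which the cluster enrichment test uses as its
#' denominator.
#'
#' @param catalog A `rab_catalog`.
#' @param present_genes Character vector of gene symbols measurable on the
#'   platform (symbols outside the catalog are ignored).
#' @return An object of class `platform_catalog`: a list with elements
#'   `catalog` (the catalog with an added logical column `present`),
#'   `present` (the intersection of catalog and platform symbols) and `N`.
#' @examples
#' catalog <- load_catalog(system.file("extdata", "rab_catalog.tsv",
#'                                     package = "rabscreen"))
#' absent <- readLines(system.file("extdata", "u133_absent_genes.txt",
#'                                 package = "rabscreen"))
#' platform <- restrict_to_platform(catalog, setdiff(catalog$symbol, absent))
#' platform$N  # 269
#' @export
restrict_to_platform <- function(catalog, present_genes) {
  stopifnot(inherits(catalog, "rab_catalog"))
  present <- intersect(catalog$symbol, present_genes)
  catalog$present <- catalog$symbol %in% present
  structure(list(catalog = catalog, present = present, N = length(present)),
            class = "platform_catalog")
}

#' Platform-present members of one cluster
#' @param platform A `platform_catalog`.
#' @param rab Cluster name.
#' @return Character vector of member symbols present on the platform.
#' @export
platform_cluster_members <- function(platform, rab) {
  stopifnot(inherits(platform, "platform_catalog"))
  m <- cluster_members(platform$catalog, rab)
  intersect(m$symbol, platform$present)
}

#' @export
print.rab_catalog <- function(x, ...) {
  cat(sprintf("Rab gene catalog: %d genes (%d clusters)\n",
              nrow(x), length(cluster_names(x))))
  print(table(x$role))
  invisible(x)
}

#' @export
print.platform_catalog <- function(x, ...) {
  cat(sprintf("Platform-restricted catalog: %d of %d genes present\n",
              x$N, nrow(x$catalog)))
  invisible(x)
}
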