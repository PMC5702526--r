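#' Load a region-of-interest atlas
#'
#' Reads a tabular atlas of spherical ROIs — one row per region with an MNI
#' millimetre centre coordinate and a network label — and returns a validated
#' atlas tibble. Row order defines node order: every matrix produced downstream
#' (connectivity, adjacency, edge statistics) is indexed in atlas row order.
#'
#' Two derived columns are added:
#' \describe{
#'   \item{hemisphere}{`"L"`, `"R"` or `"midline"`; midline means the centre
#'     lies within 3 mm of the inter-hemispheric plane (`abs(x) <= 3`).}
#'   \item{label}{display label used in edge lists: the abbreviation, with a
#'     `.L`/`.R` suffix appended only when the same abbreviation occurs for
#'     both hemispheres.}
#' }
#'
#' @param path Path to a comma- or tab-separated file with header columns
#'   `name`, `abbreviation`, `x`, `y`, `z`, `network`. The separator is
#'   inferred from the header line.
#' @return A tibble of class `ctrlnet_atlas` with columns `index`, `name`,
#'   `abbreviation`, `label`, `x`, `y`, `z`, `network`, `hemisphere`.
#' @examples
#' atlas <- load_atlas(ctrlnet_file("control_atlas.tsv"))
#' dplyr::count(atlas, network)
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) {
    stop("atlas file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           strip.white = TRUE)
  as_atlas(raw)
}

#' Construct an atlas from a data frame
#'
#' @param regions Data frame with columns `name`, `abbreviation`, `x`, `y`,
#'   `z`, `network` (one row per region, in node order).
#' @return A `ctrlnet_atlas` tibble; see [load_atlas()].
#' @export
as_atlas <- function(regions) {
  required <- c("name", "abbreviation", "x", "y", "z", "network")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("atlas is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regions) < 2) {
    stop("atlas must contain at least 2 regions (got ", nrow(regions), ")",
         call. = FALSE)
  }
  for (ax in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(regions[[ax]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0) {
      stop("non-numeric ", ax, " coordinate in atlas row ", bad[1],
           " (", regions$abbreviation[bad[1]], ")", call. = FALSE)
    }
    regions[[ax]] <- vals
  }
  known <- c("FPN", "CON", "CN", "DMN")
  bad_net <- which(!regions$network %in% known)
  if (length(bad_net) > 0) {
    stop("unknown network label '", regions$network[bad_net[1]],
         "' in atlas row ", bad_net[1], call. = FALSE)
  }

  hemisphere <- ifelse(abs(regions$x) <= 3, "midline",
                       ifelse(regions$x < 0, "L", "R"))
  dup <- regions$abbreviation %in%
    regions$abbreviation[duplicated(regions$abbreviation)]
  label <- ifelse(dup, paste0(regions$abbreviation, ".", hemisphere),
                  regions$abbreviation)
  if (anyDuplicated(label)) {
    stop("atlas (abbreviation, hemisphere) pairs are not unique: ",
         paste(unique(label[duplicated(label)]), collapse = ", "),
         call. = FALSE)
  }

  out <- tibble::tibble(
    index = seq_len(nrow(regions)),
    name = as.character(regions$name),
    abbreviation = as.character(regions$abbreviation),
    label = label,
    x = regions$x, y = regions$y, z = regions$z,
    network = as.character(regions$network),
    hemisphere = hemisphere
  )
  class(out) <- c("ctrlnet_atlas", class(out))
  out
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or a character vector of file names).
#' @export
ctrlnet_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ctrlnet")))
  }
  path <- system.file("extdata", file, package = "ctrlnet")
  if (identical(path, "")) {
    stop("no packaged file named '", file, "'", call. = FALSE)
  }
  path
}

#' Inter-regional Euclidean distances and edge classification
#'
#' Computes the straight-line distance in millimetres between every unordered
#' pair of region centres and classifies each pair as long-range (distance
#' strictly greater than `cutoff` mm) and/or inter-network (the two regions
#' belong to different networks).
#'
#' @param atlas A `ctrlnet_atlas` tibble.
#' @param cutoff Long-range cutoff in millimetres (default 75; the comparison
#'   is strict, so a pair at exactly the cutoff is short-range).
#' @return A tibble with one row per unordered pair: `i`, `j` (node indices,
#'   `i < j`), `node_i`, `node_j` (labels), `network_i`, `network_j`,
#'   `distance` (mm), `long_range`, `inter_network`.
#' @examples
#' atlas <- load_atlas(ctrlnet_file("control_atlas.tsv"))
#' dist_tab <- pairwise_distances(atlas)
#' mean(dist_tab$long_range)
#' @export
pairwise_distances <- function(atlas, cutoff = 75) {
  stopifnot(inherits(atlas, "ctrlnet_atlas"))
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  n <- nrow(xyz)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]
  j <- pairs[, 2]
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  tibble::tibble(
    i = i, j = j,
    node_i = atlas$label[i], node_j = atlas$label[j],
    network_i = atlas$network[i], network_j = atlas$network[j],
    distance = d,
    long_range = is_long_range(d, cutoff = cutoff),
    inter_network = atlas$network[i] != atlas$network[j]
  )
}

#' Is a connection long-range?
#'
#' A connection is long-range when its inter-centroid Euclidean distance is
#' strictly greater than the cutoff (default 75 mm).
#'
#' @param d Distance(s) in millimetres; must be non-negative.
#' @param cutoff Cutoff in millimetres.
#' @return Logical vector.
#' @export
is_long_range <- function(d, cutoff = 75) {
  if (any(d < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  d > cutoff
}

#' Load a component edge-list fixture
#'
#' Reads an edge list given by region labels (columns `regionA`, `regionB`,
#' plus optional `p`, `distance`, `category`) and resolves the labels against
#' an atlas. Category strings of the form `"NET1-NET2"` are parsed with the
#' shorthand `CO` normalized to `CON`, and an `inter_network` flag is derived
#' from them when present.
#'
#' @param path CSV file path.
#' @param atlas A `ctrlnet_atlas` used to resolve labels to node indices.
#' @return A tibble with `i`, `j` (node indices, `i < j`), `node_i`, `node_j`
#'   and any of `p`, `distance`, `category`, `inter_network` present.
#' @examples
#' atlas <- load_atlas(ctrlnet_file("control_atlas.tsv"))
#' comp <- load_component_edges(ctrlnet_file("nbs_component_edges.csv"), atlas)
#' nrow(comp)
#' @export
load_component_edges <- function(path, atlas) {
  stopifnot(inherits(atlas, "ctrlnet_atlas"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         strip.white = TRUE)
  for (col in c("regionA", "regionB")) {
    if (!col %in% names(raw)) {
      stop("component edge list is missing column '", col, "'", call. = FALSE)
    }
    unknown <- setdiff(raw[[col]], atlas$label)
    if (length(unknown) > 0) {
      stop("edge list label(s) not in atlas: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  ia <- match(raw$regionA, atlas$label)
  ib <- match(raw$regionB, atlas$label)
  out <- tibble::tibble(
    i = pmin(ia, ib), j = pmax(ia, ib),
    node_i = atlas$label[pmin(ia, ib)], node_j = atlas$label[pmax(ia, ib)]
  )
  if ("p" %in% names(raw)) out$p <- raw$p
  if ("distance" %in% names(raw)) out$distance <- raw$distance
  if ("category" %in% names(raw)) {
    out$category <- raw$category
    sides <- strsplit(raw$category, "-", fixed = TRUE)
    norm <- function(s) ifelse(s == "CO", "CON", s)
    out$inter_network <- vapply(
      sides, function(s) norm(s[1]) != norm(s[2]), logical(1))
  }
  if (anyDuplicated(out[, c("i", "j")])) {
    stop("duplicated edges in component edge list", call. = FALSE)
  }
  out
}
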