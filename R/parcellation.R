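# Atlas handling: vertex -> node aggregation and node -> region / RSN grouping.

#' Construct an atlas
#'
#' @param vertex2node integer vector assigning every vertex to a node id
#'   (nodes must be contiguous 1..K, each non-empty)
#' @param node_region character vector, region label per node
#' @param node_rsn character vector, resting-state-network label per node
#'   (one of DMN, DAN, SAN, AUD, VIS, Other)
#' @param node_labels optional node names
#' @return An `atlas` object.
#' @export
atlas <- function(vertex2node, node_region, node_rsn, node_labels = NULL) {
  vertex2node <- as.integer(vertex2node)
  if (anyNA(vertex2node)) stop_param("every vertex must be assigned to a node")
  k <- max(vertex2node)
  if (!setequal(unique(vertex2node), seq_len(k))) {
    stop_param("node ids must be contiguous 1..K with every node non-empty")
  }
  if (length(node_region) != k || length(node_rsn) != k) {
    stop_param("need one region and one RSN label per node (%d nodes)", k)
  }
  valid_rsn <- c("DMN", "DAN", "SAN", "AUD", "VIS", "Other")
  if (!all(node_rsn %in% valid_rsn)) {
    stop_param("RSN labels must be among %s", paste(valid_rsn, collapse = ", "))
  }
  if (is.null(node_labels)) node_labels <- sprintf("node%02d", seq_len(k))
  structure(
    list(vertex2node = vertex2node, n_nodes = k,
         node_region = as.character(node_region),
         node_rsn = as.character(node_rsn),
         node_labels = node_labels),
    class = "atlas"
  )
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("atlas: %d vertices -> %d nodes, %d regions, RSN classes: %s\n",
              length(x$vertex2node), x$n_nodes,
              length(unique(x$node_region)),
              paste(sort(unique(x$node_rsn)), collapse = ", ")))
  invisible(x)
}

#' Auto-generate a toy atlas for a mesh
#'
#' Partitions mesh vertices into `n_nodes` spatially compact nodes by k-means
#' on vertex positions (fixed internal seed, deterministic), then assigns
#' nodes round-robin to the 14 hemisphere x lobe region labels and to the six
#' RSN classes so every downstream grouping path is exercised at desk scale.
#'
#' @param mesh a `cortical_mesh`
#' @param n_nodes number of nodes (default 20)
#' @param seed integer seed for the k-means initialization (default 42)
#' @return An `atlas`.
#' @export
toy_atlas <- function(mesh, n_nodes = 20, seed = 42) {
  if (n_nodes < 2 || n_nodes > mesh$n_vertices) {
    stop_param("n_nodes must be in 2..n_vertices")
  }
  km <- with_seed(seed, stats::kmeans(mesh$vertices, centers = n_nodes,
                                      nstart = 5, iter.max = 50))
  cl <- km$cluster
  # relabel clusters by first-vertex order for a stable node numbering
  first <- match(seq_len(n_nodes), cl)
  ord <- order(first)
  relab <- integer(n_nodes)
  relab[ord] <- seq_len(n_nodes)
  cl <- relab[cl]
  regions <- region_labels()
  rsns <- c("DMN", "DAN", "SAN", "AUD", "VIS", "Other")
  atlas(cl,
        node_region = rep_len(regions, n_nodes),
        node_rsn = rep_len(rsns, n_nodes))
}

#' The 14 canonical region labels
#'
#' Seven lobe classes (occipital O, limbic L, parietal P, temporal T,
#' central C, frontal F, prefrontal PF) by hemisphere (L/R prefix).
#' @return character vector of 14 labels
#' @export
region_labels <- function() {
  classes <- c("O", "L", "P", "T", "C", "F", "PF")
  as.vector(t(outer(c("L", "R"), classes, paste, sep = "_")))
}

#' Load the shipped 68-node cortical atlas lookup table
#'
#' Returns the editable node -> region / RSN classification shipped with the
#' package (inst/extdata/dk_atlas_synthetic.csv): the 68 Desikan-Killiany
#' nodes mapped to 14 regions and six RSN classes with 44 nodes in named
#' networks. The assignment is a synthetic stand-in constructed from standard
#' anatomical groupings, not the original study table; replace the CSV to use
#' a different classification.
#'
#' @param path optional path to an alternative CSV with columns
#'   `node_id,node_label,region,rsn`
#' @return data.frame with the node classification
#' @export
dk_node_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk_atlas_synthetic.csv", package = "tcdeeg")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate a vertex map into atlas nodes
#'
#' Node value = unweighted arithmetic mean over member vertices.
#'
#' @param values numeric vector (length n_vertices) or matrix
#'   (n_vertices x k, e.g. one column per band)
#' @param atlas an `atlas` covering those vertices
#' @return n_nodes x k matrix of node means (k = 1 for vector input), with
#'   band/column names preserved.
#' @export
aggregate_vertices <- function(values, atlas) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1,
                                                 dimnames = list(NULL, "value"))
  if (nrow(v) != length(atlas$vertex2node)) {
    stop_param("values rows (%d) != atlas vertex count (%d)", nrow(v),
               length(atlas$vertex2node))
  }
  sums <- rowsum(v, atlas$vertex2node)
  counts <- tabulate(atlas$vertex2node, atlas$n_nodes)
  out <- sums / counts
  rownames(out) <- atlas$node_labels
  out
}

#' Group node values by region or RSN
#'
#' Returns node-level rows labeled with their region or RSN (replicate
#' semantics: nodes are not averaged away), plus a convenience per-group mean
#' table. Groups with no member nodes are omitted with a warning.
#'
#' @param node_values n_nodes x k matrix as returned by [aggregate_vertices()]
#' @param atlas the `atlas`
#' @param level `"region"` or `"rsn"`
#' @return list with `replicates` (data.frame: node, group, value columns)
#'   and `means` (data.frame: group, value columns averaged over member nodes)
#' @export
group_nodes <- function(node_values, atlas, level = c("region", "rsn")) {
  level <- match.arg(level)
  node_values <- as.matrix(node_values)
  if (is.null(colnames(node_values))) {
    colnames(node_values) <- if (ncol(node_values) == 1) "value" else
      sprintf("value%d", seq_len(ncol(node_values)))
  }
  if (nrow(node_values) != atlas$n_nodes) {
    stop_param("node_values rows (%d) != atlas node count (%d)",
               nrow(node_values), atlas$n_nodes)
  }
  labels <- if (level == "region") atlas$node_region else atlas$node_rsn
  universe <- if (level == "region") region_labels() else
    c("DMN", "DAN", "SAN", "AUD", "VIS", "Other")
  missing_groups <- setdiff(universe, unique(labels))
  if (length(missing_groups) > 0) {
    warning(sprintf("%s group(s) with no member nodes omitted: %s", level,
                    paste(missing_groups, collapse = ", ")), call. = FALSE)
  }
  reps <- data.frame(node = seq_len(atlas$n_nodes), group = labels,
                     node_values, row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
  means_mat <- rowsum(as.matrix(node_values), labels) /
    as.vector(table(labels)[sort(unique(labels))])
  means <- data.frame(group = rownames(means_mat), means_mat,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  list(replicates = reps, means = means)
}

#' Write / read atlas CSV files
#'
#' Three tidy CSVs: `vertex_id,node_id`; `node_id,region_label`;
#' `node_id,rsn_label`, written under `dir` as vertices.csv, regions.csv,
#' rsn.csv.
#' @param atlas an `atlas`
#' @param dir output directory
#' @export
write_atlas_csv <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(vertex_id = seq_along(atlas$vertex2node),
               node_id = atlas$vertex2node),
    file.path(dir, "vertices.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(node_id = seq_len(atlas$n_nodes),
               region_label = atlas$node_region),
    file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(node_id = seq_len(atlas$n_nodes),
               rsn_label = atlas$node_rsn),
    file.path(dir, "rsn.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas_csv
#' @export
read_atlas_csv <- function(dir) {
  v <- utils::read.csv(file.path(dir, "vertices.csv"))
  r <- utils::read.csv(file.path(dir, "regions.csv"))
  n <- utils::read.csv(file.path(dir, "rsn.csv"))
  r <- r[order(r$node_id), ]
  n <- n[order(n$node_id), ]
  atlas(v$node_id[order(v$vertex_id)], r$region_label, n$rsn_label)
}
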