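#' Write a cell map as nodes/edges TSV files
#'
#' `nodes.tsv`: assembly_id, n_proteins, members (`|`-joined), persistence
#' and, when a calibration model is supplied, diameter_nm / pi_low_nm /
#' pi_high_nm. `edges.tsv`: parent, child, containment_index.
#'
#' @param map a `cell_map`.
#' @param dir output directory (created if needed).
#' @param calibration optional `calibration_model` for diameter columns.
#' @return invisibly, the two file paths.
#' @export
write_cell_map <- function(map, dir, calibration = NULL) {
  stopifnot(inherits(map, "cell_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- data.frame(
    assembly_id = names(map$assemblies),
    n_proteins = lengths(map$assemblies),
    members = vapply(map$assemblies, paste, "", collapse = "|"),
    persistence = map$meta$persistence[match(names(map$assemblies), map$meta$id)],
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(calibration)) {
    pd <- predict_diameter(calibration, nodes$n_proteins)
    nodes <- cbind(nodes, pd)
  }
  edges <- map$edges
  names(edges)[names(edges) == "containment"] <- "containment_index"
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  data.table::fwrite(nodes, np, sep = "\t")
  data.table::fwrite(edges, ep, sep = "\t")
  invisible(c(nodes = np, edges = ep))
}

#' Read a cell map written by [write_cell_map()]
#'
#' @param nodes_path,edges_path the two TSV files.
#' @return a `cell_map`.
#' @export
read_cell_map <- function(nodes_path, edges_path) {
  nodes <- data.table::fread(nodes_path, data.table = FALSE)
  edges <- data.table::fread(edges_path, data.table = FALSE)
  assemblies <- setNames(strsplit(nodes$members, "|", fixed = TRUE),
                         nodes$assembly_id)
  names(edges)[names(edges) == "containment_index"] <- "containment"
  sizes <- lengths(assemblies)
  root <- names(assemblies)[which.max(sizes)]
  structure(list(assemblies = assemblies,
                 meta = data.frame(id = nodes$assembly_id,
                                   n_proteins = nodes$n_proteins,
                                   persistence = nodes$persistence,
                                   stringsAsFactors = FALSE),
                 edges = edges[, c("parent", "child", "containment")],
                 root = root, merged = character(0)),
            class = "cell_map")
}

#' Write a feature matrix as TSV (`protein`, f0..f{d-1})
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(protein = fm$protein_ids, fm$values,
                   stringsAsFactors = FALSE)
  names(df) <- c("protein", paste0("f", seq_len(fm$d) - 1L))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write every component of a synthetic bundle in pipeline input formats
#'
#' Emits: `edges.tsv` (bait, prey, weight), `image_features.tsv`,
#' `sec_rep<k>.tsv` (protein, frac_1..frac_K), `mutations.maf.tsv`,
#' `expected_counts.tsv`, `cohorts.tsv`, `catalog.gmt`, and
#' `truth_assemblies.tsv` (id, parent, members).
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- bundle$network
  data.table::fwrite(data.frame(bait = net$edges$a, prey = net$edges$b,
                                weight = net$edges$weight),
                     file.path(dir, "edges.tsv"), sep = "\t")
  write_feature_matrix(bundle$image_features, file.path(dir, "image_features.tsv"))
  for (r in seq_along(bundle$sec$replicates)) {
    m <- bundle$sec$replicates[[r]]
    df <- data.frame(protein = rownames(m), m, stringsAsFactors = FALSE,
                     check.names = FALSE)
    data.table::fwrite(df, file.path(dir, sprintf("sec_rep%d.tsv", r)), sep = "\t")
  }
  mut <- bundle$mutations
  data.table::fwrite(mut$maf, file.path(dir, "mutations.maf.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene = names(mut$expected), n_exp = mut$expected),
                     file.path(dir, "expected_counts.tsv"), sep = "\t")
  data.table::fwrite(mut$samples, file.path(dir, "cohorts.tsv"), sep = "\t")
  for (ci in seq_along(bundle$catalogs))
    write_gmt(bundle$catalogs[[ci]], file.path(dir, sprintf("catalog%d.gmt", ci)))
  truth <- bundle$truth
  parent_of <- setNames(truth$parent_edges$parent, truth$parent_edges$child)
  data.table::fwrite(data.frame(
    id = names(truth$assemblies),
    parent = unname(parent_of[names(truth$assemblies)]),
    members = vapply(truth$assemblies, paste, "", collapse = "|")),
    file.path(dir, "truth_assemblies.tsv"), sep = "\t")
  invisible(dir)
}
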