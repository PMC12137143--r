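#' Construct a feature matrix
#'
#' @param values numeric matrix with protein ids as rownames.
#' @param modality label, e.g. "ppi" or "image".
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, modality = "unknown") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have protein ids as rownames")
  if (anyDuplicated(rownames(values))) stop("protein ids must be unique")
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(protein_ids = rownames(values), values = values,
                 modality = modality, d = ncol(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d proteins x %d features\n",
              x$modality, length(x$protein_ids), x$d))
  invisible(x)
}

#' Load an interaction network from a bait/prey edge list
#'
#' Reads a TSV with columns bait, prey and optional weight. Duplicate edges
#' (in either orientation) are collapsed keeping the maximum weight;
#' self-loop rows are dropped with a warning. Proteins appearing in the bait
#' column are flagged as baits.
#'
#' @param path edge-list file.
#' @return an `interaction_network`.
#' @export
load_interaction_network <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("edge list needs at least bait and prey columns")
  a <- as.character(dt[[1]]); b <- as.character(dt[[2]])
  w <- if (ncol(dt) >= 3) as.numeric(dt[[3]]) else rep(1, length(a))
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive")
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop row(s)", sum(self)))
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (length(a) == 0L) stop("no edges after filtering")
  baits <- unique(a)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  agg <- tapply(w, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                      b = vapply(parts, `[`, "", 2L),
                      weight = as.numeric(agg),
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes <- sort(unique(c(edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges,
                 is_bait = setNames(nodes %in% baits, nodes)),
            class = "interaction_network")
}

#' Load a per-protein feature table
#'
#' First column is the protein id; remaining columns are numeric features.
#' Multiple rows for the same protein (e.g. replicate images) are averaged
#' element-wise.
#'
#' @param path TSV file.
#' @param modality modality label for the result.
#' @return a `feature_matrix`.
#' @export
load_feature_matrix <- function(path, modality = "image") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty feature table")
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- !is.finite(vals)
  if (any(bad)) {
    stop(sprintf("non-finite feature values for protein(s): %s",
                 paste(unique(ids[which(rowSums(bad) > 0)]), collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    vals <- rowsum(vals, ids) / as.vector(table(ids)[sort(unique(ids))])
    ids <- rownames(vals)
  } else {
    rownames(vals) <- ids
  }
  feature_matrix(vals[order(rownames(vals)), , drop = FALSE], modality = modality)
}

#' Restrict two feature matrices to their common proteins
#'
#' Both matrices are subset to the (sorted) intersection of protein ids in
#' identical row order, the joint universe over which the multimodal
#' embedding is trained.
#'
#' @param fm_x,fm_y `feature_matrix` objects.
#' @return list with elements `x` and `y` (aligned `feature_matrix`s).
#' @export
align_modalities <- function(fm_x, fm_y) {
  stopifnot(inherits(fm_x, "feature_matrix"), inherits(fm_y, "feature_matrix"))
  common <- sort(intersect(fm_x$protein_ids, fm_y$protein_ids))
  if (length(common) == 0L) stop("no proteins shared between modalities")
  message(sprintf("aligned modalities on %d shared proteins", length(common)))
  list(x = feature_matrix(fm_x$values[common, , drop = FALSE], fm_x$modality),
       y = feature_matrix(fm_y$values[common, , drop = FALSE], fm_y$modality))
}

#' Generate second-order biased random walks over an interaction network
#'
#' Walks follow the two-parameter biased scheme: from the current node, the
#' unnormalised probability of moving to neighbour t is the edge weight
#' multiplied by 1/p if t is the previous node, 1 if t is also a neighbour
#' of the previous node, and 1/q otherwise.
#'
#' @param net an `interaction_network`.
#' @param p return parameter.
#' @param q in-out parameter.
#' @param walk_length steps per walk.
#' @param walks_per_node walks started from each node.
#' @param seed integer seed.
#' @return integer matrix (walks x walk_length) of 1-based node indices into
#'   `net$nodes`; 0 pads walks stranded at isolated nodes.
#' @export
node2vec_walks <- function(net, p = 2, q = 1, walk_length = 80,
                           walks_per_node = 10, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  nodes <- net$nodes
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  ia <- idx[net$edges$a]; ib <- idx[net$edges$b]
  adj <- vector("list", n); wts <- vector("list", n)
  ord <- order(c(ia, ib))
  src <- c(ia, ib)[ord]; dst <- c(ib, ia)[ord]; ww <- rep(net$edges$weight, 2)[ord]
  split_dst <- split(dst, factor(src, levels = seq_len(n)))
  split_w <- split(ww, factor(src, levels = seq_len(n)))
  for (i in seq_len(n)) { adj[[i]] <- split_dst[[i]]; wts[[i]] <- split_w[[i]] }

  walks <- matrix(0L, n * walks_per_node, walk_length)
  withr::with_seed(derive_seed(seed, 101L), {
    row <- 1L
    for (w in seq_len(walks_per_node)) {
      for (start in seq_len(n)) {
        walk <- integer(walk_length)
        walk[1L] <- start
        if (length(adj[[start]]) > 0L) {
          cur <- start; prev <- 0L
          for (s in 2:walk_length) {
            nb <- adj[[cur]]; wv <- wts[[cur]]
            if (prev > 0L) {
              bias <- ifelse(nb == prev, 1 / p,
                             ifelse(nb %in% adj[[prev]], 1, 1 / q))
              wv <- wv * bias
            }
            nxt <- nb[sample.int(length(nb), 1L, prob = wv)]
            walk[s] <- nxt
            prev <- cur; cur <- nxt
          }
        }
        walks[row, ] <- walk
        row <- row + 1L
      }
    }
  })
  walks
}

#' Embed an interaction network by biased random walks and skip-gram
#'
#' Generates second-order biased random walks ([node2vec_walks()]) and trains
#' skip-gram with negative sampling over the walk corpus, giving one feature
#' vector per node summarising its interaction neighbourhood. Nodes in
#' connected components of size 1 have no walk context and receive zero
#' vectors (flagged in the `singletons` attribute).
#'
#' @param net an `interaction_network`.
#' @param p,q,walk_length,walks_per_node walk parameters (defaults 2, 1, 80,
#'   10).
#' @param dim embedding dimension.
#' @param window skip-gram context window.
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the walk corpus.
#' @param seed integer seed; training is single-threaded and deterministic.
#' @return a `feature_matrix` with modality "ppi".
#' @export
embed_network <- function(net, p = 2, q = 1, walk_length = 80,
                          walks_per_node = 10, dim = 1024, window = 10,
                          negatives = 5, epochs = 5, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  if (dim < 2) stop("dim must be >= 2")
  if (nrow(net$edges) == 0L) stop("empty network")
  walks <- node2vec_walks(net, p, q, walk_length, walks_per_node, seed)
  n <- length(net$nodes)
  emb <- sgns_train(walks, n, as.integer(dim), as.integer(window),
                    as.integer(negatives), as.integer(epochs), 0.025,
                    derive_seed(seed, 211L))
  rownames(emb) <- net$nodes
  deg <- table(factor(c(net$edges$a, net$edges$b), levels = net$nodes))
  singles <- net$nodes[deg == 0]
  emb[singles, ] <- 0
  fm <- feature_matrix(emb, modality = "ppi")
  attr(fm, "singletons") <- singles
  fm
}
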