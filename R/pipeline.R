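#' Run the full embed-detect-assemble pipeline
#'
#' Aligns the two modalities, trains the multimodal co-embedding, computes
#' pairwise cosine similarities, builds the threshold proximity networks,
#' detects persistent communities across resolutions and assembles them
#' into a containment DAG.
#'
#' @param fm_x,fm_y `feature_matrix` objects for the two modalities.
#' @param config a [coembed_config()].
#' @param fractions similarity fractions for [build_threshold_networks()].
#' @param persistence_k,max_resolution,resolution_grid,min_size detection
#'   parameters (see [detect_pan_resolution()]).
#' @param containment_threshold,redundancy_jaccard DAG parameters (see
#'   [build_dag()]).
#' @param seed integer seed for the detection stage (training uses
#'   `config$seed`).
#' @return list with `map` (a `cell_map`), `embedding`, `similarity`,
#'   `training_log`.
#' @export
cellmap_pipeline <- function(fm_x, fm_y, config = coembed_config(),
                             fractions = c(0.002, 0.003, 0.004, 0.005, 0.01,
                                           0.02, 0.03, 0.04, 0.05, 0.10),
                             persistence_k = 10, max_resolution = 80,
                             resolution_grid = NULL, min_size = 3,
                             containment_threshold = 0.75,
                             redundancy_jaccard = 0.90, seed = 1L) {
  al <- align_modalities(fm_x, fm_y)
  tr <- train_coembedding(al$x, al$y, config)
  sim <- pairwise_cosine(tr$embedding)
  nets <- build_threshold_networks(sim, fractions)
  asm <- detect_pan_resolution(nets, persistence_k = persistence_k,
                               max_resolution = max_resolution,
                               resolution_grid = resolution_grid,
                               min_size = min_size, seed = seed)
  if (length(asm) == 0L) stop("no persistent assemblies detected")
  map <- build_dag(asm, universe = al$x$protein_ids,
                   containment_threshold = containment_threshold,
                   redundancy_jaccard = redundancy_jaccard)
  list(map = map, embedding = tr$embedding, similarity = sim,
       training_log = tr$log)
}
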