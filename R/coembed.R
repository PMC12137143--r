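#' Configuration for the multimodal co-embedding model
#'
#' Defaults follow the published training recipe: 128-d latent space,
#' dropout 0.25, triplet margin 0.10, reconstruction-regularisation and
#' triplet weights both 5, batch size 64, Adam learning rate 1e-4, and a
#' three-phase schedule of 200/200/500 epochs with cluster labels refreshed
#' every 200 epochs in the final phase.
#'
#' @param latent_dim joint embedding dimension.
#' @param branch_hidden_dim hidden width of each modality encoder.
#' @param decoder_hidden_dims hidden widths of the two decoder hidden layers.
#' @param dropout dropout fraction in \[0, 1).
#' @param margin triplet margin epsilon (> 0).
#' @param lambda_reg weight of the decoder-weight Frobenius penalty.
#' @param lambda_triplet weight of the triplet losses.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param phase_epochs integer vector of three phase lengths.
#' @param cluster_refresh_epochs phase-3 recluster interval.
#' @param knn neighbours for the cosine k-NN graph fed to Louvain.
#' @param seed integer seed controlling initialisation, shuffling, dropout
#'   and clustering.
#' @return a `coembed_config` list.
#' @export
coembed_config <- function(latent_dim = 128, branch_hidden_dim = 512,
                           decoder_hidden_dims = c(512, 512), dropout = 0.25,
                           margin = 0.10, lambda_reg = 5, lambda_triplet = 5,
                           batch_size = 64, learning_rate = 1e-4,
                           phase_epochs = c(200, 200, 500),
                           cluster_refresh_epochs = 200, knn = 15, seed = 1L) {
  stopifnot(latent_dim > 0, dropout >= 0, dropout < 1, margin > 0,
            length(phase_epochs) == 3, all(phase_epochs >= 0),
            lambda_reg >= 0, lambda_triplet >= 0, batch_size >= 2,
            learning_rate > 0)
  structure(list(latent_dim = latent_dim, branch_hidden_dim = branch_hidden_dim,
                 decoder_hidden_dims = decoder_hidden_dims, dropout = dropout,
                 margin = margin, lambda_reg = lambda_reg,
                 lambda_triplet = lambda_triplet, batch_size = batch_size,
                 learning_rate = learning_rate, phase_epochs = phase_epochs,
                 cluster_refresh_epochs = cluster_refresh_epochs,
                 knn = knn, seed = as.integer(seed)),
            class = "coembed_config")
}

## ---- minimal layer toolkit (explicit forward/backward) ----

.lin_init <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  list(W = matrix(runif(nin * nout, -s, s), nin, nout), b = rep(0, nout))
}
.bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

.lin_fwd <- function(p, x) list(out = sweep(x %*% p$W, 2, p$b, "+"), x = x)
.lin_bwd <- function(p, cache, dout) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

.bn_fwd <- function(p, x, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, "*")
    n <- nrow(x)
    upd <- list(run_mean = (1 - momentum) * p$run_mean + momentum * mu,
                run_var = (1 - momentum) * p$run_var +
                  momentum * v * n / max(n - 1, 1))
    list(out = sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+"),
         cache = list(xhat = xhat, xc = xc, inv = inv, n = n), upd = upd)
  } else {
    xhat <- sweep(sweep(x, 2, p$run_mean), 2, 1 / sqrt(p$run_var + eps), "*")
    list(out = sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+"),
         cache = NULL, upd = NULL)
  }
}
.bn_bwd <- function(p, cache, dout) {
  n <- cache$n
  dxhat <- sweep(dout, 2, p$gamma, "*")
  # standard batch-norm backward in terms of xhat
  dx <- sweep(dxhat -
                matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*"),
              2, cache$inv, "*")
  list(dx = dx, grads = list(gamma = colSums(dout * cache$xhat),
                             beta = colSums(dout)))
}

.elu_fwd <- function(x) {
  out <- ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  list(out = out, cache = out)
}
.elu_bwd <- function(cache, dout) dout * ifelse(cache > 0, 1, cache + 1)

.tanh_fwd <- function(x) { out <- tanh(x); list(out = out, cache = out) }
.tanh_bwd <- function(cache, dout) dout * (1 - cache^2)

.drop_fwd <- function(x, p, training) {
  if (!training || p == 0) return(list(out = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}
.drop_bwd <- function(mask, dout) if (is.null(mask)) dout else dout * mask

.l2_fwd <- function(u) {
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm == 0] <- 1
  z <- u / nrm
  list(out = z, cache = list(z = z, nrm = nrm))
}
.l2_bwd <- function(cache, dout) {
  (dout - cache$z * rowSums(dout * cache$z)) / cache$nrm
}

## ---- model ----

#' Initialise a multimodal co-embedding model
#'
#' Two modality branch encoders (dropout, linear, batch-norm, ELU, dropout,
#' linear, batch-norm, tanh), a joint encoder over the concatenated branch
#' outputs (dropout, linear, batch-norm, row-wise L2 normalisation), latent
#' read-out matrices `w_x`, `w_y`, and two three-layer decoders
#' (linear, ELU, linear, tanh, linear) back to the input dimensions.
#'
#' @param input_dim_x,input_dim_y input feature dimensions.
#' @param config a [coembed_config()].
#' @return a `coembed_model` parameter store.
#' @export
init_coembed_model <- function(input_dim_x, input_dim_y, config = coembed_config()) {
  ld <- config$latent_dim; h <- config$branch_hidden_dim
  dh <- config$decoder_hidden_dims
  branch <- function(nin) list(l1 = .lin_init(nin, h), bn1 = .bn_init(h),
                               l2 = .lin_init(h, ld), bn2 = .bn_init(ld))
  decoder <- function(nout) list(l1 = .lin_init(ld, dh[1]),
                                 l2 = .lin_init(dh[1], dh[2]),
                                 l3 = .lin_init(dh[2], nout))
  m <- withr::with_seed(derive_seed(config$seed, 307L), list(
    enc_x = branch(input_dim_x),
    enc_y = branch(input_dim_y),
    joint = list(l = .lin_init(2 * ld, ld), bn = .bn_init(ld)),
    w_x = matrix(rnorm(ld * ld, sd = 1 / sqrt(ld)), ld, ld),
    w_y = matrix(rnorm(ld * ld, sd = 1 / sqrt(ld)), ld, ld),
    dec_x = decoder(input_dim_x),
    dec_y = decoder(input_dim_y)))
  m$config <- config
  class(m) <- "coembed_model"
  m
}

.branch_fwd <- function(p, x, dropout, training) {
  d1 <- .drop_fwd(x, dropout, training)
  l1 <- .lin_fwd(p$l1, d1$out)
  b1 <- .bn_fwd(p$bn1, l1$out, training)
  e1 <- .elu_fwd(b1$out)
  d2 <- .drop_fwd(e1$out, dropout, training)
  l2 <- .lin_fwd(p$l2, d2$out)
  b2 <- .bn_fwd(p$bn2, l2$out, training)
  t2 <- .tanh_fwd(b2$out)
  list(out = t2$out,
       cache = list(d1 = d1, l1 = l1, b1 = b1, e1 = e1, d2 = d2, l2 = l2,
                    b2 = b2, t2 = t2),
       upd = list(bn1 = b1$upd, bn2 = b2$upd))
}
.branch_bwd <- function(p, cache, dout) {
  g <- list()
  d <- .tanh_bwd(cache$t2$cache, dout)
  bb <- .bn_bwd(p$bn2, cache$b2$cache, d); g$bn2 <- bb$grads
  lb <- .lin_bwd(p$l2, cache$l2, bb$dx); g$l2 <- lb$grads
  d <- .drop_bwd(cache$d2$mask, lb$dx)
  d <- .elu_bwd(cache$e1$cache, d)
  bb <- .bn_bwd(p$bn1, cache$b1$cache, d); g$bn1 <- bb$grads
  lb <- .lin_bwd(p$l1, cache$l1, bb$dx); g$l1 <- lb$grads
  list(grads = g)
}

.decoder_fwd <- function(p, c) {
  l1 <- .lin_fwd(p$l1, c)
  e1 <- .elu_fwd(l1$out)
  l2 <- .lin_fwd(p$l2, e1$out)
  t1 <- .tanh_fwd(l2$out)
  l3 <- .lin_fwd(p$l3, t1$out)
  list(out = l3$out, cache = list(l1 = l1, e1 = e1, l2 = l2, t1 = t1, l3 = l3))
}
.decoder_bwd <- function(p, cache, dout) {
  g <- list()
  lb <- .lin_bwd(p$l3, cache$l3, dout); g$l3 <- lb$grads
  d <- .tanh_bwd(cache$t1$cache, lb$dx)
  lb <- .lin_bwd(p$l2, cache$l2, d); g$l2 <- lb$grads
  d <- .elu_bwd(cache$e1$cache, lb$dx)
  lb <- .lin_bwd(p$l1, cache$l1, d); g$l1 <- lb$grads
  list(dx = lb$dx, grads = g)
}

#' Forward pass of the co-embedding model
#'
#' @param model a `coembed_model`.
#' @param x,y numeric matrices (rows = proteins) in the two modalities.
#' @param training logical; when `FALSE`, dropout is off and batch-norm uses
#'   running statistics, making the pass deterministic.
#' @return list with branch outputs `a`, `b` (bounded in (-1, 1)), the
#'   unit-norm joint embedding `z`, reconstructions `xhat`, `yhat`, and
#'   (internal) caches.
#' @export
coembed_forward <- function(model, x, y, training = FALSE) {
  cfg <- model$config
  stopifnot(ncol(x) == nrow(model$enc_x$l1$W), ncol(y) == nrow(model$enc_y$l1$W),
            nrow(x) == nrow(y))
  fx <- .branch_fwd(model$enc_x, x, cfg$dropout, training)
  fy <- .branch_fwd(model$enc_y, y, cfg$dropout, training)
  ab <- cbind(fx$out, fy$out)
  dj <- .drop_fwd(ab, cfg$dropout, training)
  lj <- .lin_fwd(model$joint$l, dj$out)
  bj <- .bn_fwd(model$joint$bn, lj$out, training)
  l2 <- .l2_fwd(bj$out)
  z <- l2$out
  cx <- z %*% model$w_x
  cy <- z %*% model$w_y
  dx <- .decoder_fwd(model$dec_x, cx)
  dy <- .decoder_fwd(model$dec_y, cy)
  list(a = fx$out, b = fy$out, z = z, xhat = dx$out, yhat = dy$out,
       cache = list(fx = fx, fy = fy, dj = dj, lj = lj, bj = bj, l2 = l2,
                    cx = cx, cy = cy, dx = dx, dy = dy))
}

#' Reconstruction loss with decoder-weight regularisation
#'
#' \eqn{R = R_x + R_y + \lambda (\|w_x\|_F + \|w_y\|_F)} where
#' \eqn{R_x = \frac1n \sum_i \|x_i - \hat x_i\|^2}.
#'
#' @param x,xhat,y,yhat inputs and reconstructions (matching shapes).
#' @param w_x,w_y latent read-out matrices.
#' @param lambda_reg regularisation weight.
#' @return non-negative scalar loss.
#' @export
reconstruction_loss <- function(x, xhat, y, yhat, w_x, w_y, lambda_reg = 5) {
  stopifnot(all(dim(x) == dim(xhat)), all(dim(y) == dim(yhat)))
  n <- nrow(x)
  sum((x - xhat)^2) / n + sum((y - yhat)^2) / n +
    lambda_reg * (sqrt(sum(w_x^2)) + sqrt(sum(w_y^2)))
}

# triplet loss + gradient wrt Z for one modality's labels; Z rows unit-norm
.triplet_terms <- function(Z, labels, margin) {
  n <- nrow(Z)
  D <- 1 - tcrossprod(Z)
  G <- matrix(0, n, n)
  total <- 0; m <- 0L
  per_anchor <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- which(labels == labels[i]); pos <- pos[pos != i]
    neg <- which(labels != labels[i])
    if (length(pos) == 0L || length(neg) == 0L) next
    t <- outer(D[i, pos], D[i, neg], function(a, b) a - b) + margin
    act <- t > 0
    m <- m + sum(act)
    total <- total + sum(t[act])
    per_anchor[[i]] <- list(pos = pos, neg = neg, act = act)
  }
  if (m == 0L) return(list(value = 0, dZ = matrix(0, n, ncol(Z))))
  for (i in seq_len(n)) {
    pa <- per_anchor[[i]]
    if (is.null(pa)) next
    cj <- rowSums(pa$act); ck <- colSums(pa$act)
    G[i, pa$pos] <- G[i, pa$pos] + cj / m
    G[i, pa$neg] <- G[i, pa$neg] - ck / m
  }
  # T = sum G[a,b] * (1 - z_a . z_b) + const  =>  dT/dZ = -(G + t(G)) %*% Z
  list(value = total / m, dZ = -(G + t(G)) %*% Z)
}

#' Cluster-driven triplet loss
#'
#' Hinge loss over all (anchor, positive, negative) triples in the batch
#' where positives share the anchor's cluster and negatives do not:
#' \eqn{T = \frac1m \sum \max(D(z_i,z_j) - D(z_i,z_k) + \epsilon, 0)} with
#' D the cosine distance and m the number of strictly positive terms
#' (T = 0 when m = 0).
#'
#' @param z unit-norm embedding matrix.
#' @param labels integer or character cluster label per row.
#' @param margin margin epsilon.
#' @return scalar loss.
#' @export
triplet_loss <- function(z, labels, margin = 0.10) {
  stopifnot(nrow(z) == length(labels), margin > 0)
  .triplet_terms(as.matrix(z), as.integer(factor(labels)), margin)$value
}

#' Assign per-modality cluster labels for the triplet loss
#'
#' Builds a cosine-similarity k-nearest-neighbour graph per modality
#' (negative similarities dropped) and runs Louvain community detection.
#'
#' @param vectors named list of numeric matrices (one per modality, shared
#'   row order).
#' @param knn neighbours per node.
#' @param seed integer seed (Louvain is seed-deterministic).
#' @return named list of integer label vectors, one per modality.
#' @export
assign_triplet_clusters <- function(vectors, knn = 15, seed = 1L) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  lapply(vectors, function(v) {
    v <- as.matrix(v)
    n <- nrow(v)
    if (n < 2) stop("need at least 2 proteins to cluster")
    s <- cosine_similarity_matrix(v)
    diag(s) <- -Inf
    k <- min(knn, n - 1L)
    ei <- integer(0); ej <- integer(0); ew <- numeric(0)
    for (i in seq_len(n)) {
      nb <- order(s[i, ], decreasing = TRUE)[seq_len(k)]
      w <- s[i, nb]
      keep <- w > 0
      ei <- c(ei, rep(i, sum(keep))); ej <- c(ej, nb[keep]); ew <- c(ew, w[keep])
    }
    if (length(ei) == 0L) return(rep(1L, n))  # degenerate: no positive similarity
    lo <- pmin(ei, ej); hi <- pmax(ei, ej)
    key <- paste(lo, hi)
    dup <- duplicated(key)
    g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    cl <- withr::with_seed(derive_seed(seed, 401L),
                           igraph::cluster_louvain(g, weights = ew[!dup]))
    igraph::membership(cl)
  })
}

## ---- Adam over nested parameter lists ----

.flatten_params <- function(m) {
  out <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) out[[path]] <<- x
    else if (is.list(x)) for (nm in names(x))
      if (!nm %in% c("run_mean", "run_var", "config")) walk(x[[nm]], paste(path, nm, sep = "."))
  }
  for (nm in setdiff(names(m), "config")) walk(m[[nm]], nm)
  out
}

.get_path <- function(m, path) {
  for (nm in strsplit(path, ".", fixed = TRUE)[[1]]) m <- m[[nm]]
  m
}
.set_path <- function(m, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- paste0("m[[", paste(sprintf("'%s'", parts), collapse = "]][["), "]] <- value")
  eval(parse(text = expr))
  m
}

.adam_step <- function(model, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (path in names(grads)) {
    g <- grads[[path]]
    if (is.null(state[[path]])) state[[path]] <- list(m = g * 0, v = g * 0)
    st <- state[[path]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[path]] <- st
    mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
    model <- .set_path(model, path, .get_path(model, path) - lr * mh / (sqrt(vh) + eps))
  }
  list(model = model, state = state)
}

## ---- training ----

#' Train the self-supervised multimodal co-embedding
#'
#' Three-phase schedule: (1) reconstruction loss only; (2) full loss
#' \eqn{L = R + \lambda_{triplet}(T_x + T_y)} with cluster labels computed
#' from the raw inputs; (3) full loss with labels recomputed from the
#' current branch outputs (a, b), refreshed every
#' `cluster_refresh_epochs`. The returned embedding is computed in
#' evaluation mode (dropout off, frozen batch-norm statistics).
#'
#' @param fm_x,fm_y aligned `feature_matrix` objects (identical protein
#'   order; see [align_modalities()]).
#' @param config a [coembed_config()].
#' @param verbose print per-phase progress.
#' @return list with `embedding` (a `multimodal_embedding`: `protein_ids`
#'   plus unit-norm matrix `z`), `log` (per-epoch data.frame with R, Tx,
#'   Ty, L), and the trained `model`.
#' @export
train_coembedding <- function(fm_x, fm_y, config = coembed_config(),
                              verbose = FALSE) {
  stopifnot(inherits(fm_x, "feature_matrix"), inherits(fm_y, "feature_matrix"))
  if (!identical(fm_x$protein_ids, fm_y$protein_ids))
    stop("feature matrices are not aligned; run align_modalities() first")
  X <- fm_x$values; Y <- fm_y$values
  n <- nrow(X)
  model <- init_coembed_model(ncol(X), ncol(Y), config)
  state <- list()
  step <- 0L
  phases <- config$phase_epochs
  log_rows <- vector("list", sum(phases))
  epoch_global <- 0L
  labels <- NULL

  recluster <- function(source) {
    if (source == "inputs") {
      assign_triplet_clusters(list(x = X, y = Y), knn = config$knn,
                              seed = derive_seed(config$seed, 997L + epoch_global))
    } else {
      fw <- coembed_forward(model, X, Y, training = FALSE)
      assign_triplet_clusters(list(x = fw$a, y = fw$b), knn = config$knn,
                              seed = derive_seed(config$seed, 997L + epoch_global))
    }
  }

  withr::with_seed(derive_seed(config$seed, 509L), {
    for (phase in 1:3) {
      if (phases[phase] == 0L) next
      if (phase == 2L) labels <- recluster("inputs")
      for (ep in seq_len(phases[phase])) {
        epoch_global <- epoch_global + 1L
        if (phase == 3L && ((ep - 1L) %% config$cluster_refresh_epochs == 0L))
          labels <- recluster("branch")
        ord <- sample.int(n)
        nb <- ceiling(n / config$batch_size)
        eR <- eTx <- eTy <- eL <- 0
        for (bi in seq_len(nb)) {
          idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
          if (length(idx) < 2L) next  # batch-norm needs >= 2 rows
          xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
          fw <- coembed_forward(model, xb, yb, training = TRUE)
          nbatch <- length(idx)

          ## losses
          nfx <- sqrt(sum(model$w_x^2)); nfy <- sqrt(sum(model$w_y^2))
          R <- sum((xb - fw$xhat)^2) / nbatch + sum((yb - fw$yhat)^2) / nbatch +
            config$lambda_reg * (nfx + nfy)
          use_triplet <- phase >= 2L
          if (use_triplet) {
            tx <- .triplet_terms(fw$z, as.integer(labels$x[idx]), config$margin)
            ty <- .triplet_terms(fw$z, as.integer(labels$y[idx]), config$margin)
          } else {
            tx <- ty <- list(value = 0, dZ = 0)
          }
          L <- R + config$lambda_triplet * (tx$value + ty$value)
          if (!is.finite(L)) stop(sprintf("non-finite loss at epoch %d", epoch_global))

          ## backward
          dxh <- 2 * (fw$xhat - xb) / nbatch
          dyh <- 2 * (fw$yhat - yb) / nbatch
          gdx <- .decoder_bwd(model$dec_x, fw$cache$dx$cache, dxh)
          gdy <- .decoder_bwd(model$dec_y, fw$cache$dy$cache, dyh)
          dcx <- gdx$dx; dcy <- gdy$dx
          gwx <- crossprod(fw$z, dcx) +
            (if (nfx > 0) config$lambda_reg * model$w_x / nfx else 0)
          gwy <- crossprod(fw$z, dcy) +
            (if (nfy > 0) config$lambda_reg * model$w_y / nfy else 0)
          dz <- dcx %*% t(model$w_x) + dcy %*% t(model$w_y)
          if (use_triplet && config$lambda_triplet > 0)
            dz <- dz + config$lambda_triplet * (tx$dZ + ty$dZ)
          du <- .l2_bwd(fw$cache$l2$cache, dz)
          gb <- .bn_bwd(model$joint$bn, fw$cache$bj$cache, du)
          gl <- .lin_bwd(model$joint$l, fw$cache$lj, gb$dx)
          dab <- .drop_bwd(fw$cache$dj$mask, gl$dx)
          ld <- model$config$latent_dim
          gx <- .branch_bwd(model$enc_x, fw$cache$fx$cache,
                            dab[, seq_len(ld), drop = FALSE])
          gy <- .branch_bwd(model$enc_y, fw$cache$fy$cache,
                            dab[, ld + seq_len(ld), drop = FALSE])

          grads <- list()
          for (nm in names(gx$grads)) for (pp in names(gx$grads[[nm]]))
            grads[[paste("enc_x", nm, pp, sep = ".")]] <- gx$grads[[nm]][[pp]]
          for (nm in names(gy$grads)) for (pp in names(gy$grads[[nm]]))
            grads[[paste("enc_y", nm, pp, sep = ".")]] <- gy$grads[[nm]][[pp]]
          for (pp in names(gl$grads))
            grads[[paste("joint.l", pp, sep = ".")]] <- gl$grads[[pp]]
          for (pp in names(gb$grads))
            grads[[paste("joint.bn", pp, sep = ".")]] <- gb$grads[[pp]]
          grads[["w_x"]] <- gwx; grads[["w_y"]] <- gwy
          for (nm in names(gdx$grads)) for (pp in names(gdx$grads[[nm]]))
            grads[[paste("dec_x", nm, pp, sep = ".")]] <- gdx$grads[[nm]][[pp]]
          for (nm in names(gdy$grads)) for (pp in names(gdy$grads[[nm]]))
            grads[[paste("dec_y", nm, pp, sep = ".")]] <- gdy$grads[[nm]][[pp]]

          ## running batch-norm statistics
          for (br in c("fx", "fy")) {
            tgt <- if (br == "fx") "enc_x" else "enc_y"
            for (bn in c("bn1", "bn2")) {
              u <- fw$cache[[br]]$upd[[bn]]
              model[[tgt]][[bn]]$run_mean <- u$run_mean
              model[[tgt]][[bn]]$run_var <- u$run_var
            }
          }
          model$joint$bn$run_mean <- fw$cache$bj$upd$run_mean
          model$joint$bn$run_var <- fw$cache$bj$upd$run_var

          step <- step + 1L
          up <- .adam_step(model, grads, state, config$learning_rate, step)
          model <- up$model; state <- up$state

          eR <- eR + R; eTx <- eTx + tx$value; eTy <- eTy + ty$value; eL <- eL + L
        }
        log_rows[[epoch_global]] <- data.frame(
          epoch = epoch_global, phase = phase,
          R = eR / nb, Tx = eTx / nb, Ty = eTy / nb, L = eL / nb)
        if (verbose && epoch_global %% 25 == 0)
          message(sprintf("epoch %d (phase %d): L=%.4f R=%.4f",
                          epoch_global, phase, eL / nb, eR / nb))
      }
    }
  })

  fw <- coembed_forward(model, X, Y, training = FALSE)
  z <- fw$z
  rownames(z) <- fm_x$protein_ids
  emb <- structure(list(protein_ids = fm_x$protein_ids, z = z),
                   class = "multimodal_embedding")
  list(embedding = emb, log = do.call(rbind, log_rows), model = model)
}

#' @export
print.multimodal_embedding <- function(x, ...) {
  cat(sprintf("multimodal_embedding: %d proteins x %d dims (unit-norm rows)\n",
              length(x$protein_ids), ncol(x$z)))
  invisible(x)
}
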