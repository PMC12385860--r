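# Shared fixtures and independent oracles. Expensive objects (phantoms,
# trained ensembles) are built once per test run and cached in-session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

plain_phantom <- function() {
  cached("plain", generate_phantom(default_spec("small")))
}

gapped_phantom <- function() {
  cached("gapped", generate_phantom(default_spec(
    "small",
    gaps = list(list(side = "left", start_fraction = 0.45,
                     length_mm = 15)))))
}

double_gap_phantom <- function() {
  cached("double_gap", generate_phantom(default_spec(
    "small",
    gaps = list(list(side = "left", start_fraction = 0.45,
                     length_mm = 15),
                list(side = "right", start_fraction = 0.6,
                     length_mm = 20)))))
}

lesion_phantom <- function() {
  cached("lesion", generate_phantom(default_spec(
    "small",
    gaps = list(list(side = "left", start_fraction = 0.5,
                     length_mm = 12)),
    lesions = list(list(center = c(30, 40, 90), radius_mm = 6, hu = 80)))))
}

# 4 training phantoms with jittered anatomy and independent noise; the
# ensemble used by the segmenter unit tests and the overfit acceptance
# check. With 2 folds, each phantom is also held out from one fold's
# model, which the generalization test exploits.
training_phantoms <- function() {
  cached("train4", lapply(1:4, function(i) {
    ph <- generate_phantom(perturb_spec(default_spec("small", seed = i),
                                        seed = 500 + i))
    list(image = ph$ctu, labels = ph$truth)
  }))
}

overfit_ensemble <- function() {
  cached("ens4", train_cross_validation(training_phantoms(),
                                        unet_config("small"), seed = 42))
}

# an untrained single-model "ensemble" for inference-mechanics tests
random_ensemble <- function(config = unet_config("small"), n_models = 1,
                            seed = 5) {
  models <- lapply(seq_len(n_models), function(i)
    list(weights = focusctu:::unet_init(config, seed = seed + i),
         best_epoch = 0L, best_val_loss = NA_real_))
  structure(list(models = models, fold_assignment = integer(),
                 config = config, seed = seed),
            class = "trained_ensemble")
}

# ---- independent oracles ----------------------------------------------

# brute-force mm-spherical dilation: for every voxel, scan every
# foreground voxel and threshold the exact Euclidean distance
brute_force_dilation <- function(mask, radius_mm, spacing) {
  d <- dim(mask)
  idx <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(idx - 1, 2, spacing, "*")
  fg <- mm[as.vector(mask), , drop = FALSE]
  out <- logical(prod(d))
  for (v in seq_len(prod(d))) {
    dv <- sweep(fg, 2, mm[v, ], "-")
    out[v] <- any(rowSums(dv^2) <= radius_mm^2 + 1e-9)
  }
  array(out, dim = d)
}

# connected components through igraph (independent of the package's BFS):
# build the voxel adjacency graph and take its components
igraph_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lin <- which(mask)
  ind <- arrayInd(lin, d)
  id_of <- integer(prod(d))
  id_of[lin] <- seq_along(lin)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ind, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1 + d[2] * (nb[ok, 3] - 1))
    tgt <- id_of[nlin]
    src <- which(ok)[tgt > 0]
    edges[[r]] <- cbind(src, tgt[tgt > 0])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(unique(t(apply(e, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  comp <- igraph::components(g)
  membership <- integer(prod(d))
  membership[lin] <- as.integer(comp$membership)
  list(n = as.integer(comp$no), membership = array(membership, dim = d))
}

# exhaustive nearest pair between two mm point sets (plain R)
brute_force_nearest <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    dv <- sweep(b, 2, a[i, ], "-")
    dd <- rowSums(dv^2)
    j <- which.min(dd)
    if (dd[j] < best) {
      best <- dd[j]
      pair <- c(i, j)
    }
  }
  list(i = pair[1], j = pair[2], distance = sqrt(best))
}

deviation_from <- function(recovered, truth, volume) {
  err <- compose_transforms(recovered, invert_transform(truth))
  d <- dim(volume$voxels)
  center <- volume$origin + (d - 1) * volume$spacing / 2
  focusctu:::transform_deviation(err, center)
}
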