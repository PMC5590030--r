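# Seeded bagged-CART ensemble (random forest) for voxel classification.
# The pre-installed R stack has no forest package, so a compact one lives
# here: bootstrap-sampled trees, gini splits over a random feature subset per
# node, quantile candidate thresholds, probability = mean of tree votes.
# Deterministic given its seed.

rf_grow_tree <- function(X, y, mtry, max_depth, min_node, n_cand = 8L) {
  feat <- integer(0); thr <- numeric(0); left <- integer(0)
  right <- integer(0); prob <- numeric(0); leaf <- logical(0)
  new_node <- function() {
    feat[[length(feat) + 1L]] <<- 0L
    thr[[length(thr) + 1L]] <<- NA_real_
    left[[length(left) + 1L]] <<- 0L
    right[[length(right) + 1L]] <<- 0L
    prob[[length(prob) + 1L]] <<- NA_real_
    leaf[[length(leaf) + 1L]] <<- TRUE
    length(feat)
  }
  p <- ncol(X)
  root <- new_node()
  stack <- list(list(id = root, rows = seq_len(nrow(X)), depth = 0L))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rows <- nd$rows
    ynode <- y[rows]
    pnode <- mean(ynode)
    prob[nd$id] <- pnode
    if (nd$depth >= max_depth || length(rows) < 2L * min_node ||
        pnode == 0 || pnode == 1) next
    feats <- sample.int(p, min(mtry, p))
    best <- list(score = Inf)
    for (f in feats) {
      x <- X[rows, f]
      cands <- unique(stats::quantile(x, probs = seq(0.1, 0.9, length.out =
                                                       n_cand), names = FALSE))
      for (cc in cands) {
        lmask <- x <= cc
        nl <- sum(lmask); nr <- length(rows) - nl
        if (nl < min_node || nr < min_node) next
        pl <- mean(ynode[lmask]); pr <- mean(ynode[!lmask])
        score <- nl * pl * (1 - pl) + nr * pr * (1 - pr)
        if (score < best$score)
          best <- list(score = score, f = f, thr = cc, lmask = lmask)
      }
    }
    if (!is.finite(best$score)) next
    lid <- new_node(); rid <- new_node()
    feat[nd$id] <- best$f
    thr[nd$id] <- best$thr
    left[nd$id] <- lid
    right[nd$id] <- rid
    leaf[nd$id] <- FALSE
    stack[[length(stack) + 1L]] <- list(id = lid, rows = rows[best$lmask],
                                        depth = nd$depth + 1L)
    stack[[length(stack) + 1L]] <- list(id = rid, rows = rows[!best$lmask],
                                        depth = nd$depth + 1L)
  }
  list(feat = feat, thr = thr, left = left, right = right,
       prob = prob, leaf = leaf)
}

rf_train <- function(X, y, n_trees = 100L, mtry = NULL, max_depth = 10L,
                     min_node = 5L, max_sample = 5000L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("training table must contain both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", n_trees)
  n <- nrow(X)
  nboot <- min(n, max_sample)
  for (t in seq_len(n_trees)) {
    trees[[t]] <- with_seed(derive_seed(seed, t), {
      rows <- sample.int(n, nboot, replace = TRUE)
      rf_grow_tree(X[rows, , drop = FALSE], y[rows], mtry, max_depth,
                   min_node)
    })
  }
  structure(list(trees = trees, n_features = ncol(X), n_trees = n_trees,
                 seed = seed), class = "rf_model")
}

rf_predict <- function(model, X) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature mismatch: model expects ", model$n_features,
         " features, got ", ncol(X))
  n <- nrow(X)
  acc <- numeric(n)
  for (tree in model$trees) {
    node <- rep(1L, n)
    repeat {
      active <- which(!tree$leaf[node])
      if (!length(active)) break
      nids <- node[active]
      go_left <- X[cbind(active, tree$feat[nids])] <= tree$thr[nids]
      node[active] <- ifelse(go_left, tree$left[nids], tree$right[nids])
    }
    acc <- acc + tree$prob[node]
  }
  acc / length(model$trees)
}
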