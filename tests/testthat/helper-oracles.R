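# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorised implementations.

# per-label mean intensity by an explicit double loop over pixels
oracle_label_means <- function(label, channel) {
  ids <- sort(unique(label[label > 0]))
  out <- numeric(length(ids))
  for (k in seq_along(ids)) {
    tot <- 0; cnt <- 0
    for (r in seq_len(nrow(label))) for (c in seq_len(ncol(label))) {
      if (label[r, c] == ids[k]) { tot <- tot + channel[r, c]; cnt <- cnt + 1 }
    }
    out[k] <- tot / cnt
  }
  names(out) <- ids
  out
}

# adjacency by scanning every pixel pair within the 8-neighbourhood
oracle_adjacency <- function(label, min_shared = 3) {
  H <- nrow(label); W <- ncol(label)
  cnt <- list()
  for (r in seq_len(H)) for (c in seq_len(W)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      a <- label[r, c]; b <- label[r2, c2]
      if (a > 0 && b > 0 && a != b) {
        key <- paste(min(a, b), max(a, b))
        cnt[[key]] <- (cnt[[key]] %||% 0) + 1
      }
    }
  }
  # every unordered pixel pair was visited twice (once per orientation)
  keys <- names(cnt)[vapply(cnt, function(v) v / 2 >= min_shared, logical(1))]
  if (length(keys) == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  ft <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(from = as.integer(ft[, 1]), to = as.integer(ft[, 2]))
  out[order(out$from, out$to), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest-path (BFS) distances from a focal vertex over an edge list
oracle_bfs_dist <- function(edges, ids, focal) {
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  dist[as.character(focal)] <- 0
  frontier <- focal
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      nb <- nb[is.infinite(dist[as.character(nb)])]
      dist[as.character(nb)] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# neighbour differentiation rate by direct enumeration
oracle_neighbor_rate <- function(records, edges) {
  focal <- records$cell_id[records$transfected & records$hucd]
  seen <- integer(0)
  for (f in focal) {
    nb <- c(edges$to[edges$from == f], edges$from[edges$to == f])
    seen <- union(seen, nb)
  }
  info <- records[records$cell_id %in% seen & !records$transfected, ]
  sum(info$hucd) / nrow(info)
}

# Mann-Whitney U of sample a vs b by direct pair counting
oracle_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# random labelled mosaic for oracle tests: nearest-seed tessellation
random_test_mosaic <- function(n_cells, H = 40, W = 40, seed = 1) {
  withr::with_seed(seed, {
    sx <- runif(n_cells, 0, W - 1); sy <- runif(n_cells, 0, H - 1)
    px <- rep(0:(W - 1), each = H); py <- rep(0:(H - 1), times = W)
    lab <- integer(H * W)
    best <- rep(Inf, H * W)
    for (s in seq_len(n_cells)) {
      d <- (px - sx[s])^2 + (py - sy[s])^2
      upd <- d < best; best[upd] <- d[upd]; lab[upd] <- s
    }
    list(label = matrix(lab, H, W), sx = sx, sy = sy)
  })
}
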