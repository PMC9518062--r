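# Independent oracles used to check package results.  These deliberately
# re-derive quantities by brute force / textbook algorithms and never call
# the implementation they verify.

# -- textbook single-source Dijkstra on the 8-neighbour resistance grid ----
# step cost = mean(resistance of the two cells) * step length.
dijkstra_oracle <- function(resist, cell_size, src_rc, dst_rc = NULL) {
  nr <- nrow(resist); nc <- ncol(resist)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[src_rc[1L], src_rc[2L]] <- 0
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1); dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    r <- ((u - 1L) %% nr) + 1L; c <- ((u - 1L) %/% nr) + 1L
    if (!is.null(dst_rc) && r == dst_rc[1L] && c == dst_rc[2L]) break
    for (k in 1:8) {
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      step <- if (dr[k] != 0 && dc[k] != 0) sqrt(2) * cell_size else cell_size
      w <- (resist[r, c] + resist[r2, c2]) / 2 * step
      if (dist[r, c] + w < dist[r2, c2]) dist[r2, c2] <- dist[r, c] + w
    }
  }
  dist
}

# -- BFS hop counts between patches on a link matrix -----------------------
bfs_hops_oracle <- function(linked) {
  n <- nrow(linked)
  l <- matrix(Inf, n, n); diag(l) <- 0
  for (s in seq_len(n)) {
    frontier <- s; hop <- 0
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(frontier)) {
      hop <- hop + 1
      nxt <- integer(0)
      for (v in frontier) for (w in which(linked[v, ])) {
        if (!seen[w]) { seen[w] <- TRUE; l[s, w] <- hop; nxt <- c(nxt, w) }
      }
      frontier <- nxt
    }
  }
  l
}

# -- maximum product probability by exhaustive simple-path enumeration -----
pstar_oracle <- function(linked, p) {
  n <- nrow(linked)
  best <- matrix(0, n, n); diag(best) <- 1
  recurse <- function(path, prob, target) {
    v <- path[length(path)]
    if (v == target) {
      i <- path[1L]
      if (prob > best[i, target]) best[i, target] <<- prob
      return()
    }
    for (w in which(linked[v, ])) {
      if (!(w %in% path)) recurse(c(path, w), prob * p[v, w], target)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) recurse(i, 1, j)
  best
}

iic_oracle <- function(areas, linked, A_L) {
  l <- bfs_hops_oracle(linked)
  s <- 0
  for (i in seq_along(areas)) for (j in seq_along(areas))
    if (is.finite(l[i, j])) s <- s + areas[i] * areas[j] / (1 + l[i, j])
  s / A_L^2
}

pc_oracle <- function(areas, linked, p, A_L) {
  ps <- pstar_oracle(linked, p)
  s <- 0
  for (i in seq_along(areas)) for (j in seq_along(areas))
    s <- s + areas[i] * areas[j] * ps[i, j]
  s / A_L^2
}

# -- recursive flood fill component count ----------------------------------
flood_fill_count <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  dr <- if (connectivity == 8L) c(0, 1, 1, 1, 0, -1, -1, -1) else c(0, 1, 0, -1)
  dc <- if (connectivity == 8L) c(1, 1, 0, -1, -1, -1, 0, 1) else c(1, 0, -1, 0)
  n <- 0L
  for (start in which(mask == 1 & lab == 0L)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- c + dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          idx <- (c2 - 1L) * nr + r2
          if (mask[idx] == 1 && lab[idx] == 0L) { lab[idx] <- n; queue <- c(queue, idx) }
        }
      }
    }
  }
  list(n = n, labels = lab)
}

# -- Moran's I (queen contiguity, row-standardised weights omitted) --------
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- m - mean(m)
  num <- 0; wsum <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    c0 <- c1 - dc
    num <- num + sum(x[r0, c0] * x[r1, c1])
    wsum <- wsum + length(r0) * length(c0)
  }
  (nr * nc / wsum) * num / sum(x^2)
}

# random patch graphs for index oracles: areas + symmetric distances
random_graph_case <- function(n, seed) {
  set.seed(seed)
  areas <- runif(n, 1, 20)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  list(areas = areas, d = d,
       ps = list(patches = lapply(areas, function(a) list(area = a))))
}
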