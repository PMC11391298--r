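# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Forward Euler integration of the Lotka-Volterra diffuse-competition system
# dN_f/dt = N_f (r_f - a_ff N_f - a_fh_f sum_{k != f} N_k), run to a steady
# state (|dN| < tol). Excluded species decay towards zero.
lv_integrate <- function(r, alpha_fh, alpha_ff, n0 = NULL, dt = 4,
                         tol = 1e-12, max_steps = 1e6) {
  k <- length(r)
  n <- if (is.null(n0)) rep(0.05, k) else n0
  for (i in seq_len(max_steps)) {
    tot <- sum(n)
    dn <- n * (r - alpha_ff * n - alpha_fh * (tot - n)) * dt
    n <- pmax(0, n + dn)
    if (max(abs(dn)) < tol) break
  }
  n
}

# All-pairs least-cost by Floyd-Warshall over an explicit edge list; an
# algorithm independent of the Dijkstra path used by the package.
floyd_warshall <- function(n_nodes, from, to, w) {
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (i in seq_along(from)) {
    d[from[i], to[i]] <- min(d[from[i], to[i]], w[i])
    d[to[i], from[i]] <- min(d[to[i], from[i]], w[i])
  }
  for (k in seq_len(n_nodes)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# 8-neighbour edge list of a small grid with the resistance-cost rule,
# written out longhand for the oracle.
oracle_grid_edges <- function(elev, suit) {
  nx <- nrow(elev); ny <- ncol(elev)
  from <- c(); to <- c(); w <- c()
  for (x in 1:nx) for (y in 1:ny) {
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      x2 <- x + dx; y2 <- y + dy
      if (x2 < 1 || x2 > nx || y2 < 1 || y2 > ny) next
      i <- x + (y - 1) * nx; j <- x2 + (y2 - 1) * nx
      if (i >= j) next
      len <- sqrt(dx^2 + dy^2)
      cost <- if (suit[x, y] && suit[x2, y2]) {
        len + 0.1 * abs(elev[x, y] - elev[x2, y2]) / 100
      } else 4 * len
      from <- c(from, i); to <- c(to, j); w <- c(w, cost)
    }
  }
  list(from = from, to = to, w = w)
}

# flood-fill connected components (8-neighbour) of a logical matrix
flood_fill_labels <- function(suit) {
  nx <- nrow(suit); ny <- ncol(suit)
  lab <- matrix(NA_integer_, nx, ny)
  cur <- 0L
  for (sx in 1:nx) for (sy in 1:ny) {
    if (!suit[sx, sy] || !is.na(lab[sx, sy])) next
    cur <- cur + 1L
    queue <- list(c(sx, sy))
    lab[sx, sy] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) {
        x2 <- p[1] + dx; y2 <- p[2] + dy
        if (x2 < 1 || x2 > nx || y2 < 1 || y2 > ny) next
        if (suit[x2, y2] && is.na(lab[x2, y2])) {
          lab[x2, y2] <- cur
          queue[[length(queue) + 1]] <- c(x2, y2)
        }
      }
    }
  }
  lab
}

# shared desk-scale landscape, built once per test session
desk_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_landscape(desk_landscape_config())
    cache
  }
})

# a small fast landscape for engine-level unit tests (same geometry rules,
# fewer steps)
mini_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_landscape(desk_landscape_config(n_steps = 61L))
    }
    cache
  }
})
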