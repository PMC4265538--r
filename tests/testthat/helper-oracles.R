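# Independent oracles used to cross-check the implementation.  Each is a
# deliberately naive formulation, kept free of the package's own code paths.

# exhaustive Otsu: between-class variance of every split, computed by
# direct sums (no cumulative-sum shortcuts)
brute_otsu <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  bins <- 0:255
  sigma_b <- rep(-Inf, 256)
  for (t in 0:254) {  # t = 255 leaves the upper class empty: no valid split
    w0 <- sum(p[seq_len(t + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[seq_len(t + 1)] * bins[seq_len(t + 1)]) / w0
    mu1 <- sum(p[seq.int(t + 2, 256)] * bins[seq.int(t + 2, 256)]) / w1
    sigma_b[t + 1] <- w0 * w1 * (mu0 - mu1)^2
  }
  sigma_b
}

# flood-fill connected components with an explicit preallocated stack;
# returns a list of sorted pixel-index vectors ordered by smallest index
flood_fill_components <- function(map, connectivity) {
  h <- nrow(map)
  w <- ncol(map)
  n <- h * w
  dr <- if (connectivity == 4) c(-1L, 1L, 0L, 0L) else
    c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- if (connectivity == 4) c(0L, 0L, -1L, 1L) else
    c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  seen <- rep(FALSE, n)
  stack <- integer(n)
  members <- integer(n)
  comps <- list()
  for (start in which(as.vector(map))) {
    if (seen[start]) next
    seen[start] <- TRUE
    stack[1L] <- start
    top <- 1L
    cnt <- 0L
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      cnt <- cnt + 1L
      members[cnt] <- p
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      for (k in seq_along(dr)) {
        qr <- pr + dr[k]
        qc <- pc + dc[k]
        if (qr >= 1L && qr <= h && qc >= 1L && qc <= w) {
          q <- (qc - 1L) * h + qr
          if (map[q] && !seen[q]) {
            seen[q] <- TRUE
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members[seq_len(cnt)])
  }
  comps[order(vapply(comps, function(x) x[1], integer(1)))]
}

# canonical pixel-index form of find_components() output, for comparison
# against the oracle above
component_indices <- function(comps, h) {
  out <- lapply(comps, function(co) {
    sort(as.integer(unname((co$pixels[, 2] - 1L) * h + co$pixels[, 1])))
  })
  out[order(vapply(out, function(x) x[1], integer(1)))]
}

# exhaustive single-linkage agglomeration: repeatedly merge the pair of
# clusters with the smallest nearest-neighbour distance
single_linkage_oracle <- function(x, k) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(stats::dist(x))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  assign <- integer(n)
  for (i in seq_along(clusters)) assign[clusters[[i]]] <- i
  assign
}

# border-replicating shift used to enumerate boundary pixels by hand
shift_oracle <- function(m, dr, dc) {
  h <- nrow(m)
  w <- ncol(m)
  out <- m
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      out[r, c] <- m[min(max(r + dr, 1), h), min(max(c + dc, 1), w)]
    }
  }
  out
}

# are two flat clusterings the same partition (up to label permutation)?
same_partition <- function(a, b) {
  ka <- split(seq_along(a), a)
  kb <- split(seq_along(b), b)
  canon <- function(k) {
    k <- lapply(k, sort)
    k[order(vapply(k, min, numeric(1)))]
  }
  identical(unname(canon(ka)), unname(canon(kb)))
}
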