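# Independent oracles used by the tests. These deliberately share no code
# with the package implementation.

# Connected components by iterative label propagation: every foreground
# pixel starts with a unique label; repeatedly replace each label by the
# minimum over its neighborhood until a fixed point. Returns a partition
# as a canonical integer matrix (labels renumbered by first occurrence in
# column-major order, which is enough to compare partitions).
floodfill_oracle <- function(binary, connectivity) {
  H <- nrow(binary); W <- ncol(binary)
  lab <- matrix(0L, H, W)
  lab[binary] <- seq_len(sum(binary))
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, H, W)
    r_src <- max(1, 1 - dr):min(H, H - dr)
    c_src <- max(1, 1 - dc):min(W, W - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  cur <- ifelse(binary, lab, Inf)
  repeat {
    nxt <- cur
    for (o in offs) nxt <- pmin(nxt, shift(cur, o[1], o[2]))
    nxt[!binary] <- Inf
    nxt <- pmin(cur, nxt)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- matrix(0L, H, W)
  vals <- cur[binary]
  out[binary] <- as.integer(factor(vals, levels = unique(vals[order(which(binary))])))
  # renumber canonically by first occurrence in column-major order
  idx <- which(binary)
  first <- tapply(idx, out[idx], min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  out[idx] <- remap[out[idx]]
  out
}

# Canonical renumbering of a label matrix by first occurrence (column-major),
# for comparing partitions regardless of label order conventions.
canon_labels <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(lab)
  first <- tapply(idx, lab[idx], min)
  remap <- integer(max(lab))
  remap[as.integer(names(first))[order(first)]] <- seq_along(first)
  lab[idx] <- remap[lab[idx]]
  lab
}

# Exhaustive optimal 1-D clustering: enumerate all contiguous partitions of
# the sorted values into k groups and take the one minimizing within-group
# sum of squares (optimal 1-D clusters are contiguous in sorted order).
partition_oracle <- function(values, k) {
  n <- length(values)
  ord <- order(values)
  s <- values[ord]
  best <- NULL; best_sse <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  if (k == 1) cuts <- matrix(integer(0), nrow = 0, ncol = 1)
  for (ci in seq_len(ncol(cuts))) {
    bnd <- c(0, cuts[, ci], n)
    sse <- 0
    g <- integer(n)
    for (j in seq_len(k)) {
      span <- (bnd[j] + 1):bnd[j + 1]
      sse <- sse + sum((s[span] - mean(s[span]))^2)
      g[span] <- j - 1L
    }
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- g }
  }
  assignment <- integer(n)
  assignment[ord] <- best
  list(assignment = assignment, sse = best_sse)
}

# Brute-force one-to-one matching by permutation enumeration (small n):
# maximize matched count within radius, then minimize total distance.
match_oracle <- function(truth, det, max_dist) {
  nt <- nrow(truth); nd <- nrow(det)
  dist <- sqrt(outer(truth$x_px, det$x_px, "-")^2 +
               outer(truth$y_px, det$y_px, "-")^2)
  if (nt > nd) stop("oracle expects nt <= nd")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best_n <- -1L; best_d <- Inf
  for (p in perms(seq_len(nd))) {
    sel <- p[seq_len(nt)]
    ok <- dist[cbind(seq_len(nt), sel)] <= max_dist
    nmatch <- sum(ok)
    dtot <- sum(dist[cbind(seq_len(nt), sel)][ok])
    if (nmatch > best_n || (nmatch == best_n && dtot < best_d - 1e-12)) {
      best_n <- nmatch; best_d <- dtot
    }
  }
  list(n_matched = best_n, total_dist = best_d)
}
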