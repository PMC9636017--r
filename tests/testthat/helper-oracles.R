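# Independent oracles, deliberately written with a different structure
# than the package implementation.

# rule-list oracle for the placement-combination score: straight-line
# scalar code following the published rule list term by term
score_oracle <- function(placements, domains, resolution, params,
                         inter_domain_gaps = NULL) {
  n <- length(domains)
  placed_idx <- c()
  for (i in seq_len(n)) if (!is.null(placements[[i]])) placed_idx <- c(placed_idx, i)
  ccs <- c()
  for (i in placed_idx) ccs <- c(ccs, placements[[i]]$cc)
  score <- 0
  # transformed CA sets of the placed domains
  pc <- list()
  for (k in seq_along(placed_idx)) {
    i <- placed_idx[k]
    ca <- model_ca(domains[[i]])
    ca <- ca[!is.na(ca[, 1]), , drop = FALSE]
    tr <- placements[[i]]$transform
    pc[[k]] <- sweep(ca %*% t(tr$rotation), 2, -tr$translation)
  }
  # similarity of each placed transform to the first placed one
  sim <- rep(TRUE, length(placed_idx))
  if (length(placed_idx) >= 1) {
    t1 <- placements[[placed_idx[1]]]$transform
    for (k in seq_along(placed_idx)) {
      tk <- placements[[placed_idx[k]]]$transform
      worst <- 0
      for (i in placed_idx) {
        ca <- model_ca(domains[[i]])
        ca <- ca[!is.na(ca[, 1]), , drop = FALSE]
        a <- sweep(ca %*% t(t1$rotation), 2, -t1$translation)
        b <- sweep(ca %*% t(tk$rotation), 2, -tk$translation)
        worst <- max(worst, sqrt(mean(rowSums((a - b)^2))))
      }
      sim[k] <- worst <= resolution
    }
  }
  # overlapping CA count across placed domains
  n_ca <- 0; n_ov <- 0
  for (k in seq_along(pc)) {
    n_ca <- n_ca + nrow(pc[[k]])
    for (a in seq_len(nrow(pc[[k]]))) {
      hit <- FALSE
      for (k2 in seq_along(pc)) {
        if (k2 == k) next
        for (b in seq_len(nrow(pc[[k2]]))) {
          if (sum((pc[[k]][a, ] - pc[[k2]][b, ])^2) <=
                params$overlap_ca_ca_distance^2) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) n_ov <- n_ov + 1
    }
  }
  frac_ov <- if (n_ca > 0) n_ov / n_ca else 0
  # connectivity between sequence-consecutive placed domains
  allowed_sum <- 0; dev_sum <- 0; spannable <- TRUE; big <- FALSE
  if (length(placed_idx) >= 2) {
    for (k in 1:(length(placed_idx) - 1)) {
      i <- placed_idx[k]; j <- placed_idx[k + 1]
      gap <- if (!is.null(inter_domain_gaps)) sum(inter_domain_gaps[i:(j - 1)])
             else min(model_resno(domains[[j]])) - max(model_resno(domains[[i]])) - 1
      allowed <- 3.8 * (gap + 1)
      endi <- pc[[k]][nrow(pc[[k]]), ]
      startj <- pc[[k + 1]][1, ]
      dist <- sqrt(sum((endi - startj)^2))
      allowed_sum <- allowed_sum + allowed
      if (dist > allowed + 1e-9) {
        spannable <- FALSE
        dev_sum <- dev_sum + dist - allowed - 1e-9
      }
      if (dist > allowed + 2 * resolution +
            params$maximum_connectivity_deviation + 1e-9)
        big <- TRUE
    }
  }
  gate <- length(placed_idx) > 0 && min(ccs) >= params$minimum_docking_cc
  if (gate) {
    c1 <- min(ccs) > params$acceptable_docking_cc
    if (c1) score <- score + 200
    if (c1 && all(sim) && length(placed_idx) >= 2) score <- score + 200
    if (length(placed_idx) == n) score <- score + 200
    if (frac_ov < params$allowed_fraction_overlapping) score <- score + 200
    if (spannable) score <- score + 200
  }
  if (big) score <- score - 200
  if (length(placed_idx) > 0) {
    score <- score + min(ccs) + mean(ccs)
    score <- score - sum(!sim) / length(placed_idx)
  }
  score <- score - frac_ov
  if (allowed_sum > 0) score <- score - dev_sum / allowed_sum
  score
}

# bottleneck (widest-path) oracle: Dijkstra-style search maximizing the
# minimum grid value along the path, on the 26-connected voxel graph
widest_path_oracle <- function(grid, s_ijk, e_ijk) {
  d <- dim(grid)
  lin <- function(ijk) ijk[1] + (ijk[2] - 1) * d[1] + (ijk[3] - 1) * d[1] * d[2]
  s <- lin(s_ijk); e <- lin(e_ijk)
  if (grid[s] <= 0 || grid[e] <= 0) return(NA_real_)
  best <- rep(-Inf, prod(d))
  best[s] <- grid[s]
  visited <- rep(FALSE, prod(d))
  repeat {
    u <- which.max(replace(best, visited, -Inf))
    if (visited[u] || best[u] == -Inf) return(NA_real_)
    if (u == e) return(best[e])
    visited[u] <- TRUE
    ui <- arrayInd(u, d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      vi <- ui[1] + di; vj <- ui[2] + dj; vk <- ui[3] + dk
      if (vi < 1 || vi > d[1] || vj < 1 || vj > d[2] || vk < 1 || vk > d[3]) next
      v <- lin(c(vi, vj, vk))
      if (grid[v] <= 0) next
      cand <- min(best[u], grid[v])
      if (cand > best[v]) best[v] <- cand
    }
  }
}

# random placement combos over synthetic two-to-four domain systems
random_combo_case <- function() {
  n_dom <- sample(2:4, 1)
  base <- 0
  res0 <- 0L
  domains <- list()
  for (i in seq_len(n_dom)) {
    len <- sample(5:12, 1)
    ca <- cbind(base + seq_len(len) * 3.8, rnorm(len), rnorm(len))
    domains[[i]] <- model_new(data.frame(
      resno = res0 + seq_len(len),
      resname = "ALA", atom = "CA", element = "C",
      x = ca[, 1], y = ca[, 2], z = ca[, 3], b = 80))
    res0 <- res0 + len + sample(0:15, 1)
    base <- base + len * 3.8 + sample(0:40, 1)
  }
  placements <- lapply(seq_len(n_dom), function(i) {
    if (runif(1) < 0.25) return(NULL)
    dockrebuild:::placement_new(paste0("d", i), random_transform(),
                                runif(1, -0.2, 0.95), "correlation")
  })
  list(domains = domains, placements = placements,
       resolution = runif(1, 2, 5))
}
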