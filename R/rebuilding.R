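# Rebuilding: identify poorly fitting segments of the docked/morphed/
# refined model, create full-length candidate models with several
# density-guided strategies, and assemble the best segment of each
# candidate into the final model.

#' Identify segments needing rebuilding
#'
#' A residue is flagged for rebuilding when its chain-smoothed confidence
#' falls below `plddt_threshold` or its chain-smoothed CA density falls
#' below the outlier threshold ([density_outlier_threshold()], computed
#' from the raw per-CA density values). Contiguous flags become "rebuild"
#' segments; everything else is "keep".
#'
#' @param model docked `dr_model`.
#' @param map A `dr_map`.
#' @param confidence optional per-residue confidence (default: model's).
#' @param window smoothing window (default 10).
#' @param plddt_threshold confidence cutoff (default 70).
#' @param sd_ratio density outlier ratio (default 3).
#' @return List of class `dr_segment_plan`: `segments` data.frame with
#'   half-open `start`/`end` positions, `label` ("keep"/"rebuild"),
#'   `reason`; and `n` residues.
#' @export
identify_poor_segments <- function(model, map, confidence = NULL,
                                   window = 10, plddt_threshold = 70,
                                   sd_ratio = 3) {
  n <- model_nres(model)
  conf <- if (is.null(confidence)) normalize_confidence(model$confidence)$values
          else normalize_confidence(confidence)$values
  dens <- as.numeric(interpolate_density(map, model_ca(model)))
  conf_s <- smooth_profile(conf, window)
  dens_s <- smooth_profile(dens, window)
  thr <- density_outlier_threshold(dens, sd_ratio)
  low_conf <- conf_s < plddt_threshold
  low_dens <- dens_s < thr
  rebuild <- low_conf | low_dens
  if (all(rebuild))
    warning("every residue flagged for rebuilding (whole-model rebuild)")
  runs <- rle(rebuild)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- data.frame(
    start = starts - 1L, end = ends,
    label = ifelse(runs$values, "rebuild", "keep"),
    reason = vapply(seq_along(runs$values), function(k) {
      if (!runs$values[k]) return("")
      rng <- starts[k]:ends[k]
      if (any(low_conf[rng]) && !any(low_dens[rng])) "low_confidence"
      else if (!any(low_conf[rng]) && any(low_dens[rng])) "low_density"
      else "low_confidence+low_density"
    }, ""))
  structure(list(segments = segs, n = n), class = "dr_segment_plan")
}

#' @export
print.dr_segment_plan <- function(x, ...) {
  nr <- sum(x$segments$label == "rebuild")
  cat(sprintf("<dr_segment_plan> %d residues, %d rebuild segment(s)\n",
              x$n, nr))
  for (k in seq_len(nrow(x$segments)))
    cat(sprintf("  [%d,%d) %s %s\n", x$segments$start[k], x$segments$end[k],
                x$segments$label[k], x$segments$reason[k]))
  invisible(x)
}

#' Retrace a loop through density by the widest path
#'
#' Finds the path between the two anchors through the density grid (26-
#' connected) that maximizes the minimum grid value along the path (the
#' widest / maximum-bottleneck path), implemented by binary search over
#' density thresholds with flood-fill connectivity tests, then the
#' shortest path at the optimal threshold. The voxel path is resampled to
#' `n_residues` CA positions evenly spaced along it.
#'
#' @param map A `dr_map`.
#' @param start_anchor,end_anchor Cartesian anchor coordinates inside the
#'   map, Angstrom.
#' @param n_residues number of CA positions to return (>= 1).
#' @return `n_residues` x 3 matrix of CA coordinates with attribute
#'   `path_min` (the bottleneck value), or NULL when the anchors are not
#'   connected by positive density.
#' @export
retrace_loop <- function(map, start_anchor, end_anchor, n_residues) {
  stopifnot(n_residues >= 1)
  d <- dim(map$grid)
  to_vox <- function(p) {
    v <- round(map_frac_index(map, p))
    pmin(pmax(v, 1), matrix(d, 1))
  }
  sv <- to_vox(start_anchor); ev <- to_vox(end_anchor)
  s_lin <- sv[1] + (sv[2] - 1) * d[1] + (sv[3] - 1) * d[1] * d[2]
  e_lin <- ev[1] + (ev[2] - 1) * d[1] + (ev[3] - 1) * d[1] * d[2]
  g <- map$grid
  cap <- min(g[s_lin], g[e_lin])
  levels <- sort(unique(as.numeric(g[g > 0 & g <= cap])))
  if (length(levels) == 0) return(NULL)
  connected_at <- function(thr) grid_connected(g >= thr, s_lin, e_lin, d)
  if (!connected_at(levels[1])) return(NULL)
  lo <- 1L; hi <- length(levels)
  while (lo < hi) {               # largest level that stays connected
    mid <- (lo + hi + 1L) %/% 2L
    if (connected_at(levels[mid])) lo <- mid else hi <- mid - 1L
  }
  thr <- levels[lo]
  path <- grid_shortest_path(g >= thr, s_lin, e_lin, d)
  xyz <- map_index_coords(map, arrayInd(path, d))
  # anchor the polyline ends exactly, then resample evenly
  xyz[1, ] <- start_anchor
  xyz[nrow(xyz), ] <- end_anchor
  arc <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  total <- arc[length(arc)]
  want <- total * seq_len(n_residues) / (n_residues + 1)
  trace <- t(vapply(want, function(w) {
    i <- findInterval(w, arc, all.inside = TRUE)
    f <- (w - arc[i]) / max(arc[i + 1] - arc[i], 1e-9)
    xyz[i, ] + f * (xyz[i + 1, ] - xyz[i, ])
  }, c(0, 0, 0)))
  attr(trace, "path_min") <- thr
  trace
}

# flood-fill connectivity between two linear indices on a logical grid
grid_connected <- function(on, s, e, d) {
  if (!on[s] || !on[e]) return(FALSE)
  seen <- array(FALSE, d)
  seen[s] <- TRUE
  frontier <- s
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  while (length(frontier)) {
    if (seen[e]) return(TRUE)
    ijk <- arrayInd(frontier, d)
    ci <- rep(ijk[, 1], each = nrow(offs)) + rep(offs[, 1], length(frontier))
    cj <- rep(ijk[, 2], each = nrow(offs)) + rep(offs[, 2], length(frontier))
    ck <- rep(ijk[, 3], each = nrow(offs)) + rep(offs[, 3], length(frontier))
    okc <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
    cand <- unique((rep(frontier, each = nrow(offs)) + rep(lin_off, length(frontier)))[okc])
    cand <- cand[on[cand] & !seen[cand]]
    seen[cand] <- TRUE
    frontier <- cand
  }
  seen[e]
}

# BFS shortest path (hop count) between linear indices; returns the path
grid_shortest_path <- function(on, s, e, d) {
  parent <- array(0L, d)
  parent[s] <- s
  frontier <- s
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  while (length(frontier) && parent[e] == 0L) {
    ijk <- arrayInd(frontier, d)
    ci <- rep(ijk[, 1], each = nrow(offs)) + rep(offs[, 1], length(frontier))
    cj <- rep(ijk[, 2], each = nrow(offs)) + rep(offs[, 2], length(frontier))
    ck <- rep(ijk[, 3], each = nrow(offs)) + rep(offs[, 3], length(frontier))
    okc <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
    src <- rep(frontier, each = nrow(offs))[okc]
    cand <- (rep(frontier, each = nrow(offs)) + rep(lin_off, length(frontier)))[okc]
    keep <- on[cand] & parent[cand] == 0L
    cand <- cand[keep]; src <- src[keep]
    first <- !duplicated(cand)
    parent[cand[first]] <- src[first]
    frontier <- cand[first]
  }
  if (parent[e] == 0L) return(NULL)
  path <- e
  while (path[1] != s) path <- c(parent[path[1]], path)
  path
}

#' Rebuild a loop by seeded conformational sampling
#'
#' Generates candidate CA traces between the segment's flanking anchors
#' (seeded directional random walks with ~3.8 A steps, closed onto the
#' right anchor by cyclic-coordinate-descent pivots), scores them by mean
#' interpolated CA density (smoothness breaking ties), and returns the
#' best.
#'
#' @param model A `dr_model`.
#' @param map A `dr_map`.
#' @param segment half-open 0-based position interval `c(start, end)`.
#' @param resolution Angstrom.
#' @param n_candidates candidates sampled (default 200).
#' @param seed RNG seed (default 0).
#' @return The model with the segment's CAs replaced, or NULL when closure
#'   is infeasible (anchor span exceeds 3.8 A per virtual bond).
#' @export
fit_loop <- function(model, map, segment, resolution, n_candidates = 200,
                     seed = 0) {
  s <- segment[1]; e <- segment[2]
  n <- e - s
  nres <- model_nres(model)
  ca <- model_ca(model)
  left <- if (s > 0) ca[s, ] else NULL
  right <- if (e < nres) ca[e + 1L, ] else NULL
  if (is.null(left) || is.null(right)) {
    # terminal segment: keep it simple, walk from the available anchor
    return(NULL)
  }
  span <- sqrt(sum((right - left)^2))
  if (span > 3.8 * (n + 1)) return(NULL)
  with_seed(seed, {
    best <- NULL; best_score <- -Inf
    for (k in seq_len(n_candidates)) {
      trace <- sample_loop_trace(left, right, n)
      if (is.null(trace)) next
      dens <- mean(interpolate_density(map, trace))
      rough <- mean(rowSums(diff(diff(rbind(left, trace, right)))^2))
      score <- dens - 1e-4 * rough
      if (score > best_score) { best_score <- score; best <- trace }
    }
    if (is.null(best)) return(NULL)
    out <- model_set_ca(model, s:(e - 1L), best)
    attr(out, "loop_score") <- best_score
    out
  })
}

# one seeded loop trace: persistent random walk + CCD closure to the
# right anchor
sample_loop_trace <- function(left, right, n, step = 3.8) {
  dir <- right - left
  dir <- dir / max(sqrt(sum(dir^2)), 1e-6)
  pts <- matrix(0, n, 3)
  cur <- left
  v <- dir
  for (i in seq_len(n)) {
    v <- v + stats::rnorm(3, 0, 0.8)
    v <- v / max(sqrt(sum(v^2)), 1e-6)
    cur <- cur + step * v
    pts[i, ] <- cur
  }
  # cyclic coordinate descent: pivot rotations bringing the chain end to
  # one virtual bond from the right anchor
  chain <- rbind(left, pts)
  for (it in 1:60) {
    endp <- chain[nrow(chain), ]
    gap <- sqrt(sum((endp - right)^2))
    if (abs(gap - step) < 0.3) break
    piv <- sample(seq_len(nrow(chain) - 1), 1)
    pivot <- chain[piv, ]
    a <- endp - pivot; b <- right - pivot
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-6 || nb < 1e-6) next
    axis <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
    if (sqrt(sum(axis^2)) < 1e-6) next
    ang <- acos(pmin(1, pmax(-1, sum(a * b) / (na * nb))))
    # rotate only part way so closure distributes along the chain
    R <- rotation_axis_angle(axis, 0.5 * ang)
    idx <- (piv + 1):nrow(chain)
    chain[idx, ] <- sweep(sweep(chain[idx, , drop = FALSE], 2, pivot) %*% t(R),
                          2, -pivot)
  }
  endp <- chain[nrow(chain), ]
  if (abs(sqrt(sum((endp - right)^2)) - step) > 1.2) return(NULL)
  chain[-1, , drop = FALSE]
}

#' Combination rebuild: retrace the clear part, graft the rest
#'
#' Handles loops whose density is clear for only part of their length:
#' sub-runs of the segment with smoothed CA density at or above the
#' outlier threshold are retraced through the density; unclear runs keep
#' the refined model's conformation, grafted onto their (possibly
#' retraced) flanks with 3-residue splice morphs.
#'
#' @param model refined `dr_model`.
#' @param map A `dr_map`.
#' @param segment half-open 0-based interval.
#' @param resolution Angstrom.
#' @param sd_ratio outlier ratio for the clear/unclear split (default 3).
#' @param window smoothing window for the density profile (default 5).
#' @return The model with the segment rebuilt (falls back to graft-only
#'   when no sub-part is clear).
#' @export
combination_rebuild <- function(model, map, segment, resolution,
                                sd_ratio = 3, window = 5) {
  s <- segment[1]; e <- segment[2]
  n <- model_nres(model)
  dens <- as.numeric(interpolate_density(map, model_ca(model)))
  thr <- density_outlier_threshold(dens, sd_ratio)
  clear <- smooth_profile(dens, window) >= thr
  seg_pos <- s:(e - 1L)
  seg_clear <- clear[seg_pos + 1L]
  out <- model
  if (any(seg_clear)) {
    runs <- split(seg_pos[seg_clear],
                  cumsum(c(1, diff(seg_pos[seg_clear]) != 1)))
    for (run in runs) {
      a <- min(run); b <- max(run) + 1L
      ca <- model_ca(out)
      left <- if (a > 0) ca[a, ] else ca[a + 1L, ]
      right <- if (b < n) ca[b + 1L, ] else ca[b, ]
      tr <- retrace_loop(map_crop(map, rbind(left, right),
                                  pad = 3.8 * length(run) / 2 + 6),
                         left, right, length(run))
      if (!is.null(tr)) out <- model_set_ca(out, a:(b - 1L), tr)
    }
  }
  if (any(!seg_clear)) {
    runs <- split(seg_pos[!seg_clear],
                  cumsum(c(1, diff(seg_pos[!seg_clear]) != 1)))
    for (run in runs) {
      a <- min(run); b <- max(run) + 1L
      ca <- model_ca(out)
      splice <- min(3L, max(1L, (b - a) %/% 2L))
      lp <- max(0L, a - splice):(a - 1L)
      rp <- b:min(n - 1L, b + splice - 1L)
      if (length(lp) == 0 || min(lp) < 0 || length(rp) == 0) next
      out <- graft_segment(out, c(a, b),
                           left_target = ca[pmax(lp, 0) + 1L, , drop = FALSE],
                           right_target = ca[rp + 1L, , drop = FALSE],
                           splice_n = splice)
    }
  }
  out
}

#' Splice a matching fragment from an external model
#'
#' Searches the external model for a contiguous run with exactly the
#' segment's residue count whose terminal CAs deviate by at most
#' `ca_distance` from the corresponding end residues of the current model;
#' among qualifying fragments the one with the best mean CA density wins.
#'
#' @param model A `dr_model`.
#' @param segment half-open 0-based interval.
#' @param external_model externally built `dr_model` (already positioned
#'   in the map).
#' @param map A `dr_map` (for scoring competing fragments).
#' @param ca_distance maximum end deviation, Angstrom (default 3.8).
#' @return The model with the fragment spliced in, or NULL when no
#'   fragment qualifies.
#' @export
splice_external_fragment <- function(model, segment, external_model, map,
                                     ca_distance = 3.8) {
  if (is.null(external_model)) return(NULL)
  s <- segment[1]; e <- segment[2]
  n <- e - s
  ca <- model_ca(model)
  ext_ca <- model_ca(external_model)
  ext_resno <- model_resno(external_model)
  runs <- contiguous_segments(ext_resno)
  best <- NULL; best_score <- -Inf
  for (run in runs) {
    if (length(run) < n) next
    for (off in 0:(length(run) - n)) {
      idx <- run[off + seq_len(n)] + 1L
      frag <- ext_ca[idx, , drop = FALSE]
      if (anyNA(frag)) next
      dev1 <- sqrt(sum((frag[1, ] - ca[s + 1L, ])^2))
      dev2 <- sqrt(sum((frag[n, ] - ca[e, ])^2))
      if (dev1 > ca_distance || dev2 > ca_distance) next
      score <- mean(interpolate_density(map, frag))
      if (score > best_score) { best_score <- score; best <- frag }
    }
  }
  if (is.null(best)) return(NULL)
  model_set_ca(model, s:(e - 1L), best)
}

# the fixed strategy order (deterministic tie-breaking in assembly)
strategy_order <- c("iterative_refine", "fit_loop", "retrace", "combination",
                    "window_morph", "external")

#' Generate rebuilt full-length candidate models
#'
#' For each rebuilding strategy that succeeds on at least one rebuild
#' segment of the plan, the candidate segments replace the corresponding
#' segments of the refined input model, the full model is refined, and the
#' per-segment map correlation is recorded on the plan's segmentation.
#' Strategies (fixed order): whole-model iterative-resolution refinement,
#' loop fitting, widest-path retracing, retrace/graft combination,
#' windowed morphing, external-fragment splicing.
#'
#' @param model refined `dr_model` (already docked/morphed).
#' @param map A `dr_map`.
#' @param plan A `dr_segment_plan`.
#' @param resolution Angstrom.
#' @param external_model optional external `dr_model`.
#' @param params A [dr_params()].
#' @param seed RNG seed for stochastic strategies (default 0).
#' @return List of candidates, each `list(model, strategy,
#'   per_segment_cc)`; at least one (the refined input) is always
#'   returned.
#' @export
generate_candidates <- function(model, map, plan, resolution,
                                external_model = NULL, params = dr_params(),
                                seed = 0) {
  segs <- plan$segments
  rebuild <- segs[segs$label == "rebuild", , drop = FALSE]
  n <- model_nres(model)
  out <- list()
  add_candidate <- function(m, strategy) {
    m <- simple_real_space_refine(m, map, resolution)
    out[[length(out) + 1L]] <<- list(
      model = m, strategy = strategy,
      per_segment_cc = segment_ccs(m, map, plan, resolution, params))
  }
  if (nrow(rebuild) == 0) {
    add_candidate(model, "refined_input")
    return(out)
  }
  for (strategy in strategy_order) {
    if (strategy == "external" && is.null(external_model)) next
    cand <- model
    n_done <- 0L
    if (strategy == "iterative_refine") {
      cand <- iterative_resolution_refine(
        model, map, resolution,
        start = max(params$iterative_refine_start_resolution, resolution),
        step = params$iterative_refine_step)
      n_done <- nrow(rebuild)
    } else {
      for (k in seq_len(nrow(rebuild))) {
        seg <- c(rebuild$start[k], rebuild$end[k])
        res_k <- switch(strategy,
          fit_loop = fit_loop(cand, map, seg, resolution, seed = seed + k),
          retrace = retrace_segment(cand, map, seg),
          combination = tryCatch(
            combination_rebuild(cand, map, seg, resolution,
                                sd_ratio = params$cc_sd_ratio),
            error = function(e) NULL),
          window_morph = window_morph(cand, map, seg,
                                      n_window = params$n_window,
                                      resolution, seed = seed + k),
          external = splice_external_fragment(cand, seg, external_model,
                                              map, params$ca_distance))
        if (!is.null(res_k)) { cand <- res_k; n_done <- n_done + 1L }
      }
    }
    if (n_done > 0) add_candidate(cand, strategy)
  }
  if (length(out) == 0) add_candidate(model, "refined_input")
  out
}

# retrace one plan segment between its flanking keep residues
retrace_segment <- function(model, map, segment) {
  s <- segment[1]; e <- segment[2]
  n <- model_nres(model)
  if (s == 0 || e >= n) return(NULL)       # terminal segments keep anchors
  ca <- model_ca(model)
  left <- ca[s, ]; right <- ca[e + 1L, ]
  sub <- map_crop(map, rbind(left, right), pad = 3.8 * (e - s) / 2 + 6)
  tr <- retrace_loop(sub, left, right, e - s)
  if (is.null(tr)) return(NULL)
  model_set_ca(model, s:(e - 1L), tr)
}

# masked cc of each plan segment of a model
segment_ccs <- function(model, map, plan, resolution, params = dr_params()) {
  segs <- plan$segments
  vapply(seq_len(nrow(segs)), function(k) {
    sub <- model_subset(model, segs$start[k]:(segs$end[k] - 1L))
    tryCatch(
      suppressWarnings(map_model_cc(
        map_crop(map, model_coords(sub), params$mask_radius + 3), sub,
        resolution, params$mask_radius)$cc),
      error = function(e) NA_real_)
  }, 0)
}

#' Assemble the best segments of the candidate models
#'
#' For every segment of the plan the candidate with the highest segment
#' map correlation is chosen (ties break toward the earlier strategy in
#' the fixed order); the winning segments are concatenated into a chimera,
#' whose per-segment cc before the final refinement equals the
#' per-candidate maximum by construction. The chimera is then refined
#' against the map.
#'
#' @param candidates list from [generate_candidates()].
#' @param plan A `dr_segment_plan`.
#' @param map A `dr_map`.
#' @param resolution Angstrom.
#' @param params A [dr_params()].
#' @param refine apply the final refinement (default TRUE).
#' @return List: `model` (final), `pre_model` (chimera before the final
#'   refinement), `choices` (data.frame segment / strategy / cc).
#' @export
assemble_best_segments <- function(candidates, plan, map, resolution,
                                   params = dr_params(), refine = TRUE) {
  stopifnot(length(candidates) >= 1)
  segs <- plan$segments
  ccs <- vapply(candidates, function(cand) cand$per_segment_cc,
                numeric(nrow(segs)))
  ccs <- matrix(ccs, nrow = nrow(segs))
  pick <- apply(ccs, 1, function(v) which.max(replace(v, is.na(v), -Inf)))
  pieces <- lapply(seq_len(nrow(segs)), function(k)
    model_subset(candidates[[pick[k]]]$model,
                 segs$start[k]:(segs$end[k] - 1L)))
  chimera <- model_bind(pieces)
  choices <- data.frame(
    start = segs$start, end = segs$end, label = segs$label,
    strategy = vapply(pick, function(i) candidates[[i]]$strategy, ""),
    cc = ccs[cbind(seq_len(nrow(segs)), pick)])
  final <- if (refine) {
    refined <- simple_real_space_refine(chimera, map, resolution)
    regularize_ca_bonds(refined)
  } else chimera
  list(model = final, pre_model = chimera, choices = choices)
}
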