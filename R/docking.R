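# Domain docking: secondary-structure-matching (SSM) superposition onto
# map-derived SSEs, exhaustive rotation/translation correlation search,
# local rigid-body refinement, and placement-set expansion (shared
# transforms between domains, user-supplied symmetry operators).

placement_new <- function(domain_id, transform, cc,
                          source = c("ssm", "correlation", "reused",
                                     "symmetry")) {
  source <- match.arg(source)
  stopifnot(cc >= -1, cc <= 1)
  structure(list(domain_id = domain_id, transform = transform, cc = cc,
                 source = source), class = "dr_placement")
}

#' @export
print.dr_placement <- function(x, ...) {
  cat(sprintf("<dr_placement> domain %s, cc %.3f (%s)\n",
              x$domain_id, x$cc, x$source))
  invisible(x)
}

# cc of a domain under a transform, against a map cropped around the pose
placement_cc <- function(domain, map, resolution, tr, mask_radius = 2.5) {
  moved <- model_transform(domain, tr)
  sub <- map_crop(map, model_coords(moved), pad = mask_radius + 3)
  out <- tryCatch(
    suppressWarnings(map_model_cc(sub, moved, resolution, mask_radius)$cc),
    error = function(e) -1)
  out
}

# merge placements whose transforms give similar poses (r.m.s. coordinate
# difference below `tol` on the domain CAs), keeping the best cc
dedup_placements <- function(placements, domain, tol) {
  if (length(placements) <= 1) return(placements)
  ca <- model_ca(domain)
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  ord <- order(-vapply(placements, function(p) p$cc, 0))
  placements <- placements[ord]
  kept <- list()
  for (p in placements) {
    dup <- any(vapply(kept, function(q)
      transform_rms_difference(p$transform, q$transform, ca) <= tol, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

#' Dock a domain by secondary-structure matching
#'
#' Pairs two SSEs of the domain with two map-derived SSEs of matching kind,
#' tests every sliding alignment of the shorter element against the longer
#' (both directions, since map rods are unoriented), superposes the paired
#' CAs by least squares, and keeps transforms whose paired-CA r.m.s.
#' agreement is within `match_distance_high`. Candidate poses are scored
#' by map-model correlation; those at or above `ok_brute_force_cc` are
#' refined by rigid-body refinement and deduplicated.
#'
#' @param domain A `dr_model` with at least 2 detectable SSEs.
#' @param target_sses map-derived SSEs from [detect_sse_from_map()].
#' @param map A `dr_map`.
#' @param resolution nominal resolution, Angstrom.
#' @param params A [dr_params()] (uses `match_distance_high`,
#'   `ok_brute_force_cc`, `mask_radius`).
#' @param domain_id identifier recorded on the placements.
#' @param n_score,n_refine candidate pool sizes (performance knobs).
#' @return List of `dr_placement` sorted by decreasing cc; `NULL` when the
#'   domain has fewer than 2 SSEs (caller should use correlation docking);
#'   empty list when nothing matches.
#' @export
ssm_dock <- function(domain, target_sses, map, resolution,
                     params = dr_params(), domain_id = "domain",
                     n_score = 40, n_refine = 5) {
  dom_sses <- detect_sse_from_model(domain)
  if (length(dom_sses) < 2) return(NULL)
  if (length(target_sses) == 0) return(list())
  cand <- list()
  for (i in seq_along(dom_sses)) for (j in seq_along(dom_sses)) {
    if (j <= i) next
    for (u in seq_along(target_sses)) for (v in seq_along(target_sses)) {
      if (u == v) next
      if (dom_sses[[i]]$kind != target_sses[[u]]$kind) next
      if (dom_sses[[j]]$kind != target_sses[[v]]$kind) next
      for (ru in c(FALSE, TRUE)) for (rv in c(FALSE, TRUE)) {
        tu <- target_sses[[u]]$ca
        tv <- target_sses[[v]]$ca
        if (ru) tu <- tu[nrow(tu):1, , drop = FALSE]
        if (rv) tv <- tv[nrow(tv):1, , drop = FALSE]
        p1 <- slide_alignments(dom_sses[[i]]$ca, tu)
        p2 <- slide_alignments(dom_sses[[j]]$ca, tv)
        for (a1 in p1) for (a2 in p2) {
          A <- rbind(a1$a, a2$a); B <- rbind(a1$b, a2$b)
          tr <- kabsch(A, B)
          if (attr(tr, "rmsd") <= params$match_distance_high)
            cand[[length(cand) + 1L]] <- tr
        }
      }
    }
  }
  if (length(cand) == 0) return(list())
  # cheap pre-score: mean interpolated density at transformed CAs
  ca <- model_ca(domain); ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  pre <- vapply(cand, function(tr)
    mean(interpolate_density(map, transform_apply(tr, ca))), 0)
  cand <- cand[order(-pre)][seq_len(min(n_score, length(cand)))]
  # full cc for the shortlist
  placements <- lapply(cand, function(tr)
    placement_new(domain_id, tr,
                  placement_cc(domain, map, resolution, tr,
                               params$mask_radius), "ssm"))
  placements <- Filter(function(p) p$cc >= params$ok_brute_force_cc, placements)
  placements <- dedup_placements(placements, domain, tol = resolution)
  placements <- placements[seq_len(min(n_refine, length(placements)))]
  placements <- lapply(placements, function(p) {
    ref <- rigid_body_refine(domain, map, resolution, p$transform,
                             params = params)
    placement_new(domain_id, ref$transform, ref$cc, "ssm")
  })
  placements <- dedup_placements(placements, domain, tol = resolution)
  placements[order(-vapply(placements, function(p) p$cc, 0))]
}

# all 1:1 sliding alignments of the shorter CA list against the longer
slide_alignments <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- list()
  if (na <= nb) {
    for (off in 0:(nb - na))
      out[[length(out) + 1L]] <- list(a = a, b = b[off + seq_len(na), , drop = FALSE])
  } else {
    for (off in 0:(na - nb))
      out[[length(out) + 1L]] <- list(a = a[off + seq_len(nb), , drop = FALSE], b = b)
  }
  out
}

# quasi-uniform rotation sampling (super-Fibonacci spiral on S3)
rotation_samples <- function(n) {
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  i <- seq_len(n) - 0.5
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t); R <- sqrt(1 - t)
  q <- cbind(r * sin(d / phi), r * cos(d / phi),
             R * sin(d / psi), R * cos(d / psi))
  lapply(seq_len(n), function(k) quat_to_matrix(q[k, ]))
}

quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
           2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
           2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Dock a domain by exhaustive correlation search
#'
#' Scans a quasi-uniform rotation grid (about 24-degree spacing at the
#' default `rotation_count`); for each rotation the model-based density of
#' the rotated domain is cross-correlated with the map by FFT over all
#' grid translations (on a search grid coarsened to about half the
#' resolution). The best peaks are refined by rigid-body refinement and
#' placements reaching `minimum_docking_cc` are returned sorted by cc.
#'
#' @param domain A `dr_model` (>= 10 atoms).
#' @param map A `dr_map` large enough to contain the domain.
#' @param resolution nominal resolution, Angstrom.
#' @param params A [dr_params()] (uses `minimum_docking_cc`,
#'   `rotation_count`, `mask_radius`).
#' @param domain_id identifier recorded on the placements.
#' @param n_refine number of peak candidates refined (default 8).
#' @return List of `dr_placement` sorted by decreasing cc (possibly empty).
#' @export
correlation_dock <- function(domain, map, resolution, params = dr_params(),
                             domain_id = "domain", n_refine = 8) {
  xyz <- model_coords(domain)
  if (nrow(xyz) < 10) stop("domain has fewer than 10 atoms")
  span <- apply(xyz, 2, max) - apply(xyz, 2, min)
  mapspan <- (dim(map$grid) - 1) * map$voxel
  if (any(span > mapspan))
    stop("map grid too small to contain the domain")
  if (max(map$grid) == min(map$grid)) return(list())
  # coarse search grid (~resolution/2 voxels)
  f <- max(1L, as.integer(round(resolution / 2 / max(map$voxel))))
  d <- dim(map$grid)
  ci <- seq(1, d[1], by = f); cj <- seq(1, d[2], by = f); ck <- seq(1, d[3], by = f)
  coarse <- map_new(map$grid[ci, cj, ck, drop = FALSE], map$voxel * f,
                    map$origin, map$resolution_hint)
  cg <- coarse$grid - mean(coarse$grid)
  Fmap <- Conj(stats::fft(cg))
  dcell <- dim(cg)
  ctr_dom <- colMeans(xyz)
  c0 <- coarse$origin + (dcell %/% 2) * coarse$voxel
  # local map energy under a spherical domain-support mask, so peak scores
  # are normalized and dense regions elsewhere in the map do not dominate
  rgyr <- sqrt(max(rowSums(sweep(xyz, 2, ctr_dom)^2)))
  ax <- map_axis_coords(coarse, 1) - c0[1]
  ay <- map_axis_coords(coarse, 2) - c0[2]
  az <- map_axis_coords(coarse, 3) - c0[3]
  sphere <- outer(outer(ax^2, ay^2, "+"), az^2, "+") <= rgyr^2
  energy <- Re(stats::fft(Conj(stats::fft(cg^2)) * stats::fft(sphere + 0),
                          inverse = TRUE)) / prod(dcell)
  norm <- sqrt(pmax(energy, 1e-6 * max(energy)))
  rots <- rotation_samples(params$rotation_count)
  z <- element_electrons(domain$atoms$element)
  sigma <- gaussian_sigma(resolution)
  peaks <- data.frame(rot = integer(), k1 = integer(), k2 = integer(),
                      k3 = integer(), val = numeric())
  for (ri in seq_along(rots)) {
    R <- rots[[ri]]
    rx <- sweep(xyz, 2, ctr_dom) %*% t(R)
    rx <- sweep(rx, 2, -c0)
    synth <- suppressWarnings(
      accumulate_gaussians(rx, z, sigma, coarse))$grid
    corr <- Re(stats::fft(Fmap * stats::fft(synth), inverse = TRUE)) / norm
    best <- which.max(corr)
    ijk <- arrayInd(best, dcell)
    peaks <- rbind(peaks, data.frame(rot = ri, k1 = ijk[1], k2 = ijk[2],
                                     k3 = ijk[3], val = corr[best]))
  }
  peaks <- peaks[order(-peaks$val), , drop = FALSE]
  peaks <- peaks[seq_len(min(n_refine, nrow(peaks))), , drop = FALSE]
  placements <- list()
  for (r in seq_len(nrow(peaks))) {
    R <- rots[[peaks$rot[r]]]
    k <- c(peaks$k1[r], peaks$k2[r], peaks$k3[r]) - 1L
    k <- ifelse(k > dcell / 2, k - dcell, k)
    # corr[k] = sum_x map[x] * synth[x + k], so the shift moving the
    # synthetic density onto the map is -k
    tr <- transform_new(R, c0 - k * coarse$voxel - as.numeric(R %*% ctr_dom))
    ref <- rigid_body_refine(domain, map, resolution, tr, params = params)
    placements[[length(placements) + 1L]] <-
      placement_new(domain_id, ref$transform, ref$cc, "correlation")
    # a clearly acceptable pose ends the scan early once a few peaks are in
    if (r >= 3 && max(vapply(placements, function(p) p$cc, 0)) >=
          params$acceptable_docking_cc + 0.1) break
  }
  placements <- Filter(function(p) p$cc >= params$minimum_docking_cc,
                       placements)
  placements <- dedup_placements(placements, domain, tol = resolution)
  placements[order(-vapply(placements, function(p) p$cc, 0))]
}

#' Rigid-body refinement of a placed domain
#'
#' Local optimization of the six rigid-body parameters (rotation about the
#' placed centroid + translation) maximizing the map-model correlation.
#' The returned cc never falls below the initial cc; if the optimizer
#' fails to improve, the initial transform is returned with `improved =
#' FALSE`.
#'
#' @param domain A `dr_model`.
#' @param map A `dr_map`.
#' @param resolution nominal resolution, Angstrom.
#' @param initial starting `dr_transform`.
#' @param params A [dr_params()].
#' @param maxit optimizer iteration budget (default 200).
#' @return List with `transform`, `cc`, `improved`.
#' @export
rigid_body_refine <- function(domain, map, resolution, initial,
                              params = dr_params(), maxit = 130,
                              rounds = 2) {
  xyz <- model_coords(domain)
  z <- element_electrons(domain$atoms$element)
  sigma <- gaussian_sigma(resolution)
  cc0 <- placement_cc(domain, map, resolution, initial, params$mask_radius)
  cur <- initial
  for (round in seq_len(rounds)) {
    xyz0 <- transform_apply(cur, xyz)
    ctr <- colMeans(xyz0)
    sub <- map_crop(map, xyz0, pad = params$mask_radius + 4)
    # fast objective: correlation over a mask frozen at the round's start
    mask <- atom_mask(sub, xyz0, params$mask_radius + 1)
    mv <- sub$grid[mask]
    if (length(mv) < 2 || is.na(stats::sd(mv)) || stats::sd(mv) == 0) break
    base <- cur
    delta_tr <- function(p) {
      R <- rotvec_to_matrix(p[1:3])
      transform_compose(
        transform_new(R, ctr - as.numeric(R %*% ctr) + p[4:6]), base)
    }
    obj <- function(p) {
      moved <- transform_apply(delta_tr(p), xyz)
      synth <- suppressWarnings(accumulate_gaussians(moved, z, sigma, sub))
      sv <- synth$grid[mask]
      if (stats::sd(sv) == 0) return(0)
      -stats::cor(mv, sv)
    }
    scale <- if (round == 1) c(rep(0.15, 3), rep(1.2, 3))
             else c(rep(0.05, 3), rep(0.4, 3))
    fit <- tryCatch(
      stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, parscale = scale)),
      error = function(e) NULL)
    if (is.null(fit)) break
    cur <- delta_tr(fit$par)
  }
  cc1 <- placement_cc(domain, map, resolution, cur, params$mask_radius)
  if (cc1 <= cc0)
    return(list(transform = initial, cc = cc0, improved = FALSE))
  list(transform = cur, cc = cc1, improved = TRUE)
}

rotvec_to_matrix <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  rotation_axis_angle(v / ang, ang)
}

#' Expand per-domain placement lists
#'
#' Augments each domain's placements with (a) the transforms found for the
#' other domains (different domains often share a transform) and (b) the
#' symmetry images of every placement under user-supplied operators.
#' Correlations of borrowed/symmetry placements are recomputed and
#' duplicates merged.
#'
#' @param placements list (per domain) of lists of `dr_placement`.
#' @param domains list of `dr_model`, same order.
#' @param map A `dr_map`.
#' @param resolution Angstrom.
#' @param symmetry_ops optional list of `dr_transform` symmetry operators.
#' @param params A [dr_params()].
#' @return The expanded list of per-domain placement lists.
#' @export
expand_placements <- function(placements, domains, map, resolution,
                              symmetry_ops = NULL, params = dr_params()) {
  n <- length(domains)
  all_trs <- lapply(placements, function(pl)
    lapply(pl, function(p) p$transform))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pl <- placements[[i]]
    borrowed <- unlist(all_trs[-i], recursive = FALSE)
    for (tr in borrowed) {
      cc <- placement_cc(domains[[i]], map, resolution, tr, params$mask_radius)
      pl[[length(pl) + 1L]] <- placement_new(
        if (length(placements[[i]])) placements[[i]][[1]]$domain_id
        else paste0("domain", i), tr, max(-1, cc), "reused")
    }
    if (!is.null(symmetry_ops)) {
      base <- lapply(pl, function(p) p$transform)
      for (op in symmetry_ops) for (tr in base) {
        str_ <- transform_compose(op, tr)
        cc <- placement_cc(domains[[i]], map, resolution, str_,
                           params$mask_radius)
        pl[[length(pl) + 1L]] <- placement_new(
          pl[[1]]$domain_id, str_, max(-1, cc), "symmetry")
      }
    }
    out[[i]] <- dedup_placements(pl, domains[[i]], tol = resolution / 2)
  }
  out
}

#' Read symmetry operators from a plain-text file
#'
#' One operator per line: twelve whitespace-separated numbers forming a
#' row-major 3x4 matrix (rotation | translation).
#'
#' @param path file path.
#' @return List of `dr_transform`.
#' @export
load_symmetry_ops <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != 12) stop("expected 12 numbers per symmetry line")
    m <- matrix(v, 3, 4, byrow = TRUE)
    transform_new(m[, 1:3], m[, 4])
  })
}

#' Dock a domain: secondary-structure matching with correlation fallback
#'
#' Runs [ssm_dock()] first; when it is inapplicable (fewer than 2 SSEs) or
#' its best placement stays below `ssm_search_min_cc`, the exhaustive
#' [correlation_dock()] runs and the placement lists are merged.
#'
#' @param domain A `dr_model`.
#' @param map A `dr_map`.
#' @param resolution Angstrom.
#' @param params A [dr_params()].
#' @param domain_id identifier recorded on placements.
#' @param map_sses optional precomputed map SSEs (else detected here).
#' @return List of `dr_placement` sorted by decreasing cc, with attribute
#'   `mode` ("ssm" or "correlation").
#' @export
dock_domain <- function(domain, map, resolution, params = dr_params(),
                        domain_id = "domain", map_sses = NULL) {
  if (is.null(map_sses)) map_sses <- detect_sse_from_map(map, resolution)
  # the input pose is always a candidate: in later cycles of the
  # iterative procedure the model arrives already positioned in the map
  id_cc <- placement_cc(domain, map, resolution, transform_identity(),
                        params$mask_radius)
  seeded <- if (id_cc >= params$minimum_docking_cc)
    list(placement_new(domain_id, transform_identity(), id_cc, "reused"))
  else list()
  pl <- ssm_dock(domain, map_sses, map, resolution, params, domain_id)
  best_ssm <- if (length(pl)) pl[[1]]$cc else -Inf
  if (!is.null(pl) && best_ssm >= params$ssm_search_min_cc) {
    out <- dedup_placements(c(pl, seeded), domain, tol = resolution)
    out <- out[order(-vapply(out, function(p) p$cc, 0))]
    attr(out, "mode") <- "ssm"
    return(out)
  }
  pl2 <- correlation_dock(domain, map, resolution, params, domain_id)
  out <- dedup_placements(c(if (is.null(pl)) list() else pl, pl2, seeded),
                          domain, tol = resolution)
  out <- out[order(-vapply(out, function(p) p$cc, 0))]
  attr(out, "mode") <- "correlation"
  out
}
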