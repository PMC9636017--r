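# Simplified restrained real-space refinement: gradient ascent on summed
# interpolated density at CA positions with harmonic CA-CA virtual-bond
# terms (target 3.8 A) and optional harmonic reference restraints. Other
# atoms of a residue ride rigidly on their CA.

# central-difference gradient grids of a map
map_gradients <- function(map) {
  g <- map$grid
  d <- dim(g)
  grad <- function(axis) {
    out <- array(0, d)
    n <- d[axis]
    idx <- function(i) switch(axis,
      g[i, , , drop = FALSE], g[, i, , drop = FALSE], g[, , i, drop = FALSE])
    asn <- function(i, val) switch(axis,
      out[i, , ] <<- val, out[, i, ] <<- val, out[, , i] <<- val)
    asn(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * map$voxel[axis]))
    out
  }
  list(map_new(grad(1), map$voxel, map$origin),
       map_new(grad(2), map$voxel, map$origin),
       map_new(grad(3), map$voxel, map$origin))
}

#' Simplified restrained real-space refinement
#'
#' Gradient-based maximization of the interpolated density at CA atoms,
#' restrained by (a) harmonic CA-CA virtual-bond terms (target 3.8 A), (b)
#' an elastic network of springs between CA pairs initially within 8 A
#' that preserves local geometry while allowing collective motion (point-
#' density fitting without it collapses helices onto their own tube axis),
#' and (c) optional harmonic restraints to reference coordinates. All
#' atoms of a residue move rigidly with their CA. The map-model
#' correlation is guarded: if refinement would lower it, the input model
#' is returned with `attr(, "refine_flag") = TRUE`.
#'
#' @param model A `dr_model` inside the map.
#' @param map A `dr_map`.
#' @param resolution Angstrom.
#' @param reference optional `dr_model` supplying reference CA coordinate
#'   restraints.
#' @param positions optional 0-based residue positions allowed to move
#'   (default all).
#' @param n_iter gradient iterations (default 150).
#' @param weight_bond,weight_elastic,weight_reference restraint weights
#'   relative to a density term normalized by the map maximum.
#' @param max_step largest CA move per iteration, Angstrom.
#' @return The refined `dr_model` (attribute `refine_flag` set on guard).
#' @export
simple_real_space_refine <- function(model, map, resolution, reference = NULL,
                                     positions = NULL, n_iter = 150,
                                     weight_bond = 0.3,
                                     weight_elastic = 0.4,
                                     weight_reference = 0.05,
                                     max_step = 0.3) {
  n <- model_nres(model)
  free <- if (is.null(positions)) seq_len(n) else positions + 1L
  ca <- model_ca(model)
  ok <- stats::complete.cases(ca)
  gmax <- max(abs(map$grid))
  if (gmax == 0) {
    out <- model
    attr(out, "refine_flag") <- TRUE
    return(out)
  }
  wd <- 1 / gmax
  grads <- map_gradients(map)
  ref_ca <- if (!is.null(reference)) model_ca(reference) else NULL
  # elastic network on the starting conformation; springs touching
  # low-confidence residues are softened so unreliable local geometry does
  # not anchor the refinement
  d0 <- pairwise_dist(ca, ca)
  pairs <- which(upper.tri(d0) & d0 < 8 & d0 > 0, arr.ind = TRUE)
  rest <- d0[pairs]
  conf01 <- pmin(1, pmax(0.05, model$confidence / 100))
  pair_w <- sqrt(conf01[pairs[, 1]] * conf01[pairs[, 2]])
  cc_of <- function(m) tryCatch(
    suppressWarnings(map_model_cc(map_crop(map, model_coords(m), 6), m,
                                  resolution)$cc),
    error = function(e) NA_real_)
  cc0 <- cc_of(model)
  cur <- ca
  for (it in seq_len(n_iter)) {
    gx <- interpolate_density(grads[[1]], cur)
    gy <- interpolate_density(grads[[2]], cur)
    gz <- interpolate_density(grads[[3]], cur)
    force <- cbind(gx, gy, gz) * wd
    # harmonic CA-CA virtual bonds
    dvec <- diff(cur)
    dlen <- sqrt(rowSums(dvec^2))
    dlen[dlen == 0] <- 1e-6
    fb <- weight_bond * (dlen - 3.8) / dlen
    pull <- dvec * fb
    force[-n, ] <- force[-n, ] + pull
    force[-1, ] <- force[-1, ] - pull
    # elastic-network springs
    if (nrow(pairs) > 0) {
      ev <- cur[pairs[, 2], , drop = FALSE] - cur[pairs[, 1], , drop = FALSE]
      el <- sqrt(rowSums(ev^2)); el[el == 0] <- 1e-6
      fv <- ev * (weight_elastic * pair_w * (el - rest) / el)
      acc1 <- rowsum(fv, pairs[, 1])
      acc2 <- rowsum(fv, pairs[, 2])
      force[as.integer(rownames(acc1)), ] <-
        force[as.integer(rownames(acc1)), ] + acc1
      force[as.integer(rownames(acc2)), ] <-
        force[as.integer(rownames(acc2)), ] - acc2
    }
    if (!is.null(ref_ca))
      force <- force + weight_reference * (ref_ca - cur)
    force[!ok, ] <- 0
    fixed <- setdiff(seq_len(n), free)
    force[fixed, ] <- 0
    fm <- sqrt(max(rowSums(force^2)))
    if (fm < 1e-8) break
    step <- min(1, max_step / fm)
    cur <- cur + step * force
  }
  out <- model_set_ca(model, seq_len(n) - 1L, cur)
  cc1 <- cc_of(out)
  if (is.na(cc1) || (!is.na(cc0) && cc1 < cc0)) {
    attr(model, "refine_flag") <- TRUE
    return(model)
  }
  out
}

# bring consecutive CA distances into [2.9, 4.3] by small pair adjustments
regularize_ca_bonds <- function(model, lo = 2.9, hi = 4.3, n_iter = 50) {
  n <- model_nres(model)
  ca <- model_ca(model)
  ok <- stats::complete.cases(ca)
  for (it in seq_len(n_iter)) {
    dvec <- diff(ca)
    dlen <- sqrt(rowSums(dvec^2))
    bad <- which(ok[-n] & ok[-1] & (dlen < lo | dlen > hi))
    if (length(bad) == 0) break
    for (i in bad) {
      target <- min(max(dlen[i], lo), hi)
      corr <- (dlen[i] - target) / max(dlen[i], 1e-6) / 2
      shift <- dvec[i, ] * corr
      ca[i, ] <- ca[i, ] + shift
      ca[i + 1, ] <- ca[i + 1, ] - shift
    }
  }
  model_set_ca(model, seq_len(n) - 1L, ca)
}

#' Iterative-resolution refinement
#'
#' Refines the model repeatedly against progressively less blurred maps:
#' starting at `start` (default 6 A) and stepping by `step` (default 1 A)
#' down to the map's resolution. The low-resolution passes let badly
#' placed segments feel density from further away; the final pass sharpens
#' the fit. Consecutive-CA geometry is regularized at the end.
#'
#' @param model A `dr_model`.
#' @param map A `dr_map`.
#' @param resolution map resolution, Angstrom (must be <= `start`).
#' @param start starting (coarsest) resolution, Angstrom.
#' @param step resolution decrement per pass, Angstrom.
#' @param reference optional reference model for restraints.
#' @return The refined `dr_model`.
#' @export
iterative_resolution_refine <- function(model, map, resolution, start = 6,
                                        step = 1, reference = NULL) {
  stopifnot(resolution <= start)
  res_seq <- unique(c(seq(start, resolution, by = -step), resolution))
  for (res_k in res_seq) {
    work <- if (res_k > resolution) map_lowpass(map, resolution, res_k) else map
    model <- simple_real_space_refine(model, work, res_k,
                                      reference = reference)
  }
  regularize_ca_bonds(model)
}
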