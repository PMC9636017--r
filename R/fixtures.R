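# Synthetic fixtures: toy folds built from canonical secondary-structure
# geometry, "predicted" models derived from them by rigid-body domain
# perturbation plus correlated loop noise (with per-residue confidence
# anticorrelated with the introduced local error), and simulated maps.
# Everything is a pure function of (spec, seed).

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic test structure
#'
#' @param topology data.frame with columns `element` ("helix", "strand" or
#'   "loop") and `length` (residues).
#' @param domains integer per topology row assigning each element to a
#'   rigid domain (0 = linker, not part of any domain). Defaults to one
#'   domain holding every non-loop element, with loops joined to it.
#' @param perturbation list per domain id: `list(rotation = degrees,
#'   translation = Angstrom magnitude)` applied when deriving the
#'   "predicted" model. Missing entries mean no perturbation.
#' @param loop_noise per-coordinate noise s.d. (Angstrom) applied to loop
#'   residues of the predicted model.
#' @param resolution nominal map resolution, Angstrom.
#' @param map_noise map noise s.d. as a fraction of the maximum density.
#' @param voxel map voxel size, Angstrom.
#' @param seed integer fixing all randomness.
#' @return A `dr_fixture_spec` list.
#' @export
fixture_spec <- function(topology, domains = NULL, perturbation = list(),
                         loop_noise = 0, resolution = 3, map_noise = 0,
                         voxel = 1, seed = 0) {
  topology <- as.data.frame(topology)
  stopifnot(all(topology$element %in% c("helix", "strand", "loop")),
            all(topology$length >= 1), resolution > 0)
  if (is.null(domains)) domains <- ifelse(topology$element == "loop", 0L, 1L)
  stopifnot(length(domains) == nrow(topology))
  structure(list(topology = topology, domains = as.integer(domains),
                 perturbation = perturbation, loop_noise = loop_noise,
                 resolution = resolution, map_noise = map_noise,
                 voxel = voxel, seed = as.integer(seed)),
            class = "dr_fixture_spec")
}

# canonical helix CA trace: radius 2.3 A, rise 1.5 A/residue, 100 deg/residue
helix_trace <- function(n, base, dir_z = 1, phase = 0) {
  i <- 0:(n - 1)
  phi <- phase + i * 100 * pi / 180
  cbind(base[1] + 2.3 * cos(phi), base[2] + 2.3 * sin(phi),
        base[3] + dir_z * 1.5 * i)
}

# canonical strand CA trace: rise 3.3 A/residue with 0.8 A lateral zigzag
strand_trace <- function(n, base, dir_z = 1) {
  i <- 0:(n - 1)
  cbind(base[1] + rep(0, n), base[2] + 0.8 * (-1)^i, base[3] + dir_z * 3.3 * i)
}

# loop CA trace from p0 to p1 (exclusive) along a quadratic Bezier whose
# bulge is tuned so the arc length is ~3.8 A per virtual bond
loop_trace <- function(n, p0, p1, bulge_dir, jitter = 0.2) {
  target <- 3.8 * (n + 1)
  span <- sqrt(sum((p1 - p0)^2))
  if (span > target)
    stop("impossible closure: loop of ", n, " residues cannot span ",
         round(span, 1), " A")
  mid <- (p0 + p1) / 2
  bezier_len <- function(b) {
    ctrl <- mid + b * bulge_dir
    t <- seq(0, 1, length.out = 256)
    pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  lo <- 0; hi <- target
  for (it in 1:40) {
    b <- (lo + hi) / 2
    if (bezier_len(b) < target) lo <- b else hi <- b
  }
  ctrl <- mid + ((lo + hi) / 2) * bulge_dir
  t <- seq(0, 1, length.out = 512)
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  want <- arc[length(arc)] * seq_len(n) / (n + 1)
  idx <- vapply(want, function(w) which.min(abs(arc - w)), 1L)
  out <- pts[idx, , drop = FALSE]
  out + matrix(stats::rnorm(3 * n, 0, jitter), n, 3)
}

# backbone N, C, O atoms placed in a local frame around each CA
backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- if (i == 1) ca[1, ] else ca[i - 1, ]
    b <- if (i == n) ca[n, ] else ca[i + 1, ]
    v <- b - a
    u[i, ] <- v / max(sqrt(sum(v^2)), 1e-6)
  }
  ref <- cbind(rep(0, n), rep(0, n), rep(1, n))
  flat <- abs(rowSums(u * ref)) > 0.9
  ref[flat, ] <- matrix(rep(c(1, 0, 0), sum(flat)), ncol = 3, byrow = TRUE)
  w <- cbind(u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
             u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
             u[, 1] * ref[, 2] - u[, 2] * ref[, 1])
  w <- w / sqrt(rowSums(w^2))
  list(N = ca - 1.2 * u + 0.7 * w,
       C = ca + 1.2 * u + 0.5 * w,
       O = ca + 1.2 * u + 1.7 * w)
}

#' Build the ground-truth toy fold for a fixture spec
#'
#' Secondary-structure elements are laid out as an antiparallel bundle per
#' domain (axes 10 A apart), domains are separated along x, and loops are
#' smooth seeded connectors with consecutive-CA spacing near 3.8 A. The
#' model carries backbone atoms (N, CA, C, O) only. Residue names encode
#' the element type (helix ALA, strand VAL, loop GLY).
#'
#' @param spec A `dr_fixture_spec`.
#' @return A `dr_model` (deterministic given `spec$seed`).
#' @export
make_toy_fold <- function(spec) {
  with_seed(spec$seed, {
    topo <- spec$topology
    nel <- nrow(topo)
    dom_ids <- sort(unique(spec$domains[spec$domains > 0]))
    dom_x <- stats::setNames((match(dom_ids, dom_ids) - 1) * 45, dom_ids)
    within_idx <- integer(nel)
    for (d in dom_ids) {
      rows <- which(spec$domains == d & topo$element != "loop")
      within_idx[rows] <- seq_along(rows) - 1L
    }
    traces <- vector("list", nel)
    # lay out rigid elements first
    for (e in seq_len(nel)) {
      if (topo$element[e] == "loop") next
      d <- spec$domains[e]
      k <- within_idx[e]
      base_x <- dom_x[as.character(d)] + 10 * k
      up <- k %% 2 == 0
      L <- topo$length[e]
      rise <- if (topo$element[e] == "helix") 1.5 else 3.3
      z0 <- if (up) 0 else rise * (L - 1)
      traces[[e]] <- if (topo$element[e] == "helix")
        helix_trace(L, c(base_x, 0, z0), if (up) 1 else -1)
      else strand_trace(L, c(base_x, 0, z0), if (up) 1 else -1)
    }
    # then seeded loop connectors between them
    for (e in seq_len(nel)) {
      if (topo$element[e] != "loop") next
      if (e == 1 || e == nel) {
        # terminal tail: short walk off the neighbouring element
        nb <- if (e == 1) traces[[e + 1]] else traces[[e - 1]]
        endpt <- if (e == 1) nb[1, ] else nb[nrow(nb), ]
        dirv <- c(0, 4, 2); dirv <- dirv / sqrt(sum(dirv^2))
        n <- topo$length[e]
        steps <- outer(if (e == 1) rev(-seq_len(n)) else seq_len(n), 3.3 * dirv)
        traces[[e]] <- sweep(steps, 2, -endpt) +
          matrix(stats::rnorm(3 * n, 0, 0.2), n, 3)
      } else {
        p0 <- traces[[e - 1]][nrow(traces[[e - 1]]), ]
        p1 <- traces[[e + 1]][1, ]
        traces[[e]] <- loop_trace(topo$length[e], p0, p1, c(0, 1, 0.15))
      }
    }
    ca <- do.call(rbind, traces)
    elem_of <- rep(topo$element, topo$length)
    bb <- backbone_from_ca(ca)
    n <- nrow(ca)
    resname <- c(helix = "ALA", strand = "VAL", loop = "GLY")[elem_of]
    atoms <- data.frame(
      resno = rep(seq_len(n), each = 4L),
      resname = rep(resname, each = 4L),
      atom = rep(c("N", "CA", "C", "O"), n),
      element = rep(c("N", "C", "C", "O"), n),
      x = as.numeric(rbind(bb$N[, 1], ca[, 1], bb$C[, 1], bb$O[, 1])),
      y = as.numeric(rbind(bb$N[, 2], ca[, 2], bb$C[, 2], bb$O[, 2])),
      z = as.numeric(rbind(bb$N[, 3], ca[, 3], bb$C[, 3], bb$O[, 3])),
      b = 90, stringsAsFactors = FALSE)
    model_new(atoms, "A")
  })
}

# per-residue element type and domain id for a spec
fixture_residue_info <- function(spec) {
  data.frame(element = rep(spec$topology$element, spec$topology$length),
             domain = rep(spec$domains, spec$topology$length))
}

#' Derive a "predicted" model from a toy-fold truth
#'
#' Each domain is rigid-body perturbed by its spec'd rotation (about the
#' domain centroid, seeded random axis) and translation (seeded random
#' direction). Loop residues receive chain-correlated Gaussian noise of the
#' spec'd sigma; linker residues between two perturbed domains are blended
#' between the flanking domain transforms so the chain stays connected.
#' Per-residue confidence emulates plDDT: it reflects *local* (internal)
#' error only, `conf = 100 * exp(-err / 4)` clipped to `[20, 98]`, where
#' `err` is the chain-smoothed magnitude of the non-rigid displacement.
#' A rigidly moved domain therefore keeps high confidence, exactly as a
#' confidently predicted but misplaced domain does.
#'
#' @param truth model from [make_toy_fold()].
#' @param spec the same `dr_fixture_spec`.
#' @return A `dr_model` with confidence in both `confidence` and the atom
#'   B column.
#' @export
make_predicted_like <- function(truth, spec) {
  with_seed(spec$seed + 1L, {
    info <- fixture_residue_info(spec)
    n <- nrow(info)
    resno <- model_resno(truth)
    ca <- model_ca(truth)
    dom_ids <- sort(unique(spec$domains[spec$domains > 0]))
    trs <- list()
    for (d in dom_ids) {
      p <- spec$perturbation[[as.character(d)]]
      if (is.null(p)) { trs[[as.character(d)]] <- transform_identity(); next }
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      centroid <- colMeans(ca[info$domain == d, , drop = FALSE])
      trs[[as.character(d)]] <- transform_about_center(
        axis, p$rotation * pi / 180, centroid, p$translation * tdir)
    }
    # per-residue blend weights between flanking domains for linker runs
    xyz <- model_coords(truth)
    new_ca <- ca
    dom_res <- info$domain
    for (i in seq_len(n)) {
      if (dom_res[i] > 0) {
        new_ca[i, ] <- transform_apply(trs[[as.character(dom_res[i])]], ca[i, ])
      }
    }
    linker <- which(dom_res == 0 & info$element == "loop")
    if (length(linker) > 0) {
      runs <- split(linker, cumsum(c(1, diff(linker) != 1)))
      for (r in runs) {
        before <- if (min(r) > 1) dom_res[min(r) - 1] else 0
        after <- if (max(r) < n) dom_res[max(r) + 1] else 0
        tb <- if (before > 0) trs[[as.character(before)]] else transform_identity()
        ta <- if (after > 0) trs[[as.character(after)]] else transform_identity()
        w <- seq_along(r) / (length(r) + 1)
        pb <- transform_apply(tb, ca[r, , drop = FALSE])
        pa <- transform_apply(ta, ca[r, , drop = FALSE])
        new_ca[r, ] <- (1 - w) * pb + w * pa
      }
    }
    # chain-correlated loop noise (moving average of iid normals, window 3,
    # rescaled to the requested per-coordinate sigma)
    noise <- matrix(0, n, 3)
    loops <- info$element == "loop"
    if (spec$loop_noise > 0 && any(loops)) {
      raw <- matrix(stats::rnorm(3 * n), n, 3)
      sm <- apply(raw, 2, function(v)
        stats::filter(v, rep(1 / 3, 3), sides = 2))
      sm[is.na(sm)] <- raw[is.na(sm)]
      sm <- sm * sqrt(3)              # restore unit variance after averaging
      noise[loops, ] <- spec$loop_noise * sm[loops, ]
    }
    new_ca <- new_ca + noise
    # move every atom of a residue with its CA
    shift <- new_ca - ca
    res_index <- match(truth$atoms$resno, resno)
    xyz <- xyz + shift[res_index, , drop = FALSE]
    # confidence from local (non-rigid) error, chain-smoothed
    err <- sqrt(rowSums(noise^2))
    err_s <- as.numeric(stats::filter(err, rep(1 / 3, 3), sides = 2))
    err_s[is.na(err_s)] <- err[is.na(err_s)]
    err_s[!loops] <- 0            # rigid residues keep their internal geometry
    conf <- pmin(98, pmax(20, 100 * exp(-err_s / 4)))
    atoms <- truth$atoms
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    atoms$b <- conf[res_index]
    model_new(atoms, truth$chain_id, conf)
  })
}

#' Simulate a density map from a truth model
#'
#' Synthesizes Gaussian-atom density on a padded grid (>= 10 A margin) and
#' optionally adds seeded Gaussian noise.
#'
#' @param truth A `dr_model`.
#' @param resolution Angstrom.
#' @param noise_sigma noise s.d. as a fraction of the maximum density.
#' @param voxel voxel size, Angstrom (default 1.0).
#' @param seed seed for the noise.
#' @param pad margin around the model, Angstrom (default 10).
#' @return A `dr_map` with `resolution_hint` set.
#' @export
make_synthetic_map <- function(truth, resolution, noise_sigma = 0, voxel = 1,
                               seed = 0, pad = 10) {
  xyz <- model_coords(truth)
  lo <- floor(apply(xyz, 2, min) - pad)
  hi <- ceiling(apply(xyz, 2, max) + pad)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  template <- map_new(array(0, dims), voxel = voxel, origin = lo,
                      resolution_hint = resolution)
  m <- synthesize_map(truth, resolution, template)
  m$resolution_hint <- resolution
  if (noise_sigma > 0) {
    with_seed(seed, {
      m$grid <- m$grid + stats::rnorm(length(m$grid), 0,
                                      noise_sigma * max(m$grid))
    })
  }
  m
}

#' The standard two-domain benchmark fixture
#'
#' Two 3-helix domains joined by a 20-residue linker; the helices of the
#' two domains have different lengths (12/12/12 vs 16/14/10) so the
#' domains are distinguishable in density, as real domains are. The
#' second domain of the predicted model is rotated 15 degrees and
#' translated 4 A, all loops carry 3 A noise; the map is a noiseless 3 A
#' synthesis from the truth.
#'
#' @param seed integer seed.
#' @return List with `spec`, `truth`, `predicted`, `map`.
#' @export
fixture_two_domain <- function(seed = 0) {
  topo <- data.frame(
    element = c("helix", "loop", "helix", "loop", "helix",
                "loop",
                "helix", "loop", "helix", "loop", "helix"),
    length = c(12, 4, 12, 4, 12, 20, 16, 4, 14, 4, 10))
  domains <- c(1L, 1L, 1L, 1L, 1L, 0L, 2L, 2L, 2L, 2L, 2L)
  spec <- fixture_spec(topo, domains,
                       perturbation = list(`2` = list(rotation = 15, translation = 4)),
                       loop_noise = 3, resolution = 3, map_noise = 0,
                       voxel = 1, seed = seed)
  truth <- make_toy_fold(spec)
  predicted <- make_predicted_like(truth, spec)
  map <- make_synthetic_map(truth, spec$resolution, spec$map_noise,
                            spec$voxel, seed = seed)
  list(spec = spec, truth = truth, predicted = predicted, map = map)
}

#' A compact single-domain fixture (3-helix bundle)
#'
#' @param seed integer seed.
#' @param perturb optional `list(rotation = degrees, translation = A)` for
#'   the predicted model.
#' @return List with `spec`, `truth`, `predicted`, `map`.
#' @export
fixture_single_domain <- function(seed = 0, perturb = NULL) {
  topo <- data.frame(element = c("helix", "loop", "helix", "loop", "helix"),
                     length = c(12, 4, 12, 4, 12))
  pert <- if (is.null(perturb)) list() else list(`1` = perturb)
  spec <- fixture_spec(topo, c(1L, 1L, 1L, 1L, 1L), perturbation = pert,
                       loop_noise = 0, resolution = 3, voxel = 1, seed = seed)
  truth <- make_toy_fold(spec)
  predicted <- make_predicted_like(truth, spec)
  map <- make_synthetic_map(truth, spec$resolution, 0, spec$voxel, seed = seed)
  list(spec = spec, truth = truth, predicted = predicted, map = map)
}
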