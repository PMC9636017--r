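#' Shift fields: smooth displacement fields anchored on CA atoms
#'
#' A shift field is a set of (anchor coordinate, shift vector) pairs plus a
#' distance scale `D` (`shift_field_distance`, default 10 A). The field at
#' any point is the weighted average of all shift vectors with Gaussian
#' weights `exp(-|point - anchor|^2 / D^2)`. Local distortions of a
#' morphed model therefore occur on a scale of about `D`; the default is a
#' compromise between preserving model geometry (large D) and matching
#' docked domains closely (small D).
#'
#' @param anchors n x 3 matrix of anchor coordinates, Angstrom.
#' @param vectors n x 3 matrix of shift vectors, Angstrom.
#' @param distance the shift-field distance scale D, Angstrom (default 10).
#' @return An object of class `dr_shift_field`.
#' @export
shift_field <- function(anchors, vectors, distance = 10) {
  anchors <- matrix(as.numeric(anchors), ncol = 3)
  vectors <- matrix(as.numeric(vectors), ncol = 3)
  stopifnot(nrow(anchors) >= 1, nrow(anchors) == nrow(vectors), distance > 0)
  structure(list(anchors = anchors, vectors = vectors, distance = distance),
            class = "dr_shift_field")
}

#' Evaluate a shift field at points
#'
#' @param field A `dr_shift_field`.
#' @param points n x 3 matrix (or length-3 vector) of positions.
#' @return n x 3 matrix of displacement vectors.
#' @export
evaluate_shift_field <- function(field, points) {
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1, 3)
  d2 <- pairwise_dist(points, field$anchors)^2
  w <- exp(-d2 / field$distance^2)
  sw <- rowSums(w)
  # far from every anchor the weights flatten; guard exact underflow only
  zero <- sw == 0
  if (any(zero)) { w[zero, ] <- 1; sw[zero] <- ncol(w) }
  out <- (w %*% field$vectors) / sw
  if (vec) out[1, ] else out
}

#' Build a shift field from docked domains
#'
#' One anchor per CA atom of each docked domain: the anchor coordinate is
#' the corresponding CA position in the full model, and the shift vector is
#' the docked CA position minus that full-model CA position.
#'
#' @param full_model the complete `dr_model` before docking.
#' @param docked_domains list of placed `dr_model` domains whose residue
#'   numbers are a subset of the full model's.
#' @param distance shift-field distance scale (default 10 A).
#' @return A `dr_shift_field`.
#' @export
build_field_from_docked <- function(full_model, docked_domains, distance = 10) {
  resno_full <- model_resno(full_model)
  ca_full <- model_ca(full_model)
  anchors <- NULL; vectors <- NULL
  for (dom in docked_domains) {
    rn <- model_resno(dom)
    idx <- match(rn, resno_full)
    if (anyNA(idx))
      stop("docked domain residues not present in the full model: ",
           paste(rn[is.na(idx)], collapse = ", "))
    a <- ca_full[idx, , drop = FALSE]
    v <- model_ca(dom) - a
    anchors <- rbind(anchors, a); vectors <- rbind(vectors, v)
  }
  ok <- stats::complete.cases(anchors) & stats::complete.cases(vectors)
  shift_field(anchors[ok, , drop = FALSE], vectors[ok, , drop = FALSE],
              distance)
}

#' Morph a model with a shift field
#'
#' Every atom (not just CA) is displaced by the field evaluated at its own
#' coordinate, so side-chain/backbone atoms follow their CA smoothly.
#' Topology, numbering and confidence are unchanged.
#'
#' @param model A `dr_model`.
#' @param field A `dr_shift_field`.
#' @return The morphed `dr_model`.
#' @export
morph_model <- function(model, field) {
  xyz <- model_coords(model)
  model_set_coords(model, xyz + evaluate_shift_field(field, xyz))
}

#' Windowed density-guided morphing of a segment
#'
#' Morphs a segment into density six residues from each end at a time
#' (`n_window`): each end window is rigidly shifted to increase the mean
#' interpolated density at its CA atoms (seeded random-restart local
#' search, consecutive-CA distances kept within 2.9-4.3 A), the remainder
#' of the segment is superimposed on the morphed windows through a shift
#' field, the windows step one residue inward, and the process repeats
#' until the whole segment has been morphed.
#'
#' @param model A `dr_model`.
#' @param map A `dr_map`.
#' @param segment half-open 0-based position interval `c(start, end)`.
#' @param n_window residues per end window (default 6); windows truncate
#'   for short segments.
#' @param resolution nominal resolution, Angstrom.
#' @param seed seed for the local search (default 0).
#' @return The model with the segment morphed.
#' @export
window_morph <- function(model, map, segment, n_window = 6, resolution = 3,
                         seed = 0) {
  n <- model_nres(model)
  s <- segment[1]; e <- segment[2]
  if (s < 0 || e > n || s >= e) stop("segment outside model")
  with_seed(seed, {
    r0 <- s; r1 <- e - 1L
    while (r0 <= r1) {
      w1 <- r0:min(r0 + n_window - 1L, r1)
      w2 <- max(r1 - n_window + 1L, r0):r1
      win <- sort(unique(c(w1, w2)))
      ca <- model_ca(model)
      shift <- optimize_window_shift(map, ca, win, s, e, n)
      if (sqrt(sum(shift^2)) > 1e-4) {
        new_win_ca <- sweep(ca[win + 1L, , drop = FALSE], 2, -shift)
        # superimpose the remainder of the segment on the morphed windows
        interior <- setdiff(s:(e - 1L), win)
        fld <- shift_field(ca[win + 1L, , drop = FALSE],
                           new_win_ca - ca[win + 1L, , drop = FALSE])
        model <- model_set_ca(model, win, new_win_ca)
        if (length(interior) > 0) {
          ca2 <- model_ca(model)
          disp <- evaluate_shift_field(fld, ca2[interior + 1L, , drop = FALSE])
          model <- model_set_ca(model, interior,
                                ca2[interior + 1L, , drop = FALSE] + disp)
        }
      }
      r0 <- r0 + 1L; r1 <- r1 - 1L
    }
    model
  })
}

# best rigid translation of a window of CAs: maximize mean interpolated
# density, penalizing bond-length violations to fixed neighbours
optimize_window_shift <- function(map, ca, win, s, e, n, n_restart = 4) {
  wxyz <- ca[win + 1L, , drop = FALSE]
  nb <- c(min(win) - 1L, max(win) + 1L)
  nb <- nb[nb >= 0 & nb < n & !(nb %in% win)]
  nb_xyz <- ca[nb + 1L, , drop = FALSE]
  nb_attach <- vapply(nb, function(p)
    if (p < min(win)) 1L else nrow(wxyz), 1L)
  objective <- function(shift) {
    pts <- sweep(wxyz, 2, -shift)
    val <- mean(interpolate_density(map, pts))
    pen <- 0
    if (length(nb) > 0) {
      d <- sqrt(rowSums((pts[nb_attach, , drop = FALSE] - nb_xyz)^2))
      pen <- sum(pmax(0, d - 4.3)^2 + pmax(0, 2.9 - d)^2)
    }
    val - pen
  }
  best <- c(0, 0, 0); bestv <- objective(best)
  for (r in seq_len(n_restart)) {
    cur <- if (r == 1) c(0, 0, 0) else stats::rnorm(3, 0, 1)
    curv <- objective(cur)
    step <- 0.6
    while (step > 0.05) {
      improved <- FALSE
      for (ax in 1:3) for (sgn in c(-1, 1)) {
        cand <- cur; cand[ax] <- cand[ax] + sgn * step
        cv <- objective(cand)
        if (cv > curv) { cur <- cand; curv <- cv; improved <- TRUE }
      }
      if (!improved) step <- step / 2
    }
    if (curv > bestv) { best <- cur; bestv <- curv }
  }
  best
}

#' Graft a segment onto fixed flank coordinates
#'
#' Builds a shift field from `splice_n` residues at each end of the segment
#' (anchor = current CA, vector = target CA - current CA) and morphs the
#' whole segment with it, so the splice residues land on the targets while
#' the interior deforms smoothly.
#'
#' @param model A `dr_model` containing the segment.
#' @param segment half-open 0-based position interval `c(start, end)`.
#' @param left_target,right_target `splice_n` x 3 matrices: target CA
#'   coordinates for the first and last `splice_n` residues of the segment.
#' @param splice_n splice length in residues (default 3).
#' @param distance shift-field distance scale (default 10 A).
#' @return The model with the segment grafted.
#' @export
graft_segment <- function(model, segment, left_target, right_target,
                          splice_n = 3, distance = 10) {
  s <- segment[1]; e <- segment[2]
  len <- e - s
  splice_n <- min(splice_n, len %/% 2L)
  if (splice_n < 1) splice_n <- 1L
  if (is.null(left_target) || is.null(right_target)) stop("missing flank")
  left_target <- matrix(left_target, ncol = 3)
  right_target <- matrix(right_target, ncol = 3)
  stopifnot(nrow(left_target) >= splice_n, nrow(right_target) >= splice_n)
  ca <- model_ca(model)
  lp <- s:(s + splice_n - 1L)
  rp <- (e - splice_n):(e - 1L)
  anchors <- rbind(ca[lp + 1L, , drop = FALSE], ca[rp + 1L, , drop = FALSE])
  targets <- rbind(left_target[seq_len(splice_n), , drop = FALSE],
                   right_target[nrow(right_target) - splice_n + seq_len(splice_n), ,
                                drop = FALSE])
  fld <- shift_field(anchors, targets - anchors, distance)
  seg_pos <- s:(e - 1L)
  disp <- evaluate_shift_field(fld, ca[seg_pos + 1L, , drop = FALSE])
  model_set_ca(model, seg_pos, ca[seg_pos + 1L, , drop = FALSE] + disp)
}
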