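# Secondary-structure element (SSE) detection, from models (CA geometry)
# and from density maps (rod-like high-density regions). Map-derived SSEs
# feed the secondary-structure-matching docking; the map detector is a
# functional stand-in for map-based helix/strand finding, not a clone of
# any particular tool.

sse_new <- function(kind, ca, positions = NULL) {
  structure(list(kind = kind, ca = ca, positions = positions),
            class = "dr_sse")
}

#' @export
print.dr_sse <- function(x, ...) {
  cat(sprintf("<dr_sse> %s, %d CA%s\n", x$kind, nrow(x$ca),
              if (is.null(x$positions)) " (map-derived)" else ""))
  invisible(x)
}

#' Detect secondary-structure elements from CA geometry
#'
#' Helices are recognized from the characteristic CA(i)-CA(i+3) (~5.1 A)
#' and CA(i)-CA(i+4) (~6.2 A) distances, strands from extended
#' CA(i)-CA(i+2) (~6.6 A) distances. Detection runs within contiguous
#' residue runs only.
#'
#' @param model A `dr_model` with CA atoms.
#' @param min_helix,min_strand minimum element lengths in residues.
#' @return List of `dr_sse` (possibly empty), each carrying the 0-based
#'   residue positions it covers.
#' @export
detect_sse_from_model <- function(model, min_helix = 6, min_strand = 4) {
  resno <- model_resno(model)
  ca <- model_ca(model)
  runs <- contiguous_segments(resno)
  out <- list()
  for (run in runs) {
    idx <- run + 1L
    n <- length(idx)
    if (n < min_strand) next
    xyz <- ca[idx, , drop = FALSE]
    if (anyNA(xyz)) next
    helix_mark <- logical(n); strand_mark <- logical(n)
    for (i in seq_len(n - 3)) {
      d13 <- sqrt(sum((xyz[i + 3, ] - xyz[i, ])^2))
      d14 <- if (i + 4 <= n) sqrt(sum((xyz[i + 4, ] - xyz[i, ])^2)) else NA
      if (d13 >= 4.2 && d13 <= 5.8 && (is.na(d14) || (d14 >= 5.5 && d14 <= 7.2)))
        helix_mark[i:(i + 3)] <- TRUE
    }
    for (i in seq_len(n - 2)) {
      d02 <- sqrt(sum((xyz[i + 2, ] - xyz[i, ])^2))
      d03 <- if (i + 3 <= n) sqrt(sum((xyz[i + 3, ] - xyz[i, ])^2)) else NA
      # d03 filters curved extended loops that mimic strand spacing
      if (d02 >= 6.2 && d02 <= 7.3 && (is.na(d03) || (d03 >= 9.0 && d03 <= 10.6)))
        strand_mark[i:(i + 2)] <- TRUE
    }
    strand_mark <- strand_mark & !helix_mark
    for (kind in c("helix", "strand")) {
      mark <- if (kind == "helix") helix_mark else strand_mark
      minlen <- if (kind == "helix") min_helix else min_strand
      r <- rle(mark)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (s in which(r$values & r$lengths >= minlen)) {
        pos <- run[starts[s]:ends[s]]
        out[[length(out) + 1L]] <- sse_new(kind, ca[pos + 1L, , drop = FALSE],
                                           positions = pos)
      }
    }
  }
  out
}

#' Detect secondary-structure elements in a density map
#'
#' Thresholds the map, finds 26-connected components of high density, and
#' keeps elongated (rod-like) components. Each rod is traced by
#' density-weighted centroids of slabs along its principal axis and
#' returned as a helix (thick rod) or strand (thin rod) axis trace with
#' CA-like spacing. Map-derived SSEs carry no residue interval.
#'
#' @param map A `dr_map`.
#' @param resolution nominal resolution, Angstrom (useful output needs
#'   about 5 A or better).
#' @param min_length minimum rod length, Angstrom (default 8).
#' @return List of `dr_sse` (empty when nothing rod-like is found; callers
#'   fall back to correlation docking).
#' @export
detect_sse_from_map <- function(map, resolution, min_length = 10) {
  g <- map$grid
  mu <- mean(g); sg <- stats::sd(as.numeric(g))
  rods <- list()
  # sweep several thresholds: low ones keep full-length rods, higher ones
  # split rods that merge through weaker connecting density
  for (mult in c(2, 3, 4, 5, 6, 7)) {
    on <- g > mu + mult * sg
    if (sum(on) < 20) next
    labels <- label_components(on)
    for (lab in seq_len(max(labels))) {
      vox <- which(labels == lab)
      if (length(vox) < 25) next
      ijk <- arrayInd(vox, dim(g))
      xyz <- map_index_coords(map, ijk)
      w <- g[vox]
      ctr <- colSums(xyz * w) / sum(w)
      xc <- sweep(xyz, 2, ctr)
      cov <- crossprod(xc * sqrt(w / sum(w)))
      eig <- eigen(cov, symmetric = TRUE)
      axis <- eig$vectors[, 1]
      proj <- as.numeric(xc %*% axis)
      extent <- diff(range(proj))
      if (extent < min_length) next
      # straight rods only: cross-section must stay compact (curved tubes
      # and sheets have a large second principal component) and clearly
      # shorter than the axial extent
      if (sqrt(eig$values[2]) > 4) next
      if (extent < 3.2 * sqrt(eig$values[2])) next
      perp <- xc - outer(proj, axis)
      rad <- sqrt(rowSums(perp^2))
      thick <- sqrt(sum(w * rad^2) / sum(w))
      # helix tubes (CA radius 2.3 A) are thicker than strand zigzags
      # (~0.8 A) after blurring by the resolution-dependent kernel width
      kind <- if (thick >= sqrt(1.3^2 + gaussian_sigma(resolution)^2))
        "helix" else "strand"
      step <- if (kind == "helix") 1.5 else 3.3
      halfwin <- if (kind == "helix") 2.8 else 1.8  # ~half a helical turn
      ts <- seq(min(proj) + step / 2, max(proj) - step / 2, by = step)
      if (length(ts) < 3) next
      trace <- t(vapply(ts, function(t0) {
        sel <- abs(proj - t0) <= halfwin
        if (!any(sel)) return(ctr + t0 * axis)
        colSums(xyz[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
      }, c(0, 0, 0)))
      rods[[length(rods) + 1L]] <- sse_new(kind, trace)
    }
  }
  dedup_sses(rods)
}

# merge rod traces that follow the same density feature, keeping the longer
dedup_sses <- function(sses, tol = 2.5) {
  if (length(sses) <= 1) return(sses)
  ord <- order(-vapply(sses, function(s) nrow(s$ca), 0L))
  sses <- sses[ord]
  kept <- list()
  for (s in sses) {
    dup <- any(vapply(kept, function(k) {
      d <- pairwise_dist(s$ca, k$ca)
      mean(apply(d, 1, min)) < tol
    }, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- s
  }
  kept
}

# label 26-connected components of a logical 3D array
label_components <- function(on) {
  d <- dim(on)
  labels <- array(0L, d)
  idx_on <- which(on)
  if (length(idx_on) == 0) return(labels)
  # neighbour offsets in linear index space
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  cur <- 0L
  for (s in idx_on) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    frontier <- s
    while (length(frontier)) {
      ijk <- arrayInd(frontier, d)
      cand <- rep(frontier, each = nrow(offs)) + rep(lin_off, length(frontier))
      # mask neighbours that would wrap across grid faces
      ci <- rep(ijk[, 1], each = nrow(offs)) + rep(offs[, 1], length(frontier))
      cj <- rep(ijk[, 2], each = nrow(offs)) + rep(offs[, 2], length(frontier))
      ck <- rep(ijk[, 3], each = nrow(offs)) + rep(offs[, 3], length(frontier))
      okc <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
      cand <- unique(cand[okc])
      cand <- cand[on[cand] & labels[cand] == 0L]
      labels[cand] <- cur
      frontier <- cand
    }
  }
  labels
}
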