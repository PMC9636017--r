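#' Normalize a raw confidence column to the 0-100 plDDT scale
#'
#' Predicted models store per-residue confidence on either a 0-1 or a 0-100
#' scale. If the maximum raw value is <= 1 the values are treated as 0-1
#' and multiplied by 100; otherwise they pass through unchanged.
#'
#' @param raw numeric vector of per-residue B-values.
#' @return List of class `dr_conf_profile` with `values` (0-100 scale) and
#'   `source_scale` ("0-1" or "0-100").
#' @export
normalize_confidence <- function(raw) {
  stopifnot(length(raw) >= 1)
  if (max(raw) <= 1.0) {
    values <- raw * 100
    scale <- "0-1"
  } else {
    values <- raw
    scale <- "0-100"
  }
  if (any(values < 0) || any(values > 100.5))
    stop("values outside [0, 100.5] after normalization: ",
         "not a confidence column")
  structure(list(values = values, source_scale = scale),
            class = "dr_conf_profile")
}

#' Centered running-mean smoothing of a per-residue profile
#'
#' At the chain ends the window truncates to the available residues.
#'
#' @param values numeric per-residue vector.
#' @param window window size in residues (default 10).
#' @return Smoothed vector of the same length.
#' @export
smooth_profile <- function(values, window = 10) {
  stopifnot(window >= 1)
  n <- length(values)
  if (window == 1 || n == 1) return(values)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove low-confidence residues from a model
#'
#' The profile is smoothed (running mean, window configurable; window 1
#' disables smoothing) and residues whose smoothed confidence falls below
#' the threshold are removed. 70 is the conventional boundary for a "good"
#' prediction. Residue numbering is preserved.
#'
#' @param model A `dr_model`.
#' @param profile `dr_conf_profile` or numeric vector (0-100 scale);
#'   defaults to the model's own confidence.
#' @param threshold plDDT cutoff (default 70).
#' @param window smoothing window (default 10).
#' @return Trimmed `dr_model`.
#' @export
trim_low_confidence <- function(model, profile = NULL, threshold = 70,
                                window = 10) {
  if (is.null(profile)) profile <- normalize_confidence(model$confidence)
  vals <- if (inherits(profile, "dr_conf_profile")) profile$values else profile
  stopifnot(length(vals) == model_nres(model))
  sm <- smooth_profile(vals, window)
  keep <- which(sm >= threshold)
  if (length(keep) == 0) {
    cond <- simpleError(sprintf(
      "all residues removed by trimming (max smoothed confidence %.1f < threshold %.1f)",
      max(sm), threshold))
    cond$max_smoothed_confidence <- max(sm)
    stop(cond)
  }
  model_subset(model, keep - 1L)
}

# contiguous runs of residue numbers -> list of 0-based position vectors
contiguous_segments <- function(resno) {
  split(seq_along(resno) - 1L, cumsum(c(1L, diff(resno) != 1L)))
}

# 0-based positions -> half-open [start, end) interval matrix
positions_to_intervals <- function(positions) {
  positions <- sort(positions)
  runs <- split(positions, cumsum(c(1L, diff(positions) != 1L)))
  t(vapply(runs, function(r) c(r[1], r[length(r)] + 1L), c(0, 0)))
}

#' Split a trimmed model into compact domains
#'
#' Groups the retained residues into up to `maximum_domains` compact units,
#' each a set of half-open residue-position intervals. The default
#' "proximity" method single-linkage clusters the model's contiguous
#' segments by minimum inter-segment CA-CA distance, merging while more
#' than `maximum_domains` clusters remain or while two clusters approach
#' within `join_distance`. The "pae" method instead joins segments whose
#' between-segment predicted aligned error is below `pae_cutoff`. Clusters
#' shorter than `minimum_domain_length` are merged into the nearest
#' cluster.
#'
#' @param model trimmed `dr_model`.
#' @param maximum_domains upper bound on domain count (default 3).
#' @param minimum_domain_length minimum residues per domain (default 10).
#' @param method "proximity" (default) or "pae".
#' @param pae square PAE matrix (Angstrom) over the model's residues,
#'   required for the "pae" method.
#' @param pae_cutoff PAE below which two residues count as rigidly related
#'   (default 6 A).
#' @param join_distance proximity method: clusters closer than this are
#'   always merged (default 12 A).
#' @return List of class `dr_domain_set`: `domains` (each with `positions`,
#'   0-based, and `intervals`), `method`.
#' @export
split_into_domains <- function(model, maximum_domains = 3,
                               minimum_domain_length = 10,
                               method = c("proximity", "pae"), pae = NULL,
                               pae_cutoff = 6, join_distance = 12) {
  method <- match.arg(method)
  n <- model_nres(model)
  resno <- model_resno(model)
  segs <- contiguous_segments(resno)
  if (n < minimum_domain_length) {
    warning("model shorter than minimum_domain_length; returning one domain")
    return(domain_set(list(0:(n - 1L)), method))
  }
  ca <- model_ca(model)
  if (method == "proximity") {
    clusters <- as.list(seq_along(segs))
    seg_dist <- function(c1, c2) {
      p1 <- unlist(segs[c1]) + 1L; p2 <- unlist(segs[c2]) + 1L
      min(pairwise_dist(ca[p1, , drop = FALSE], ca[p2, , drop = FALSE]))
    }
    repeat {
      k <- length(clusters)
      if (k <= 1L) break
      dmin <- Inf; best <- NULL
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        dij <- seg_dist(clusters[[i]], clusters[[j]])
        if (dij < dmin) { dmin <- dij; best <- c(i, j) }
      }
      if (k > maximum_domains || dmin < join_distance) {
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
      } else break
    }
  } else {
    if (is.null(pae)) stop("pae matrix required for method = 'pae'")
    stopifnot(nrow(pae) == n, ncol(pae) == n)
    k <- length(segs)
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      pi <- unlist(segs[i]) + 1L; pj <- unlist(segs[j]) + 1L
      adj[i, j] <- stats::median(pae[pi, pj]) < pae_cutoff
    }
    comp <- connected_components(adj)
    clusters <- split(seq_len(k), comp)
    # still respect the maximum: merge most-related components first
    while (length(clusters) > maximum_domains) {
      k2 <- length(clusters)
      best <- c(1, 2); bestv <- Inf
      for (i in 1:(k2 - 1)) for (j in (i + 1):k2) {
        pi <- unlist(segs[clusters[[i]]]) + 1L
        pj <- unlist(segs[clusters[[j]]]) + 1L
        v <- stats::median(pae[pi, pj])
        if (v < bestv) { bestv <- v; best <- c(i, j) }
      }
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
  }
  # enforce the minimum domain length by merging short clusters inward
  repeat {
    sizes <- vapply(clusters, function(cl) length(unlist(segs[cl])), 1L)
    if (length(clusters) <= 1L || all(sizes >= minimum_domain_length)) break
    s <- which.min(sizes)
    dbest <- Inf; jbest <- NA
    for (j in seq_along(clusters)) {
      if (j == s) next
      p1 <- unlist(segs[clusters[[s]]]) + 1L
      p2 <- unlist(segs[clusters[[j]]]) + 1L
      dij <- min(pairwise_dist(ca[p1, , drop = FALSE], ca[p2, , drop = FALSE]))
      if (dij < dbest) { dbest <- dij; jbest <- j }
    }
    clusters[[jbest]] <- c(clusters[[jbest]], clusters[[s]])
    clusters[[s]] <- NULL
  }
  pos_lists <- lapply(clusters, function(cl) sort(unlist(segs[cl])))
  pos_lists <- pos_lists[order(vapply(pos_lists, min, 0))]
  domain_set(pos_lists, method)
}

domain_set <- function(pos_lists, method) {
  domains <- lapply(pos_lists, function(p)
    list(positions = as.integer(p), intervals = positions_to_intervals(p)))
  structure(list(domains = domains, method = method), class = "dr_domain_set")
}

#' @export
print.dr_domain_set <- function(x, ...) {
  cat(sprintf("<dr_domain_set> %d domain(s), method %s\n",
              length(x$domains), x$method))
  for (i in seq_along(x$domains)) {
    iv <- x$domains[[i]]$intervals
    cat(sprintf("  domain %d: %d residues [%s)\n", i,
                length(x$domains[[i]]$positions),
                paste(apply(iv, 1, function(r)
                  sprintf("%d,%d", r[1], r[2])), collapse = ") [")))
  }
  invisible(x)
}

#' Extract one domain of a model as a sub-model
#' @param model the model that was split.
#' @param domain_set a `dr_domain_set` from [split_into_domains()].
#' @param i domain index.
#' @return A `dr_model` holding the domain's residues.
#' @export
domain_model <- function(model, domain_set, i)
  model_subset(model, domain_set$domains[[i]]$positions)

#' Read a predicted-aligned-error matrix from JSON
#'
#' Accepts the common predicted-model JSON dialect: a (possibly
#' list-wrapped) object with `predicted_aligned_error` as a list of lists.
#'
#' @param path JSON file path.
#' @return Square numeric matrix, Angstrom.
#' @export
load_pae <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(x)) x <- as.list(x)
  pae <- x[["predicted_aligned_error"]]
  if (is.null(pae) && is.list(x) && length(x) >= 1)
    pae <- x[[1]][["predicted_aligned_error"]]
  if (is.null(pae)) stop("no predicted_aligned_error entry in ", path)
  if (is.list(pae) && !is.matrix(pae)) pae <- do.call(rbind, pae)
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("PAE matrix is not square")
  if (any(pae < 0)) stop("PAE values must be non-negative")
  pae
}

# all pairwise Euclidean distances between two coordinate sets
pairwise_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}
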