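# The empirical scoring function choosing which domains to include and
# where to place them, and the combination search that maximizes it.

#' Score a combination of domain placements
#'
#' The score starts at zero. If every placed domain has cc >=
#' `minimum_docking_cc`, 200-unit bonuses are added for each of: (1)
#' lowest cc of all docked domains above `acceptable_docking_cc`; (2) given
#' (1), all placements sharing similar transformations (r.m.s. coordinate
#' difference on a domain at most the map resolution); (3) all domains
#' docked; (4) fraction of overlapping residues (CA within
#' `overlap_ca_ca_distance` of another domain) below
#' `allowed_fraction_overlapping`; (5) no two sequence-consecutive domains
#' further apart than their intervening residues can span (3.8 A per
#' residue). If any pair exceeds that spannable distance by more than
#' twice the resolution plus `maximum_connectivity_deviation`, 200 units
#' are subtracted. The score is then adjusted by: + lowest cc, + mean cc,
#' - fraction of transforms differing from the first, - fraction of
#' overlapping CAs, - sum of connectivity deviations normalized to the sum
#' of allowed distances.
#'
#' @param placements list, one entry per domain: a `dr_placement` or NULL
#'   (domain not placed).
#' @param domains list of `dr_model` in sequence order (residue numbers
#'   give the intervening gaps).
#' @param resolution map resolution, Angstrom.
#' @param params A [dr_params()].
#' @param inter_domain_gaps optional integer vector overriding the number
#'   of intervening residues between consecutive domains.
#' @return List of class `dr_combo`: `placements`, `score`, `breakdown`
#'   (named terms summing exactly to `score`).
#' @export
score_placement_combo <- function(placements, domains, resolution,
                                  params = dr_params(),
                                  inter_domain_gaps = NULL) {
  n <- length(domains)
  stopifnot(length(placements) == n)
  placed <- which(!vapply(placements, is.null, TRUE))
  ccs <- vapply(placements[placed], function(p) p$cc, 0)
  br <- c()
  cas <- lapply(domains, function(d) {
    ca <- model_ca(d); ca[stats::complete.cases(ca), , drop = FALSE]
  })
  placed_ca <- lapply(placed, function(i)
    transform_apply(placements[[i]]$transform, cas[[i]]))
  # transform similarity to the first placed transform: max r.m.s.
  # difference over every placed domain's CA set
  similar <- logical(length(placed))
  if (length(placed) > 0) {
    t1 <- placements[[placed[1]]]$transform
    similar <- vapply(seq_along(placed), function(k) {
      tk <- placements[[placed[k]]]$transform
      max(vapply(placed, function(i)
        transform_rms_difference(t1, tk, cas[[i]]), 0)) <= resolution
    }, TRUE)
  }
  frac_different <- if (length(placed)) mean(!similar) else 0
  # CA overlap between placed domains
  n_ca <- sum(vapply(placed_ca, nrow, 0L))
  n_overlap <- 0L
  if (length(placed) > 1) {
    for (a in seq_along(placed)) {
      other <- do.call(rbind, placed_ca[-a])
      d <- pairwise_dist(placed_ca[[a]], other)
      n_overlap <- n_overlap + sum(apply(d, 1, min) <= params$overlap_ca_ca_distance)
    }
  }
  frac_overlap <- if (n_ca > 0) n_overlap / n_ca else 0
  # connectivity between sequence-consecutive placed domains
  gaps <- numeric(0); dists <- numeric(0)
  if (length(placed) > 1) {
    for (k in seq_len(length(placed) - 1)) {
      i <- placed[k]; j <- placed[k + 1]
      gap <- if (!is.null(inter_domain_gaps)) {
        sum(inter_domain_gaps[i:(j - 1)])
      } else {
        min(model_resno(domains[[j]])) - max(model_resno(domains[[i]])) - 1
      }
      ei <- placed_ca[[k]][nrow(placed_ca[[k]]), ]
      sj <- placed_ca[[k + 1]][1, ]
      gaps <- c(gaps, gap)
      dists <- c(dists, sqrt(sum((ei - sj)^2)))
    }
  }
  allowed <- 3.8 * (gaps + 1)
  # small epsilon so exactly-spannable gaps are not penalized by rounding
  dev <- pmax(0, dists - allowed - 1e-9)
  spannable <- all(dev == 0)
  big_violation <- any(dists > allowed + 2 * resolution +
                         params$maximum_connectivity_deviation + 1e-9)
  gate <- length(placed) > 0 && all(ccs >= params$minimum_docking_cc)
  if (gate) {
    lowest_ok <- min(ccs) > params$acceptable_docking_cc
    br["bonus_lowest_cc"] <- if (lowest_ok) 200 else 0
    # similarity is only evidence of rigid-body docking when at least two
    # domains are placed; a lone placement earns no vacuous bonus here
    br["bonus_similar_transforms"] <-
      if (lowest_ok && all(similar) && length(placed) >= 2) 200 else 0
    br["bonus_all_docked"] <- if (length(placed) == n) 200 else 0
    br["bonus_low_overlap"] <-
      if (frac_overlap < params$allowed_fraction_overlapping) 200 else 0
    br["bonus_connectivity"] <- if (spannable) 200 else 0
  }
  br["penalty_connectivity"] <- if (big_violation) -200 else 0
  br["adj_lowest_cc"] <- if (length(placed)) min(ccs) else 0
  br["adj_average_cc"] <- if (length(placed)) mean(ccs) else 0
  br["adj_fraction_different"] <- -frac_different
  br["adj_fraction_overlap"] <- -frac_overlap
  br["adj_connectivity_deviation"] <-
    if (length(allowed) && sum(allowed) > 0) -sum(dev) / sum(allowed) else 0
  structure(list(placements = placements, score = sum(br), breakdown = br),
            class = "dr_combo")
}

#' @export
print.dr_combo <- function(x, ...) {
  placed <- sum(!vapply(x$placements, is.null, TRUE))
  cat(sprintf("<dr_combo> %d/%d domains placed, score %.3f\n",
              placed, length(x$placements), x$score))
  nz <- x$breakdown[x$breakdown != 0]
  if (length(nz))
    cat(paste0("  ", names(nz), ": ", sprintf("%.3f", nz), collapse = "\n"), "\n")
  invisible(x)
}

#' Choose the best combination of domain placements
#'
#' Enumerates every combination of (top-K placements per domain + "not
#' placed") when the product of options is at most `max_exhaustive`,
#' otherwise runs a greedy beam search (the beam holds the best partial
#' combinations domain by domain). Exhaustive mode is optimal by
#' construction.
#'
#' @param placement_lists list (per domain) of lists of `dr_placement`,
#'   each sorted by decreasing cc.
#' @param domains list of `dr_model` in sequence order.
#' @param resolution Angstrom.
#' @param params A [dr_params()] (`top_k_placements` caps the options per
#'   domain).
#' @param inter_domain_gaps optional override, see
#'   [score_placement_combo()].
#' @param max_exhaustive combination-count bound for exhaustive search
#'   (default 10000).
#' @param beam_width beam size for the greedy fallback (default 50).
#' @return The best-scoring `dr_combo`; when no domain has any placement,
#'   an all-unplaced combo with attribute `diagnostic`.
#' @export
select_placements <- function(placement_lists, domains, resolution,
                              params = dr_params(), inter_domain_gaps = NULL,
                              max_exhaustive = 10000, beam_width = 50) {
  n <- length(domains)
  options <- lapply(placement_lists, function(pl) {
    pl <- pl[seq_len(min(length(pl), params$top_k_placements))]
    c(pl, list(NULL))
  })
  if (all(vapply(options, length, 0L) == 1L)) {
    combo <- score_placement_combo(vector("list", n), domains, resolution,
                                   params, inter_domain_gaps)
    attr(combo, "diagnostic") <- "no domain could be placed"
    return(combo)
  }
  counts <- vapply(options, length, 0L)
  scorer <- function(sel) {
    placements <- lapply(seq_len(n), function(i) options[[i]][[sel[i]]])
    score_placement_combo(placements, domains, resolution, params,
                          inter_domain_gaps)
  }
  if (prod(counts) <= max_exhaustive) {
    grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
    best <- NULL
    for (r in seq_len(nrow(grid))) {
      combo <- scorer(grid[r, ])
      if (is.null(best) || combo$score > best$score) best <- combo
    }
  } else {
    beams <- list(integer(0))
    for (i in seq_len(n)) {
      cand <- list()
      for (b in beams) for (o in seq_len(counts[i]))
        cand[[length(cand) + 1L]] <- c(b, o)
      # score partial combinations with the remaining domains unplaced
      # (the last option index of each domain is the NULL placement)
      rest <- if (i < n) counts[(i + 1):n] else integer(0)
      sc <- vapply(cand, function(sel) scorer(c(sel, rest))$score, 0)
      beams <- cand[order(-sc)][seq_len(min(beam_width, length(cand)))]
    }
    best <- NULL
    for (b in beams) {
      combo <- scorer(b)
      if (is.null(best) || combo$score > best$score) best <- combo
    }
  }
  best
}
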