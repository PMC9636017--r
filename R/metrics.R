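#' Kabsch superposition of paired coordinates
#'
#' @param mobile,target n x 3 matrices of paired coordinates (n >= 3).
#' @return A `dr_transform` mapping mobile onto target, with attribute
#'   `rmsd`.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- transform_new(R, ct - as.numeric(R %*% cm))
  moved <- transform_apply(tr, mobile)
  attr(tr, "rmsd") <- sqrt(mean(rowSums((moved - target)^2)))
  tr
}

# global sequence alignment (match +1, mismatch -1, gap -2 per residue)
# via Biostrings; returns 1-based index pairs of aligned positions
align_sequences <- function(a, b) {
  letters_all <- unique(c(a, b))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    paste(a, collapse = ""), paste(b, collapse = ""), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- 0L; j <- 0L
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") i <- i + 1L
    if (sa[k] != "-") j <- j + 1L
    if (pa[k] != "-" && sa[k] != "-") { pi <- c(pi, i); pj <- c(pj, j) }
  }
  cbind(pi, pj)
}

#' Least-squares superposition of two models
#'
#' CA pairs are identified by global sequence alignment (identity scoring:
#' match +1, mismatch -1, gap -2) and superposed by the Kabsch algorithm.
#'
#' @param mobile,target `dr_model` objects sharing >= 3 aligned residues.
#' @return List of class `dr_superposition`: `transform` (maps mobile onto
#'   target), `rmsd` (over the aligned CA pairs), `n_pairs`.
#' @export
superpose_lsq <- function(mobile, target) {
  pairs <- align_sequences(model_sequence(mobile), model_sequence(target))
  cam <- model_ca(mobile)[pairs[, 1], , drop = FALSE]
  cat_ <- model_ca(target)[pairs[, 2], , drop = FALSE]
  ok <- stats::complete.cases(cam) & stats::complete.cases(cat_)
  if (sum(ok) < 3) stop("fewer than 3 aligned CA pairs")
  tr <- kabsch(cam[ok, , drop = FALSE], cat_[ok, , drop = FALSE])
  structure(list(transform = tr, rmsd = attr(tr, "rmsd"), n_pairs = sum(ok)),
            class = "dr_superposition")
}

#' Connectivity-blind CA match statistics between superposed models
#'
#' Counts the target CA atoms that are matched within `match_distance` by
#' *any* CA atom of the comparison model (no superposition is performed
#' here; matching any copy is allowed, so chain connectivity is ignored).
#'
#' @param target reference `dr_model` (its CA count is the denominator).
#' @param model comparison `dr_model`, already superposed.
#' @param match_distance matching cutoff in Angstrom (default 3.0; 2.0 is
#'   a common stricter variant).
#' @return List of class `dr_comparison`: `n_target_ca`, `n_matched`,
#'   `fraction_matched`, `rmsd_matched` (over matched nearest-neighbour
#'   distances), `pbs` (percentile-based spread of those distances).
#' @export
chain_comparison <- function(target, model, match_distance = 3.0) {
  ta <- model_ca(target); mo <- model_ca(model)
  ta <- ta[stats::complete.cases(ta), , drop = FALSE]
  mo <- mo[stats::complete.cases(mo), , drop = FALSE]
  if (nrow(ta) == 0) stop("empty target model")
  d <- pairwise_dist(ta, mo)
  nearest <- apply(d, 1, min)
  matched <- nearest <= match_distance
  structure(list(
    n_target_ca = nrow(ta),
    n_matched = sum(matched),
    fraction_matched = mean(matched),
    rmsd_matched = if (any(matched)) sqrt(mean(nearest[matched]^2)) else NA_real_,
    pbs = if (any(matched)) percentile_based_spread(nearest) else NA_real_),
    class = "dr_comparison")
}

#' @export
print.dr_comparison <- function(x, ...) {
  cat(sprintf("<dr_comparison> %d/%d CA matched (%.1f%%), rmsd %.2f A, pbs %.2f A\n",
              x$n_matched, x$n_target_ca, 100 * x$fraction_matched,
              x$rmsd_matched, x$pbs))
  invisible(x)
}

#' Percentile-based spread of coordinate deviations
#'
#' A robust alternative to the r.m.s.d. that de-emphasizes large
#' discrepancies. Implemented as a median-calibrated scale estimate: with
#' `m` the median of the 3D deviation magnitudes, the spread is
#' `sqrt(3) * m / q`, where `q` is the median of the Maxwell (3D Gaussian
#' magnitude) distribution with unit per-coordinate sigma (about 1.5382).
#' For exactly Gaussian deviations this converges to the ordinary r.m.s.d.;
#' because it depends only on the median it is insensitive to inflating the
#' largest few percent of deviations.
#'
#' @param deviations non-negative deviation magnitudes, Angstrom.
#' @return Spread in Angstrom.
#' @export
percentile_based_spread <- function(deviations) {
  stopifnot(length(deviations) >= 1, all(deviations >= 0))
  sqrt(3) * stats::median(deviations) / maxwell_median()
}

maxwell_median <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cdf <- function(x) stats::pgamma(x^2 / 2, shape = 1.5)
      cache <<- stats::uniroot(function(x) cdf(x) - 0.5, c(0.1, 5),
                               tol = 1e-12)$root
    }
    cache
  }
})
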