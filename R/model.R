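#' Structure model container
#'
#' A `dr_model` holds one protein chain as a flat atom table plus a
#' per-residue confidence vector. Predicted models carry their confidence
#' (plDDT semantics, 0-100) in the B-value column; on load it is copied
#' verbatim into `confidence` and can be normalized with
#' [normalize_confidence()].
#'
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (3-letter code), `atom` (atom name, e.g. "CA"), `element`, `x`, `y`,
#'   `z` (Angstrom) and `b`.
#' @param chain_id single chain identifier (multi-character IDs allowed).
#' @param confidence optional per-residue numeric; defaults to the B-value
#'   of each residue's CA atom.
#' @return An object of class `dr_model`.
#' @export
model_new <- function(atoms, chain_id = "A", confidence = NULL) {
  need <- c("resno", "resname", "atom", "element", "x", "y", "z", "b")
  stopifnot(all(need %in% names(atoms)))
  atoms <- as.data.frame(atoms)[, need]
  atoms$resno <- as.integer(atoms$resno)
  resno <- unique(atoms$resno)
  if (any(diff(resno) <= 0))
    stop("residue numbers must be strictly increasing within a chain")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  m <- structure(list(chain_id = chain_id, atoms = atoms,
                      confidence = NULL), class = "dr_model")
  if (is.null(confidence)) {
    ca <- atoms[atoms$atom == "CA", , drop = FALSE]
    confidence <- atoms$b[match(resno, atoms$resno)]
    hit <- match(resno, ca$resno)
    confidence[!is.na(hit)] <- ca$b[hit[!is.na(hit)]]
  }
  stopifnot(length(confidence) == length(resno))
  m$confidence <- as.numeric(confidence)
  m
}

#' @export
print.dr_model <- function(x, ...) {
  cat(sprintf("<dr_model> chain %s: %d residues, %d atoms\n",
              x$chain_id, model_nres(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a model
#' @param model A `dr_model`.
#' @return Integer residue count.
#' @export
model_nres <- function(model) length(unique(model$atoms$resno))

#' Residue numbers of a model
#' @param model A `dr_model`.
#' @return Integer vector of residue numbers (labels), in chain order.
#' @export
model_resno <- function(model) unique(model$atoms$resno)

#' CA coordinates of a model
#' @param model A `dr_model`.
#' @return n x 3 matrix of CA coordinates in residue order; residues
#'   without a CA atom yield NA rows.
#' @export
model_ca <- function(model) {
  resno <- model_resno(model)
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  idx <- match(resno, ca$resno)
  out <- cbind(ca$x[idx], ca$y[idx], ca$z[idx])
  rownames(out) <- resno
  out
}

#' All-atom coordinates of a model
#' @param model A `dr_model`.
#' @return n_atoms x 3 coordinate matrix.
#' @export
model_coords <- function(model)
  as.matrix(model$atoms[, c("x", "y", "z")])

#' Replace all-atom coordinates of a model
#' @param model A `dr_model`.
#' @param xyz n_atoms x 3 matrix.
#' @return The model with new coordinates.
#' @export
model_set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' One-letter amino-acid sequence of a model
#' @param model A `dr_model`.
#' @return Character vector of one-letter codes (X for unknown residues).
#' @export
model_sequence <- function(model) {
  resno <- model_resno(model)
  three <- model$atoms$resname[match(resno, model$atoms$resno)]
  one <- bio3d::aa321(three)
  one[is.na(one)] <- "X"
  one
}

#' Subset a model by residue position
#'
#' Positions are 0-based indices into the chain; intervals elsewhere in the
#' package are half-open `[start, end)` on these indices, with the residue
#' number kept as an independent label.
#'
#' @param model A `dr_model`.
#' @param positions integer vector of 0-based residue positions to keep.
#' @return The sub-model (residue numbering preserved).
#' @export
model_subset <- function(model, positions) {
  resno <- model_resno(model)
  keep <- resno[positions + 1L]
  sel <- model$atoms$resno %in% keep
  if (!any(sel)) stop("subset removes every residue")
  model_new(model$atoms[sel, , drop = FALSE], model$chain_id,
            model$confidence[positions + 1L])
}

#' Apply a rigid transform to a whole model
#' @param model A `dr_model`.
#' @param tr A `dr_transform`.
#' @return The transformed model.
#' @export
model_transform <- function(model, tr)
  model_set_coords(model, transform_apply(tr, model_coords(model)))

#' Replace the coordinates of a run of residues
#'
#' @param model A `dr_model`.
#' @param positions 0-based residue positions being replaced.
#' @param ca n x 3 matrix of new CA coordinates for those positions.
#' @details Every atom of each touched residue is translated rigidly with
#'   its CA, so backbone geometry within a residue is preserved.
#' @return The edited model.
#' @export
model_set_ca <- function(model, positions, ca) {
  stopifnot(nrow(ca) == length(positions))
  resno <- model_resno(model)
  old <- model_ca(model)
  xyz <- model_coords(model)
  for (k in seq_along(positions)) {
    rn <- resno[positions[k] + 1L]
    shift <- ca[k, ] - old[positions[k] + 1L, ]
    rows <- which(model$atoms$resno == rn)
    xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, -shift)
  }
  model_set_coords(model, xyz)
}

#' Concatenate the atoms of several models covering disjoint residue ranges
#' @param models list of `dr_model` objects with disjoint, ordered residue
#'   numbers.
#' @return One combined `dr_model`.
#' @export
model_bind <- function(models) {
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  conf <- unlist(lapply(models, function(m) m$confidence))
  model_new(atoms, models[[1]]$chain_id, conf)
}
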