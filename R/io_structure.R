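#' Read a structure model from PDB or mmCIF
#'
#' Parses coordinates, residue numbering and the B-value column (which for
#' predicted models carries per-residue confidence; it is copied verbatim
#' into `confidence`, rescaling is left to [normalize_confidence()]).
#' Hydrogens are dropped on input; the machinery downstream operates at the
#' CA/heavy-atom level.
#'
#' @param path file path.
#' @param format one of `"auto"` (default, by extension), `"pdb"`, `"mmcif"`.
#' @return A `dr_model` if the file holds one chain, otherwise a named list
#'   of `dr_model`, one per chain.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- substr(at$elety[is.na(elem) | elem == ""], 1, 1)
  keep <- toupper(elem) != "H"
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  if (nrow(at) == 0L) stop("no non-hydrogen atoms in ", path)
  chains <- unique(at$chain)
  models <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    e <- elem[at$chain == ch]
    if (!any(a$elety == "CA"))
      stop("empty model: chain ", ch, " of ", path, " has no CA atoms")
    model_new(data.frame(resno = a$resno, resname = a$resid, atom = a$elety,
                         element = toupper(e), x = a$x, y = a$y, z = a$z,
                         b = a$b, stringsAsFactors = FALSE),
              chain_id = ch)
  })
  names(models) <- chains
  if (length(models) == 1L) models[[1L]] else models
}

#' Write a structure model to PDB or mmCIF
#'
#' The per-residue `confidence` vector is written into the B-value column
#' of every atom of the residue, mirroring how predicted models store
#' plDDT. Round-trips preserve coordinates to PDB precision (1e-3 A) and
#' residue numbering exactly.
#'
#' @param model A `dr_model` (or list of them, written as separate chains).
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
save_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  models <- if (inherits(model, "dr_model")) list(model) else model
  if (length(models) == 0L || any(!vapply(models, function(m) nrow(m$atoms) > 0, TRUE)))
    stop("cannot save an empty model")
  tabs <- lapply(models, function(m) {
    a <- m$atoms
    resno <- model_resno(m)
    a$b <- m$confidence[match(a$resno, resno)]
    a$chain <- m$chain_id
    a
  })
  at <- do.call(rbind, tabs)
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resname, eleno = seq_len(nrow(at)),
                     elety = at$atom, chain = at$chain, b = at$b,
                     o = rep(1, nrow(at)), elesy = at$element)
  } else {
    write_mmcif_atoms(at, path)
  }
  invisible(path)
}

# minimal atom_site mmCIF writer (coordinates, B column, chain ids)
write_mmcif_atoms <- function(at, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
    seq_len(nrow(at)), at$element, at$atom, at$resname, at$chain, at$resno,
    at$x, at$y, at$z, at$b, at$resno, at$resname, at$chain, at$atom)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
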