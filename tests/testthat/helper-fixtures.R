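# shared helpers for building tiny in-code fixtures

# a minimal hand-written 3-residue PDB text
write_tiny_pdb <- function(path, resno = c(1L, 2L, 3L)) {
  lines <- c(
    sprintf("ATOM  %5d  N   ALA A%4d      11.104   6.134  -6.504  1.00 91.40           N", 1, resno[1]),
    sprintf("ATOM  %5d  CA  ALA A%4d      11.639   6.071  -5.147  1.00 91.40           C", 2, resno[1]),
    sprintf("ATOM  %5d  C   ALA A%4d      10.898   6.962  -4.155  1.00 91.40           C", 3, resno[1]),
    sprintf("ATOM  %5d  O   ALA A%4d      10.062   7.784  -4.525  1.00 91.40           O", 4, resno[1]),
    sprintf("ATOM  %5d  N   GLY A%4d      11.225   6.818  -2.871  1.00 85.20           N", 5, resno[2]),
    sprintf("ATOM  %5d  CA  GLY A%4d      10.602   7.602  -1.809  1.00 85.20           C", 6, resno[2]),
    sprintf("ATOM  %5d  C   GLY A%4d      11.107   9.040  -1.781  1.00 85.20           C", 7, resno[2]),
    sprintf("ATOM  %5d  O   GLY A%4d      12.306   9.291  -1.914  1.00 85.20           O", 8, resno[2]),
    sprintf("ATOM  %5d  N   VAL A%4d      10.190   9.990  -1.611  1.00 77.70           N", 9, resno[3]),
    sprintf("ATOM  %5d  CA  VAL A%4d      10.542  11.405  -1.551  1.00 77.70           C", 10, resno[3]),
    sprintf("ATOM  %5d  C   VAL A%4d       9.955  12.118  -0.336  1.00 77.70           C", 11, resno[3]),
    sprintf("ATOM  %5d  O   VAL A%4d       8.781  11.943   0.003  1.00 77.70           O", 12, resno[3]),
    "END")
  writeLines(lines, path)
  path
}

# independent raw MRC writer used to test header conventions: writes the
# grid with an arbitrary axis permutation and NSTART values
write_raw_mrc <- function(path, grid, voxel = 1, mapcrs = c(1L, 2L, 3L),
                          nstart = c(0L, 0L, 0L), origin = c(0, 0, 0),
                          angles = c(90, 90, 90)) {
  d_xyz <- dim(grid)
  perm <- mapcrs                      # file axis f stores crystal axis mapcrs[f]
  file_dims <- d_xyz[perm]
  arr <- aperm(grid, perm)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(file_dims); wi(2); wi(nstart[perm]); wi(d_xyz)
  wf(d_xyz * voxel); wf(angles)
  wi(mapcrs)
  wf(c(min(grid), max(grid), mean(grid)))
  wi(1); wi(0); wi(rep(0, 25))
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  wf(stats::sd(as.numeric(grid)))
  wi(0)
  writeBin(raw(800), con)
  wf(as.numeric(arr))
  path
}

# random rigid transform under the current RNG
random_transform <- function(max_angle = pi, max_shift = 10) {
  axis <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle)
  transform_new(rotation_axis_angle(axis, ang),
                stats::runif(3, -max_shift, max_shift))
}

# a small two-perpendicular-helix model with clean rods in its map
# (no loops, so map-derived SSE detection is unambiguous)
two_helix_model <- function() {
  h1 <- dockrebuild:::helix_trace(12, c(0, 0, 0), 1)
  h2t <- dockrebuild:::helix_trace(12, c(0, 0, 0), 1)
  R <- rotation_axis_angle(c(0, 1, 0), pi / 2)
  h2 <- sweep(h2t %*% t(R), 2, -c(10, 0, 8))
  ca <- rbind(h1, h2)
  n <- nrow(ca)
  atoms <- data.frame(resno = c(1:12, 31:42), resname = "ALA", atom = "CA",
                      element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      b = 90)
  # add N, C, O around each CA for realistic mass
  bb <- dockrebuild:::backbone_from_ca(ca)
  full <- do.call(rbind, lapply(seq_len(n), function(i) {
    rn <- atoms$resno[i]
    data.frame(resno = rn, resname = "ALA",
               atom = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(bb$N[i, 1], ca[i, 1], bb$C[i, 1], bb$O[i, 1]),
               y = c(bb$N[i, 2], ca[i, 2], bb$C[i, 2], bb$O[i, 2]),
               z = c(bb$N[i, 3], ca[i, 3], bb$C[i, 3], bb$O[i, 3]),
               b = 90)
  }))
  model_new(full, "A")
}
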