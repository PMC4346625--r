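# Multi-model PDB trajectory I/O. One MODEL per frame; the CRYST1 record
# carries the periodic z repeat length. Atom parameters (charge, LJ, Born
# radius) travel in a sidecar CSV, since PDB has no fields for them.

pdb_atom_line <- function(serial, name, resname, resid, xyz) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000, substr(name, 1, 4), resname, resid %% 10000,
          xyz[1], xyz[2], xyz[3])
}

#' Write a fibre trajectory as a multi-model PDB plus sidecar CSV
#'
#' Each frame becomes one MODEL; monomers are residues (resname BTA). The
#' CRYST1 record stores the periodic z length (a, b set to the extended
#' diameter). The sidecar CSV stores, per atom: id, name, monomer, charge
#' (e), LJ epsilon (kcal/mol), LJ sigma (Angstrom) and intrinsic Born radius
#' (Angstrom).
#'
#' @param trajectory a `fiber_trajectory` (or single `fiber_frame`).
#' @param topology the matching `fiber_topology`.
#' @param pdb_path output PDB path.
#' @param sidecar_path output CSV path (default: PDB path with
#'   `_params.csv`).
#' @return `pdb_path`, invisibly.
#' @export
write_fiber_pdb <- function(trajectory, topology, pdb_path,
                            sidecar_path = sub("\\.pdb$", "_params.csv",
                                               pdb_path)) {
  frames <- if (inherits(trajectory, "fiber_frame")) list(trajectory)
  else trajectory$frames
  at <- topology$atoms
  con <- file(pdb_path, "w")
  on.exit(close(con))
  box_z <- frames[[1]]$box_z
  lat <- topology$extended_diameter
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    lat, lat, box_z, 90, 90, 90), con)
  atom_names <- paste0(at$name, ifelse(at$name == "B", "", ""), at$arm)
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    co <- frames[[m]]$coords
    writeLines(vapply(seq_len(nrow(at)), function(i) {
      pdb_atom_line(at$id[i], atom_names[i], "BTA", at$monomer[i], co[i, ])
    }, character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  write.csv(data.frame(atom_id = at$id, name = at$name, arm = at$arm,
                       monomer = at$monomer, charge = at$charge,
                       lj_eps = at$eps, lj_sigma = at$sigma,
                       born_radius = at$rho_born),
            sidecar_path, row.names = FALSE, quote = FALSE)
  invisible(pdb_path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL blocks into frames and the CRYST1 c axis into the periodic z
#' length. Returns coordinates only; topology information comes from the
#' sidecar CSV via [read_sidecar()].
#'
#' @param pdb_path path to a PDB written by [write_fiber_pdb()].
#' @return a `fiber_trajectory`.
#' @export
read_fiber_pdb <- function(pdb_path) {
  lines <- readLines(pdb_path)
  cry <- grep("^CRYST1", lines, value = TRUE)[1]
  box_z <- as.numeric(substr(cry, 25, 33))
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  assert_that(length(model_starts) == length(model_ends) &&
                length(model_starts) >= 1, "malformed multi-model PDB")
  frames <- lapply(seq_along(model_starts), function(m) {
    blk <- lines[(model_starts[m] + 1):(model_ends[m] - 1)]
    blk <- blk[startsWith(blk, "ATOM")]
    co <- cbind(as.numeric(substr(blk, 31, 38)),
                as.numeric(substr(blk, 39, 46)),
                as.numeric(substr(blk, 47, 54)))
    structure(list(coords = co, box_z = box_z, time = m - 1),
              class = "fiber_frame")
  })
  structure(list(frames = frames, n_frames = length(frames),
                 times = seq_along(frames) - 1),
            class = "fiber_trajectory")
}

#' @rdname read_fiber_pdb
#' @param sidecar_path path to the parameter sidecar CSV.
#' @return `read_sidecar` returns the atom parameter data.frame.
#' @export
read_sidecar <- function(sidecar_path) {
  read.csv(sidecar_path)
}
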