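# Structured-text I/O.  System definitions, selections and run configs are
# YAML; trajectories, exchange logs and analysis tables are TSV; structures
# optionally round-trip through a one-bead-per-CA PDB dialect (via bio3d).

#' Write a system (and optional selection) to a YAML file
#'
#' The schema has top-level keys `atoms` (mass, charge, epsilon, sigma,
#' x, y, z per atom), `bonds`, `angles`, `dihedrals`, `restraints` (lists
#' of term records), `nonbonded` (logical), and optionally `selection`
#' (`atoms`, `categories`).
#'
#' @param system a [toy_system()].
#' @param path output file.
#' @param sel optional [solute_selection()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path, sel = NULL) {
  df_list <- function(d) if (NROW(d) == 0) list() else
    lapply(seq_len(nrow(d)), function(r) as.list(d[r, ]))
  obj <- list(
    atoms = lapply(seq_len(system$n_atoms), function(i) list(
      mass = system$masses[i], charge = system$charges[i],
      epsilon = system$lj[i, "epsilon"], sigma = system$lj[i, "sigma"],
      x = system$positions[i, 1], y = system$positions[i, 2],
      z = system$positions[i, 3])),
    bonds = df_list(system$bonds),
    angles = df_list(system$angles),
    dihedrals = df_list(system$dihedrals),
    restraints = df_list(system$restraints),
    nonbonded = system$nonbonded)
  if (!is.null(sel))
    obj$selection <- list(atoms = as.list(sel$atoms),
                          categories = as.list(sel$categories))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a system YAML file
#' @param path file written by [write_system()].
#' @return List with `system` and `sel` (`NULL` when the file stores none).
#' @export
read_system <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$atoms)) stop("not a system file (no atoms key): ", path)
  at <- do.call(rbind, lapply(obj$atoms, as.data.frame))
  tab <- function(key) if (length(obj[[key]]) == 0) NULL else
    do.call(rbind, lapply(obj[[key]], as.data.frame))
  system <- toy_system(
    positions = as.matrix(at[, c("x", "y", "z")]),
    masses = at$mass, charges = at$charge,
    lj = cbind(epsilon = at$epsilon, sigma = at$sigma),
    bonds = tab("bonds"), angles = tab("angles"),
    dihedrals = tab("dihedrals"), restraints = tab("restraints"),
    nonbonded = isTRUE(obj$nonbonded))
  sel <- if (!is.null(obj$selection))
    solute_selection(unlist(obj$selection$atoms),
                     unlist(obj$selection$categories), system$n_atoms)
  list(system = system, sel = sel)
}

#' Write/read a coordinate set as TSV (atom, x, y, z)
#' @param x n x 3 matrix.
#' @param path file path.
#' @return `path` / the coordinate matrix.
#' @export
write_coords <- function(x, path) {
  d <- data.frame(atom = seq_len(nrow(x)), x = x[, 1], y = x[, 2], z = x[, 3])
  utils::write.table(format(d, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  as.matrix(d[, c("x", "y", "z")])
}

#' Write a gREST run to delimited-text files
#'
#' Emits `<prefix>_frames.tsv` (per-frame metadata and energies),
#' `<prefix>_coords.tsv` (long-format coordinates), `<prefix>_exchange.tsv`
#' (the exchange log), and `<prefix>_manifest.yaml` (seed, resolved config,
#' package version, file inventory with MD5 hashes).
#'
#' @param run a `grest_run`.
#' @param prefix output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_run <- function(run, prefix) {
  fr <- run$frames
  frames_path <- paste0(prefix, "_frames.tsv")
  coords_path <- paste0(prefix, "_coords.tsv")
  exch_path <- paste0(prefix, "_exchange.tsv")
  manifest_path <- paste0(prefix, "_manifest.yaml")
  meta <- data.frame(frame = seq_along(fr$sweep), sweep = fr$sweep,
                     replica = fr$replica, param = fr$param,
                     E_uu = fr$E_uu, E_vv = fr$E_vv, E_scaled = fr$E_scaled)
  utils::write.table(format(meta, digits = 17), frames_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  n <- nrow(fr$coords[[1]])
  co <- do.call(rbind, lapply(seq_along(fr$coords), function(f)
    cbind(frame = f, atom = seq_len(n), fr$coords[[f]])))
  colnames(co) <- c("frame", "atom", "x", "y", "z")
  utils::write.table(format(as.data.frame(co), digits = 17), coords_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(run$exchange_log, digits = 17), exch_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(frames = frames_path, coords = coords_path, exchange = exch_path)
  manifest <- list(
    seed = run$config$seed,
    config = run$config,
    package_version = as.character(utils::packageVersion("grest")),
    files = lapply(seq_along(files), function(i) list(
      role = names(files)[i], path = basename(files[i]),
      md5 = unname(tools::md5sum(files[i])))))
  yaml::write_yaml(manifest, manifest_path, precision = 15)
  invisible(c(files, manifest = manifest_path))
}

#' Read Cα coordinates from a PDB file
#'
#' Extracts the Cα (or single-bead CA record) coordinates from standard
#' `ATOM` records, for use as RMSD references.
#'
#' @param path PDB file.
#' @return n x 3 coordinate matrix.
#' @export
read_pdb_ca <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sele <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sele$atom) == 0) stop("no CA atoms in ", path)
  matrix(pdb$xyz[sele$xyz], ncol = 3, byrow = TRUE)
}

#' Write coordinates as a minimal Cα-only PDB
#'
#' One `ATOM` record per bead, named CA in residue GLY, chain A — a minimal
#' dialect interoperable with [read_pdb_ca()] and standard viewers.
#'
#' @param x n x 3 coordinate matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(x, path) {
  x <- as.matrix(x)
  n <- nrow(x)
  bio3d::write.pdb(file = path, xyz = as.vector(t(x)),
                   resno = seq_len(n), resid = rep("GLY", n),
                   chain = rep("A", n), elety = rep("CA", n))
  invisible(path)
}
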