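## Minimal GRO / PDB coordinate I/O. Coordinates are nm internally (GRO
## native; PDB Angstrom values are converted on the way in/out). Only
## orthorhombic boxes are supported; box periodicity is x,y (in-plane)
## for clustering and x,y,z for contacts.

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
             "HIS", "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE",
             "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Default species and marker-atom mapping
#'
#' Maps force-field residue names to the package's closed species
#' vocabulary (DPPC, POPC, POPG, CHOL, PROTEIN, CHEMICAL, WATER, ION)
#' and atom names to analysis roles: per-chain first/10th/16th acyl
#' carbons (CHARMM sn-2 chain `C22`/`C210`/`C216`, sn-1 chain
#' `C32`/`C310`/`C316`), the cholesterol C14 packing marker and O3
#' head marker, and the phosphate `P`. The synthetic builder emits the
#' same names, so one map covers both. Extend by editing the returned
#' list (or load a JSON file of the same shape with
#' [readSpeciesMap()]).
#'
#' @return A list with elements `residues` (named character:
#'   residue name -> species) and `roles` (data.frame: `atom`, `role`
#'   in first/mid/last/chol_marker/chol_head/phosphate, `chain`).
#' @export
defaultSpeciesMap <- function() {
  residues <- c(DPPC = "DPPC", POPC = "POPC", POPG = "POPG",
                CHL1 = "CHOL", CHOL = "CHOL",
                TIP3 = "WATER", TIP4 = "WATER", OPC = "WATER",
                SOL = "WATER", HOH = "WATER", W = "WATER",
                SOD = "ION", CLA = "ION", POT = "ION", MG = "ION",
                CHEM = "CHEMICAL", BA = "CHEMICAL", BPGA = "CHEMICAL",
                PROT = "PROTEIN")
  residues <- c(residues,
                stats::setNames(rep("PROTEIN", length(.AMINO3)), .AMINO3))
  roles <- data.frame(
    atom = c("C22", "C210", "C216", "C32", "C310", "C316", "C14", "O3",
             "P"),
    role = c("first", "mid", "last", "first", "mid", "last",
             "chol_marker", "chol_head", "phosphate"),
    chain = c(1L, 1L, 1L, 2L, 2L, 2L, NA, NA, NA))
  list(residues = residues, roles = roles)
}

#' Read a species map from JSON
#'
#' @param path JSON file with keys `residues` (object: residue ->
#'   species) and optionally `roles` (records with `atom`, `role`,
#'   `chain`); missing pieces fall back to [defaultSpeciesMap()].
#' @return A species-map list.
#' @export
readSpeciesMap <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- defaultSpeciesMap()
  if (!is.null(raw$residues))
    map$residues <- c(unlist(raw$residues), map$residues)
  if (!is.null(raw$roles))
    map$roles <- as.data.frame(raw$roles)
  map
}

.guess_element <- function(atom_name, res_name) {
  ion <- c(SOD = "Na", CLA = "Cl", POT = "K", MG = "Mg", `NA` = "Na",
           CL = "Cl", K = "K")
  out <- ion[res_name]
  first <- toupper(substring(gsub("[^A-Za-z].*$", "",
                                  sub("^[0-9]+", "", atom_name)), 1, 1))
  ifelse(is.na(out), ifelse(nzchar(first), first, "X"), out)
}

.frame_from_table <- function(resid, resname, atomname, xyz, box, map,
                              frame_time = NA_real_, element = NULL) {
  unknown <- setdiff(unique(resname), names(map$residues))
  if (length(unknown))
    stop(sprintf("residue name(s) without a species mapping: %s",
                 paste(unknown, collapse = ", ")))
  species <- unname(map$residues[resname])
  ## new molecule whenever the (possibly wrapping) residue id changes
  mol <- cumsum(c(TRUE, resid[-1] != resid[-length(resid)] |
                          resname[-1] != resname[-length(resname)]))
  if (is.null(element))
    element <- .guess_element(atomname, resname)
  MonolayerFrame(coords = xyz, atomName = atomname, element = element,
                 resName = resname, species = species,
                 moleculeId = as.integer(mol), box = box,
                 frameTime = frame_time)
}

.read_gro <- function(path, map) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) ) { pos <- pos + 1L; next }
    title <- lines[pos]
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms))
      stop(sprintf("malformed GRO atom count at line %d of %s",
                   pos + 1L, path))
    at <- lines[seq.int(pos + 2L, pos + 1L + natoms)]
    box_line <- trimws(lines[pos + 2L + natoms])
    box <- as.numeric(strsplit(box_line, "\\s+")[[1]])[1:3]
    if (any(is.na(box)))
      stop(sprintf("missing or malformed box line in %s", path))
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    frame_time <- if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) / 1000 else NA_real_  # ps -> ns
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    frames[[length(frames) + 1L]] <- .frame_from_table(
      resid = as.integer(substr(at, 1, 5)),
      resname = trimws(substr(at, 6, 10)),
      atomname = trimws(substr(at, 11, 15)),
      xyz = xyz, box = box, map = map, frame_time = frame_time)
    pos <- pos + 3L + natoms
  }
  frames
}

.read_pdb <- function(path, map) {
  lines <- readLines(path, warn = FALSE)
  box <- NULL
  cl <- lines[startsWith(lines, "CRYST1")]
  if (length(cl)) {
    box <- c(as.numeric(substr(cl[1], 7, 15)),
             as.numeric(substr(cl[1], 16, 24)),
             as.numeric(substr(cl[1], 25, 33))) / 10  # A -> nm
  }
  if (is.null(box) || any(is.na(box)))
    stop(sprintf("PDB file %s lacks a usable CRYST1 box record", path))
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_breaks <- startsWith(lines, "MODEL")
  model_id <- cumsum(model_breaks)
  model_id[model_id == 0L] <- 1L
  frames <- list()
  for (m in unique(model_id[is_atom])) {
    at <- lines[is_atom & model_id == m]
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54))) / 10
    el <- trimws(substr(at, 77, 78))
    el[!nzchar(el)] <- NA_character_
    resname <- trimws(substr(at, 18, 21))
    atomname <- trimws(substr(at, 13, 16))
    if (anyNA(el))
      el[is.na(el)] <- .guess_element(atomname[is.na(el)],
                                      resname[is.na(el)])
    frames[[length(frames) + 1L]] <- .frame_from_table(
      resid = as.integer(substr(at, 23, 26)), resname = resname,
      atomname = atomname, xyz = xyz, box = box, map = map,
      element = el)
  }
  frames
}

#' Load monolayer coordinate frames from GRO or PDB files
#'
#' Reads single- or multi-frame GRO files and single- or multi-MODEL PDB
#' files, resolving residue names to the closed species vocabulary via
#' the species map. Unknown residue names raise a mapping error listing
#' them; a missing box record is an error.
#'
#' @param paths character vector of `.gro` / `.pdb` file paths (read in
#'   order).
#' @param speciesMap species map, see [defaultSpeciesMap()].
#' @return A list of [MonolayerFrame-class] objects.
#' @export
loadFrames <- function(paths, speciesMap = defaultSpeciesMap()) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p))
      stop(sprintf("coordinate file not found: %s", p))
    ext <- tolower(tools::file_ext(p))
    fr <- switch(ext,
                 gro = .read_gro(p, speciesMap),
                 pdb = .read_pdb(p, speciesMap),
                 stop(sprintf("unsupported coordinate format '.%s' (use .gro or .pdb): %s",
                              ext, p)))
    out <- c(out, fr)
  }
  out
}

#' Write monolayer frames to a GRO file
#'
#' Fixed-width GROMACS GRO output (nm, 3 decimals); multiple frames are
#' concatenated as consecutive blocks, which [loadFrames()] reads back.
#'
#' @param frames a [MonolayerFrame-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGRO <- function(frames, path) {
  if (is(frames, "MonolayerFrame")) frames <- list(frames)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr@coords)
    title <- if (is.na(fr@frameTime)) "monolayer frame" else
      sprintf("monolayer frame t= %.4f", fr@frameTime * 1000)
    lines <- c(title, sprintf("%5d", n),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fr@moleculeId %% 100000L,
                       substr(fr@resName, 1, 5),
                       substr(fr@atomName, 1, 5),
                       seq_len(n) %% 100000L,
                       fr@coords[, 1], fr@coords[, 2], fr@coords[, 3]),
               sprintf("%10.5f%10.5f%10.5f", fr@box[1], fr@box[2],
                       fr@box[3]))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write monolayer frames to a PDB file
#'
#' Multi-frame input becomes MODEL/ENDMDL blocks; coordinates are
#' converted nm -> Angstrom and the box is written as a CRYST1 record.
#'
#' @param frames a [MonolayerFrame-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(frames, path) {
  if (is(frames, "MonolayerFrame")) frames <- list(frames)
  con <- file(path, open = "wb")
  on.exit(close(con))
  box <- frames[[1]]@box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con,
             useBytes = TRUE)
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi)
      writeLines(sprintf("MODEL     %4d", m), con, useBytes = TRUE)
    xyz <- fr@coords * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(xyz)) %% 100000L, substr(fr@atomName, 1, 4),
      substr(fr@resName, 1, 4), fr@moleculeId %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(fr@element, 1, 2))
    writeLines(lines, con, useBytes = TRUE)
    if (multi) writeLines("ENDMDL", con, useBytes = TRUE)
  }
  writeLines("END", con, useBytes = TRUE)
  invisible(path)
}
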