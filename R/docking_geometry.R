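# Docking-preparation geometry: fixed-column PDB parsing (via bio3d),
# structure screening, docking-box construction from co-crystal ligand
# coordinates, and raw-coordinate RMSD redocking validation. Docking
# itself (engine execution, protonation, format conversion) is out of
# scope: this module prepares inputs for and validates outputs of any
# engine.

.WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB structure (atoms + header metadata)
#'
#' Parses fixed-column ATOM/HETATM records through bio3d and resolves
#' alternate locations: for each atom (chain, residue, atom name), the
#' blank or highest-occupancy altloc is kept, ties broken by altloc
#' letter (so 'A' wins a tie). Header metadata (experimental method,
#' REMARK 2 resolution, organism, chain count) is extracted when
#' present; absent fields are returned as \code{NA} ("unknown").
#'
#' @param input path to a PDB file, or a character vector of PDB lines
#'   (recognized by containing newlines or multiple elements).
#' @return list with \code{atoms} (data.frame: record kind, element,
#'   coordinates, residue name/number, chain, altloc, occupancy) and
#'   \code{meta} (list: \code{method}, \code{resolution},
#'   \code{n_chains}, \code{organism}).
#' @export
readPDB <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    path <- input
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM/HETATM records in PDB input")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    record = a$type, serial = a$eleno, name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resid = trimws(a$resid), chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = .elementOf(a))
  atoms <- .resolveAltloc(atoms)
  meta <- .parseHeaderMeta(lines, atoms)
  list(atoms = atoms, meta = meta)
}

.elementOf <- function(a) {
  el <- trimws(a$elesy)
  miss <- is.na(el) | !nzchar(el)
  # fall back to the first letter of the atom name, stripping digits
  el[miss] <- substr(gsub("[0-9' ]", "", a$elety[miss]), 1, 1)
  toupper(substr(el, 1, 1)) |>
    paste0(tolower(substr(el, 2, 2)))
}

.resolveAltloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    blank <- idx[atoms$altloc[idx] == ""]
    if (length(blank)) { sel <- blank[1] } else {
      occ <- atoms$occupancy[idx]
      best <- idx[occ == max(occ)]
      sel <- best[order(atoms$altloc[best])][1]
    }
    keep[setdiff(idx, sel)] <- FALSE
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.parseHeaderMeta <- function(lines, atoms) {
  method <- NA_character_
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta)) method <- trimws(substring(expdta[1], 11))
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    num <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(num)) resolution <- as.numeric(num)
  }
  organism <- NA_character_
  src <- grep("ORGANISM_SCIENTIFIC:", lines, value = TRUE)
  if (length(src))
    organism <- trimws(sub(";.*$", "",
                           sub(".*ORGANISM_SCIENTIFIC:", "", src[1])))
  prot_chains <- unique(atoms$chain[atoms$record == "ATOM"])
  list(method = method, resolution = resolution,
       n_chains = length(prot_chains), organism = organism)
}

#' Extract co-crystal ligand coordinates
#'
#' Returns the HETATM atoms of the requested residue name, restricted to
#' the first (chain, residue number) instance in file order, with the
#' file's atom ordering preserved (downstream RMSD correspondence relies
#' on it). Water residues cannot be extracted as ligands.
#'
#' @param atoms atom data.frame from [readPDB()] (or a list holding it).
#' @param residue ligand residue name, e.g. \code{"LIG"}.
#' @return list with \code{coords} (n x 3 matrix, Angstrom),
#'   \code{elements}, \code{residue}, \code{chain}, \code{resno}.
#' @export
extractLigand <- function(atoms, residue) {
  if (is.list(atoms) && !is.data.frame(atoms)) atoms <- atoms$atoms
  residue <- toupper(trimws(residue))
  if (residue %in% .WATER_RES)
    stop("refusing to extract water ('", residue, "') as a ligand")
  het <- atoms[atoms$record == "HETATM" & atoms$resid == residue, ,
               drop = FALSE]
  if (!nrow(het)) stop("ligand residue not found: ", residue)
  first <- het[1, ]
  inst <- het[het$chain == first$chain & het$resno == first$resno, ,
              drop = FALSE]
  list(coords = as.matrix(inst[, c("x", "y", "z")]),
       elements = inst$element, residue = residue,
       chain = first$chain, resno = first$resno)
}

#' Estimate a ligand's molecular weight from its heavy atoms
#'
#' Sums atomic masses of the elements present in the coordinate record.
#' PDB files usually omit hydrogens, so this is a heavy-atom estimate
#' (a lower bound on the true molecular weight).
#'
#' @param ligand list from [extractLigand()].
#' @return estimated molecular weight (Da).
#' @export
ligandWeight <- function(ligand) {
  el <- ligand$elements
  known <- el %in% names(.atomicMass)
  if (!all(known))
    warning("unknown element(s) ignored: ",
            paste(unique(el[!known]), collapse = ","))
  sum(.atomicMass[el[known]])
}

#' Screen a structure against docking-suitability criteria
#'
#' Accepts a structure iff all four criteria hold: human origin, X-ray
#' method with resolution strictly below the cutoff (default 3.0 A),
#' single protein chain, and a co-crystal ligand of molecular weight at
#' least 100 Da (inclusive). Unknown metadata fields fail closed with an
#' \code{unknown-<field>} reason.
#'
#' @param meta metadata list from [readPDB()] (\code{method},
#'   \code{resolution}, \code{n_chains}, \code{organism}), plus a
#'   \code{ligand_mw} entry (supply e.g. via [ligandWeight()]).
#' @param max_resolution exclusive resolution cutoff (A).
#' @param min_ligand_mw inclusive ligand molecular-weight cutoff (Da).
#' @return list with \code{accept} (logical) and \code{reasons}
#'   (character vector, empty when accepted).
#' @export
screenStructure <- function(meta, max_resolution = 3.0,
                            min_ligand_mw = 100) {
  reasons <- character()
  org <- meta$organism
  if (is.null(org) || is.na(org)) reasons <- c(reasons, "unknown-organism")
  else if (!grepl("homo sapiens", org, ignore.case = TRUE))
    reasons <- c(reasons, "non-human-organism")
  if (is.null(meta$method) || is.na(meta$method))
    reasons <- c(reasons, "unknown-method")
  else if (!grepl("X-RAY", meta$method, ignore.case = TRUE))
    reasons <- c(reasons, "non-xray-method")
  if (is.null(meta$resolution) || is.na(meta$resolution))
    reasons <- c(reasons, "unknown-resolution")
  else if (meta$resolution >= max_resolution)
    reasons <- c(reasons, "resolution-too-low")
  if (is.null(meta$n_chains) || is.na(meta$n_chains))
    reasons <- c(reasons, "unknown-chain-count")
  else if (meta$n_chains != 1L)
    reasons <- c(reasons, "not-single-chain")
  if (is.null(meta$ligand_mw) || is.na(meta$ligand_mw))
    reasons <- c(reasons, "unknown-ligand-mw")
  else if (meta$ligand_mw < min_ligand_mw)
    reasons <- c(reasons, "ligand-too-small")
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Build a docking box from ligand coordinates
#'
#' The box center is the per-axis midpoint of the ligand extent,
#' \eqn{Center = (max + min)/2}, and the size is the per-axis extent
#' plus twice the padding, \eqn{Size = (max - min) + 2\delta}. A single
#' atom therefore yields a box of size \eqn{(2\delta, 2\delta,
#' 2\delta)} centered on it.
#'
#' @param ligand n x 3 coordinate matrix, or a list from
#'   [extractLigand()].
#' @param padding padding distance delta in Angstrom (default 4.0).
#' @return a [DockingBox-class].
#' @examples
#' computeBox(rbind(c(0, 0, 0), c(2, 4, 6)))
#' @export
computeBox <- function(ligand, padding = 4.0) {
  coords <- if (is.list(ligand) && !is.null(ligand$coords))
    ligand$coords else as.matrix(ligand)
  if (!nrow(coords)) stop("ligand has no atoms")
  if (ncol(coords) != 3L) stop("coordinates must be n x 3")
  if (padding < 0) stop("padding must be non-negative")
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  new("DockingBox", center = unname((hi + lo) / 2),
      size = unname(hi - lo + 2 * padding), padding = padding)
}

#' Emit a docking box as a Vina-style configuration block
#'
#' @param box a [DockingBox-class].
#' @return character scalar with \code{center_x .. size_z} lines.
#' @export
vinaConfig <- function(box) {
  stopifnot(is(box, "DockingBox"))
  paste(sprintf("%s = %.3f",
                c("center_x", "center_y", "center_z",
                  "size_x", "size_y", "size_z"),
                c(boxCenter(box), boxSize(box))),
        collapse = "\n")
}

#' Raw-coordinate RMSD between two poses
#'
#' \eqn{RMSD = \sqrt{\frac{1}{N}\sum_i \|r_i - r'_i\|^2}} with atom
#' correspondence by list position and no superposition: both poses are
#' assumed to live in the shared docking reference frame, so a uniform
#' translation of one pose contributes its full displacement.
#'
#' @param a,b n x 3 coordinate matrices (or lists from
#'   [extractLigand()]) with identical atom ordering.
#' @return RMSD in Angstrom.
#' @examples
#' a <- rbind(c(0, 0, 0), c(1, 0, 0))
#' computeRMSD(a, a + rep(c(3, 4, 0), each = 2))  # 5
#' @export
computeRMSD <- function(a, b) {
  ca <- if (is.list(a) && !is.null(a$coords)) a$coords else as.matrix(a)
  cb <- if (is.list(b) && !is.null(b$coords)) b$coords else as.matrix(b)
  if (!nrow(ca)) stop("empty coordinate set")
  if (nrow(ca) != nrow(cb))
    stop("atom count mismatch: ", nrow(ca), " vs ", nrow(cb))
  sqrt(mean(rowSums((ca - cb)^2)))
}

#' Redocking validation against an RMSD threshold
#'
#' Passes iff the redocked pose deviates from the reference by at most
#' the threshold (inclusive at the boundary).
#'
#' @param rmsd non-negative RMSD (A).
#' @param threshold acceptance threshold (A), default 2.0.
#' @return logical.
#' @examples
#' redockCheck(2.0)   # TRUE (inclusive)
#' redockCheck(2.01)  # FALSE
#' @export
redockCheck <- function(rmsd, threshold = 2.0) {
  stopifnot(all(rmsd >= 0), threshold >= 0)
  rmsd <= threshold
}
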