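# Distance-cutoff protein-ligand interaction typing. Criteria are
# distance-only on heavy atoms (hydrogens are usually absent from PDB
# coordinate records): hydrogen bonds for donor/acceptor pairs within
# 3.5 A, salt bridges for cation/anion pairs within 5.5 A, hydrophobic
# contacts for apolar carbon pairs within 4.0 A, and pi interactions
# (ring-ring or ring-cation, by ring centroid) within 5.5 A. Protein
# roles come from residue/atom-name templates; ligand roles are
# perceived from element identity and distance-based connectivity.

#' Default protein-ligand interaction distance cutoffs (Angstrom)
#'
#' @return named numeric: \code{hbond} 3.5, \code{saltbridge} 5.5,
#'   \code{hydrophobic} 4.0, \code{pi} 5.5.
#' @export
defaultCutoffs <- function() {
  c(hbond = 3.5, saltbridge = 5.5, hydrophobic = 4.0, pi = 5.5)
}

.roleCache <- new.env(parent = emptyenv())

.proteinRoleTable <- function() {
  if (!is.null(.roleCache$tab)) return(.roleCache$tab)
  path <- system.file("extdata", "protein_roles.tsv",
                      package = "GradeScreen", mustWork = TRUE)
  ln <- readLines(path)
  ln <- ln[!grepl("^[[:space:]]*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  tab <- data.frame(resid = vapply(parts, `[`, "", 1L),
                    atom = vapply(parts, `[`, "", 2L),
                    roles = vapply(parts, `[`, "", 3L))
  .roleCache$tab <- tab
  tab
}

.emptyTyped <- function() {
  list(atoms = data.frame(idx = integer(), x = numeric(), y = numeric(),
                          z = numeric(), element = character(),
                          residue = character(), donor = logical(),
                          acceptor = logical(), cation = logical(),
                          anion = logical(), hydrophobic = logical()),
       rings = data.frame(ring_id = integer(), x = numeric(),
                          y = numeric(), z = numeric(),
                          residue = character(), first_atom = integer()))
}

#' Assign interaction roles to atoms
#'
#' Protein atoms are typed from the packaged residue/atom-name template
#' table (backbone N donor, backbone O acceptor, Asp/Glu carboxylates
#' anionic, Lys/Arg side-chain nitrogens cationic, apolar side-chain
#' carbons hydrophobic, Phe/Tyr/Trp/His rings aromatic). Ligand atoms
#' are typed from element identity and distance-based connectivity
#' (bond when heavy atoms lie within 1.75 A, 1.95 A when S or P is
#' involved): N/O acceptors, hydroxyl O and low-degree N donors,
#' carboxylate O anions, terminal amine N cations, carbons without N/O
#' neighbors hydrophobic, and planar 5/6-cycles of C/N as aromatic
#' rings with their centroid.
#'
#' @param atoms atom data.frame from [readPDB()] (rows of one source).
#' @param source \code{"protein"} (template typing) or \code{"ligand"}
#'   (connectivity typing).
#' @return list with \code{atoms} (role flags per atom; \code{idx}
#'   refers to the row order of the input) and \code{rings} (one row
#'   per aromatic ring: centroid coordinates, residue descriptor,
#'   first member atom index).
#' @export
typeAtoms <- function(atoms, source = c("protein", "ligand")) {
  source <- match.arg(source)
  if (!nrow(atoms)) return(.emptyTyped())
  res_desc <- paste0(atoms$resid, atoms$resno, ":", atoms$chain)
  out <- data.frame(idx = seq_len(nrow(atoms)),
                    x = atoms$x, y = atoms$y, z = atoms$z,
                    element = atoms$element, residue = res_desc,
                    donor = FALSE, acceptor = FALSE, cation = FALSE,
                    anion = FALSE, hydrophobic = FALSE)
  rings <- .emptyTyped()$rings
  if (source == "protein") {
    tab <- .proteinRoleTable()
    ring_groups <- list()
    for (i in seq_len(nrow(atoms))) {
      hit <- tab[(tab$resid == atoms$resid[i] | tab$resid == "*") &
                   tab$atom == atoms$name[i], , drop = FALSE]
      if (!nrow(hit)) next
      roles <- unlist(strsplit(hit$roles, ",", fixed = TRUE))
      for (r in roles) {
        if (r %in% c("donor", "acceptor", "cation", "anion",
                     "hydrophobic")) {
          out[[r]][i] <- TRUE
        } else if (grepl("^ring[0-9]+$", r)) {
          key <- paste0(res_desc[i], "/", r)
          ring_groups[[key]] <- c(ring_groups[[key]], i)
        }
      }
    }
    if (length(ring_groups)) {
      keep <- vapply(ring_groups, length, 0L) >= 5L
      ring_groups <- ring_groups[keep]
      if (length(ring_groups))
        rings <- data.frame(
          ring_id = seq_along(ring_groups),
          x = vapply(ring_groups, function(ii) mean(atoms$x[ii]), 0),
          y = vapply(ring_groups, function(ii) mean(atoms$y[ii]), 0),
          z = vapply(ring_groups, function(ii) mean(atoms$z[ii]), 0),
          residue = vapply(ring_groups,
                           function(ii) res_desc[ii[1]], ""),
          first_atom = vapply(ring_groups, min, 0L))
    }
  } else {
    out <- .typeLigandAtoms(atoms, out)
    rings <- .ligandRings(atoms, res_desc)
  }
  rownames(out) <- NULL
  list(atoms = out, rings = rings)
}

.bondMatrix <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  soft <- atoms$element %in% c("S", "P")
  cut <- matrix(1.75, n, n)
  cut[soft, ] <- 1.95
  cut[, soft] <- 1.95
  bonded <- d > 0.4 & d <= cut
  diag(bonded) <- FALSE
  bonded
}

.typeLigandAtoms <- function(atoms, out) {
  n <- nrow(atoms)
  bonded <- .bondMatrix(atoms)
  el <- atoms$element
  deg <- rowSums(bonded)
  for (i in seq_len(n)) {
    nb <- which(bonded[i, ])
    if (el[i] == "O") {
      out$acceptor[i] <- TRUE
      if (length(nb) == 1L && el[nb] == "C") {
        cO <- which(bonded[nb, ] & el == "O" & deg == 1)
        if (length(cO) >= 2L) out$anion[i] <- TRUE   # carboxylate-like
        else out$donor[i] <- TRUE                    # hydroxyl-like
      }
    } else if (el[i] == "N") {
      out$acceptor[i] <- TRUE
      if (deg[i] <= 2L) out$donor[i] <- TRUE
      if (deg[i] <= 1L) out$cation[i] <- TRUE        # protonatable amine
    } else if (el[i] == "C") {
      if (!any(el[nb] %in% c("N", "O"))) out$hydrophobic[i] <- TRUE
    }
  }
  out
}

# Planar 5/6-membered C/N cycles in the distance-based bond graph.
.ligandRings <- function(atoms, res_desc) {
  empty <- .emptyTyped()$rings
  n <- nrow(atoms)
  if (n < 5L) return(empty)
  bonded <- .bondMatrix(atoms)
  eligible <- atoms$element %in% c("C", "N")
  cycles <- list()
  # bounded DFS for simple cycles of length 5 or 6
  search <- function(path) {
    last <- path[length(path)]
    for (nxt in which(bonded[last, ] & eligible)) {
      if (nxt == path[1] && length(path) >= 5L) {
        key <- paste(sort(path), collapse = "-")
        cycles[[key]] <<- path
      } else if (!(nxt %in% path) && length(path) < 6L && nxt > path[1]) {
        search(c(path, nxt))
      }
    }
  }
  for (s in which(eligible)) search(s)
  if (!length(cycles)) return(empty)
  planar <- Filter(function(ii) {
    xyz <- as.matrix(atoms[ii, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    dev <- sweep(xyz, 2L, ctr)
    normal <- svd(dev)$v[, 3]
    max(abs(dev %*% normal)) < 0.15
  }, cycles)
  if (!length(planar)) return(empty)
  data.frame(
    ring_id = seq_along(planar),
    x = vapply(planar, function(ii) mean(atoms$x[ii]), 0),
    y = vapply(planar, function(ii) mean(atoms$y[ii]), 0),
    z = vapply(planar, function(ii) mean(atoms$z[ii]), 0),
    residue = vapply(planar, function(ii) res_desc[ii[1]], ""),
    first_atom = vapply(planar, min, 0L))
}

.pairDist <- function(a, b) {
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Find typed protein-ligand contacts
#'
#' All-pairs scan under the distance cutoffs: hydrogen bonds between
#' donor and acceptor heavy atoms (either orientation), salt bridges
#' between cations and anions, hydrophobic contacts between apolar
#' carbon pairs, and pi interactions between aromatic-ring centroids or
#' between a ring centroid and a cation. Each qualifying pair is
#' reported once per kind with its distance.
#'
#' @param ligand,protein typed atom sets from [typeAtoms()].
#' @param cutoffs named cutoffs (A), see [defaultCutoffs()].
#' @return a [ContactSet-class]; \code{ligand_atom} is the ligand atom
#'   index (first ring member for pi contacts via a ligand ring).
#' @export
findContacts <- function(ligand, protein, cutoffs = defaultCutoffs()) {
  stopifnot(all(c("hbond", "saltbridge", "hydrophobic", "pi") %in%
                  names(cutoffs)), all(cutoffs >= 0))
  la <- ligand$atoms; pa <- protein$atoms
  res <- list()
  add <- function(kind, lig_idx, residue, dist) {
    res[[length(res) + 1L]] <<- data.frame(
      kind = kind, ligand_atom = lig_idx, residue = residue,
      distance = dist)
  }
  if (nrow(la) && nrow(pa)) {
    d <- .pairDist(la, pa)
    pick <- function(mask, cutoff, kind) {
      hit <- which(mask & d <= cutoff & d > 0, arr.ind = TRUE)
      if (nrow(hit))
        add(kind, la$idx[hit[, 1]], pa$residue[hit[, 2]],
            d[hit])
    }
    pick(outer(la$donor, pa$acceptor, "&") |
           outer(la$acceptor, pa$donor, "&"),
         cutoffs[["hbond"]], "hydrogen-bond")
    pick(outer(la$cation, pa$anion, "&") |
           outer(la$anion, pa$cation, "&"),
         cutoffs[["saltbridge"]], "salt-bridge")
    pick(outer(la$hydrophobic & la$element == "C",
               pa$hydrophobic & pa$element == "C", "&"),
         cutoffs[["hydrophobic"]], "hydrophobic")
  }
  lr <- ligand$rings; pr <- protein$rings
  if (nrow(lr) && nrow(pr)) {
    d <- .pairDist(lr, pr)
    hit <- which(d <= cutoffs[["pi"]] & d > 0, arr.ind = TRUE)
    if (nrow(hit))
      add("pi", lr$first_atom[hit[, 1]], pr$residue[hit[, 2]],
          d[hit])
  }
  if (nrow(lr) && nrow(pa) && any(pa$cation)) {
    pc <- pa[pa$cation, , drop = FALSE]
    d <- .pairDist(lr, pc)
    hit <- which(d <= cutoffs[["pi"]] & d > 0, arr.ind = TRUE)
    if (nrow(hit))
      add("pi", lr$first_atom[hit[, 1]], pc$residue[hit[, 2]],
          d[hit])
  }
  if (nrow(la) && any(la$cation) && nrow(pr)) {
    lc <- la[la$cation, , drop = FALSE]
    d <- .pairDist(lc, pr)
    hit <- which(d <= cutoffs[["pi"]] & d > 0, arr.ind = TRUE)
    if (nrow(hit))
      add("pi", lc$idx[hit[, 1]], pr$residue[hit[, 2]],
          d[hit])
  }
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(kind = character(), ligand_atom = integer(),
               residue = character(), distance = numeric())
  tab <- tab[order(tab$kind, tab$ligand_atom, tab$residue), , drop = FALSE]
  rownames(tab) <- NULL
  new("ContactSet", contacts = tab, cutoffs = cutoffs)
}

#' Profile the contacts of a protein-ligand complex
#'
#' Convenience composition: parse the PDB input, split the named ligand
#' residue from the protein ATOM records, type both sides and scan for
#' contacts.
#'
#' @param input PDB path or text (see [readPDB()]).
#' @param ligand ligand residue name.
#' @param cutoffs distance cutoffs, see [defaultCutoffs()].
#' @return a [ContactSet-class].
#' @export
profileComplex <- function(input, ligand, cutoffs = defaultCutoffs()) {
  parsed <- readPDB(input)
  atoms <- parsed$atoms
  ligand <- toupper(trimws(ligand))
  lig_rows <- atoms[atoms$record == "HETATM" & atoms$resid == ligand, ,
                    drop = FALSE]
  if (!nrow(lig_rows)) stop("ligand residue not found: ", ligand)
  first <- lig_rows[1, ]
  lig_rows <- lig_rows[lig_rows$chain == first$chain &
                         lig_rows$resno == first$resno, , drop = FALSE]
  prot_rows <- atoms[atoms$record == "ATOM", , drop = FALSE]
  findContacts(typeAtoms(lig_rows, "ligand"),
               typeAtoms(prot_rows, "protein"), cutoffs)
}

#' Summarize contacts per protein residue
#'
#' Groups contacts by protein residue and interaction kind, reporting
#' the number of contacts and the minimum distance per group, ordered
#' by residue number then kind.
#'
#' @param x a [ContactSet-class] or its contact data.frame.
#' @return data.frame with columns \code{residue}, \code{kind},
#'   \code{n}, \code{min_distance}.
#' @export
summarizeContacts <- function(x) {
  tab <- if (is(x, "ContactSet")) contacts(x) else x
  if (!nrow(tab))
    return(data.frame(residue = character(), kind = character(),
                      n = integer(), min_distance = numeric()))
  key <- paste(tab$residue, tab$kind, sep = "\r")
  agg <- do.call(rbind, lapply(split(tab, key), function(g)
    data.frame(residue = g$residue[1], kind = g$kind[1],
               n = nrow(g), min_distance = min(g$distance))))
  resno <- as.integer(sub("^[A-Za-z]+([0-9]+):.*$", "\\1", agg$residue))
  agg <- agg[order(resno, agg$kind), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a contact table as CSV
#'
#' @param x a [ContactSet-class].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeContacts <- function(x, path) {
  utils::write.csv(contacts(x), path, row.names = FALSE)
  invisible(path)
}
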