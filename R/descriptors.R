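# Physicochemical descriptors, QED, synthetic-accessibility estimate and
# structural-alert detection. All structure perception goes through
# OpenBabel (ChemmineR/ChemmineOB); molecules are first normalized to
# their canonical isomeric SMILES so explicit vs implicit hydrogens and
# atom-order differences cannot change any descriptor.

# Descriptor computation is cached per canonical structure key: synthetic
# libraries repeat panel structures heavily.
.descCache <- new.env(parent = emptyenv())

.atomicMass <- c(H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.18, Na = 22.99,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  Ar = 39.948, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922,
  Se = 78.971, Br = 79.904, I = 126.9, Hg = 200.59, Pb = 207.2)

# Parse a molecular formula like C24H23FN4O3 into a named count vector.
.parseFormula <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]+$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, el, sum)
}

.smartsCount <- function(sdfset, smarts) {
  as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}

# SMARTS used for descriptor counts (heavy-atom, implicit-H conventions):
#  - rotatable bond: acyclic single bond between two non-terminal,
#    non-triple-bond atoms
#  - aromatic rings counted as unique 5- and 6-membered aromatic cycles
.SMARTS_ROTB <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
.SMARTS_AROM6 <- "a1aaaaa1"
.SMARTS_AROM5 <- "a1aaaa1"

# Parse one canonical SMILES into a single-molecule SDFset, or NULL.
.parseOne <- function(smiles) {
  tryCatch(ChemmineR::smiles2sdf(smiles), error = function(e) NULL,
           warning = function(w) NULL)
}

.computeOne <- function(key) {
  if (!is.null(.descCache[[key]])) return(.descCache[[key]])
  sdf <- .parseOne(key)
  if (is.null(sdf)) stop("unparseable structure: ", key)
  prop <- ChemmineR::propOB(sdf)
  counts <- .parseFormula(prop$formula[1])
  mass_known <- names(counts) %in% names(.atomicMass)
  if (!all(mass_known))
    warning("unknown element(s) ignored in atom count: ",
            paste(names(counts)[!mass_known], collapse = ","))
  heavy <- sum(ChemmineR::atomcount(sdf)[[1]])
  arom <- .smartsCount(sdf, .SMARTS_AROM6) + .smartsCount(sdf, .SMARTS_AROM5)
  d <- list(
    mw = prop$MW[1],
    logp = prop$logP[1],
    hbd = as.integer(prop$HBD[1]),
    hba = as.integer(prop$HBA1[1]),
    rotb = .smartsCount(sdf, .SMARTS_ROTB),
    tpsa = prop$TPSA[1],
    molar_refractivity = prop$MR[1],
    atom_count = as.integer(sum(counts)),
    heavy_atoms = as.integer(heavy),
    aromatic_rings = as.integer(arom),
    n_fused_atoms = .smartsCount(sdf, "[R2]"),
    n_macro_atoms = .smartsCount(sdf, "[r;!r3;!r4;!r5;!r6;!r7;!r8]"),
    n_rings = max(0L, nrow(ChemmineR::bondblock(sdf[[1]])) - heavy + 1L),
    n_stereo = lengths(regmatches(key, gregexpr("@", key)))[1] -
      lengths(regmatches(key, gregexpr("@@", key)))[1],
    n_unusual = as.integer(sum(!names(counts) %in%
      c("C", "H", "N", "O", "F", "S", "Cl", "Br", "P", "I")))
  )
  .descCache[[key]] <- d
  d
}

#' Compute the descriptor set consumed by the drug-likeness scorers
#'
#' For each compound: molecular weight (Da), an atom-contribution logP
#' estimate (OpenBabel's Wildman-Crippen-type model), hydrogen-bond
#' donor and acceptor counts, rotatable bonds, topological polar surface
#' area (A^2), molar refractivity, total atom count (H included), heavy
#' atoms, aromatic ring count, raw QED ([0,1], see [qedScore()]), raw
#' synthetic-accessibility estimate ([1,10], 1 = easiest; see
#' [saScore()]) and structural-alert counts from the PAINS and BRENK
#' catalogs.
#'
#' Descriptors are deterministic functions of the canonical structure
#' key, so equivalent SMILES encodings (including explicit-hydrogen
#' forms) give identical rows.
#'
#' @param records data.frame with columns \code{identifier} and
#'   \code{smiles} (e.g. from [parseCompoundTable()] or
#'   [records()] of a [CompoundLibrary-class]), or a character vector of
#'   SMILES.
#' @return data.frame, one row per compound, with the columns above plus
#'   \code{identifier}.
#' @examples
#' computeDescriptors(c(ethanol = "CCO"))
#' @export
computeDescriptors <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("mol_", seq_along(records))
    records <- data.frame(identifier = ids, smiles = unname(records))
  }
  stopifnot(all(c("identifier", "smiles") %in% names(records)))
  if (anyDuplicated(records$identifier))
    stop("compound identifiers must be unique")
  keys <- canonicalStructureKey(records$smiles)
  bad <- which(is.na(keys))
  if (length(bad))
    stop("unparseable structure for record(s): ",
         paste(records$identifier[bad], collapse = ", "))
  # alert counts are cached per structure key, like the descriptors
  newkeys <- unique(keys[!vapply(keys, function(k)
    !is.null(.alertCountCache[[k]]), TRUE)])
  if (length(newkeys)) {
    tab <- detectAlerts(data.frame(identifier = newkeys,
                                   smiles = newkeys))
    for (k in newkeys)
      .alertCountCache[[k]] <- c(
        pains = sum(tab$identifier == k & tab$catalog == "PAINS"),
        brenk = sum(tab$identifier == k & tab$catalog == "BRENK"))
  }
  n_alert <- function(cat) {
    vapply(keys, function(k)
      as.integer(.alertCountCache[[k]][[tolower(cat)]]), 0L,
      USE.NAMES = FALSE)
  }
  rows <- lapply(keys, .computeOne)
  out <- data.frame(
    identifier = records$identifier,
    mw = vapply(rows, `[[`, 0, "mw"),
    logp = vapply(rows, `[[`, 0, "logp"),
    hbd = vapply(rows, `[[`, 0L, "hbd"),
    hba = vapply(rows, `[[`, 0L, "hba"),
    rotb = vapply(rows, `[[`, 0L, "rotb"),
    tpsa = vapply(rows, `[[`, 0, "tpsa"),
    molar_refractivity = vapply(rows, `[[`, 0, "molar_refractivity"),
    atom_count = vapply(rows, `[[`, 0L, "atom_count"),
    heavy_atoms = vapply(rows, `[[`, 0L, "heavy_atoms"),
    aromatic_rings = vapply(rows, `[[`, 0L, "aromatic_rings"),
    n_pains = n_alert("PAINS"),
    n_brenk = n_alert("BRENK"))
  out$n_alerts <- out$n_pains + out$n_brenk
  out$qed_raw <- mapply(function(r, nb) qedScore(
      mw = r$mw, alogp = r$logp, hba = r$hba, hbd = r$hbd, psa = r$tpsa,
      rotb = r$rotb, arom = r$aromatic_rings, alerts = nb),
    rows, out$n_brenk)
  out$sa_raw <- vapply(rows, function(r) saScore(
      heavy = r$heavy_atoms, n_rings = r$n_rings,
      n_fused_atoms = r$n_fused_atoms, n_stereo = r$n_stereo,
      macrocycle = r$n_macro_atoms > 0, n_unusual = r$n_unusual), 0)
  rownames(out) <- NULL
  out
}

# Alert catalog cache (name -> data.frame(name, smarts)).
.alertCache <- new.env(parent = emptyenv())
# Per-structure-key alert counts (key -> c(pains=, brenk=)).
.alertCountCache <- new.env(parent = emptyenv())

#' Load a structural-alert SMARTS catalog shipped with the package
#'
#' @param catalog \code{"PAINS"} or \code{"BRENK"}.
#' @return data.frame with columns \code{name}, \code{smarts}.
#' @export
loadAlertCatalog <- function(catalog = c("PAINS", "BRENK")) {
  catalog <- match.arg(catalog)
  if (!is.null(.alertCache[[catalog]])) return(.alertCache[[catalog]])
  path <- system.file("extdata", "alerts",
                      paste0(tolower(catalog), ".tsv"),
                      package = "GradeScreen", mustWork = TRUE)
  ln <- readLines(path)
  ln <- ln[!grepl("^[[:space:]]*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  out <- data.frame(name = vapply(parts, `[`, "", 1L),
                    smarts = vapply(parts, `[`, "", 2L))
  .alertCache[[catalog]] <- out
  out
}

#' Detect PAINS/BRENK structural alerts
#'
#' Scans each compound against the requested SMARTS catalogs and reports
#' one row per (compound, catalog, alert) with at least one substructure
#' match. Deterministic; an empty catalog set yields an empty table.
#'
#' @param records data.frame with \code{identifier} and \code{smiles}
#'   columns, or a character vector of SMILES.
#' @param catalogs subset of \code{c("PAINS", "BRENK")}.
#' @return data.frame with columns \code{identifier}, \code{catalog},
#'   \code{alert}.
#' @examples
#' detectAlerts(c(catechol = "Oc1ccccc1O"), catalogs = "PAINS")
#' @export
detectAlerts <- function(records, catalogs = c("PAINS", "BRENK")) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("mol_", seq_along(records))
    records <- data.frame(identifier = ids, smiles = unname(records))
  }
  if (length(catalogs) && !all(catalogs %in% c("PAINS", "BRENK")))
    stop("unknown catalog: ",
         paste(setdiff(catalogs, c("PAINS", "BRENK")), collapse = ", "))
  empty <- data.frame(identifier = character(), catalog = character(),
                      alert = character())
  if (!length(catalogs) || !nrow(records)) return(empty)
  keys <- canonicalStructureKey(records$smiles)
  bad <- which(is.na(keys))
  if (length(bad))
    stop("unparseable structure for record(s): ",
         paste(records$identifier[bad], collapse = ", "))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(keys, make.unique(records$identifier)))
  res <- list(empty)
  for (cat in catalogs) {
    tab <- loadAlertCatalog(cat)
    for (i in seq_len(nrow(tab))) {
      hits <- as.integer(ChemmineR::smartsSearchOB(sdf, tab$smarts[i],
                                                   uniqueMatches = TRUE))
      hit_idx <- which(hits > 0)
      if (length(hit_idx))
        res[[length(res) + 1L]] <- data.frame(
          identifier = records$identifier[hit_idx],
          catalog = cat, alert = tab$name[i])
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$identifier, records$identifier),
                   out$catalog, out$alert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a descriptor table as CSV
#'
#' @param descriptors data.frame from [computeDescriptors()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeDescriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
  invisible(path)
}
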