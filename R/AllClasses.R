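#' @import methods
NULL

#' CompoundLibrary: a validated, deduplicated compound collection
#'
#' Holds the compound records kept after the validity/uniqueness filter
#' together with a rejection log that accounts for every removed record.
#' The two slots partition the input: \code{nrow(records) + nrow(rejections)}
#' equals the number of records fed to [filterValidUnique()].
#'
#' @slot records data.frame with columns \code{identifier}, \code{name},
#'   \code{smiles}, \code{source}, \code{structure_key} (canonical isomeric
#'   SMILES used for deduplication).
#' @slot rejections data.frame with columns \code{identifier},
#'   \code{reason} (one of \code{missing-smiles}, \code{unparseable-smiles},
#'   \code{duplicate-structure}).
#'
#' @seealso [filterValidUnique()], [parseCompoundTable()]
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
  representation(records = "data.frame", rejections = "data.frame"))

setValidity("CompoundLibrary", function(object) {
  msg <- character()
  need <- c("identifier", "name", "smiles", "source", "structure_key")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  if (!all(c("identifier", "reason") %in% names(object@rejections)))
    msg <- c(msg, "rejections must have columns: identifier, reason")
  if (nrow(object@records)) {
    if (anyDuplicated(object@records$identifier))
      msg <- c(msg, "identifiers must be unique among kept records")
    if (anyDuplicated(object@records$structure_key))
      msg <- c(msg, "structure keys must be unique among kept records")
    if (any(!nzchar(object@records$identifier)))
      msg <- c(msg, "identifiers must be non-empty")
  }
  if (nrow(object@rejections)) {
    ok <- object@rejections$reason %in%
      c("missing-smiles", "unparseable-smiles", "duplicate-structure")
    if (!all(ok)) msg <- c(msg, "unknown rejection reason code")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreCardSet: per-compound component scores, totals and grades
#'
#' One row per compound holding the seven normalized component scores
#' (each in \[0,1\]), the weighted total \eqn{S_{total} = \sum_i w_i S_i}
#' and the letter grade. The weight vector used is stored alongside so a
#' ScoreCardSet is always self-consistent: the validity method recomputes
#' every total from the stored components and weights and requires
#' agreement within 1e-12.
#'
#' @slot cards data.frame with columns \code{identifier},
#'   \code{s_lipinski}, \code{s_veber}, \code{s_ghose}, \code{s_qed},
#'   \code{s_sa}, \code{s_admet}, \code{s_pains}, \code{s_total},
#'   \code{grade}.
#' @slot weights named numeric of length 7 summing to 1 (names
#'   \code{lipinski}, \code{veber}, \code{ghose}, \code{qed}, \code{sa},
#'   \code{admet}, \code{pains}).
#'
#' @seealso [scoreCompounds()], [summarizeLibrary()]
#' @exportClass ScoreCardSet
setClass("ScoreCardSet",
  representation(cards = "data.frame", weights = "numeric"))

setValidity("ScoreCardSet", function(object) {
  msg <- character()
  comp_cols <- paste0("s_", c("lipinski", "veber", "ghose", "qed",
                              "sa", "admet", "pains"))
  need <- c("identifier", comp_cols, "s_total", "grade")
  if (!all(need %in% names(object@cards)))
    return(paste("cards must have columns:", paste(need, collapse = ", ")))
  w <- object@weights
  if (length(w) != 7L || is.null(names(w)) ||
      !identical(sort(names(w)),
                 sort(c("lipinski", "veber", "ghose", "qed", "sa",
                        "admet", "pains"))))
    return("weights must be a named numeric of length 7")
  if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "weights must sum to 1")
  if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
  if (nrow(object@cards)) {
    comp <- as.matrix(object@cards[, comp_cols])
    if (any(comp < -1e-12 | comp > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "component scores must lie in [0,1]")
    redo <- as.numeric(comp %*% w[c("lipinski", "veber", "ghose", "qed",
                                    "sa", "admet", "pains")])
    if (any(abs(redo - object@cards$s_total) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "s_total must equal the weighted component sum (1e-12)")
    g <- assignGrade(pmin(pmax(object@cards$s_total, 0), 1))
    if (!all(g == object@cards$grade))
      msg <- c(msg, "grades inconsistent with the grade bands")
  }
  if (length(msg)) msg else TRUE
})

#' GradeSummary: library-level grade distribution statistics
#'
#' @slot counts named integer, one count per grade A-F.
#' @slot percentages named numeric, 100*count/total rounded half-up to
#'   one decimal.
#' @slot mean_total mean total score (three decimals).
#' @slot median_total median total score (three decimals).
#' @slot n library size.
#'
#' @seealso [summarizeLibrary()], [gradePercentages()]
#' @exportClass GradeSummary
setClass("GradeSummary",
  representation(counts = "integer", percentages = "numeric",
                 mean_total = "numeric", median_total = "numeric",
                 n = "integer"))

setValidity("GradeSummary", function(object) {
  msg <- character()
  if (!identical(names(object@counts), c("A", "B", "C", "D", "F")))
    msg <- c(msg, "counts must be named A,B,C,D,F")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "counts must sum to library size")
  if (object@n > 0L) {
    s <- sum(object@percentages)
    if (abs(s - 100) > 0.3)
      msg <- c(msg, "percentages must sum to 100 within rounding slack 0.3")
  }
  if (length(msg)) msg else TRUE
})

#' DockingBox: a rectangular docking search volume
#'
#' Axis-aligned box derived from co-crystal ligand coordinates: the
#' center is the per-axis midpoint of the ligand extent and the size is
#' the per-axis extent plus twice the padding distance.
#'
#' @slot center numeric xyz center (Angstrom).
#' @slot size numeric xyz edge lengths (Angstrom).
#' @slot padding padding distance delta (Angstrom), default 4.0.
#'
#' @seealso [computeBox()], [vinaConfig()]
#' @exportClass DockingBox
setClass("DockingBox",
  representation(center = "numeric", size = "numeric", padding = "numeric"))

setValidity("DockingBox", function(object) {
  msg <- character()
  if (length(object@center) != 3L || length(object@size) != 3L)
    msg <- c(msg, "center and size must have length 3")
  if (any(!is.finite(object@center)) || any(!is.finite(object@size)))
    msg <- c(msg, "center and size must be finite")
  if (length(object@padding) != 1L || object@padding < 0)
    msg <- c(msg, "padding must be a single non-negative number")
  if (!length(msg) && any(object@size < 2 * object@padding - 1e-9))
    msg <- c(msg, "each size component must be >= 2*padding")
  if (length(msg)) msg else TRUE
})

#' ContactSet: typed protein-ligand contacts
#'
#' @slot contacts data.frame with columns \code{kind} (one of
#'   \code{hydrogen-bond}, \code{salt-bridge}, \code{hydrophobic},
#'   \code{pi}), \code{ligand_atom} (index into the ligand atom order),
#'   \code{residue} (protein residue descriptor \code{NAME<resno>:<chain>}),
#'   \code{distance} (Angstrom).
#' @slot cutoffs named numeric distance cutoffs per kind (Angstrom).
#'
#' @seealso [findContacts()], [summarizeContacts()]
#' @exportClass ContactSet
setClass("ContactSet",
  representation(contacts = "data.frame", cutoffs = "numeric"))

setValidity("ContactSet", function(object) {
  msg <- character()
  need <- c("kind", "ligand_atom", "residue", "distance")
  if (!all(need %in% names(object@contacts)))
    return(paste("contacts must have columns:", paste(need, collapse = ", ")))
  kinds <- c(`hydrogen-bond` = "hbond", `salt-bridge` = "saltbridge",
             hydrophobic = "hydrophobic", pi = "pi")
  if (nrow(object@contacts)) {
    if (!all(object@contacts$kind %in% names(kinds)))
      msg <- c(msg, "unknown contact kind")
    cut <- object@cutoffs[kinds[object@contacts$kind]]
    if (any(object@contacts$distance > cut + 1e-9) ||
        any(object@contacts$distance <= 0))
      msg <- c(msg, "each distance must lie in (0, cutoff] for its kind")
  }
  if (length(msg)) msg else TRUE
})

#' GeneNetwork: a thresholded protein-protein interaction network
#'
#' Wraps an undirected, simple igraph graph whose edges carry a STRING
#' style confidence score (0-1000). All retained edges have
#' score >= the configured threshold; self-loops and duplicate edges are
#' removed on construction.
#'
#' @slot graph igraph object (undirected, simple, vertex attribute
#'   \code{name} = gene symbol, edge attribute \code{score}).
#' @slot threshold minimum confidence score retained (inclusive).
#'
#' @seealso [readEdgeList()], [rankGenes()], [topologyStats()]
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  representation(graph = "ANY", threshold = "numeric"))

setValidity("GeneNetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "duplicate edges are not allowed")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$score
    if (is.null(sc) || any(sc < object@threshold))
      msg <- c(msg, "all edges must carry score >= threshold")
  }
  if (length(msg)) msg else TRUE
})
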