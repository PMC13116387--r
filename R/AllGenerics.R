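# Accessor generics for the package's S4 containers. Slot access from
# user code should always go through these.

#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))
#' @export
setGeneric("cards", function(x) standardGeneric("cards"))
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))
#' @export
setGeneric("gradeCounts", function(x) standardGeneric("gradeCounts"))
#' @export
setGeneric("gradePercent", function(x) standardGeneric("gradePercent"))
#' @export
setGeneric("boxCenter", function(x) standardGeneric("boxCenter"))
#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))
#' @export
setGeneric("boxPadding", function(x) standardGeneric("boxPadding"))
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @export
setGeneric("contactCutoffs", function(x) standardGeneric("contactCutoffs"))
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @describeIn CompoundLibrary kept compound records
#' @param x object
#' @aliases records
#' @export
setMethod("records", "CompoundLibrary", function(x) x@records)

#' @describeIn CompoundLibrary rejection log
#' @aliases rejections
#' @export
setMethod("rejections", "CompoundLibrary", function(x) x@rejections)

#' @describeIn ScoreCardSet score card table
#' @param x object
#' @aliases cards
#' @export
setMethod("cards", "ScoreCardSet", function(x) x@cards)

#' @describeIn ScoreCardSet weight vector in use
#' @aliases scoreWeights
#' @export
setMethod("scoreWeights", "ScoreCardSet", function(x) x@weights)

#' @describeIn GradeSummary per-grade counts
#' @param x object
#' @aliases gradeCounts
#' @export
setMethod("gradeCounts", "GradeSummary", function(x) x@counts)

#' @describeIn GradeSummary per-grade percentages (one decimal, half-up)
#' @aliases gradePercent
#' @export
setMethod("gradePercent", "GradeSummary", function(x) x@percentages)

#' @describeIn DockingBox box center (Angstrom)
#' @param x object
#' @aliases boxCenter
#' @export
setMethod("boxCenter", "DockingBox", function(x) x@center)

#' @describeIn DockingBox box edge lengths (Angstrom)
#' @aliases boxSize
#' @export
setMethod("boxSize", "DockingBox", function(x) x@size)

#' @describeIn DockingBox padding distance (Angstrom)
#' @aliases boxPadding
#' @export
setMethod("boxPadding", "DockingBox", function(x) x@padding)

#' @describeIn ContactSet typed contact table
#' @param x object
#' @aliases contacts
#' @export
setMethod("contacts", "ContactSet", function(x) x@contacts)

#' @describeIn ContactSet distance cutoffs per interaction kind
#' @aliases contactCutoffs
#' @export
setMethod("contactCutoffs", "ContactSet", function(x) x@cutoffs)

#' @describeIn GeneNetwork underlying igraph object
#' @param x object
#' @aliases networkGraph
#' @export
setMethod("networkGraph", "GeneNetwork", function(x) x@graph)

#' @describeIn GeneNetwork confidence-score threshold in force
#' @aliases scoreThreshold
#' @export
setMethod("scoreThreshold", "GeneNetwork", function(x) x@threshold)

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary:", nrow(object@records), "kept,",
      nrow(object@rejections), "rejected\n")
  if (nrow(object@rejections)) {
    tab <- table(object@rejections$reason)
    cat("  rejections:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "ScoreCardSet", function(object) {
  cat("ScoreCardSet:", nrow(object@cards), "compounds\n")
  if (nrow(object@cards)) {
    tab <- table(factor(object@cards$grade, levels = c("A", "B", "C", "D", "F")))
    cat("  grades:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  S_total: mean", sprintf("%.3f", mean(object@cards$s_total)),
        "median", sprintf("%.3f", stats::median(object@cards$s_total)), "\n")
  }
})

setMethod("show", "GradeSummary", function(object) {
  cat("GradeSummary (n =", object@n, ")\n")
  for (g in names(object@counts))
    cat(sprintf("  %s: n=%d (%.1f%%)\n", g, object@counts[[g]],
                object@percentages[[g]]))
  cat(sprintf("  mean S_total %.3f, median %.3f\n",
              object@mean_total, object@median_total))
})

setMethod("show", "DockingBox", function(object) {
  cat(sprintf("DockingBox center (%.3f, %.3f, %.3f) size (%.3f, %.3f, %.3f) padding %.1f A\n",
              object@center[1], object@center[2], object@center[3],
              object@size[1], object@size[2], object@size[3], object@padding))
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet:", nrow(object@contacts), "contacts\n")
  if (nrow(object@contacts)) {
    tab <- table(object@contacts$kind)
    cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", igraph::vcount(object@graph), "genes,",
      igraph::ecount(object@graph), "edges (score >=",
      object@threshold, ")\n")
})
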