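# The seven-criterion weighted drug-likeness framework: each criterion
# is normalized to [0,1] (rule-based criteria as the fraction of their
# sub-rules passed), aggregated as S_total = sum(w_i * S_i) with fixed
# weights, and mapped to a letter grade A-F on fixed left-closed bands.

.COMPONENTS <- c("lipinski", "veber", "ghose", "qed", "sa", "admet", "pains")

#' Default component weights of the total drug-likeness score
#'
#' QED and ADMET carry the highest weights (0.20 each) as the strongest
#' predictors of clinical attrition; Lipinski and synthetic
#' accessibility carry 0.15; Veber, Ghose and the structural-alert
#' score act as supplementary filters at 0.10 each. The vector sums to 1.
#'
#' @return named numeric of length 7.
#' @export
defaultWeights <- function() {
  c(lipinski = 0.15, veber = 0.10, ghose = 0.10, qed = 0.20,
    sa = 0.15, admet = 0.20, pains = 0.10)
}

#' Grade-band boundaries of the total score
#'
#' Left-closed bands on \[0,1\]: A >= 0.85 > B >= 0.70 > C >= 0.55 >
#' D >= 0.40 > F.
#'
#' @return named numeric of lower bounds for grades A-D.
#' @export
gradeBands <- function() c(A = 0.85, B = 0.70, C = 0.55, D = 0.40)

#' Rule-based component scores
#'
#' Each scorer returns the fraction of its sub-rules passed, a graded
#' value in \[0,1\]:
#' \itemize{
#'   \item \code{scoreLipinski}: mw <= 500, logp <= 5, hbd <= 5,
#'     hba <= 10 (4 rules).
#'   \item \code{scoreVeber}: rotb <= 10, tpsa <= 140 (2 rules).
#'   \item \code{scoreGhose}: 160 <= mw <= 480, -0.4 <= logp <= 5.6,
#'     40 <= molar refractivity <= 130, 20 <= atom count <= 70 (4 rules).
#'   \item \code{scoreAdmet}: 150 <= mw <= 500, -0.7 <= logp <= 5.0,
#'     tpsa <= 140, rotb <= 10, hbd <= 5, aromatic rings <= 4 (6 rules).
#' }
#'
#' @param d one descriptor row (list or single-row data.frame) from
#'   [computeDescriptors()].
#' @return component score in \[0,1\].
#' @examples
#' d <- computeDescriptors(c(ola = "CCO"))
#' scoreLipinski(d)
#' @export
scoreLipinski <- function(d) {
  mean(c(d$mw <= 500, d$logp <= 5, d$hbd <= 5, d$hba <= 10))
}

#' @rdname scoreLipinski
#' @export
scoreVeber <- function(d) {
  mean(c(d$rotb <= 10, d$tpsa <= 140))
}

#' @rdname scoreLipinski
#' @export
scoreGhose <- function(d) {
  mean(c(d$mw >= 160 & d$mw <= 480,
         d$logp >= -0.4 & d$logp <= 5.6,
         d$molar_refractivity >= 40 & d$molar_refractivity <= 130,
         d$atom_count >= 20 & d$atom_count <= 70))
}

#' @rdname scoreLipinski
#' @export
scoreAdmet <- function(d) {
  mean(c(d$mw >= 150 & d$mw <= 500,
         d$logp >= -0.7 & d$logp <= 5.0,
         d$tpsa <= 140,
         d$rotb <= 10,
         d$hbd <= 5,
         d$aromatic_rings <= 4))
}

#' QED and synthetic-accessibility component scores
#'
#' \code{scoreQed} passes the raw QED through unchanged;
#' \code{scoreSa} maps the raw 1-10 SA estimate (1 = easiest) to
#' \[0,1\] with higher = more synthesizable: (10 - sa_raw)/9. Raw SA
#' values outside \[1,10\] are clamped with a warning.
#'
#' @param d one descriptor row from [computeDescriptors()].
#' @return component score in \[0,1\].
#' @export
scoreQed <- function(d) d$qed_raw

#' @rdname scoreQed
#' @export
scoreSa <- function(d) {
  sa <- d$sa_raw
  if (sa < 1 || sa > 10) {
    warning("raw SA score ", sa, " outside [1,10]; clamping")
    sa <- min(max(sa, 1), 10)
  }
  (10 - sa) / 9
}

#' Structural-alert component score
#'
#' 1.0 for an alert-free compound, minus 0.5 per structural alert,
#' floored at 0 (so one alert scores 0.5 and two or more score 0).
#'
#' @param n_alerts number of structural alerts (PAINS + BRENK hits), or
#'   an alert table from [detectAlerts()] whose rows are counted.
#' @return component score in \[0,1\].
#' @examples
#' scoreAlerts(0); scoreAlerts(1); scoreAlerts(3)
#' @export
scoreAlerts <- function(n_alerts) {
  if (is.data.frame(n_alerts)) n_alerts <- nrow(n_alerts)
  max(0, 1 - 0.5 * n_alerts)
}

#' Aggregate component scores into the total drug-likeness score
#'
#' \eqn{S_{total} = \sum_{i=1}^{7} w_i S_i}. With components in \[0,1\]
#' and the default weight vector the total is bounded in \[0,1\] and is
#' monotone non-decreasing in every component.
#'
#' @param components named numeric of the 7 component scores (names
#'   \code{lipinski}, \code{veber}, \code{ghose}, \code{qed}, \code{sa},
#'   \code{admet}, \code{pains}).
#' @param weights named weight vector summing to 1; see
#'   [defaultWeights()].
#' @return total score.
#' @examples
#' aggregateTotal(c(lipinski = 1, veber = 1, ghose = 1, qed = 0.5,
#'                  sa = 1, admet = 0.5, pains = 1))
#' @export
aggregateTotal <- function(components, weights = defaultWeights()) {
  if (length(weights) != 7L || is.null(names(weights)) ||
      !all(.COMPONENTS %in% names(weights)))
    stop("weights must be named over: ", paste(.COMPONENTS, collapse = ", "))
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (got ", sum(weights), ")")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is.null(names(components))) names(components) <- .COMPONENTS
  if (!all(.COMPONENTS %in% names(components)))
    stop("components must be named over: ",
         paste(.COMPONENTS, collapse = ", "))
  sum(weights[.COMPONENTS] * components[.COMPONENTS])
}

#' Assign letter grades to total scores
#'
#' Left-closed bands: A for S >= 0.85, B for 0.70 <= S < 0.85, C for
#' 0.55 <= S < 0.70, D for 0.40 <= S < 0.55, F below 0.40. Total and
#' single-valued on \[0,1\]; inputs outside \[0,1\] are an error.
#'
#' @param s_total numeric vector of total scores in \[0,1\].
#' @param bands named lower bounds for grades A-D, strictly decreasing;
#'   see [gradeBands()].
#' @return character vector of grades.
#' @examples
#' assignGrade(c(0.85, 0.8499, 0.55, 0.40, 0.39))
#' @export
assignGrade <- function(s_total, bands = gradeBands()) {
  if (any(!is.finite(s_total)) || any(s_total < 0) || any(s_total > 1))
    stop("total scores must lie in [0,1]")
  stopifnot(identical(names(bands), c("A", "B", "C", "D")),
            all(diff(bands) < 0), all(bands > 0), all(bands < 1))
  b <- bands
  ifelse(s_total >= b[["A"]], "A",
  ifelse(s_total >= b[["B"]], "B",
  ifelse(s_total >= b[["C"]], "C",
  ifelse(s_total >= b[["D"]], "D", "F"))))
}

.componentRow <- function(d) {
  c(lipinski = scoreLipinski(d), veber = scoreVeber(d),
    ghose = scoreGhose(d), qed = scoreQed(d), sa = scoreSa(d),
    admet = scoreAdmet(d), pains = scoreAlerts(d$n_alerts))
}

#' Score compounds through the full seven-criterion framework
#'
#' Composition of descriptor computation, the seven component scorers,
#' weighted aggregation and grading. Deterministic for fixed structures.
#'
#' @param records data.frame with \code{identifier} and \code{smiles}
#'   columns (or a character vector of SMILES), a
#'   [CompoundLibrary-class], or a precomputed descriptor table from
#'   [computeDescriptors()] (recognized by its \code{mw} column).
#' @param weights component weight vector; see [defaultWeights()].
#' @return a [ScoreCardSet-class]; its \code{cards} table carries the
#'   seven component scores, \code{s_total} and \code{grade} per
#'   compound.
#' @examples
#' sc <- scoreCompounds(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' cards(sc)
#' @export
scoreCompounds <- function(records, weights = defaultWeights()) {
  if (is(records, "CompoundLibrary")) records <- records(records)
  desc <- if (is.data.frame(records) && "mw" %in% names(records))
    records else computeDescriptors(records)
  n <- nrow(desc)
  comp <- t(vapply(seq_len(n),
                   function(i) .componentRow(desc[i, , drop = FALSE]),
                   numeric(7)))
  s_total <- apply(comp, 1L, aggregateTotal, weights = weights)
  cards <- data.frame(identifier = desc$identifier)
  for (nm in .COMPONENTS) cards[[paste0("s_", nm)]] <- comp[, nm]
  cards$s_total <- s_total
  cards$grade <- assignGrade(pmin(pmax(s_total, 0), 1))
  new("ScoreCardSet", cards = cards, weights = weights[.COMPONENTS])
}

#' Round half-up to a fixed number of decimals
#'
#' Unlike \code{round()} (banker's rounding), 0.05 rounds up to 0.1.
#' Used for printed grade percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-grade percentages from grade counts
#'
#' @param counts named vector of grade counts (names among A, B, C, D,
#'   F; missing grades count 0).
#' @return named numeric percentages (100*count/total), rounded half-up
#'   to one decimal.
#' @examples
#' gradePercentages(c(A = 25, B = 92, C = 37, D = 10, F = 7))
#' @export
gradePercentages <- function(counts) {
  full <- c(A = 0, B = 0, C = 0, D = 0, F = 0)
  full[names(counts)] <- counts
  total <- sum(full)
  if (total == 0) stop("empty library")
  roundHalfUp(100 * full / total, 1)
}

#' Summarize a scored library
#'
#' Per-grade counts and percentages (half-up, one decimal) plus the
#' mean and median total score (three decimals).
#'
#' @param x a [ScoreCardSet-class] or its \code{cards} data.frame.
#' @return a [GradeSummary-class].
#' @examples
#' sc <- scoreCompounds(c(a = "CCO", b = "c1ccccc1"))
#' summarizeLibrary(sc)
#' @export
summarizeLibrary <- function(x) {
  tab <- if (is(x, "ScoreCardSet")) cards(x) else x
  if (!nrow(tab)) stop("empty library")
  counts <- table(factor(tab$grade, levels = c("A", "B", "C", "D", "F")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  new("GradeSummary",
      counts = counts,
      percentages = gradePercentages(counts),
      mean_total = roundHalfUp(mean(tab$s_total), 3),
      median_total = roundHalfUp(stats::median(tab$s_total), 3),
      n = nrow(tab))
}
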