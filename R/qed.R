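# Quantitative estimate of drug-likeness (QED): the geometric mean of
# eight desirability functions, each an asymmetric double sigmoid (ADS)
# fitted to the property distribution of approved oral drugs. Parameters
# (a, b, c, d, e, f, dmax per property) and the property weights are the
# published values of the original QED formulation. Property inputs here
# come from OpenBabel, and the ALERTS property counts hits in the
# package's BRENK-style unwanted-functionality catalog, so absolute QED
# values can differ slightly from toolkits using other perception rules;
# the score remains a deterministic [0,1] desirability composite.

.QED_ADS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764,
             d = 2.419764353, e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431,
             d = 4.581497897, e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657,
             d = 4.435986202, e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388,
             d = 0.000000001, e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.8436261, c = 62.90774896,
             d = 87.83366614, e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.010000000, b = 272.4121427, c = 2.558379970,
             d = 1.565547684, e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939,
             d = 0.000000001, e = 1.317690384, f = 0.375760881,
             dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883,
             d = 0.000000001, e = 0.185904477, f = 0.875193782,
             dmax = 417.7253140))

.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  val <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  max(val / p[["dmax"]], 1e-9)
}

#' Quantitative estimate of drug-likeness (weighted QED)
#'
#' Computes the weighted QED: each of eight properties (molecular
#' weight, logP, H-bond acceptors/donors, polar surface area, rotatable
#' bonds, aromatic rings, structural alerts) is mapped through a fitted
#' desirability function d_i in (0,1], and QED is the weighted geometric
#' mean exp(sum(w_i log d_i) / sum(w_i)).
#'
#' @param mw molecular weight (Da).
#' @param alogp atom-contribution logP estimate.
#' @param hba,hbd hydrogen-bond acceptor and donor counts.
#' @param psa topological polar surface area (A^2).
#' @param rotb rotatable-bond count.
#' @param arom aromatic-ring count.
#' @param alerts structural-alert count.
#' @return QED value in \[0,1\].
#' @examples
#' qedScore(mw = 300, alogp = 2.5, hba = 3, hbd = 1, psa = 60,
#'          rotb = 4, arom = 2, alerts = 0)
#' @export
qedScore <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts) {
  x <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
         ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(x), function(nm) .ads(x[[nm]], .QED_ADS[[nm]]), 0)
  q <- exp(sum(.QED_WEIGHTS * log(d)) / sum(.QED_WEIGHTS))
  min(max(q, 0), 1)
}
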