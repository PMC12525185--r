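#' Statistical defect of one attribute
#'
#' Measures how differently an attribute is represented across the active
#' training, passive training and calibration sets.  With `p = n/size` the
#' per-set probability of a compound containing the attribute,
#' `dk = |pA-pP|/(nA+nP) + |pA-pC|/(nA+nC) + |pP-pC|/(nP+nC)`.
#' An attribute absent from any one of the three sets is maximally
#' unreliable and receives `dk = 1` by convention; an attribute absent from
#' all three is unknown and raises an error.
#'
#' @param nA,nP,nC Number of compounds containing the attribute in the
#'   active training, passive training and calibration sets (vectors OK).
#' @param sizeA,sizeP,sizeC Set sizes (positive).
#' @return Numeric vector of defect values, `>= 0`, zero when the three
#'   probabilities agree exactly.
#' @export
attribute_defect <- function(nA, nP, nC, sizeA, sizeP, sizeC) {
  if (any(c(sizeA, sizeP, sizeC) <= 0)) stop("set sizes must be positive")
  if (any(nA < 0 | nP < 0 | nC < 0)) stop("counts must be non-negative")
  if (any(nA == 0 & nP == 0 & nC == 0))
    stop("unknown attribute: zero frequency in all three sets")
  pA <- nA / sizeA; pP <- nP / sizeP; pC <- nC / sizeC
  dk <- abs(pA - pP) / (nA + nP) + abs(pA - pC) / (nA + nC) +
    abs(pP - pC) / (nP + nC)
  dk[nA == 0 | nP == 0 | nC == 0] <- 1
  dk
}

# Domain model for a fitted split: per-attribute defects over the active
# (non-blocked) attributes, per-compound defect sums, and the mean defect
# over active-training compounds.
build_domain <- function(profiles, idx, active, ids) {
  freq_in <- function(i) {
    f <- compound_frequencies(profiles[i])
    out <- stats::setNames(integer(length(active)), active)
    hit <- intersect(names(f), active)
    out[hit] <- f[hit]
    out
  }
  nA <- freq_in(idx$A); nP <- freq_in(idx$P); nC <- freq_in(idx$C)
  dk <- attribute_defect(nA, nP, nC,
                         length(idx$A), length(idx$P), length(idx$C))
  X <- attribute_matrix(profiles, active)
  dj <- as.vector(X %*% dk)
  names(dj) <- ids
  list(defects = data.frame(attribute = active, nA = unname(nA),
                            nP = unname(nP), nC = unname(nC),
                            dk = unname(dk), stringsAsFactors = FALSE,
                            row.names = NULL),
       dj = dj,
       dbar = mean(dj[idx$A]))
}

#' Per-compound statistical defect
#'
#' Sums the attribute defects over all non-blocked attributes of a compound,
#' once per occurrence.  Attributes never seen in any modelling set (possible
#' only for prediction-time compounds) count `dk = 1` each, the same
#' maximal-unreliability convention used for attributes missing from one set.
#'
#' @param profile An [attribute_profile()].
#' @param domain The `domain` component of a fitted [cw_fit()] model.
#' @param blocked Character vector of blocked attributes (contribute
#'   nothing).
#' @return The compound defect Dj (a single number).
#' @export
compound_defect <- function(profile, domain, blocked = character(0L)) {
  cnt <- profile_counts(profile)
  if (length(blocked)) cnt <- cnt[!(names(cnt) %in% blocked)]
  dk <- domain$defects$dk[match(names(cnt), domain$defects$attribute)]
  dk[is.na(dk)] <- 1  # attribute unseen in A/P/C
  sum(cnt * dk)
}

#' Applicability-domain rule
#'
#' A compound falls in the domain of applicability when its statistical
#' defect is strictly below twice the mean defect of the active training
#' set: `Dj < 2 * Dbar`.
#'
#' @param dj Compound defect value(s).
#' @param dbar Mean defect over active-training compounds (positive).
#' @return Logical vector.
#' @export
in_domain <- function(dj, dbar) {
  if (any(dbar <= 0)) stop("dbar must be positive")
  dj < 2 * dbar
}

#' Outliers of a fitted model by the statistical-defect rule
#'
#' Lists the compounds whose defect Dj fails the domain rule `Dj < 2*Dbar`,
#' grouped by their split membership.
#'
#' @param model A fitted [cw_fit()] model.
#' @return A list with `by_set` (named list of id vectors for A/P/C/V),
#'   `counts` (per-set outlier counts), and `total`.
#' @export
cw_outliers <- function(model) {
  stopifnot(inherits(model, "cw_model"))
  dj <- model$domain$dj
  out_ids <- names(dj)[!in_domain(dj, model$domain$dbar)]
  set_of <- stats::setNames(model$split$set, model$split$id)
  by_set <- lapply(c(A = "A", P = "P", C = "C", V = "V"), function(s)
    out_ids[set_of[out_ids] == s])
  list(by_set = by_set,
       counts = vapply(by_set, length, integer(1L)),
       total = length(out_ids))
}
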