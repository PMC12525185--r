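#' Attributes active at rarity threshold T
#'
#' An attribute (Sk or SSk) is active when it occurs in at least `threshold`
#' compounds of the active training set; all other attributes are blocked
#' (their correlation weight is pinned at zero).  Occurrence is counted per
#' compound containing the attribute, not per total occurrence; the two
#' readings coincide at the threshold T = 1 used by the published models.
#'
#' @param profiles List of [attribute_profile()] objects for the active
#'   training set.
#' @param threshold Positive integer T.
#' @return Character vector of active attribute names (sorted).
#' @export
active_attributes <- function(profiles, threshold = 1L) {
  if (length(profiles) == 0L) stop("empty active training set")
  if (threshold < 1L) stop("threshold must be >= 1")
  freq <- compound_frequencies(profiles)
  sort_c(names(freq)[freq >= threshold])
}

# locale-independent (C collation) sort so attribute order — and with it the
# seeded optimization path — does not depend on LC_COLLATE
sort_c <- function(x) sort(x, method = "radix")

# number of compounds (profiles) containing each attribute
compound_frequencies <- function(profiles) {
  tab <- table(unlist(lapply(profiles, function(p)
    names(profile_counts(p)))))
  stats::setNames(as.integer(tab), names(tab))
}

# n_compounds x n_attributes count matrix over the given attribute names
attribute_matrix <- function(profiles, attributes) {
  X <- matrix(0, nrow = length(profiles), ncol = length(attributes),
              dimnames = list(NULL, attributes))
  for (i in seq_along(profiles)) {
    cnt <- profile_counts(profiles[[i]])
    keep <- names(cnt) %in% attributes
    if (any(keep)) X[i, names(cnt)[keep]] <- cnt[keep]
  }
  X
}

#' Descriptor of correlation weights (DCW)
#'
#' The molecular descriptor is the plain sum of the correlation weights of
#' all active attributes of the molecule, each counted with its multiplicity:
#' `DCW = sum count(Sk) * CW(Sk) + sum count(SSk) * CW(SSk)`.  Blocked and
#' unseen attributes contribute zero.
#'
#' @param profile An [attribute_profile()].
#' @param weights Named numeric vector of correlation weights.
#' @param blocked Character vector of blocked attribute names (weight forced
#'   to zero even if present in `weights`).
#' @return The DCW value (a single number).
#' @export
dcw <- function(profile, weights, blocked = character(0L)) {
  cnt <- profile_counts(profile)
  if (length(blocked)) cnt <- cnt[!(names(cnt) %in% blocked)]
  w <- weights[names(cnt)]
  w[is.na(w)] <- 0
  sum(cnt * w)
}

#' One-variable least-squares calibration line
#'
#' Ordinary least squares of the endpoint on the DCW descriptor, the Eq.
#' `endpoint = C0 + C1 * DCW` mapping descriptor values to predictions.
#'
#' @param dcw_values Numeric descriptor values (>= 3, non-constant).
#' @param endpoints Numeric observed endpoints.
#' @return Named numeric `c(c0 = intercept, c1 = slope)`.
#' @export
fit_calibration_line <- function(dcw_values, endpoints) {
  check_pair(dcw_values, endpoints, 3L)
  xbar <- mean(dcw_values)
  sxx <- sum((dcw_values - xbar)^2)
  if (sxx == 0)
    stop("degenerate descriptor: dcw_values have zero variance")
  c1 <- sum((dcw_values - xbar) * (endpoints - mean(endpoints))) / sxx
  c(c0 = mean(endpoints) - c1 * xbar, c1 = c1)
}
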