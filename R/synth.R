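#' True attribute weights of the synthetic generator
#'
#' The synthetic benchmark draws endpoints from a known linear model over
#' attribute counts, `endpoint = c0 + sum w(attr) * count(attr) + noise`.
#' The default weights follow the qualitative structure seen in acute
#' aquatic toxicity: halogens and sulfur raise pLC50, nitrogen and oxygen
#' (polarity) lower it, carbons contribute mildly.  Attributes not listed
#' contribute zero.
#'
#' @return Named list with `weights` (named numeric over Sk and SSk
#'   attributes) and `c0` (intercept).
#' @export
synth_truth <- function() {
  list(weights = c(
    "C" = 0.30, "c" = 0.15, "N" = -0.45, "O" = -0.35, "S" = 0.85,
    "Cl" = 1.00, "1" = -0.15, "2" = -0.10, "=" = 0.20,
    "CC" = 0.05, "cc" = 0.08, "cC" = 0.10, "NC" = -0.10
  ), c0 = 0.5)
}

# One random SMILES-like string.  Balanced parentheses and paired ring
# digits by construction, so every generated string tokenizes.
synth_smiles_one <- function(exotic = FALSE) {
  atoms <- c("C", "C", "C", "C", "N", "O", "S")
  branches <- c("(C)", "(Cl)", "(O)", "(N)", "(CC)", "(=O)")
  rings <- c("c1ccccc1", "c1ccc(Cl)cc1", "C1CCCC1", "c1ccncc1")
  if (exotic) {
    branches <- c(branches, "([N+])", "([NH])")
    rings <- c(rings, "C%11CCCC%11")
  }
  n_chain <- sample(3:8, 1L)
  parts <- character(0L)
  for (i in seq_len(n_chain)) {
    a <- sample(atoms, 1L)
    if (i > 1L && stats::runif(1L) < 0.15 && a %in% c("C", "N", "O"))
      parts <- c(parts, "=")
    parts <- c(parts, a)
    if (i > 1L && i < n_chain && stats::runif(1L) < 0.30)
      parts <- c(parts, sample(branches, 1L))
  }
  if (stats::runif(1L) < 0.5) {
    parts <- c(parts, sample(rings, 1L))
    if (stats::runif(1L) < 0.3)
      parts <- c(parts, gsub("1", "2", sample(rings[1:4], 1L), fixed = TRUE))
  }
  paste0(parts, collapse = "")
}

#' Generate a synthetic SMILES dataset with known linear truth
#'
#' Assembles `n` random SMILES-like strings from a small closed grammar
#' (chains over C/N/O/S with optional branches, double bonds and up to two
#' rings) and draws their endpoints from the linear truth
#' `endpoint = c0 + sum w(attr) * count(attr) + Normal(0, sigma)`, where the
#' counts are taken from the same attribute profile the model sees.  The
#' noise level is specified relative to the spread of the noise-free signal,
#' so `noise = 0.1` means sigma equal to 10% of the signal standard
#' deviation.  An optional atypical fraction receives a constant endpoint
#' offset, reproducing the two-cluster phenomenology of mixed populations.
#'
#' @param n Number of compounds (>= 20).
#' @param noise Noise standard deviation as a fraction of the signal SD
#'   (default 0.1; 0 gives a noiseless dataset).
#' @param seed Integer seed.
#' @param atypical_frac Fraction of compounds receiving `atypical_offset`
#'   added to their endpoint (default 0).
#' @param atypical_offset Endpoint offset of the atypical group (default 2).
#' @param exotic If `TRUE`, the grammar also emits bracket atoms and `%NN`
#'   ring closures to exercise the tokenizer (default `FALSE`).
#' @param truth Truth specification from [synth_truth()].
#' @return List of class `"cw_synth"`: `data` (data frame `id`, `smiles`,
#'   `endpoint`), and `truth` (weights, c0, sigma actually used, noise
#'   ratio, seed, atypical ids).
#' @examples
#' syn <- cw_synth(n = 50, noise = 0, seed = 3)
#' head(syn$data)
#' @export
cw_synth <- function(n = 200L, noise = 0.1, seed = 1L,
                     atypical_frac = 0, atypical_offset = 2,
                     exotic = FALSE, truth = synth_truth()) {
  if (n < 20L) stop("n must be at least 20")
  if (noise < 0) stop("noise must be non-negative")
  with_seed(seed, {
    smiles <- vapply(seq_len(n), function(i) synth_smiles_one(exotic),
                     character(1L))
    profiles <- lapply(smiles, attribute_profile)
    signal <- vapply(profiles, function(p) {
      cnt <- profile_counts(p)
      w <- truth$weights[names(cnt)]
      w[is.na(w)] <- 0
      truth$c0 + sum(cnt * w)
    }, numeric(1L))
    sigma <- noise * stats::sd(signal)
    y <- signal + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
    atypical <- rep(FALSE, n)
    if (atypical_frac > 0) {
      atypical <- stats::runif(n) < atypical_frac
      y[atypical] <- y[atypical] + atypical_offset
    }
    ids <- sprintf("syn%04d", seq_len(n))
    structure(list(
      data = data.frame(id = ids, smiles = smiles, endpoint = y,
                        stringsAsFactors = FALSE),
      truth = list(weights = truth$weights, c0 = truth$c0, sigma = sigma,
                   noise_ratio = noise, seed = as.integer(seed),
                   atypical_ids = ids[atypical])
    ), class = "cw_synth")
  })
}

#' @export
print.cw_synth <- function(x, ...) {
  cat("Synthetic SMILES dataset:", nrow(x$data), "compounds, sigma =",
      format(x$truth$sigma, digits = 4),
      sprintf("(%.0f%% of signal SD), seed = %d\n",
              100 * x$truth$noise_ratio, x$truth$seed))
  invisible(x)
}
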