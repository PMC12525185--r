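#' Independent optimization probes on the same split
#'
#' Re-runs the Monte Carlo optimization `n_probes` times with seeds derived
#' from `control$seed`, holding data, split and all other settings fixed.
#' The resulting family of weight tables supports the promoter analysis:
#' attributes whose weight keeps one sign across independent runs carry a
#' stable mechanistic signal.
#'
#' @param data,split,control As in [cw_fit()].
#' @param n_probes Number of probes (default `control$probes`, >= 2).
#' @return List of `n_probes` fitted `cw_model` objects.
#' @export
cw_probes <- function(data, split, control = cw_control(),
                      n_probes = control$probes) {
  if (n_probes < 2L) stop("need at least 2 probes")
  lapply(seq_len(n_probes), function(i) {
    ctl <- control
    ctl$seed <- derive_seed(control$seed, i)
    cw_fit(data, split, ctl)
  })
}

#' Classify attributes as promoters of endpoint increase or decrease
#'
#' An attribute is a promoter of an increased endpoint when its correlation
#' weight is strictly positive in every probe, a promoter of a decrease when
#' strictly negative in every probe, and unstable otherwise (including any
#' exactly-zero weight).  The report carries the per-set frequencies and the
#' statistical defect of each attribute so it can be read alongside the
#' applicability-domain table.
#'
#' @param probes List of fitted models from [cw_probes()] (or a list of
#'   named weight vectors over a common attribute set).
#' @return Data frame of class `"cw_promoters"`: one row per active
#'   attribute with columns `attribute`, `cw_probe1..k`, `nA`, `nP`, `nC`,
#'   `dk`, `classification`; sorted by classification (increase, decrease,
#'   unstable) then decreasing `nA`.
#' @export
classify_promoters <- function(probes) {
  if (length(probes) < 2L) stop("need at least 2 probes")
  tables <- lapply(probes, function(p)
    if (inherits(p, "cw_model")) p$weights else p)
  attrs <- names(tables[[1L]])
  for (tb in tables[-1L])
    if (!identical(sort(names(tb)), sort(attrs)))
      stop("probes must share a common active-attribute set")
  W <- vapply(tables, function(tb) tb[attrs], numeric(length(attrs)))
  W <- matrix(W, nrow = length(attrs),
              dimnames = list(attrs, paste0("cw_probe", seq_along(tables))))
  cls <- apply(W, 1L, function(w)
    if (all(w > 0)) "increase" else if (all(w < 0)) "decrease" else "unstable")
  out <- data.frame(attribute = attrs, W, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  if (inherits(probes[[1L]], "cw_model")) {
    def <- probes[[1L]]$domain$defects
    m <- match(attrs, def$attribute)
    out$nA <- def$nA[m]; out$nP <- def$nP[m]; out$nC <- def$nC[m]
    out$dk <- def$dk[m]
  } else {
    out$nA <- out$nP <- out$nC <- NA_integer_
    out$dk <- NA_real_
  }
  out$classification <- cls
  ord <- order(match(cls, c("increase", "decrease", "unstable")), -out$nA)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cw_promoters", "data.frame")
  out
}
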