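#' Target functions for the Monte Carlo optimization
#'
#' `tf0` combines the determination coefficients of the active and passive
#' training sets with a penalty on their disagreement:
#' `TF0 = r2_active + r2_passive - w * |r2_active - r2_passive|`.
#' `tf1` adds the index of ideality of correlation computed on the
#' calibration set: `TF1 = TF0 + iic_weight * iic_calibration`.  The
#' discrepancy term's sign is configurable (`sign = -1` penalizes, the
#' default; `+1` rewards disagreement, provided for comparison only).
#'
#' @param r2_active,r2_passive Determination coefficients in \[0, 1\].
#' @param w Discrepancy weight (default 0.1).
#' @param sign Sign applied to the discrepancy term (default -1).
#' @return Target-function value.
#' @examples
#' tf0(0.5, 0.3)                   # 0.78
#' tf1(0.5, 0.3, iic = 0.8)        # 0.98
#' @export
tf0 <- function(r2_active, r2_passive, w = 0.1, sign = -1) {
  r2_active + r2_passive + sign * w * abs(r2_active - r2_passive)
}

#' @rdname tf0
#' @param iic Index of ideality of correlation on the calibration set.
#' @param iic_weight Weight of the IIC term (default 0.25).
#' @export
tf1 <- function(r2_active, r2_passive, iic, w = 0.1, iic_weight = 0.25,
                sign = -1) {
  tf0(r2_active, r2_passive, w, sign) + iic_weight * iic
}

#' Optimization settings for correlation-weight models
#'
#' Collects the tunable parameters of the Monte Carlo optimization.  The two
#' published presets are `target = "TF0"` with 3 epochs (DCW(1,3)) and
#' `target = "TF1"` with 15 epochs (DCW(1,15)); when `epochs` is not given it
#' defaults accordingly.
#'
#' @param target `"TF1"` (default) or `"TF0"`.
#' @param threshold Rarity threshold T: minimum number of active-training
#'   compounds containing an attribute for it to receive a weight (default 1).
#' @param epochs Number of optimization epochs N; default 15 for TF1, 3 for
#'   TF0.
#' @param iic_weight Weight of the calibration-set IIC term in TF1
#'   (default 0.25).
#' @param discrepancy_weight Weight of the train/train disagreement term
#'   (default 0.1).
#' @param discrepancy_sign Sign of the disagreement term (default -1,
#'   a penalty).
#' @param init_range Range of the uniform initialization of weights.
#' @param step_max Maximum proposal step size; each proposal draws
#'   `delta ~ Uniform(0, step_max]`.
#' @param probes Number of independent optimization probes used by
#'   [cw_probes()] (default 3).
#' @param seed Integer seed; the entire fit is a deterministic function of
#'   (data, split, control).
#' @return A list of class `"cw_control"`.
#' @export
cw_control <- function(target = c("TF1", "TF0"), threshold = 1L,
                       epochs = NULL, iic_weight = 0.25,
                       discrepancy_weight = 0.1, discrepancy_sign = -1,
                       init_range = c(-1, 1), step_max = 0.1,
                       probes = 3L, seed = 1L) {
  target <- match.arg(target)
  if (is.null(epochs)) epochs <- if (target == "TF1") 15L else 3L
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (step_max <= 0) stop("step_max must be positive")
  if (threshold < 1L) stop("threshold must be >= 1")
  if (probes < 1L) stop("probes must be >= 1")
  if (length(init_range) != 2L || init_range[1L] >= init_range[2L])
    stop("init_range must be (lo, hi) with lo < hi")
  structure(list(target = target, threshold = as.integer(threshold),
                 epochs = epochs, iic_weight = iic_weight,
                 discrepancy_weight = discrepancy_weight,
                 discrepancy_sign = discrepancy_sign,
                 init_range = as.numeric(init_range),
                 step_max = step_max, probes = as.integer(probes),
                 seed = as.integer(seed)),
            class = "cw_control")
}

# Internal state evaluation shared by cw_fit and cw_evaluate.
# env carries precomputed quantities: X, y, idx (list A/P/C/V), control.
# Returns tf (=-Inf for degenerate states), r2a, r2p, r2c, c0, c1.
eval_dcw_state <- function(dcwv, y, idx, control) {
  dA <- dcwv[idx$A]; yA <- y[idx$A]
  dP <- dcwv[idx$P]; yP <- y[idx$P]
  dC <- dcwv[idx$C]; yC <- y[idx$C]
  bad <- list(tf = -Inf, r2a = NA_real_, r2p = NA_real_, r2c = NA_real_,
              c0 = NA_real_, c1 = NA_real_)
  sxxA <- sum((dA - mean(dA))^2)
  if (!is.finite(sxxA) || sxxA <= 0) return(bad)
  r2 <- function(d, yy) {
    sxx <- sum((d - mean(d))^2)
    if (sxx <= 0) return(NA_real_)
    syy <- sum((yy - mean(yy))^2)
    sxy <- sum((d - mean(d)) * (yy - mean(yy)))
    sxy * sxy / (sxx * syy)
  }
  r2a <- r2(dA, yA)
  r2p <- r2(dP, yP)
  if (is.na(r2a) || is.na(r2p)) return(bad)
  c1 <- sum((dA - mean(dA)) * (yA - mean(yA))) / sxxA
  c0 <- mean(yA) - c1 * mean(dA)
  r2c <- r2(dC, yC)
  tf <- tf0(r2a, r2p, control$discrepancy_weight, control$discrepancy_sign)
  if (control$target == "TF1") {
    predC <- c0 + c1 * dC
    if (stats::sd(predC) == 0 || is.na(r2c)) return(bad)
    iicC <- stats::cor(yC, predC) * mae_ratio(yC - predC)
    tf <- tf + control$iic_weight * iicC
  }
  list(tf = tf, r2a = r2a, r2p = r2p, r2c = r2c, c0 = c0, c1 = c1)
}

#' Evaluate a correlation-weight table on a split dataset
#'
#' Computes the DCW descriptor for every compound, refits the calibration
#' line on the active training set, and returns the target-function value
#' together with the per-set statistics bundles.  Degenerate weight tables
#' (all descriptor values equal on the active training set) receive
#' `tf = -Inf` so the optimizer can never accept them.
#'
#' @param weights Named numeric vector of correlation weights.
#' @param data Data frame with columns `id`, `smiles`, `endpoint`.
#' @param split A [cw_split()] covering `data$id`.
#' @param control A [cw_control()].
#' @return List with `tf`, `c0`, `c1`, and `stats` (per-set list of
#'   [stat_bundle()] results, `NULL` for degenerate states).
#' @export
cw_evaluate <- function(weights, data, split, control = cw_control()) {
  data <- check_dataset(data)
  profiles <- lapply(data$smiles, attribute_profile)
  X <- attribute_matrix(profiles, names(weights))
  y <- data$endpoint
  idx <- split_index(split, data$id)
  dcwv <- as.vector(X %*% weights)
  st <- eval_dcw_state(dcwv, y, idx, control)
  stats_out <- NULL
  if (is.finite(st$tf)) {
    pred <- st$c0 + st$c1 * dcwv
    stats_out <- lapply(idx, function(i)
      stat_bundle(y[i], pred[i], dcwv[i]))
  }
  list(tf = st$tf, c0 = st$c0, c1 = st$c1, r2 = st[c("r2a", "r2p", "r2c")],
       stats = stats_out)
}

#' Fit a correlation-weight QSAR model by Monte Carlo optimization
#'
#' The central fitting routine.  SMILES are tokenized into attributes;
#' attributes occurring in at least `threshold` active-training compounds
#' become active and receive a correlation weight, initialized uniformly in
#' `init_range`; all other attributes are blocked at weight zero.  Each epoch
#' visits every active attribute in a fresh random order and proposes the
#' two moves `CW + delta` and `CW - delta` with `delta ~ Uniform(0,
#' step_max]`; the better move is accepted only if it strictly increases the
#' target function (TF0 on the training sets, or TF1 which adds
#' `iic_weight` times the calibration-set IIC).  After the last epoch the
#' calibration line `endpoint = C0 + C1 * DCW` is fitted on the active
#' training set and the applicability-domain statistics are computed.
#'
#' @param data Data frame with columns `id` (unique), `smiles`, `endpoint`
#'   (numeric, e.g. pLC50).
#' @param split A [cw_split()] assigning every id to one of A/P/C/V.
#' @param control A [cw_control()] with the optimization settings.
#' @return An object of class `"cw_model"` with components `weights`,
#'   `blocked`, `c0`, `c1`, `history` (one row per epoch: `epoch, tf,
#'   r2_active, r2_passive, r2_calibration`), `stats` (per-set
#'   [stat_bundle()]), `domain` (defect table, per-compound defects, mean
#'   defect), `control`, `split`, `data`.
#' @examples
#' syn <- cw_synth(n = 60, seed = 11)
#' sp <- cw_split(syn$data$id, seed = 11)
#' fit <- cw_fit(syn$data, sp, cw_control(target = "TF1", epochs = 5, seed = 1))
#' summary(fit)
#' @seealso [cw_control()], [cw_probes()], [predict.cw_model()]
#' @export
cw_fit <- function(data, split, control = cw_control()) {
  data <- check_dataset(data)
  stopifnot(inherits(control, "cw_control"))
  profiles <- lapply(data$smiles, attribute_profile)
  idx <- split_index(split, data$id)
  if (!length(idx$A) || !length(idx$P) || !length(idx$C))
    stop("active training, passive training and calibration sets must be non-empty")
  active <- active_attributes(profiles[idx$A], control$threshold)
  if (length(active) == 0L)
    stop("no active attributes at threshold T = ", control$threshold)
  all_attrs <- sort_c(unique(unlist(lapply(profiles,
                                           function(p) names(profile_counts(p))))))
  blocked <- setdiff(all_attrs, active)
  X <- attribute_matrix(profiles, active)
  y <- data$endpoint
  m <- length(active)
  ne <- control$epochs

  run <- with_seed(control$seed, {
    w <- stats::runif(m, control$init_range[1L], control$init_range[2L])
    dcwv <- as.vector(X %*% w)
    cur <- eval_dcw_state(dcwv, y, idx, control)
    hist <- matrix(NA_real_, nrow = ne, ncol = 5L,
                   dimnames = list(NULL, c("epoch", "tf", "r2_active",
                                           "r2_passive", "r2_calibration")))
    for (epoch in seq_len(ne)) {
      for (k in sample.int(m)) {
        delta <- stats::runif(1L) * control$step_max
        xk <- X[, k]
        up <- eval_dcw_state(dcwv + delta * xk, y, idx, control)
        dn <- eval_dcw_state(dcwv - delta * xk, y, idx, control)
        if (up$tf >= dn$tf) { best <- up; move <- delta }
        else               { best <- dn; move <- -delta }
        if (best$tf > cur$tf) {
          w[k] <- w[k] + move
          dcwv <- dcwv + move * xk
          cur <- best
        }
      }
      hist[epoch, ] <- c(epoch, cur$tf, cur$r2a, cur$r2p, cur$r2c)
    }
    list(w = w, dcwv = dcwv, cur = cur, hist = hist)
  })

  if (!is.finite(run$cur$tf))
    stop("optimization never reached a non-degenerate state; ",
         "check that the endpoint varies and the dataset is large enough")

  w <- stats::setNames(run$w, active)
  line <- fit_calibration_line(run$dcwv[idx$A], y[idx$A])
  pred <- line["c0"] + line["c1"] * run$dcwv
  set_stats <- lapply(idx, function(i)
    if (length(i) >= 2L) stat_bundle(y[i], pred[i], run$dcwv[i]) else NULL)
  domain <- build_domain(profiles, idx, active, data$id)

  structure(list(
    weights = w,
    blocked = blocked,
    c0 = unname(line["c0"]),
    c1 = unname(line["c1"]),
    dcw = stats::setNames(run$dcwv, data$id),
    fitted = stats::setNames(as.vector(pred), data$id),
    stats = set_stats,
    history = local({
      h <- as.data.frame(run$hist)
      h$epoch <- as.integer(h$epoch)
      h
    }),
    domain = domain,
    control = control,
    split = split,
    data = data,
    version = as.character(utils::packageVersion("cwqsar"))
  ), class = "cw_model")
}

check_dataset <- function(data) {
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  need <- c("id", "smiles", "endpoint")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "))
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id))
    stop("duplicate compound id: ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "))
  if (!is.numeric(data$endpoint)) stop("'endpoint' must be numeric")
  data
}
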