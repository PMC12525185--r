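#' Random four-way split into active/passive training, calibration, validation
#'
#' Assigns every compound independently to one of the four modelling roles
#' (`A` active training, `P` passive training, `C` calibration, `V`
#' validation) with the given probabilities.  Independent per-compound
#' assignment (rather than exact quotas) is deliberate: it yields the
#' unequal, split-to-split varying set sizes seen in practice.  Draws are
#' repeated until every set is non-empty.
#'
#' @param ids Character or numeric vector of unique compound ids (>= 8).
#' @param proportions Four positive numbers summing to 1; default equal 25%.
#' @param seed Integer seed; the assignment is a pure function of
#'   `(ids, proportions, seed)`.
#' @param split_id Integer label stored on the result.
#' @return A `cw_split` object: data frame with columns `id` and `set`.
#' @examples
#' sp <- cw_split(sprintf("m%03d", 1:40), seed = 7)
#' table(sp$set)
#' @export
cw_split <- function(ids, proportions = c(0.25, 0.25, 0.25, 0.25),
                     seed = 1L, split_id = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (length(ids) < 8L) stop("need at least 8 compounds to split four ways")
  if (length(proportions) != 4L || any(proportions <= 0))
    stop("'proportions' must be four positive numbers")
  proportions <- proportions / sum(proportions)
  labels <- c("A", "P", "C", "V")
  set <- with_seed(seed, {
    repeat {
      s <- sample(labels, length(ids), replace = TRUE, prob = proportions)
      if (all(labels %in% s)) break
    }
    s
  })
  structure(data.frame(id = ids, set = set, stringsAsFactors = FALSE),
            split_id = as.integer(split_id), seed = as.integer(seed),
            class = c("cw_split", "data.frame"))
}

#' Families of independent four-way splits
#'
#' Generates `k` splits of the same id list with distinct seeds derived from
#' `base_seed`, for split-to-split stability analyses.
#'
#' @inheritParams cw_split
#' @param k Number of splits (>= 1).
#' @param base_seed Integer base seed.
#' @return List of `k` [cw_split()] objects with `split_id` 1..k.
#' @export
cw_splits <- function(ids, k, base_seed = 1L,
                      proportions = c(0.25, 0.25, 0.25, 0.25)) {
  if (k < 1L) stop("k must be >= 1")
  lapply(seq_len(k), function(i)
    cw_split(ids, proportions, seed = derive_seed(base_seed, i), split_id = i))
}

# Deterministic child seeds, kept inside 32-bit integer range.
derive_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) * 104729 + i * 7919) %% 2147483587)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# id vectors per set from a split, in dataset order
split_index <- function(split, ids) {
  m <- match(ids, split$id)
  if (anyNA(m)) stop("split does not cover all compound ids")
  set <- split$set[m]
  lapply(c(A = "A", P = "P", C = "C", V = "V"), function(s) which(set == s))
}

#' Write / read a split as a two-column CSV
#'
#' @param split A [cw_split()] object.
#' @param path File path.
#' @return `read_split` returns a `cw_split`; `write_split` returns `path`
#'   invisibly.
#' @export
write_split <- function(split, path) {
  utils::write.csv(as.data.frame(split)[, c("id", "set")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @param split_id Integer label for the re-read split.
#' @export
read_split <- function(path, split_id = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "set") %in% names(df)))
    stop("split file must have columns 'id' and 'set'")
  if (!all(df$set %in% c("A", "P", "C", "V")))
    stop("split labels must be A, P, C or V")
  structure(df[, c("id", "set")], split_id = as.integer(split_id),
            class = c("cw_split", "data.frame"))
}
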