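#' Normalize a SMILES string for attribute extraction
#'
#' Prepares raw SMILES text for tokenization into SMILES attributes.
#' Stereochemistry markers (`/`, `\`, `@`, `@@`) are removed because the
#' correlation-weight model carries no 3D information, and every closing
#' parenthesis is folded into `(` so that branch context is represented by a
#' single attribute symbol (the attribute vocabulary uses only the open
#' spelling, e.g. `"Cl("`).  Surrounding whitespace is stripped; all other
#' characters are preserved in order.
#'
#' @param smiles Character vector of raw SMILES strings.
#' @return Character vector of normalized SMILES, same length as `smiles`.
#' @examples
#' normalize_smiles("C/C=C\\C")        # "CC=CC"
#' normalize_smiles("Oc1ccc(Cl)cc1")   # "Oc1ccc(Cl(cc1"
#' @seealso [tokenize_smiles()], [attribute_profile()]
#' @export
normalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L)
    stop("'smiles' must be a non-empty character vector")
  out <- trimws(smiles)
  out <- gsub("[/\\\\@]", "", out)
  out <- gsub(")", "(", out, fixed = TRUE)
  if (any(!nzchar(out)))
    stop("malformed SMILES record: empty after normalization (record ",
         paste(which(!nzchar(out)), collapse = ", "), ")")
  out
}

#' Tokenize a normalized SMILES string into SMILES atoms
#'
#' Performs a deterministic left-to-right scan producing the indivisible
#' fragments ("SMILES atoms") of the string: the two-character elements `Cl`
#' and `Br`, bracket atoms `[...]` kept opaque as one token, ring-closure
#' escapes `%NN` (percent followed by exactly two digits), and every other
#' character as a single token.
#'
#' @param normalized A single normalized SMILES string (see
#'   [normalize_smiles()]).
#' @return Character vector of tokens whose concatenation reproduces the
#'   input.
#' @examples
#' tokenize_smiles("Cl")            # "Cl"
#' tokenize_smiles("C%11")          # "C"  "%11"
#' tokenize_smiles("C[N+](C(C")     # "C" "[N+]" "(" "C" "(" "C"
#' @export
tokenize_smiles <- function(normalized) {
  if (!is.character(normalized) || length(normalized) != 1L)
    stop("'normalized' must be a single string")
  chars <- strsplit(normalized, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(n)  # at most n tokens
  nt <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop("malformed SMILES: unterminated '[' in ", normalized)
      tok <- paste0(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(chars[(i + 1L):(i + 2L)] %in% as.character(0:9)))
        stop("malformed SMILES: '%' must be followed by two digits in ",
             normalized)
      tok <- paste0(chars[i:(i + 2L)], collapse = "")
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tok <- "Cl"
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tok <- "Br"
      i <- i + 2L
    } else {
      tok <- ch
      i <- i + 1L
    }
    nt <- nt + 1L
    tokens[nt] <- tok
  }
  tokens[seq_len(nt)]
}

#' Canonical spelling of a neighbor-pair attribute
#'
#' Two adjacent SMILES atoms form one pair attribute (SSk) regardless of
#' reading direction.  The canonical spelling puts first the token whose
#' leading character has the larger character code (so `("c","C")` and
#' `("C","c")` both give `"cC"`); ties on the leading character are broken by
#' full-string comparison.  This reproduces the published attribute
#' vocabulary spellings such as `"cC"`, `"Cl("`, `"=1"`.
#'
#' @param a,b Character vectors of tokens (recycled to common length).
#' @return Character vector of canonical pair-attribute strings.
#' @examples
#' pair_attribute("c", "C")    # "cC"
#' pair_attribute("(", "Cl")   # "Cl("
#' pair_attribute("=", "1")    # "=1"
#' @export
pair_attribute <- function(a, b) {
  if (length(a) != length(b)) {
    len <- max(length(a), length(b))
    a <- rep_len(a, len)
    b <- rep_len(b, len)
  }
  code <- function(x) vapply(substr(x, 1L, 1L), utf8ToInt, integer(1L),
                             USE.NAMES = FALSE)
  ca <- code(a)
  cb <- code(b)
  swap <- cb > ca | (cb == ca & b > a)
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  paste0(first, second)
}

#' Extract the attribute profile of a SMILES string
#'
#' Computes the multiset of SMILES attributes of one molecule: single-atom
#' attributes (Sk, one per token occurrence) and neighbor-pair attributes
#' (SSk, one per adjacent token pair after canonical ordering by
#' [pair_attribute()]).  Input may be raw SMILES (normalized internally) or a
#' pre-tokenized character vector.
#'
#' @param smiles A single SMILES string, or a character vector of tokens when
#'   `tokenized = TRUE`.
#' @param tokenized Logical; if `TRUE`, `smiles` is taken as an already
#'   tokenized sequence.
#' @return An object of class `"attribute_profile"`: a list with integer
#'   vectors `sk_counts` (named by token) and `ssk_counts` (named by pair
#'   attribute), and `n_tokens`.
#' @examples
#' p <- attribute_profile("Oc1ccc(Cl)cc1")
#' p$sk_counts["Cl"]
#' p$ssk_counts["Cl("]
#' @export
attribute_profile <- function(smiles, tokenized = FALSE) {
  tokens <- if (tokenized) smiles else tokenize_smiles(normalize_smiles(smiles))
  n <- length(tokens)
  sk <- table(tokens)
  sk_counts <- stats::setNames(as.integer(sk), names(sk))
  if (n >= 2L) {
    pairs <- pair_attribute(tokens[-n], tokens[-1L])
    ssk <- table(pairs)
    ssk_counts <- stats::setNames(as.integer(ssk), names(ssk))
  } else {
    ssk_counts <- stats::setNames(integer(0L), character(0L))
  }
  structure(list(sk_counts = sk_counts, ssk_counts = ssk_counts,
                 n_tokens = n),
            class = "attribute_profile")
}

# Flat named count vector over both attribute classes.  Sk and SSk keys
# cannot collide: a multi-character Sk token is only "Cl", "Br", "%NN" or a
# bracket atom, none of which is the concatenation of two valid tokens.
profile_counts <- function(profile) {
  c(profile$sk_counts, profile$ssk_counts)
}

#' @export
print.attribute_profile <- function(x, ...) {
  cat("SMILES attribute profile:", x$n_tokens, "tokens,",
      length(x$sk_counts), "distinct Sk,",
      length(x$ssk_counts), "distinct SSk\n")
  invisible(x)
}
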