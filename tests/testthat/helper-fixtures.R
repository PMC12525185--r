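# Shared fixtures built in code.

# Published example molecules (SMILES, pLC50)
hexachlorophene <- "Oc1c(Cl)cc(Cl)c(Cl)c1Cc1c(O)c(Cl)cc(Cl)c1Cl"
thiuram <- "CCN(CC)C(=S)SSC(=S)N(CC)CC"
dichlorophen <- "Oc1ccc(Cl)cc1Cc1cc(Cl)ccc1O"

# Published per-set statistics: target, split, set, n, r2, f (F only where
# printed).  Validation rows carry no F.
published_stats <- local({
  tf0 <- rbind(
    c(1, "A", 63, 0.4791, 56), c(1, "P", 63, 0.3648, 35),
    c(1, "C", 65, 0.4507, 52), c(1, "V", 60, 0.6360, NA),
    c(2, "A", 62, 0.4473, 49), c(2, "P", 59, 0.3894, 36),
    c(2, "C", 63, 0.4161, 43), c(2, "V", 67, 0.4696, NA),
    c(3, "A", 66, 0.4589, 54), c(3, "P", 60, 0.4700, 51),
    c(3, "C", 59, 0.5530, 71), c(3, "V", 66, 0.5378, NA),
    c(4, "A", 66, 0.5687, 84), c(4, "P", 64, 0.3214, 29),
    c(4, "C", 62, 0.4549, 50), c(4, "V", 59, 0.5075, NA),
    c(5, "A", 60, 0.4992, 58), c(5, "P", 66, 0.4753, 58),
    c(5, "C", 61, 0.5726, 79), c(5, "V", 64, 0.6604, NA))
  tf1 <- rbind(
    c(1, "A", 63, 0.3206, 29), c(1, "P", 63, 0.2829, 24),
    c(1, "C", 65, 0.6803, 134), c(1, "V", 60, 0.7189, NA),
    c(2, "A", 62, 0.4053, 41), c(2, "P", 59, 0.3246, 27),
    c(2, "C", 63, 0.6543, 115), c(2, "V", 67, 0.6404, NA),
    c(3, "A", 66, 0.4588, 54), c(3, "P", 60, 0.4267, 43),
    c(3, "C", 59, 0.7075, 138), c(3, "V", 66, 0.7027, NA),
    c(4, "A", 66, 0.5773, 87), c(4, "P", 64, 0.3646, 36),
    c(4, "C", 62, 0.6193, 98), c(4, "V", 59, 0.6744, NA),
    c(5, "A", 60, 0.5218, 63), c(5, "P", 66, 0.4557, 54),
    c(5, "C", 61, 0.6524, 111), c(5, "V", 64, 0.6276, NA))
  df <- as.data.frame(rbind(cbind("TF0", tf0), cbind("TF1", tf1)),
                      stringsAsFactors = FALSE)
  names(df) <- c("target", "split", "set", "n", "r2", "f")
  df$split <- as.integer(df$split)
  df$n <- as.integer(df$n)
  df$r2 <- as.numeric(df$r2)
  df$f <- as.numeric(df$f)
  df
})

# Published pair-attribute spellings (promoter table row labels)
published_pairs <- c("cC", "NC", "cN", "cO", "C=", "Cl(", "c1", "O1", "2(",
                     "=1", "N=", "3(", "C2", "c3", "C3", "N1", "N2", "5(")

# small deterministic dataset for fast fits
tiny_dataset <- function(n = 60, noise = 0.1, seed = 11) {
  cw_synth(n = n, noise = noise, seed = seed)
}

# quadratic re-scan oracle for attribute extraction: counts every token and
# every unordered adjacent pair by direct enumeration
profile_oracle <- function(tokens) {
  sk <- integer(0)
  for (t in tokens) sk[t] <- if (is.na(sk[t])) 1L else sk[t] + 1L
  ssk <- integer(0)
  if (length(tokens) >= 2) {
    for (i in seq_len(length(tokens) - 1L)) {
      key <- pair_attribute(tokens[i], tokens[i + 1L])
      ssk[key] <- if (is.na(ssk[key])) 1L else ssk[key] + 1L
    }
  }
  list(sk = sk[order(names(sk))], ssk = ssk[order(names(ssk))])
}
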