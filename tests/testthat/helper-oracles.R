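# Independent brute-force oracles.  These re-derive expected values from
# first principles and deliberately share no code with the package.

# --- tandem repeats -------------------------------------------------------

oracle_primitive <- function(core) {
  L <- nchar(core)
  if (L == 1L) return(TRUE)
  for (d in seq_len(L - 1L)) {
    if (L %% d != 0L) next
    if (paste(rep(substr(core, 1L, d), L / d), collapse = "") == core)
      return(FALSE)
  }
  TRUE
}

oracle_qualifies <- function(L, n) {
  (L == 1 && n >= 6) || (L >= 2 && L <= 9 && n >= 3) || (L >= 10 && n >= 2)
}

# enumerate every (start, core length, repeat count) run directly from the
# definition: primitive core, qualifying count, maximal both directions,
# N matches nothing
oracle_find_trs <- function(seq, max_core = 60L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sub <- function(i, L) paste(ch[i:(i + L - 1L)], collapse = "")
  hasN <- function(i, L) any(ch[i:(i + L - 1L)] == "N")
  res <- list()
  for (L in seq_len(min(max_core, n %/% 2))) {
    for (s in seq_len(n - 2L * L + 1L)) {
      if (hasN(s, L)) next
      core <- sub(s, L)
      # count whole adjacent copies (copies with N can never match)
      r <- 1L
      while (s + (r + 1L) * L - 1L <= n &&
             !hasN(s + r * L, L) && sub(s + r * L, L) == core) r <- r + 1L
      # maximality
      if (s - L >= 1L && !hasN(s - L, L) && sub(s - L, L) == core) next
      if (!oracle_qualifies(L, r)) next
      if (!oracle_primitive(core)) next
      res[[length(res) + 1L]] <- c(start = s - 1L, core_length = L,
                                   n_repeats = r)
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), core_length = integer(),
                      n_repeats = integer()))
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$start, out$core_length), , drop = FALSE]
}

rand_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", if (p_n > 0) "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), if (p_n > 0) p_n)),
        collapse = "")
}

# --- Fisher ---------------------------------------------------------------

# full enumeration with explicit binomial coefficients (no dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0 || k == 0 || k == m + n2) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  probs <- choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  p_obs <- choose(m, a) * choose(n2, k - a) / choose(m + n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# --- alignment ------------------------------------------------------------

# exhaustive global alignment score by memoless recursion over the three
# Gotoh states; tractable only for very short sequences
oracle_align_score <- function(a, b, mat, go, ge) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i == 0 && j == 0) {
      if (state == "M") return(0) else return(-Inf)
    }
    best <- -Inf
    if (state == "M" && i > 0 && j > 0) {
      s <- mat[va[i], vb[j]]
      best <- max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "X"),
                  rec(i - 1, j - 1, "Y")) + s
    } else if (state == "X" && i > 0) {
      best <- max(rec(i - 1, j, "M") - go - ge, rec(i - 1, j, "X") - ge,
                  rec(i - 1, j, "Y") - go - ge)
    } else if (state == "Y" && j > 0) {
      best <- max(rec(i, j - 1, "M") - go - ge, rec(i, j - 1, "Y") - ge,
                  rec(i, j - 1, "X") - go - ge)
    }
    best
  }
  max(rec(length(va), length(vb), "M"), rec(length(va), length(vb), "X"),
      rec(length(va), length(vb), "Y"))
}

rand_protein <- function(n, first_m = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  body <- paste(sample(aa, n - first_m, replace = TRUE), collapse = "")
  if (first_m) paste0("M", body) else body
}

# --- tiny in-memory bundles ----------------------------------------------

# build a tr_bundle directly from a compact spec: list of rows
# (species, gene, upstream, protein)
toy_bundle <- function(rows, reference_species) {
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(species = r$species, gene_name = r$gene,
               gene_id = paste0("G_", r$gene),
               transcript_id = sprintf("tx%02d", i),
               upstream_seq = r$upstream, protein_seq = r$protein,
               stringsAsFactors = FALSE)
  }))
  tr_bundle(df, reference_species)
}
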