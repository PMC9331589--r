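.tistr_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 scoring matrix (including `X`), fetched from
#' Biostrings and cached.
#'
#' @return Numeric matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.tistr_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tistr_cache$blosum62 <- e$BLOSUM62
  }
  .tistr_cache$blosum62
}

#' Global protein alignment with affine gaps
#'
#' Needleman–Wunsch global alignment under the Gotoh three-state
#' recursion.  A gap of length `L` costs `gap_open + L * gap_extend`
#' (opening charged once, extension for every gapped column).  Percent
#' identity is the fraction of alignment columns with identical residues;
#' percent similarity the fraction with a positive substitution score
#' (the EMBOSS-needle notion).  Residues absent from the matrix are
#' treated as `X`.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param substitution_matrix Scoring matrix; default [blosum62()].
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults
#'   10 and 0.5).
#' @return Class `alignment_result`: list with `score`,
#'   `percent_identity`, `percent_similarity`, `alignment_length`, and
#'   `alignment` (the two gapped strings).
#' @examples
#' global_align("MKWVTF", "MKWVTF")$percent_similarity  # 100
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  mat <- if (is.null(substitution_matrix)) blosum62() else substitution_matrix
  va <- strsplit(toupper(seq_a), "")[[1]]
  vb <- strsplit(toupper(seq_b), "")[[1]]
  va[!va %in% rownames(mat)] <- "X"
  vb[!vb %in% colnames(mat)] <- "X"
  n <- length(va); m <- length(vb)
  go <- gap_open; ge <- gap_extend
  NEG <- -Inf

  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  pM <- pX <- pY <- matrix(0L, n + 1L, m + 1L)  # predecessor state 1=M 2=Ix 3=Iy
  M[1, 1] <- 0
  if (n >= 1) Ix[2:(n + 1), 1] <- -(go + (1:n) * ge)
  if (m >= 1) Iy[1, 2:(m + 1)] <- -(go + (1:m) * ge)
  pX[2:(n + 1), 1] <- 2L; pX[2, 1] <- 1L
  pY[1, 2:(m + 1)] <- 3L; pY[1, 2] <- 1L

  smat <- mat[va, vb, drop = FALSE]
  for (i in 1:n) {
    for (j in 1:m) {
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      s <- which.max(cand)
      M[i + 1, j + 1] <- cand[s] + smat[i, j]
      pM[i + 1, j + 1] <- s
      cand <- c(M[i, j + 1] - go - ge, Ix[i, j + 1] - ge,
                Iy[i, j + 1] - go - ge)
      s <- which.max(cand)
      Ix[i + 1, j + 1] <- cand[s]; pX[i + 1, j + 1] <- s
      cand <- c(M[i + 1, j] - go - ge, Ix[i + 1, j] - go - ge,
                Iy[i + 1, j] - ge)
      s <- which.max(cand)
      Iy[i + 1, j + 1] <- cand[s]; pY[i + 1, j + 1] <- if (s == 3L) 3L else s
    }
  }
  finals <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]

  # traceback
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ai <- c(va[i], ai); bi <- c(vb[j], bi)
      state <- pM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ai <- c(va[i], ai); bi <- c("-", bi)
      state <- pX[i + 1, j + 1]; i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(vb[j], bi)
      state <- pY[i + 1, j + 1]; j <- j - 1L
    }
  }
  alen <- length(ai)
  both <- ai != "-" & bi != "-"
  ident <- sum(ai[both] == bi[both])
  simil <- sum(mat[cbind(match(ai[both], rownames(mat)),
                         match(bi[both], colnames(mat)))] > 0)
  structure(list(score = score,
                 percent_identity = 100 * ident / alen,
                 percent_similarity = 100 * simil / alen,
                 alignment_length = alen,
                 alignment = c(a = paste(ai, collapse = ""),
                               b = paste(bi, collapse = ""))),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, length %d\n", x$score,
              x$alignment_length))
  cat(sprintf("  identity %.1f%%, similarity %.1f%%\n",
              x$percent_identity, x$percent_similarity))
  cat("  ", x$alignment[["a"]], "\n  ", x$alignment[["b"]], "\n", sep = "")
  invisible(x)
}

#' Rank-based comparison of two similarity distributions
#'
#' Two-sided Mann–Whitney U test of the per-pair similarity values from
#' the specific-TR group against the non-specific group: exact
#' enumeration when both groups have at most 20 values and no ties,
#' normal approximation with tie correction otherwise.  A fully tied
#' comparison returns p = 1.
#'
#' @param similarities_specific,similarities_nonspecific Non-empty
#'   numeric vectors.
#' @return List: `statistic` (U for the specific group), `p_value`,
#'   `median_specific`, `median_nonspecific`, `direction`.
#' @export
compare_groups <- function(similarities_specific, similarities_nonspecific) {
  x <- as.numeric(similarities_specific)
  y <- as.numeric(similarities_nonspecific)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (is.na(p) || is.nan(p)) p <- 1  # zero-variance (fully tied) case
  mx <- stats::median(x); my <- stats::median(y)
  list(statistic = unname(ht$statistic), p_value = p,
       median_specific = mx, median_nonspecific = my,
       direction = if (mx < my) "specific group lower"
                   else if (mx > my) "specific group higher" else "equal medians")
}

# all (reference transcript, partner transcript) pairs for one flag group,
# carrying full protein sequences
.protein_pairs <- function(groups, flags, ref_group) {
  r <- groups$records
  f <- flags[match(r$transcript_id, flags$transcript_id), , drop = FALSE]
  sel_a <- f$is_reference &
    (if (ref_group == "specific") f$has_ref_specific_tr
     else f$has_any_tr & !f$has_ref_specific_tr)
  sel_b <- !f$is_reference & f$has_any_tr
  ta <- data.frame(gene_key = r$gene_key[sel_a],
                   ref_transcript_id = r$transcript_id[sel_a],
                   protein_a = r$protein_seq[sel_a], stringsAsFactors = FALSE)
  tb <- data.frame(gene_key = r$gene_key[sel_b],
                   other_transcript_id = r$transcript_id[sel_b],
                   other_species = r$species[sel_b],
                   protein_b = r$protein_seq[sel_b], stringsAsFactors = FALSE)
  merge(ta, tb, by = "gene_key", sort = FALSE)
}

#' Full-protein divergence check between TR groups
#'
#' Complementary analysis: globally aligns each flagged reference protein
#' against the proteins of all TR-carrying partners in its gene group,
#' then compares the percent-similarity distributions of the specific-TR
#' and non-specific-TR groups with [compare_groups()].
#'
#' @param groups A `gene_groups` object.
#' @param flags Output of [flag_transcripts()].
#' @param ... Passed to [global_align()] (gap penalties, matrix).
#' @return List: `pairs` (per-pair data.frame with `group`,
#'   `percent_similarity`, `percent_identity`, `score`), `comparison`
#'   (the [compare_groups()] result), `per_gene_best` (best partner
#'   similarity per gene and group).
#' @export
protein_divergence_check <- function(groups, flags, ...) {
  out <- lapply(c("specific", "nonspecific"), function(grp) {
    pp <- .protein_pairs(groups, flags, grp)
    if (nrow(pp) == 0L) return(NULL)
    al <- Map(function(a, b) global_align(a, b, ...), pp$protein_a, pp$protein_b)
    pp$percent_similarity <- vapply(al, `[[`, numeric(1), "percent_similarity")
    pp$percent_identity <- vapply(al, `[[`, numeric(1), "percent_identity")
    pp$score <- vapply(al, `[[`, numeric(1), "score")
    pp$group <- grp
    pp[c("group", "gene_key", "ref_transcript_id", "other_transcript_id",
         "other_species", "percent_similarity", "percent_identity", "score")]
  })
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs) || !all(c("specific", "nonspecific") %in% pairs$group))
    stop("both TR groups must yield at least one alignable pair")
  comp <- compare_groups(
    pairs$percent_similarity[pairs$group == "specific"],
    pairs$percent_similarity[pairs$group == "nonspecific"])
  best <- do.call(rbind, lapply(split(pairs, pairs[c("gene_key", "group")],
                                      drop = TRUE), function(d)
    d[which.max(d$percent_similarity), , drop = FALSE]))
  rownames(best) <- NULL
  list(pairs = pairs, comparison = comp, per_gene_best = best)
}
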