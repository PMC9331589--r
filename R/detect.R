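#' Tandem-repeat qualification rule
#'
#' A run of `n_repeats` adjacent copies of a core qualifies as a tandem
#' repeat when: mononucleotide cores repeat at least 6 times; 2–9 bp cores
#' at least 3 times; longer cores at least twice.
#'
#' @param core_length Integer vector of core lengths (>= 1).
#' @param n_repeats Integer vector of repeat counts (>= 1).
#' @return Logical vector.
#' @examples
#' tr_qualifies(1, 6)   # TRUE
#' tr_qualifies(4, 2)   # FALSE
#' @export
tr_qualifies <- function(core_length, n_repeats) {
  core_length <- as.integer(core_length)
  n_repeats <- as.integer(n_repeats)
  if (any(is.na(core_length)) || any(core_length < 1L))
    stop("core_length must be >= 1")
  if (any(is.na(n_repeats)) || any(n_repeats < 1L))
    stop("n_repeats must be >= 1")
  (core_length == 1L & n_repeats >= 6L) |
    (core_length >= 2L & core_length <= 9L & n_repeats >= 3L) |
    (core_length >= 10L & n_repeats >= 2L)
}

#' Core-length category
#'
#' Bands a tandem-repeat core length into four categories:
#' 1 = 1–6 bp, 2 = 7–9 bp, 3 = 10–15 bp, 4 = 16 bp and longer.
#'
#' @param core_length Integer vector in `[1, 60]`.
#' @return Integer vector of categories in `{1, 2, 3, 4}`.
#' @examples
#' tr_category(c(6, 7, 10, 15, 16))
#' @export
tr_category <- function(core_length) {
  core_length <- as.integer(core_length)
  if (any(is.na(core_length)) || any(core_length < 1L) || any(core_length > 60L))
    stop("core_length must be in [1, 60]")
  ifelse(core_length <= 6L, 1L,
         ifelse(core_length <= 9L, 2L,
                ifelse(core_length <= 15L, 3L, 4L)))
}

#' Detect tandem repeats in upstream sequences
#'
#' Finds every maximal run of a primitive core whose repeat count passes
#' [tr_qualifies()].  A run is maximal when it cannot be extended by one
#' full core copy on either side; a core is primitive when it is not a
#' whole-number repetition of a shorter unit.  The same core string at
#' different phases gives distinct hits (e.g. `"CTCTCTC"` carries both
#' `(CT)3` and `(TC)3`).  `N` never matches anything, so runs cannot
#' contain `N`; trailing partial core copies are not counted.  Coordinates
#' are 0-based half-open on the given string, whose last base is assumed to
#' sit immediately 5' of the start codon.
#'
#' @param sequences Character vector of DNA sequences over `A/C/G/T/N`
#'   (lower case accepted), or a [Biostrings::DNAStringSet].
#' @param transcript_ids Identifiers, one per sequence; defaults to
#'   `names(sequences)`.
#' @param max_core Largest core length scanned (default 60).
#' @return A data.frame with columns `transcript_id`, `core`,
#'   `core_length`, `n_repeats`, `start`, `end`, `category`, sorted by
#'   `(start, core_length)` within each transcript.
#' @examples
#' find_tandem_repeats("GGTTTTTTGG", "t1")       # (T)6 at 2
#' find_tandem_repeats("ACTCTCTGA", "t1")        # (CT)3 at 1
#' @export
find_tandem_repeats <- function(sequences, transcript_ids = NULL, max_core = 60L) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences)) stop("sequences must be a character vector")
  if (is.null(transcript_ids)) transcript_ids <- names(sequences)
  if (is.null(transcript_ids)) transcript_ids <- paste0("seq", seq_along(sequences))
  if (length(transcript_ids) != length(sequences))
    stop("transcript_ids must match sequences in length")
  max_core <- as.integer(max_core)
  if (is.na(max_core) || max_core < 1L) stop("max_core must be >= 1")

  sequences <- toupper(sequences)
  h <- .tr_scan_batch(sequences, max_core)
  ord <- order(h$seq_index, h$start, h$core_length)
  i <- h$seq_index[ord]
  start <- h$start[ord]
  L <- h$core_length[ord]
  n <- h$n_repeats[ord]
  res <- data.frame(
    transcript_id = transcript_ids[i],
    core = substring(sequences[i], start + 1L, start + L),
    core_length = L,
    n_repeats = n,
    start = start,
    end = start + L * n,
    category = if (length(L)) tr_category(L) else integer(0),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Detect tandem repeats across a dataset bundle
#'
#' Convenience wrapper running [find_tandem_repeats()] on every upstream
#' sequence of a bundle.
#'
#' @param bundle A `tr_bundle` from [read_bundle()] or [simulate_bundle()].
#' @param max_core Largest core length scanned.
#' @return Hit data.frame as in [find_tandem_repeats()].
#' @export
detect_bundle <- function(bundle, max_core = 60L) {
  stopifnot(inherits(bundle, "tr_bundle"))
  find_tandem_repeats(bundle$records$upstream_seq,
                      bundle$records$transcript_id, max_core = max_core)
}
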