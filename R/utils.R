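# Internal helpers shared across modules.

#' Convert a Phred+33 encoded quality string to integer scores
#' @param q a single character string
#' @return integer vector of Phred scores
#' @keywords internal
#' @noRd
phred_ints <- function(q) {
  if (is.na(q) || !nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

#' @noRd
phred_chars <- function(ints) {
  if (length(ints) == 0L) return("")
  intToUtf8(as.integer(ints) + 33L)
}

# Count occurrences of a fixed single character in each element of a
# character vector without splitting (vectorised over the strings).
#' @noRd
count_char <- function(s, ch) {
  nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))
}

# Per-row counts of A, C, G, T for a vector of call strings.
#' @noRd
base_count_matrix <- function(calls) {
  m <- cbind(
    A = count_char(calls, "A"),
    C = count_char(calls, "C"),
    G = count_char(calls, "G"),
    T = count_char(calls, "T")
  )
  storage.mode(m) <- "integer"
  m
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific sub-seed from one top-level seed so that every
# simulator stage draws from an independent, reproducible stream.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

# Union of 0-based half-open intervals given as a two-column matrix/df.
# Returns a data.frame(start, end) sorted, non-overlapping.
#' @noRd
interval_union <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  k <- 1L
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[k]) {
      if (end[i] > out_e[k]) out_e[k] <- end[i]
    } else {
      k <- k + 1L
      out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Membership of 0-based positions in a sorted non-overlapping interval set.
#' @noRd
in_intervals <- function(pos0, ivl) {
  if (nrow(ivl) == 0L || length(pos0) == 0L) return(rep(FALSE, length(pos0)))
  idx <- findInterval(pos0, ivl$start)
  idx > 0L & pos0 < ivl$end[pmax(idx, 1L)]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data.frames; NULL when the list is empty.
#' @noRd
rbind_all <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
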