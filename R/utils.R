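# Internal constants and small helpers shared across modules.

# Canonical set labels, in reporting order. "val" may be empty (40/-/40 splits).
.SETS <- c("train", "val", "test")

# Sentinel endpoints for surgery start/end transitions. Reserved: a phase
# vocabulary may not use these labels.
.START_SENTINEL <- "START"
.END_SENTINEL <- "END"

`%||%` <- function(a, b) if (is.null(a)) b else a

is_sentinel <- function(x) x %in% c(.START_SENTINEL, .END_SENTINEL)

#' Canonical key for a phase transition
#'
#' @param source,target phase labels or the `START`/`END` sentinels.
#' @return character key, e.g. `"P1 -> P2"`.
#' @export
transition_key <- function(source, target) paste(source, target, sep = " -> ")

# Split a transition key back into source/target.
parse_transition_key <- function(key) {
  parts <- strsplit(key, " -> ", fixed = TRUE)
  list(source = vapply(parts, `[`, "", 1L), target = vapply(parts, `[`, "", 2L))
}

# Deterministic "smooth" apportionment of n items over named fractions:
# item i goes to the set with the largest deficit frac*i - assigned.
apportion_sets <- function(n, frac) {
  frac <- frac / sum(frac)
  assigned <- setNames(numeric(length(frac)), names(frac))
  out <- character(n)
  for (i in seq_len(n)) {
    deficit <- frac * i - assigned
    pick <- names(frac)[which.max(deficit)]
    assigned[pick] <- assigned[pick] + 1
    out[i] <- pick
  }
  out
}
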