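# Instrument-level attributes: individual occurrence, exact-set co-occurrence
# combinations, singletons and idle frames.
#
# Under exact-set semantics every instrument-annotated frame belongs to
# exactly one of three disjoint families — idle (no instrument), singleton
# (one instrument), or a combination (its full visible set, |S| >= 2) — so
# the three families partition the instrument-annotated frames of a set.
# A "subset" semantics switch is provided in which a combination S counts
# every frame whose visible set is a superset of S.

#' Canonical key for an instrument combination
#'
#' Combinations are keyed by the "+"-joined labels sorted in configuration
#' (index) order, so keys are deterministic and order-independent.
#'
#' @param instruments character vector of instrument labels.
#' @param config optional [dataset_config()]; when given, sorting follows the
#'   configured instrument order instead of lexicographic order.
#' @export
combo_key <- function(instruments, config = NULL) {
  instruments <- if (!is.null(config)) {
    config$instruments[sort(match(instruments, config$instruments))]
  } else {
    sort(instruments)
  }
  paste(instruments, collapse = "+")
}

#' Classify a single frame's instrument bit-vector
#'
#' @param bits 0/1 vector of length I (names taken as instrument labels when
#'   present).
#' @param instruments instrument labels, in the same order as `bits`.
#' @return list with `kind` (`"idle"`, `"singleton"` or `"combination"`),
#'   `instruments` (the visible set) and `key` (the canonical combination
#'   key; `""` for idle).
#' @export
classify_frame <- function(bits, instruments = NULL) {
  instruments <- instruments %||% names(bits) %||%
    paste0("I", seq_along(bits))
  vis <- instruments[bits == 1L]
  kind <- if (length(vis) == 0L) "idle"
          else if (length(vis) == 1L) "singleton"
          else "combination"
  list(kind = kind, instruments = vis, key = paste(vis, collapse = "+"))
}

# Exact visible-set key per row of a 0/1 matrix; "" = idle. Columns must be
# in configuration order so keys are canonical.
frame_keys <- function(mat) {
  labs <- colnames(mat)
  apply(mat == 1L, 1L, function(b) paste(labs[b], collapse = "+"))
}

# Gather per-frame combo keys and set labels over all instrument-annotated
# surgeries.
.gather_keys <- function(surgeries, split) {
  lk <- .assert_assigned(surgeries, split)
  with_i <- Filter(function(s) !is.null(s$instruments), surgeries)
  if (!length(with_i)) stop("no surgery has instrument annotations")
  keys <- unlist(lapply(with_i, function(s) frame_keys(s$instruments)),
                 use.names = FALSE)
  sets <- rep(unname(lk[vapply(with_i, `[[`, "", "surgery_id")]),
              vapply(with_i, `[[`, 0L, "duration"))
  list(keys = keys, sets = factor(sets, levels = .SETS))
}

#' Aggregate individual instrument occurrence over a split
#'
#' Individual occurrence counts every frame in which the instrument is
#' visible, regardless of co-visible instruments. Idle frames (no instrument
#' visible) are tallied separately, and only where an instrument vector
#' exists.
#'
#' @inheritParams aggregate_phase_counts
#' @return object of class `instrument_counts`: list with `instruments`
#'   (data frame `instrument`, `set`, `frames`), `idle` (data frame `set`,
#'   `frames`) and `annotated` (data frame `set`, `frames`: total
#'   instrument-annotated frames per set).
#' @export
aggregate_instrument_counts <- function(surgeries, split, config) {
  lk <- .assert_assigned(surgeries, split)
  with_i <- Filter(function(s) !is.null(s$instruments), surgeries)
  if (!length(with_i)) stop("no surgery has instrument annotations")
  I <- length(config$instruments)
  counts <- matrix(0L, nrow = I, ncol = length(.SETS),
                   dimnames = list(config$instruments, .SETS))
  idle <- stats::setNames(integer(length(.SETS)), .SETS)
  annotated <- stats::setNames(integer(length(.SETS)), .SETS)
  for (s in with_i) {
    set <- unname(lk[s$surgery_id])
    counts[, set] <- counts[, set] + colSums(s$instruments)
    idle[set] <- idle[set] + sum(rowSums(s$instruments) == 0L)
    annotated[set] <- annotated[set] + nrow(s$instruments)
  }
  inst_df <- as.data.frame.table(counts, responseName = "frames",
                                 stringsAsFactors = FALSE)
  colnames(inst_df) <- c("instrument", "set", "frames")
  inst_df$frames <- as.integer(inst_df$frames)
  structure(list(instruments = inst_df,
                 idle = data.frame(set = .SETS, frames = as.integer(idle),
                                   stringsAsFactors = FALSE),
                 annotated = data.frame(set = .SETS,
                                        frames = as.integer(annotated),
                                        stringsAsFactors = FALSE)),
            class = "instrument_counts")
}

#' Aggregate instrument co-occurrence combinations over a split
#'
#' Under the default exact-set semantics, a frame showing instruments
#' \{A,B,C\} counts toward the combination \{A,B,C\} only — combinations form
#' disjoint nodes as in a Radial Sets display. Under `semantics = "subset"`,
#' the frame additionally counts toward every sub-combination of size >= 2
#' (\{A,B\}, \{A,C\}, \{B,C\}), which is the superset-inclusive reading.
#' Combinations never observed anywhere are absent from the result.
#'
#' @inheritParams aggregate_phase_counts
#' @param semantics `"exact"` (default) or `"subset"`.
#' @return object of class `combination_counts`: list with `combinations`
#'   (data frame `combination`, `set`, `frames`), `singletons` (data frame
#'   `instrument`, `set`, `frames`), `idle` (data frame `set`, `frames`) and
#'   `semantics`.
#' @export
aggregate_combination_counts <- function(surgeries, split, config,
                                         semantics = c("exact", "subset")) {
  semantics <- match.arg(semantics)
  g <- .gather_keys(surgeries, split)
  tab <- table(key = g$keys, set = g$sets)
  keys <- rownames(tab)
  sizes <- vapply(strsplit(keys, "+", fixed = TRUE), length, 0L)

  idle_row <- if (any(sizes == 0L)) as.integer(tab[sizes == 0L, ]) else
    integer(length(.SETS))
  idle_df <- data.frame(set = .SETS, frames = idle_row, stringsAsFactors = FALSE)

  single <- matrix(0L, nrow = length(config$instruments), ncol = length(.SETS),
                   dimnames = list(config$instruments, .SETS))
  if (any(sizes == 1L)) {
    sk <- keys[sizes == 1L]
    single[sk, ] <- tab[sizes == 1L, , drop = FALSE]
  }
  single_df <- as.data.frame.table(single, responseName = "frames",
                                   stringsAsFactors = FALSE)
  colnames(single_df) <- c("instrument", "set", "frames")
  single_df$frames <- as.integer(single_df$frames)

  combos <- list()
  if (any(sizes >= 2L)) {
    exact <- tab[sizes >= 2L, , drop = FALSE]
    if (semantics == "exact") {
      for (k in rownames(exact)) combos[[k]] <- as.integer(exact[k, ])
    } else {
      for (k in rownames(exact)) {
        members <- strsplit(k, "+", fixed = TRUE)[[1L]]
        for (m in 2:length(members)) {
          subs <- utils::combn(members, m, simplify = FALSE)
          for (sub in subs) {
            sk <- paste(sub, collapse = "+")
            combos[[sk]] <- (combos[[sk]] %||% integer(length(.SETS))) +
              as.integer(exact[k, ])
          }
        }
      }
    }
  }
  if (length(combos)) {
    ck <- sort(names(combos))
    combo_df <- data.frame(
      combination = rep(ck, each = length(.SETS)),
      set = rep(.SETS, times = length(ck)),
      frames = as.integer(unlist(combos[ck], use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    combo_df <- data.frame(combination = character(), set = character(),
                           frames = integer(), stringsAsFactors = FALSE)
  }
  structure(list(combinations = combo_df, singletons = single_df,
                 idle = idle_df, semantics = semantics),
            class = "combination_counts")
}

#' Share of an instrument's frames spent in a combination
#'
#' For a combination S and each involved instrument i, reports
#' `count(S) / frame_count(i)` — the proportion of the instrument's frames in
#' which the whole combination is visible. Shares are in `[0, 1]` under
#' exact-set semantics.
#'
#' @param combination character vector of instrument labels, or a "+"-joined
#'   key.
#' @param inst_counts an [aggregate_instrument_counts()] result.
#' @param combo_counts an [aggregate_combination_counts()] result.
#' @param set optional set label to restrict to; default sums over all sets.
#' @return named numeric vector of per-instrument shares.
#' @export
cooccurrence_share <- function(combination, inst_counts, combo_counts,
                               set = NULL) {
  key <- if (length(combination) > 1L) paste(combination, collapse = "+")
         else combination
  members <- strsplit(key, "+", fixed = TRUE)[[1L]]
  cdf <- combo_counts$combinations
  rows <- cdf[cdf$combination == key, , drop = FALSE]
  if (!nrow(rows)) stop("combination not observed: ", key)
  if (!is.null(set)) rows <- rows[rows$set == set, , drop = FALSE]
  c_s <- sum(rows$frames)
  idf <- inst_counts$instruments
  if (!is.null(set)) idf <- idf[idf$set == set, , drop = FALSE]
  shares <- vapply(members, function(i) {
    f_i <- sum(idf$frames[idf$instrument == i])
    if (f_i == 0L) {
      stop("internal inconsistency: instrument ", i,
           " has zero frames but is involved in an observed combination")
    }
    c_s / f_i
  }, 0)
  shares
}
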