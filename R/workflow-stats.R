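# Phase-level attributes: phase occurrence, phase transitions with START/END
# sentinels and forward/backward direction, and surgery durations.
#
# Conventions: phase occurrence is counted in frames; transitions are counted
# in occurrences (one per boundary between consecutive distinct runs). The
# conceptual phase order comes from the configuration, so a transition is
# "forward" iff its target appears later in that order than its source.

#' Run-length encode a phase label sequence
#'
#' @param x character vector of per-frame labels, or a [surgery()].
#' @return data frame with columns `phase` and `length`; concatenating the
#'   runs reproduces the input, and adjacent runs always have distinct phases.
#' @export
run_length_encode <- function(x) {
  if (inherits(x, "surgery")) x <- x$phases
  if (is.null(x) || length(x) == 0L) stop("empty phase sequence")
  r <- rle(as.character(x))
  data.frame(phase = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' Extract phase transition occurrences from one surgery
#'
#' Produces one row per boundary between consecutive distinct phase runs,
#' plus the two sentinel transitions `START -> first run` and
#' `last run -> END`, i.e. `#runs + 1` rows in total. Self-transitions cannot
#' occur by construction. Direction is `forward` if the target phase comes
#' later in the conceptual order than the source, `backward` if earlier, and
#' `boundary` for sentinel transitions.
#'
#' @param x a [surgery()] with phase labels, or a character label vector.
#' @param config a [dataset_config()] supplying the conceptual phase order.
#' @return data frame with columns `source`, `target`, `direction`.
#' @export
extract_transitions <- function(x, config) {
  runs <- run_length_encode(x)$phase
  unknown <- setdiff(runs, config$phases)
  if (length(unknown)) {
    stop("phase label(s) outside the configured order: ",
         paste(unknown, collapse = ", "))
  }
  src <- c(.START_SENTINEL, runs)
  tgt <- c(runs, .END_SENTINEL)
  o_s <- match(src, config$phases)
  o_t <- match(tgt, config$phases)
  direction <- ifelse(is.na(o_s) | is.na(o_t), "boundary",
                      ifelse(o_t > o_s, "forward", "backward"))
  data.frame(source = src, target = tgt, direction = direction,
             stringsAsFactors = FALSE)
}

# Validate that every surgery id is assigned in the split; returns the lookup.
.assert_assigned <- function(surgeries, split) {
  lk <- split_lookup(split)
  ids <- vapply(surgeries, function(s) s$surgery_id, "")
  missing <- setdiff(ids, names(lk))
  if (length(missing)) {
    stop("surgery id(s) not assigned in the split: ", paste(missing, collapse = ", "))
  }
  lk
}

#' Aggregate per-phase frame counts over a split
#'
#' For each phase and set, sums the frames labelled with that phase over the
#' surgeries of the set; also counts, per phase, the number of surgeries in
#' which the phase occurs at all (the number shown at the centre of a phase
#' node in the phase view).
#'
#' @param surgeries list of [surgery()] objects.
#' @param split a [split_assignment()] covering all surgeries.
#' @param config a [dataset_config()].
#' @return object of class `phase_counts`: list with `frames` (data frame
#'   `phase`, `set`, `frames`, complete over the phase vocabulary and all
#'   three sets) and `surgeries` (data frame `phase`, `n_surgeries`).
#' @export
aggregate_phase_counts <- function(surgeries, split, config) {
  lk <- .assert_assigned(surgeries, split)
  with_p <- Filter(function(s) !is.null(s$phases), surgeries)
  phase_vec <- unlist(lapply(with_p, `[[`, "phases"), use.names = FALSE)
  set_vec <- rep(unname(lk[vapply(with_p, `[[`, "", "surgery_id")]),
                 vapply(with_p, `[[`, 0L, "duration"))
  tab <- table(phase = factor(phase_vec, levels = config$phases),
               set = factor(set_vec, levels = .SETS))
  frames <- as.data.frame(tab, responseName = "frames", stringsAsFactors = FALSE)
  frames$frames <- as.integer(frames$frames)
  n_surg <- vapply(config$phases, function(p) {
    sum(vapply(with_p, function(s) p %in% s$phases, logical(1L)))
  }, 0L)
  structure(list(frames = frames,
                 surgeries = data.frame(phase = config$phases,
                                        n_surgeries = as.integer(n_surg),
                                        stringsAsFactors = FALSE)),
            class = "phase_counts")
}

#' Aggregate phase transition occurrence counts over a split
#'
#' @inheritParams aggregate_phase_counts
#' @return object of class `transition_counts`: data frame with columns
#'   `source`, `target`, `direction`, `set`, `count`, containing every
#'   transition observed anywhere, completed with zero rows for the sets in
#'   which it does not occur.
#' @export
aggregate_transition_counts <- function(surgeries, split, config) {
  lk <- .assert_assigned(surgeries, split)
  with_p <- Filter(function(s) !is.null(s$phases), surgeries)
  if (!length(with_p)) stop("no surgery has phase annotations")
  rows <- lapply(with_p, function(s) {
    tr <- extract_transitions(s, config)
    tr$set <- unname(lk[s$surgery_id])
    tr
  })
  all_tr <- do.call(rbind, rows)
  all_tr$key <- transition_key(all_tr$source, all_tr$target)
  tab <- table(key = all_tr$key, set = factor(all_tr$set, levels = .SETS))
  counts <- as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
  counts$count <- as.integer(counts$count)
  meta <- unique(all_tr[c("key", "source", "target", "direction")])
  out <- merge(meta, counts, by = "key", sort = FALSE)
  out <- out[order(out$key, match(out$set, .SETS)),
             c("source", "target", "direction", "set", "count")]
  rownames(out) <- NULL
  class(out) <- c("transition_counts", "data.frame")
  out
}

#' Per-phase, per-instrument frame counts over a split
#'
#' Counts, for every (phase, instrument, set) triple, the frames in which the
#' phase is active and the instrument visible — the data behind the centred
#' per-phase instrument bar charts. Surgeries lacking either stream are
#' skipped; it is an error if no surgery carries both.
#'
#' @inheritParams aggregate_phase_counts
#' @return data frame `phase`, `instrument`, `set`, `frames`, complete over
#'   the full vocabulary grid.
#' @export
per_phase_instrument_counts <- function(surgeries, split, config) {
  lk <- .assert_assigned(surgeries, split)
  both <- Filter(function(s) !is.null(s$phases) && !is.null(s$instruments),
                 surgeries)
  if (!length(both)) stop("no surgery has both phase and instrument annotations")
  counts <- array(0L,
                  dim = c(length(config$phases), length(config$instruments),
                          length(.SETS)),
                  dimnames = list(phase = config$phases,
                                  instrument = config$instruments, set = .SETS))
  for (s in both) {
    set <- unname(lk[s$surgery_id])
    agg <- rowsum(s$instruments, group = s$phases)
    counts[rownames(agg), , set] <- counts[rownames(agg), , set] + agg
  }
  out <- as.data.frame.table(counts, responseName = "frames",
                             stringsAsFactors = FALSE)
  out$frames <- as.integer(out$frames)
  out
}

#' Per-surgery durations and per-set averages
#'
#' Duration is the total number of frames of a surgery at the common rate.
#' The per-set mean is the dashed average line of the supplementary view; it
#' is `NA` for an empty set.
#'
#' @inheritParams aggregate_phase_counts
#' @return list with `per_surgery` (data frame `surgery_id`, `set`, `frames`)
#'   and `per_set` (data frame `set`, `surgeries`, `frames`, `mean_frames`).
#' @export
surgery_durations <- function(surgeries, split) {
  lk <- .assert_assigned(surgeries, split)
  ids <- vapply(surgeries, `[[`, "", "surgery_id")
  per <- data.frame(surgery_id = ids, set = unname(lk[ids]),
                    frames = vapply(surgeries, `[[`, 0L, "duration"),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  setf <- factor(per$set, levels = .SETS)
  n <- as.integer(table(setf))
  tot <- as.integer(tapply(per$frames, setf, sum, default = 0L))
  per_set <- data.frame(set = .SETS, surgeries = n, frames = tot,
                        mean_frames = ifelse(n > 0L, tot / n, NA_real_),
                        stringsAsFactors = FALSE)
  list(per_surgery = per, per_set = per_set)
}
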