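# Split auditing: long-form attribute counts across the four audited
# families (phases, transitions, instruments, combinations), unrepresented-
# attribute detection, summary matrix, per-set totals, pure re-assignment
# with a diff report, and a greedy hill-climbing split improver.
#
# Absence is always judged against the non-empty sets only: a 40/-/40 split
# audits train vs test. Sentinel (START/END) transitions are audited but
# reported under their own kind, "sentinel_transition", so either convention
# for a summary table (with or without them) is recoverable.

.AUDIT_KINDS <- c("phase", "transition", "sentinel_transition",
                  "instrument", "combination")

#' Long-form attribute counts over a split
#'
#' Builds one table of per-set counts keyed by (kind, attribute) across all
#' families computable from the data: phase frame counts, transition
#' occurrence counts (sentinel transitions under their own kind), individual
#' instrument frame counts, and exact-set combination frame counts. Families
#' without data (e.g. instruments in a phase-only dataset) are simply absent.
#'
#' @inheritParams aggregate_phase_counts
#' @param semantics combination-counting semantics, see
#'   [aggregate_combination_counts()].
#' @return data frame with columns `kind`, `key`, `set`, `count`.
#' @export
attribute_counts <- function(surgeries, split, config,
                             semantics = c("exact", "subset")) {
  semantics <- match.arg(semantics)
  has_phases <- any(vapply(surgeries, function(s) !is.null(s$phases), logical(1L)))
  has_instr <- any(vapply(surgeries, function(s) !is.null(s$instruments), logical(1L)))
  out <- list()
  if (has_phases) {
    pc <- aggregate_phase_counts(surgeries, split, config)
    out$phase <- data.frame(kind = "phase", key = pc$frames$phase,
                            set = pc$frames$set, count = pc$frames$frames,
                            stringsAsFactors = FALSE)
    tc <- aggregate_transition_counts(surgeries, split, config)
    out$transition <- data.frame(
      kind = ifelse(tc$direction == "boundary", "sentinel_transition", "transition"),
      key = transition_key(tc$source, tc$target),
      set = tc$set, count = tc$count, stringsAsFactors = FALSE)
  }
  if (has_instr) {
    ic <- aggregate_instrument_counts(surgeries, split, config)
    out$instrument <- data.frame(kind = "instrument",
                                 key = ic$instruments$instrument,
                                 set = ic$instruments$set,
                                 count = ic$instruments$frames,
                                 stringsAsFactors = FALSE)
    cc <- aggregate_combination_counts(surgeries, split, config, semantics)
    if (nrow(cc$combinations)) {
      out$combination <- data.frame(kind = "combination",
                                    key = cc$combinations$combination,
                                    set = cc$combinations$set,
                                    count = cc$combinations$frames,
                                    stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find attributes unrepresented in at least one non-empty set
#'
#' An attribute is flagged iff it occurs somewhere in the dataset (global
#' count > 0) but has zero count in at least one of the split's non-empty
#' sets. Attributes with global count zero (e.g. a vocabulary phase never
#' used) are never flagged — vacuous absence is excluded.
#'
#' @param counts long-form counts from [attribute_counts()].
#' @param split the [split_assignment()] the counts were computed over.
#' @return data frame with columns `kind`, `key`, one count column per set,
#'   and `absent_in` (comma-separated non-empty sets with zero count).
#' @export
find_unrepresented <- function(counts, split) {
  present <- sets_present(split)
  id <- paste(counts$kind, counts$key, sep = "\r")
  mat <- tapply(counts$count, list(id = id, set = counts$set), sum)
  mat[is.na(mat)] <- 0
  mat <- mat[, intersect(.SETS, colnames(mat)), drop = FALSE]
  for (s in setdiff(.SETS, colnames(mat))) {
    mat <- cbind(mat, stats::setNames(data.frame(rep(0, nrow(mat))), s))
  }
  mat <- as.matrix(mat[, .SETS, drop = FALSE])
  total <- rowSums(mat)
  absent <- mat[, present, drop = FALSE] == 0
  flagged <- total > 0 & rowSums(absent) > 0
  ids <- rownames(mat)[flagged]
  parts <- strsplit(ids, "\r", fixed = TRUE)
  out <- data.frame(
    kind = vapply(parts, `[`, "", 1L),
    key = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  for (s in .SETS) out[[s]] <- as.integer(mat[flagged, s])
  out$absent_in <- vapply(seq_len(sum(flagged)), function(i) {
    paste(present[absent[flagged, , drop = FALSE][i, ]], collapse = ", ")
  }, "")
  out <- out[order(match(out$kind, .AUDIT_KINDS), out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Audit a dataset split
#'
#' Computes all attribute families over the split, flags unrepresented
#' attributes, builds the kind-by-set summary matrix and the per-set totals.
#'
#' @inheritParams attribute_counts
#' @return object of class `audit_report`: list with `name`, `semantics`,
#'   `sets_present`, `counts` (long form), `unrepresented` (flag table),
#'   `summary` (kind x set matrix of absence counts; `NA` for empty sets and
#'   kinds without data), and `totals` (per-set surgeries/frames/mean
#'   duration).
#' @export
audit_splits <- function(surgeries, split, config,
                         semantics = c("exact", "subset")) {
  semantics <- match.arg(semantics)
  counts <- attribute_counts(surgeries, split, config, semantics)
  flags <- find_unrepresented(counts, split)
  present <- sets_present(split)
  kinds_with_data <- unique(counts$kind)
  summary <- matrix(NA_integer_, nrow = length(.AUDIT_KINDS),
                    ncol = length(.SETS),
                    dimnames = list(kind = .AUDIT_KINDS,
                                    absent_in = .SETS))
  for (k in intersect(.AUDIT_KINDS, kinds_with_data)) {
    for (s in present) {
      fk <- flags[flags$kind == k, , drop = FALSE]
      hit <- vapply(strsplit(fk$absent_in, ", ", fixed = TRUE),
                    function(a) s %in% a, logical(1L))
      summary[k, s] <- sum(hit)
    }
  }
  structure(list(name = config$name, semantics = semantics,
                 sets_present = present, counts = counts,
                 unrepresented = flags, summary = summary,
                 totals = per_set_totals(surgeries, split)),
            class = "audit_report")
}

#' Summary matrix of unrepresented attributes
#'
#' @param report an [audit_splits()] result.
#' @return integer matrix, kinds x sets; cell (kind, S) is the number of
#'   attributes of that kind with zero count in set S. Columns are labelled
#'   by the set the attribute is absent from; `NA` marks empty sets and kinds
#'   for which the dataset carries no data.
#' @export
summarize_unrepresented <- function(report) {
  stopifnot(inherits(report, "audit_report"))
  report$summary
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %s (%s combination semantics)\n", x$name, x$semantics))
  cat("sets:", paste(x$sets_present, collapse = "/"), "\n")
  cat("unrepresented attributes per (kind, absent set):\n")
  print(x$summary)
  if (nrow(x$unrepresented)) {
    cat(sprintf("%d flagged attribute(s); first few:\n", nrow(x$unrepresented)))
    print(utils::head(x$unrepresented, 5L))
  } else {
    cat("no unrepresented attributes\n")
  }
  invisible(x)
}

#' Per-set totals
#'
#' @inheritParams aggregate_phase_counts
#' @return data frame `set`, `surgeries`, `frames`, `mean_frames`
#'   (`NA` for empty sets).
#' @export
per_set_totals <- function(surgeries, split) {
  surgery_durations(surgeries, split)$per_set
}

# Expand a flag table into "kind | key | set" strings, one per (attribute,
# absent set) pair. Used as the default greedy objective and in diffs.
flag_pairs <- function(report) {
  f <- report$unrepresented
  if (!nrow(f)) return(character())
  unlist(lapply(seq_len(nrow(f)), function(i) {
    paste(f$kind[i], f$key[i], strsplit(f$absent_in[i], ", ", fixed = TRUE)[[1L]],
          sep = " | ")
  }), use.names = FALSE)
}

# Normalize moves given as a data frame (surgery_id, to) or a named vector.
.normalize_moves <- function(moves) {
  if (is.data.frame(moves)) {
    stopifnot(all(c("surgery_id", "to") %in% colnames(moves)))
    data.frame(surgery_id = as.character(moves$surgery_id),
               to = as.character(moves$to), stringsAsFactors = FALSE)
  } else {
    data.frame(surgery_id = names(moves), to = unname(as.character(moves)),
               stringsAsFactors = FALSE)
  }
}

#' Re-assign surgeries between sets
#'
#' A pure function: the input split is not modified. Moving a surgery to the
#' set it is already in triggers a warning and is dropped as a no-op. When
#' `surgeries` and `config` are supplied, the diff additionally contains
#' before/after audit reports and the explicit lists of newly covered and
#' newly lost attributes (re-partitions can trade one flag for another).
#'
#' @param split a [split_assignment()].
#' @param moves data frame with columns `surgery_id`, `to`, or a named
#'   character vector (names = ids, values = target sets).
#' @param surgeries,config optional; enable the audit diff.
#' @param semantics combination semantics for the audit diff.
#' @return object of class `reassignment`: list with `split` (the new
#'   assignment) and `diff`.
#' @export
reassign <- function(split, moves, surgeries = NULL, config = NULL,
                     semantics = c("exact", "subset")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(split, "split_assignment"))
  moves <- .normalize_moves(moves)
  lk <- split_lookup(split)
  unknown <- setdiff(moves$surgery_id, names(lk))
  if (length(unknown)) stop("unknown surgery id(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(moves$to, .SETS)
  if (length(bad)) stop("invalid target set(s): ", paste(bad, collapse = ", "))
  noop <- lk[moves$surgery_id] == moves$to
  if (any(noop)) {
    warning("no-op move(s) ignored: ",
            paste(moves$surgery_id[noop], collapse = ", "))
    moves <- moves[!noop, , drop = FALSE]
  }
  new_lk <- lk
  new_lk[moves$surgery_id] <- moves$to
  ids <- sort(names(lk))  # canonical id order, so re-assignment is involutive
  new_split <- split_assignment(train = ids[new_lk[ids] == "train"],
                                val = ids[new_lk[ids] == "val"],
                                test = ids[new_lk[ids] == "test"])
  diff <- list(moves = moves,
               sizes_before = set_sizes(split),
               sizes_after = set_sizes(new_split))
  if (!is.null(surgeries) && !is.null(config)) {
    before <- audit_splits(surgeries, split, config, semantics)
    after <- audit_splits(surgeries, new_split, config, semantics)
    pb <- flag_pairs(before); pa <- flag_pairs(after)
    diff$unrepresented_before <- length(pb)
    diff$unrepresented_after <- length(pa)
    diff$newly_covered <- setdiff(pb, pa)
    diff$newly_lost <- setdiff(pa, pb)
    diff$before <- before
    diff$after <- after
  }
  structure(list(split = new_split, diff = diff), class = "reassignment")
}

#' @export
print.reassignment <- function(x, ...) {
  d <- x$diff
  cat(sprintf("<reassignment> %d move(s); sizes %s -> %s\n", nrow(d$moves),
              paste(d$sizes_before, collapse = "/"),
              paste(d$sizes_after, collapse = "/")))
  if (!is.null(d$unrepresented_before)) {
    cat(sprintf("unrepresented flags: %d -> %d (%d newly covered, %d newly lost)\n",
                d$unrepresented_before, d$unrepresented_after,
                length(d$newly_covered), length(d$newly_lost)))
  }
  invisible(x)
}

#' Greedily improve a split by swapping surgeries between sets
#'
#' First-improvement hill climbing over single swaps (or, when set sizes may
#' change, single moves as well). Candidates are enumerated in lexicographic
#' surgery-id order and a candidate is accepted only if the objective
#' strictly decreases, so objective ties keep the incumbent and the default
#' path is fully deterministic. The objective defaults to the number of
#' (attribute, absent set) flag pairs of the audit.
#'
#' @inheritParams attribute_counts
#' @param objective function(split) -> numeric to minimize; default counts
#'   unrepresented flag pairs.
#' @param keep_set_sizes if `TRUE` (default) only pairwise swaps are tried,
#'   so set cardinalities are preserved exactly.
#' @param max_iter maximum accepted improvement steps.
#' @param seed optional integer; when given, deterministically shuffles the
#'   candidate scan order each iteration (the default, seedless path scans
#'   lexicographically).
#' @return object of class `greedy_improvement`: list with `split`,
#'   `initial_objective`, `objective`, `trace` (one row per accepted step),
#'   and `converged` (`TRUE` if a local optimum was reached before
#'   `max_iter`).
#' @export
greedy_improve <- function(surgeries, split, config, objective = NULL,
                           keep_set_sizes = TRUE, max_iter = 100L,
                           seed = NULL, semantics = c("exact", "subset")) {
  semantics <- match.arg(semantics)
  obj <- objective %||% function(sp) {
    length(flag_pairs(audit_splits(surgeries, sp, config, semantics)))
  }
  current <- split
  cur_obj <- obj(current)
  init_obj <- cur_obj
  trace <- data.frame(iter = integer(), objective = numeric(),
                      move = character(), stringsAsFactors = FALSE)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (cur_obj == 0) { converged <- TRUE; break }
    lk <- split_lookup(current)
    ids <- sort(names(lk))
    cands <- list()
    if (!keep_set_sizes) {
      for (id in ids) for (s in setdiff(sets_present(current), lk[id])) {
        cands[[length(cands) + 1L]] <- list(kind = "move", a = id, to = s)
      }
    }
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && lk[ids[i]] != lk[ids[j]]) {
        cands[[length(cands) + 1L]] <- list(kind = "swap", a = ids[i], b = ids[j])
      }
    }
    if (!is.null(seed)) {
      # deterministic shuffle without touching the global RNG stream
      ord <- withr_seed_sample(length(cands), seed + it)
      cands <- cands[ord]
    }
    improved <- FALSE
    for (cand in cands) {
      mv <- if (cand$kind == "move") {
        stats::setNames(cand$to, cand$a)
      } else {
        stats::setNames(c(unname(lk[cand$b]), unname(lk[cand$a])),
                        c(cand$a, cand$b))
      }
      new_split <- suppressWarnings(reassign(current, mv))$split
      o <- obj(new_split)
      if (o < cur_obj) {
        current <- new_split
        cur_obj <- o
        trace <- rbind(trace, data.frame(
          iter = it, objective = o,
          move = if (cand$kind == "move") paste0(cand$a, "->", cand$to)
                 else paste0(cand$a, "<->", cand$b),
          stringsAsFactors = FALSE))
        improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }
  }
  structure(list(split = current, initial_objective = init_obj,
                 objective = cur_obj, trace = trace, converged = converged),
            class = "greedy_improvement")
}

# Sample a permutation of seq_len(n) from a local RNG state.
withr_seed_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' @export
print.greedy_improvement <- function(x, ...) {
  cat(sprintf("<greedy_improvement> objective %g -> %g in %d step(s)%s\n",
              x$initial_objective, x$objective, nrow(x$trace),
              if (x$converged) " (local optimum)" else " (max_iter reached)"))
  invisible(x)
}
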