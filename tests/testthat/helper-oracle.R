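# Independent naive frame-loop oracle for all aggregates. Deliberately dumb:
# explicit loops over frames and runs, environment-based tallies, no reuse of
# the package's vectorized/table-based code paths.

oracle_tally <- function() new.env(parent = emptyenv())

oracle_add <- function(env, key, n = 1L) {
  cur <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else 0L
  assign(key, cur + n, envir = env)
}

oracle_get <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else 0L
}

# Full recount of every aggregate over a list of surgeries and a split.
# Returns flat named lists keyed by "<...>|<set>" strings.
oracle_recount <- function(surgeries, split, config) {
  lk <- splitaudit::split_lookup(split)
  phase_frames <- oracle_tally()
  phase_surgeries <- oracle_tally()
  transitions <- oracle_tally()
  inst_frames <- oracle_tally()
  idle_frames <- oracle_tally()
  annotated <- oracle_tally()
  singles <- oracle_tally()
  combos <- oracle_tally()
  ppi <- oracle_tally()
  durations <- list()
  for (s in surgeries) {
    set <- unname(lk[s$surgery_id])
    durations[[s$surgery_id]] <- s$duration
    if (!is.null(s$phases)) {
      seen <- character()
      prev <- "START"
      for (t in seq_len(s$duration)) {
        ph <- s$phases[t]
        oracle_add(phase_frames, paste(ph, set, sep = "|"))
        if (!(ph %in% seen)) {
          seen <- c(seen, ph)
          oracle_add(phase_surgeries, ph)
        }
        if (ph != prev) {
          oracle_add(transitions, paste(prev, ph, set, sep = "|"))
          prev <- ph
        }
      }
      oracle_add(transitions, paste(prev, "END", set, sep = "|"))
    }
    if (!is.null(s$instruments)) {
      labs <- colnames(s$instruments)
      for (t in seq_len(nrow(s$instruments))) {
        oracle_add(annotated, set)
        vis <- character()
        for (j in seq_along(labs)) {
          if (s$instruments[t, j] == 1L) {
            vis <- c(vis, labs[j])
            oracle_add(inst_frames, paste(labs[j], set, sep = "|"))
            if (!is.null(s$phases)) {
              oracle_add(ppi, paste(s$phases[t], labs[j], set, sep = "|"))
            }
          }
        }
        if (length(vis) == 0L) {
          oracle_add(idle_frames, set)
        } else if (length(vis) == 1L) {
          oracle_add(singles, paste(vis, set, sep = "|"))
        } else {
          oracle_add(combos, paste(paste(vis, collapse = "+"), set, sep = "|"))
        }
      }
    }
  }
  list(phase_frames = phase_frames, phase_surgeries = phase_surgeries,
       transitions = transitions, inst_frames = inst_frames,
       idle_frames = idle_frames, annotated = annotated, singles = singles,
       combos = combos, ppi = ppi, durations = durations)
}

# Compare package aggregates against the oracle recount; returns a character
# vector of mismatch descriptions (empty = full agreement).
oracle_compare <- function(surgeries, split, config) {
  o <- oracle_recount(surgeries, split, config)
  bad <- character()
  chk <- function(cond, msg) if (!cond) bad <<- c(bad, msg)

  pc <- splitaudit::aggregate_phase_counts(surgeries, split, config)
  for (i in seq_len(nrow(pc$frames))) {
    r <- pc$frames[i, ]
    chk(r$frames == oracle_get(o$phase_frames, paste(r$phase, r$set, sep = "|")),
        sprintf("phase %s/%s", r$phase, r$set))
  }
  for (i in seq_len(nrow(pc$surgeries))) {
    r <- pc$surgeries[i, ]
    chk(r$n_surgeries == oracle_get(o$phase_surgeries, r$phase),
        sprintf("phase surgeries %s", r$phase))
  }

  tc <- splitaudit::aggregate_transition_counts(surgeries, split, config)
  for (i in seq_len(nrow(tc))) {
    r <- tc[i, ]
    chk(r$count == oracle_get(o$transitions,
                              paste(r$source, r$target, r$set, sep = "|")),
        sprintf("transition %s->%s/%s", r$source, r$target, r$set))
  }
  # total transitions must match too (no transition missing from the package)
  pkg_total <- sum(tc$count)
  orc_total <- sum(vapply(ls(o$transitions), function(k)
    oracle_get(o$transitions, k), 0L))
  chk(pkg_total == orc_total, "transition totals")

  ic <- splitaudit::aggregate_instrument_counts(surgeries, split, config)
  for (i in seq_len(nrow(ic$instruments))) {
    r <- ic$instruments[i, ]
    chk(r$frames == oracle_get(o$inst_frames, paste(r$instrument, r$set, sep = "|")),
        sprintf("instrument %s/%s", r$instrument, r$set))
  }
  for (i in seq_len(nrow(ic$idle))) {
    r <- ic$idle[i, ]
    chk(r$frames == oracle_get(o$idle_frames, r$set), sprintf("idle/%s", r$set))
  }

  cc <- splitaudit::aggregate_combination_counts(surgeries, split, config)
  for (i in seq_len(nrow(cc$combinations))) {
    r <- cc$combinations[i, ]
    chk(r$frames == oracle_get(o$combos, paste(r$combination, r$set, sep = "|")),
        sprintf("combo %s/%s", r$combination, r$set))
  }
  chk(sum(cc$combinations$frames) ==
        sum(vapply(ls(o$combos), function(k) oracle_get(o$combos, k), 0L)),
      "combo totals")
  for (i in seq_len(nrow(cc$singletons))) {
    r <- cc$singletons[i, ]
    chk(r$frames == oracle_get(o$singles, paste(r$instrument, r$set, sep = "|")),
        sprintf("singleton %s/%s", r$instrument, r$set))
  }

  pic <- splitaudit::per_phase_instrument_counts(surgeries, split, config)
  for (i in seq_len(nrow(pic))) {
    r <- pic[i, ]
    chk(r$frames == oracle_get(o$ppi, paste(r$phase, r$instrument, r$set, sep = "|")),
        sprintf("ppi %s/%s/%s", r$phase, r$instrument, r$set))
  }

  dur <- splitaudit::surgery_durations(surgeries, split)
  for (i in seq_len(nrow(dur$per_surgery))) {
    r <- dur$per_surgery[i, ]
    chk(r$frames == o$durations[[r$surgery_id]],
        sprintf("duration %s", r$surgery_id))
  }
  bad
}
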