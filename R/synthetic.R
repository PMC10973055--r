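# Synthetic surgical-workflow annotation generator.
#
# A surgery is a Markov chain over phases with geometric (memoryless) run
# lengths, which is the simplest model producing variable durations and phase
# re-occurrences. Instrument bit-vectors are drawn per frame conditioned on
# the active phase; an optional persistence parameter makes usage bursty by
# copying the previous frame's vector. Quirk patterns (skipped first phase,
# early end) are assigned to the lexicographically first floor(fraction * N)
# unquirked surgery ids so tests can name the affected surgeries.

#' Specification of a synthetic dataset generator
#'
#' Defaults describe a heavily imbalanced but plausible workflow: a mostly
#' forward chain with occasional backward and skip transitions, per-phase mean
#' run lengths spanning more than a 10x range (heavy-tailed durations), a
#' small chance of ending early, one or two signature instruments per phase,
#' and a quarter of surgeries skipping the first phase.
#'
#' @param n_phases,n_instruments,n_surgeries problem size.
#' @param phase_labels,instrument_labels label vocabularies.
#' @param trans row-stochastic matrix, `n_phases` rows and `n_phases + 1`
#'   columns; the last column is the probability of ending the surgery
#'   (END). Default: forward 0.7, skip-one 0.1, backward 0.15, tiny early
#'   END, renormalized; the final phase ends with probability 0.6.
#' @param init initial-phase distribution; default all mass on phase 1.
#' @param mean_run per-phase mean run length in frames (geometric, >= 1).
#'   Default recycles `c(4, 40, 12, 3, 8)` — a >10x spread.
#' @param inst_prob `n_phases` x `n_instruments` matrix of per-frame
#'   visibility probabilities. Default: one signature instrument at 0.8, a
#'   secondary at 0.4, base rate 0.05.
#' @param persistence probability of copying the previous frame's instrument
#'   vector instead of drawing fresh (bursty usage); default 0.
#' @param quirks list of `list(pattern =, fraction =)` entries; supported
#'   patterns: `"skip_first"` (surgery starts in phase 2) and `"early_end"`
#'   (surgery stops after its third run).
#' @param split_frac named fractions for the train/val/test apportionment.
#' @param phase_fps,instrument_fps frame rates used when writing fixtures.
#' @param max_frames hard cutoff per surgery; a chain that cannot reach END
#'   at all is rejected up front, one that merely runs long is truncated.
#' @param name dataset name.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_phases = 5L, n_instruments = 4L, n_surgeries = 12L,
                           phase_labels = sprintf("P%d", seq_len(n_phases)),
                           instrument_labels = LETTERS[seq_len(n_instruments)],
                           trans = NULL, init = NULL, mean_run = NULL,
                           inst_prob = NULL, persistence = 0,
                           quirks = list(list(pattern = "skip_first", fraction = 0.25)),
                           split_frac = c(train = 0.5, val = 0.25, test = 0.25),
                           phase_fps = 5L, instrument_fps = 1L,
                           max_frames = 2000L, name = "synthetic") {
  P <- as.integer(n_phases); I <- as.integer(n_instruments)
  N <- as.integer(n_surgeries)
  stopifnot(P >= 1L, I >= 0L, N >= 2L)
  if (is.null(trans)) trans <- default_transition_matrix(P)
  stopifnot(nrow(trans) == P, ncol(trans) == P + 1L, all(trans >= 0))
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-8)) trans <- trans / rs
  if (is.null(init)) init <- c(1, rep(0, P - 1L))
  stopifnot(length(init) == P, all(init >= 0), sum(init) > 0)
  init <- init / sum(init)
  if (is.null(mean_run)) mean_run <- rep_len(c(4, 40, 12, 3, 8), P)
  stopifnot(length(mean_run) == P, all(mean_run >= 1))
  if (is.null(inst_prob)) {
    inst_prob <- matrix(0.05, nrow = P, ncol = I)
    if (I > 0L) for (p in seq_len(P)) {
      inst_prob[p, ((p - 1L) %% I) + 1L] <- 0.8
      inst_prob[p, (p %% I) + 1L] <- 0.4
    }
  }
  stopifnot(nrow(inst_prob) == P, ncol(inst_prob) == I,
            all(inst_prob >= 0 & inst_prob <= 1),
            persistence >= 0, persistence <= 1)
  structure(list(n_phases = P, n_instruments = I, n_surgeries = N,
                 phase_labels = as.character(phase_labels),
                 instrument_labels = as.character(instrument_labels),
                 trans = trans, init = init, mean_run = mean_run,
                 inst_prob = inst_prob, persistence = persistence,
                 quirks = quirks, split_frac = split_frac,
                 phase_fps = as.integer(phase_fps),
                 instrument_fps = as.integer(instrument_fps),
                 max_frames = as.integer(max_frames),
                 name = name, planted = NULL),
            class = "generator_spec")
}

# Mostly-forward chain with backward and skip moves; END mass mostly on the
# final phase, with a tiny early-termination probability elsewhere.
default_transition_matrix <- function(P) {
  m <- matrix(0, nrow = P, ncol = P + 1L)
  for (p in seq_len(P)) {
    if (p < P) {
      m[p, p + 1L] <- 0.7
      if (p + 2L <= P) m[p, p + 2L] <- 0.1
      if (p > 1L) m[p, p - 1L] <- 0.15
      m[p, P + 1L] <- 0.02
    } else {
      m[p, P + 1L] <- 0.6
      if (p > 1L) m[p, p - 1L] <- 0.25
      if (p > 2L) m[p, p - 2L] <- 0.15
    }
  }
  m / rowSums(m)
}

#' A dense generator specification
#'
#' All phases are reachable from all phases, surgeries are long with many
#' short runs, every surgery starts in phase 1 and can only end from the last
#' phase, and every instrument is visible with probability `inst_prob` in
#' every frame. Under this spec, every internal transition, both sentinel
#' transitions, and every instrument combination occur in every set with high
#' probability — the regime needed for closed-loop audit-recovery tests,
#' where a single planted absence must be the only flag.
#'
#' @inheritParams generator_spec
#' @param end_prob probability of ending when in the final phase.
#' @param mean_run scalar mean run length.
#' @param inst_prob scalar per-frame visibility probability.
#' @export
dense_generator_spec <- function(n_phases = 4L, n_instruments = 3L,
                                 n_surgeries = 18L, end_prob = 0.08,
                                 mean_run = 2, inst_prob = 0.5,
                                 max_frames = 2000L, name = "synthetic-dense") {
  P <- as.integer(n_phases)
  trans <- matrix(0, nrow = P, ncol = P + 1L)
  for (p in seq_len(P)) {
    others <- setdiff(seq_len(P), p)
    if (p == P) {
      trans[p, P + 1L] <- end_prob
      trans[p, others] <- (1 - end_prob) / length(others)
    } else {
      trans[p, others] <- 1 / length(others)
    }
  }
  generator_spec(n_phases = P, n_instruments = n_instruments,
                 n_surgeries = n_surgeries, trans = trans,
                 init = c(1, rep(0, P - 1L)),
                 mean_run = rep(mean_run, P),
                 inst_prob = matrix(inst_prob, nrow = P,
                                    ncol = as.integer(n_instruments)),
                 quirks = list(),
                 split_frac = c(train = 1, val = 1, test = 1) / 3,
                 max_frames = max_frames, name = name)
}

#' Plant an attribute so it is unrepresented in one set
#'
#' Modifies the spec so the given attribute cannot arise by chance anywhere
#' (the transition probability is zeroed; frames that would show exactly the
#' planted combination are adjusted), and is then injected into the first
#' surgery of every non-victim set. A closed-loop audit of the generated data
#' must flag exactly this attribute for the victim set.
#'
#' @param spec a [generator_spec()].
#' @param attribute `list(kind = "transition", source =, target =)` or
#'   `list(kind = "combination", instruments = c(...))` (labels).
#' @param victim_set the set the attribute must be absent from.
#' @export
plant_unrepresented <- function(spec, attribute, victim_set) {
  stopifnot(inherits(spec, "generator_spec"),
            victim_set %in% .SETS,
            attribute$kind %in% c("transition", "combination"))
  if (attribute$kind == "transition") {
    si <- match(attribute$source, spec$phase_labels)
    ti <- match(attribute$target, spec$phase_labels)
    if (is.na(si) || is.na(ti) || si == ti) stop("invalid planted transition")
  } else {
    mi <- match(attribute$instruments, spec$instrument_labels)
    if (anyNA(mi) || length(mi) < 2L) stop("invalid planted combination")
  }
  spec$planted <- list(attribute = attribute, victim = victim_set)
  spec
}

#' Generate a synthetic annotation dataset
#'
#' Deterministic for a fixed seed. Returns the surgeries, a matching
#' [dataset_config()] (including the deterministic split assignment), and a
#' ground-truth inventory: the exact per-set sets of transitions, instrument
#' combinations, phases and instruments present in the generated data.
#'
#' @param spec a [generator_spec()].
#' @param seed integer RNG seed.
#' @return object of class `synthetic_dataset`: list with `surgeries`
#'   (named list of [surgery()]), `config`, `inventory`, `spec`, `seed`.
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  P <- spec$n_phases; I <- spec$n_instruments; N <- spec$n_surgeries
  trans <- spec$trans
  planted <- spec$planted
  planted_combo_bits <- NULL
  if (!is.null(planted) && planted$attribute$kind == "transition") {
    si <- match(planted$attribute$source, spec$phase_labels)
    ti <- match(planted$attribute$target, spec$phase_labels)
    trans[si, ti] <- 0
    if (sum(trans[si, ]) == 0) stop("planting removed all exits from a phase")
    trans[si, ] <- trans[si, ] / sum(trans[si, ])
  }
  if (!is.null(planted) && planted$attribute$kind == "combination") {
    planted_combo_bits <- as.integer(spec$instrument_labels %in%
                                       planted$attribute$instruments)
  }
  quirk_end_possible <- any(vapply(spec$quirks, function(q)
    q$pattern == "early_end", logical(1L)))
  if (all(trans[, P + 1L] == 0) && !quirk_end_possible) {
    stop("degenerate generator spec: END is unreachable from every phase")
  }

  set.seed(as.integer(seed))
  ids <- sprintf("s%02d", seq_len(N))
  set_of <- stats::setNames(apportion_sets(N, spec$split_frac), ids)

  # quirk assignment: lexicographically first floor(fraction * N) ids per
  # quirk, skipping ids already claimed by an earlier quirk
  quirk_of <- stats::setNames(rep("", N), ids)
  for (q in spec$quirks) {
    k <- floor(q$fraction * N)
    free <- ids[quirk_of == ""]
    take <- utils::head(sort(free), k)
    quirk_of[take] <- q$pattern
  }

  gen_runs <- function(quirk) {
    p <- if (quirk == "skip_first" && P >= 2L) 2L
         else sample.int(P, 1L, prob = spec$init)
    phases <- integer(); lens <- integer(); frames <- 0L
    repeat {
      len <- 1L + stats::rgeom(1L, 1 / spec$mean_run[p])
      if (frames + len > spec$max_frames) {
        len <- spec$max_frames - frames
        if (len > 0L) { phases <- c(phases, p); lens <- c(lens, len) }
        break
      }
      phases <- c(phases, p); lens <- c(lens, len); frames <- frames + len
      if (quirk == "early_end" && length(phases) >= 3L) break
      nxt <- sample.int(P + 1L, 1L, prob = trans[p, ])
      if (nxt == P + 1L) break
      p <- nxt
    }
    list(phases = phases, lens = lens)
  }
  runs <- lapply(ids, function(id) gen_runs(quirk_of[id]))
  names(runs) <- ids

  # planted transition: splice a src-run + tgt-run into the middle of the
  # first surgery of every non-victim present set
  if (!is.null(planted) && planted$attribute$kind == "transition") {
    si <- match(planted$attribute$source, spec$phase_labels)
    ti <- match(planted$attribute$target, spec$phase_labels)
    for (s in setdiff(unique(unname(set_of)), planted$victim)) {
      id <- sort(ids[set_of == s])[1L]
      r <- runs[[id]]
      mid <- max(1L, length(r$phases) %/% 2L)
      r$phases <- append(r$phases, c(si, ti), after = mid)
      r$lens <- append(r$lens, c(2L, 2L), after = mid)
      runs[[id]] <- r
    }
  }

  surgeries <- vector("list", N); names(surgeries) <- ids
  stride <- spec$phase_fps %/% spec$instrument_fps
  for (id in ids) {
    r <- runs[[id]]
    phase_idx <- rep(r$phases, r$lens)
    n <- length(phase_idx)
    mat <- NULL
    if (I > 0L) {
      probs <- spec$inst_prob[phase_idx, , drop = FALSE]
      mat <- matrix(stats::rbinom(n * I, 1L, as.vector(probs)), nrow = n,
                    ncol = I, dimnames = list(NULL, spec$instrument_labels))
      if (spec$persistence > 0 && n > 1L) {
        copy <- stats::runif(n) < spec$persistence
        for (t in 2:n) if (copy[t]) mat[t, ] <- mat[t - 1L, ]
      }
      if (!is.null(planted_combo_bits)) {
        hit <- which(colSums(t(mat) == planted_combo_bits) == I)
        if (length(hit)) {
          first_member <- which(planted_combo_bits == 1L)[1L]
          mat[hit, first_member] <- 0L
        }
      }
      storage.mode(mat) <- "integer"
    }
    surgeries[[id]] <- surgery(id,
                               phases = spec$phase_labels[phase_idx],
                               instruments = mat,
                               frame_index = (seq_len(n) - 1L) * stride)
  }

  # planted combination: overwrite three mid-surgery frames of the first
  # surgery of every non-victim present set with exactly the planted set
  if (!is.null(planted_combo_bits)) {
    for (s in setdiff(unique(unname(set_of)), planted$victim)) {
      id <- sort(ids[set_of == s])[1L]
      sg <- surgeries[[id]]
      n <- sg$duration
      pos <- unique(pmin(n, (n %/% 2L) + 0:2))
      sg$instruments[pos, ] <- rep(planted_combo_bits, each = length(pos))
      surgeries[[id]] <- sg
    }
  }

  split <- split_assignment(train = ids[set_of == "train"],
                            val = ids[set_of == "val"],
                            test = ids[set_of == "test"])
  config <- dataset_config(name = spec$name, phases = spec$phase_labels,
                           instruments = if (I > 0L) spec$instrument_labels
                                         else character(),
                           phase_fps = spec$phase_fps,
                           instrument_fps = spec$instrument_fps,
                           split = split)
  structure(list(surgeries = surgeries, config = config,
                 inventory = .scan_inventory(surgeries, set_of),
                 spec = spec, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

# Ground-truth attribute inventory: per set, the exact sets of transition
# keys (incl. sentinels), combination keys (|S| >= 2), phases and
# instruments present in the generated data.
.scan_inventory <- function(surgeries, set_of) {
  inv <- list()
  for (s in unique(unname(set_of))) {
    inv[[s]] <- list(transitions = character(), combinations = character(),
                     phases = character(), instruments = character())
  }
  for (sg in surgeries) {
    s <- unname(set_of[sg$surgery_id])
    if (!is.null(sg$phases)) {
      vals <- rle(sg$phases)$values
      keys <- transition_key(c(.START_SENTINEL, vals), c(vals, .END_SENTINEL))
      inv[[s]]$transitions <- union(inv[[s]]$transitions, keys)
      inv[[s]]$phases <- union(inv[[s]]$phases, unique(vals))
    }
    if (!is.null(sg$instruments)) {
      fk <- frame_keys(sg$instruments)
      inv[[s]]$combinations <- union(inv[[s]]$combinations,
                                     unique(fk[grepl("+", fk, fixed = TRUE)]))
      vis <- colnames(sg$instruments)[colSums(sg$instruments) > 0L]
      inv[[s]]$instruments <- union(inv[[s]]$instruments, vis)
    }
  }
  inv
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d surgeries, seed %d\n",
              x$config$name, length(x$surgeries), x$seed))
  invisible(x)
}

#' Write a synthetic dataset as annotation files on disk
#'
#' Emits `config.json` plus, per surgery, a phase file (`<id>-phase.txt`,
#' labels expanded to `phase_fps`) and an instrument file (`<id>-tool.txt`,
#' sampled at `instrument_fps`) in the Cholec80 dialect. The files round-trip
#' through [load_dataset()].
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset_config(ds$config, file.path(dir, "config.json"))
  stride <- ds$config$phase_fps %/% ds$config$instrument_fps
  for (sg in ds$surgeries) {
    if (!is.null(sg$phases)) {
      write_phase_file(sg$phases,
                       file.path(dir, paste0(sg$surgery_id, "-phase.txt")),
                       stride = stride)
    }
    if (!is.null(sg$instruments)) {
      write_instrument_file(sg$instruments,
                            file.path(dir, paste0(sg$surgery_id, "-tool.txt")),
                            frame_index = sg$frame_index)
    }
  }
  invisible(dir)
}
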