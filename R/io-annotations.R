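# Readers/writers for frame-wise annotation files and assembly of surgeries.
#
# Dialects (Cholec80 / M2CAI family):
#   phase file:      TSV "Frame\tPhase", one row per frame at phase_fps,
#                    header optional (sniffed from the first line);
#   instrument file: TSV "Frame\t<Instr1>\t...", 0/1 cells, header required,
#                    one row per sampled frame at instrument_fps.
# Frame indexing is 0-based in source-video frame units throughout; tool files
# sample frames 0, s, 2s, ... where s = phase_fps / instrument_fps.

#' Read a frame-wise phase annotation file
#'
#' @param path TSV file with columns Frame (integer) and Phase (text); a header
#'   row is accepted but not required.
#' @param config a [dataset_config()]; labels must come from `config$phases`
#'   plus, if set, `config$idle_phase_label`.
#' @return character vector of phase labels in row order, with an integer
#'   attribute `frame_index` (the Frame column).
#' @export
read_phase_file <- function(path, config) {
  if (!file.exists(path)) stop("phase file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(fields) >= 2L &&
    is.na(suppressWarnings(as.integer(fields[1L])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          col.names = c("Frame", "Phase"),
                          colClasses = c("integer", "character"),
                          quote = "", comment.char = "")
  idx <- df$Frame
  if (length(idx) > 1L && any(diff(idx) <= 0L)) {
    stop("non-monotone frame index in ", path)
  }
  allowed <- c(config$phases, config$idle_phase_label)
  bad <- setdiff(unique(df$Phase), allowed)
  if (length(bad)) {
    stop("unknown phase label(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  structure(df$Phase, frame_index = idx)
}

#' Read a frame-wise binary instrument annotation file
#'
#' The header names are matched against `config$instruments` by name, so the
#' column order of the file does not matter; the returned matrix always has
#' columns in configuration order.
#'
#' @param path TSV file: first column Frame, then one 0/1 column per
#'   instrument; header row required.
#' @param config a [dataset_config()].
#' @return integer matrix (frames x instruments) with `colnames` equal to
#'   `config$instruments` and attribute `frame_index`.
#' @export
read_instrument_file <- function(path, config) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("instrument file needs a Frame column plus >=1 instrument: ", path)
  idx <- as.integer(df[[1L]])
  if (length(idx) > 1L && any(diff(idx) <= 0L)) {
    stop("non-monotone frame index in ", path)
  }
  header <- colnames(df)[-1L]
  if (!setequal(header, config$instruments)) {
    stop("instrument header of ", path, " does not match configured vocabulary; ",
         "file has {", paste(header, collapse = ", "), "}, config has {",
         paste(config$instruments, collapse = ", "), "}")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("instrument cells must be 0 or 1 in ", path)
  }
  m <- m[, config$instruments, drop = FALSE]
  rownames(m) <- NULL
  structure(m, frame_index = idx)
}

#' Downsample a phase label sequence to the instrument sampling rate
#'
#' Keeps exactly the labels at frame indices 0, s, 2s, ... where
#' `s = phase_fps / instrument_fps`, matching the frames sampled by the tool
#' annotation files. Output length is `ceiling(length(labels) / s)`.
#'
#' @param labels character vector of per-frame labels at `phase_fps`.
#' @param phase_fps,instrument_fps frame rates; `phase_fps` must be divisible
#'   by `instrument_fps`.
#' @export
downsample_phases <- function(labels, phase_fps, instrument_fps) {
  phase_fps <- as.integer(phase_fps); instrument_fps <- as.integer(instrument_fps)
  if (instrument_fps < 1L || phase_fps < instrument_fps ||
      phase_fps %% instrument_fps != 0L) {
    stop("phase_fps must be a multiple of instrument_fps")
  }
  stride <- phase_fps %/% instrument_fps
  keep <- seq.int(1L, length(labels), by = stride)
  fi <- attr(labels, "frame_index")
  out <- as.character(labels)[keep]
  attr(out, "frame_index") <- if (!is.null(fi)) fi[keep] else (keep - 1L)
  out
}

#' A single surgery's aligned annotation streams
#'
#' Holds one procedure's frame-indexed phase labels and/or instrument presence
#' vectors at the common (post-downsampling) rate. Duration is the total
#' number of frames. Either stream may be `NULL` (phase-only datasets such as
#' M2CAI-workflow; instrument-only such as M2CAI-tool), but not both.
#'
#' @param surgery_id surgery identifier.
#' @param phases character vector of per-frame labels, or `NULL`.
#' @param instruments 0/1 integer matrix (frames x instruments), or `NULL`.
#' @param frame_index optional 0-based strictly increasing integer indices in
#'   source-video frame units; defaults to the `frame_index` attribute of a
#'   stream, else `0:(n-1)`.
#' @return object of class `surgery` with fields `surgery_id`, `phases`,
#'   `instruments`, `frame_index`, `duration`.
#' @export
surgery <- function(surgery_id, phases = NULL, instruments = NULL,
                    frame_index = NULL) {
  if (is.null(phases) && is.null(instruments)) {
    stop("a surgery needs phase and/or instrument annotations")
  }
  n_p <- if (!is.null(phases)) length(phases) else NA_integer_
  n_i <- if (!is.null(instruments)) nrow(instruments) else NA_integer_
  if (!is.na(n_p) && !is.na(n_i) && n_p != n_i) {
    stop("phase and instrument streams differ in length (", n_p, " vs ", n_i,
         "); align them first")
  }
  n <- if (!is.na(n_p)) n_p else n_i
  if (n == 0L) stop("a surgery must contain at least one frame")
  if (is.null(frame_index)) {
    frame_index <- attr(phases, "frame_index") %||%
      attr(instruments, "frame_index") %||% (seq_len(n) - 1L)
  }
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n) stop("frame_index length mismatch")
  if (n > 1L && any(diff(frame_index) <= 0L)) {
    stop("frame indices must be strictly increasing")
  }
  if (!is.null(instruments)) {
    attr(instruments, "frame_index") <- NULL
    storage.mode(instruments) <- "integer"
  }
  structure(list(surgery_id = as.character(surgery_id),
                 phases = if (!is.null(phases)) as.character(phases),
                 instruments = instruments,
                 frame_index = frame_index,
                 duration = as.integer(n)),
            class = "surgery")
}

#' @export
print.surgery <- function(x, ...) {
  cat(sprintf("<surgery> %s: %d frames%s%s\n", x$surgery_id, x$duration,
              if (!is.null(x$phases)) sprintf(", %d phase runs", length(rle(x$phases)$values)) else "",
              if (!is.null(x$instruments)) sprintf(", %d instruments", ncol(x$instruments)) else ""))
  invisible(x)
}

#' Remove idle frames from a surgery
#'
#' Drops all frames labelled with the idle phase (e.g. the CATARACTS "Idle"
#' step that precedes every real step) so that downstream statistics see a
#' linear workflow. Remaining frames keep their original indices; runs of the
#' same phase that were separated only by idle frames become adjacent and are
#' merged by the run-length encoding downstream, so no self-transition is ever
#' created.
#'
#' @param surg a [surgery()].
#' @param idle_label the phase label to drop; `NULL` is a no-op.
#' @export
exclude_idle <- function(surg, idle_label) {
  stopifnot(inherits(surg, "surgery"))
  if (is.null(idle_label) || is.null(surg$phases)) return(surg)
  keep <- surg$phases != idle_label
  if (all(keep)) return(surg)
  if (!any(keep)) stop("surgery ", surg$surgery_id, " contains only idle frames")
  surgery(surg$surgery_id,
          phases = surg$phases[keep],
          instruments = if (!is.null(surg$instruments))
            surg$instruments[keep, , drop = FALSE],
          frame_index = surg$frame_index[keep])
}

#' Load a dataset of surgeries from annotation files
#'
#' For each surgery id in the split, looks for `<id>-phase.txt` and
#' `<id>-tool.txt` under `dir` (or uses explicit `paths`). Phase labels are
#' downsampled to the instrument rate; if the two streams still disagree in
#' length (Cholec80 videos differ by a few frames), both are truncated to the
#' shorter with a warning naming the dropped-frame count. Idle frames are
#' excluded at load time when `config$idle_phase_label` is set.
#'
#' @param config a [dataset_config()] with a split.
#' @param dir directory holding the annotation files.
#' @param paths alternative to `dir`: list with named character vectors
#'   `phase` and/or `instrument`, names = surgery ids, values = file paths.
#' @return object of class `surgical_dataset`: list with `surgeries` (named
#'   list of [surgery()]), `config`, and `coverage` (data frame reporting
#'   which surgeries have phase-only or instrument-only annotations).
#' @export
load_dataset <- function(config, dir = NULL, paths = NULL) {
  stopifnot(inherits(config, "dataset_config"), !is.null(config$split))
  ids <- unlist(config$split, use.names = FALSE)
  lk <- split_lookup(config$split)
  path_of <- function(id, kind) {
    if (!is.null(paths)) {
      p <- paths[[kind]][id]
      if (!is.null(p) && !is.na(p) && file.exists(p)) p else NULL
    } else {
      suffix <- if (kind == "phase") "-phase.txt" else "-tool.txt"
      p <- file.path(dir, paste0(id, suffix))
      if (file.exists(p)) p else NULL
    }
  }
  surgeries <- vector("list", length(ids)); names(surgeries) <- ids
  cov <- data.frame(surgery_id = ids, set = unname(lk[ids]),
                    has_phases = FALSE, has_instruments = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    pp <- path_of(id, "phase"); ip <- path_of(id, "instrument")
    if (is.null(pp) && is.null(ip)) {
      stop("surgery \"", id, "\" is in the split but has no annotation file")
    }
    labels <- NULL; mat <- NULL
    if (!is.null(pp)) {
      labels <- downsample_phases(read_phase_file(pp, config),
                                  config$phase_fps, config$instrument_fps)
    }
    if (!is.null(ip)) mat <- read_instrument_file(ip, config)
    if (!is.null(labels) && !is.null(mat) && length(labels) != nrow(mat)) {
      n <- min(length(labels), nrow(mat))
      dropped <- max(length(labels), nrow(mat)) - n
      warning("surgery ", id, ": phase/instrument streams differ in length; ",
              "truncated to ", n, " frames (dropped ", dropped, ")")
      fi <- attr(mat, "frame_index")[seq_len(n)]
      labels <- structure(labels[seq_len(n)], frame_index = fi)
      mat <- structure(mat[seq_len(n), , drop = FALSE], frame_index = fi)
    }
    s <- surgery(id, phases = labels, instruments = mat)
    if (!is.null(config$idle_phase_label)) {
      s <- exclude_idle(s, config$idle_phase_label)
    }
    surgeries[[id]] <- s
    cov$has_phases[i] <- !is.null(labels)
    cov$has_instruments[i] <- !is.null(mat)
  }
  structure(list(surgeries = surgeries, config = config, coverage = cov),
            class = "surgical_dataset")
}

#' @export
print.surgical_dataset <- function(x, ...) {
  cat(sprintf("<surgical_dataset> %s: %d surgeries (%d with phases, %d with instruments)\n",
              x$config$name, nrow(x$coverage), sum(x$coverage$has_phases),
              sum(x$coverage$has_instruments)))
  invisible(x)
}

#' Write a phase annotation file in the Cholec80 dialect
#'
#' Labels at the common rate are expanded back to `phase_fps` by repeating
#' each label `stride` times, one row per frame.
#'
#' @param labels character vector of labels at the instrument (common) rate.
#' @param path output path.
#' @param stride phase_fps / instrument_fps expansion factor.
#' @param header write a `Frame\tPhase` header row.
#' @export
write_phase_file <- function(labels, path, stride = 1L, header = TRUE) {
  stride <- as.integer(stride)
  n <- length(labels) * stride
  df <- data.frame(Frame = seq_len(n) - 1L,
                   Phase = rep(as.character(labels), each = stride))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Write an instrument annotation file in the Cholec80 dialect
#'
#' @param mat 0/1 integer matrix (frames x instruments) with instrument
#'   colnames.
#' @param path output path.
#' @param frame_index 0-based source-unit frame indices; defaults to
#'   `(0:(n-1)) * stride`.
#' @param stride sampling stride in source frame units.
#' @export
write_instrument_file <- function(mat, path, frame_index = NULL, stride = 1L) {
  fi <- frame_index %||% ((seq_len(nrow(mat)) - 1L) * as.integer(stride))
  df <- data.frame(Frame = fi, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read the generic long-format CSV fallback
#'
#' Columns: `surgery_id`, `frame`, optional `phase`, then one 0/1 column per
#' instrument named after `config$instruments`. Useful for datasets shipped as
#' a single table (e.g. pre-converted CaDIS presence tables).
#'
#' @param path CSV path.
#' @param config a [dataset_config()].
#' @return named list of [surgery()] objects.
#' @export
read_long_csv <- function(path, config) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("surgery_id", "frame") %in% colnames(df))) {
    stop("long CSV needs surgery_id and frame columns")
  }
  has_phase <- "phase" %in% colnames(df)
  inst_cols <- intersect(config$instruments, colnames(df))
  out <- lapply(split(df, df$surgery_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    mat <- NULL
    if (length(inst_cols)) {
      if (!setequal(inst_cols, config$instruments)) {
        stop("long CSV instrument columns do not cover the configured vocabulary")
      }
      mat <- as.matrix(d[, config$instruments, drop = FALSE])
      storage.mode(mat) <- "integer"
      rownames(mat) <- NULL
    }
    surgery(d$surgery_id[1L],
            phases = if (has_phase) d$phase,
            instruments = mat,
            frame_index = d$frame)
  })
  out[order(names(out))]
}
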