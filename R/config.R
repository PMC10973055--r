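#' Assignment of surgeries to train/validation/test sets
#'
#' A split assigns every surgery id to exactly one of the sets `train`, `val`
#' and `test`. The validation set may be empty (e.g. the common 40/-/40
#' Cholec80 split); train and test must not be. An empty `val` is represented
#' as an empty set, not a missing key, so per-set reports have a uniform shape
#' across 40/-/40 and 32/8/40 style splits.
#'
#' @param train,val,test character vectors of surgery ids.
#' @return an object of class `split_assignment`: a named list with elements
#'   `train`, `val`, `test`.
#' @examples
#' split_assignment(train = c("s01", "s02"), test = "s03")
#' @export
split_assignment <- function(train, val = character(), test) {
  train <- as.character(train); val <- as.character(val); test <- as.character(test)
  ids <- c(train, val, test)
  if (anyDuplicated(ids) > 0L) {
    dup <- unique(ids[duplicated(ids)])
    stop("surgery id(s) assigned to more than one set: ", paste(dup, collapse = ", "))
  }
  if (length(train) == 0L || length(test) == 0L) {
    stop("train and test sets must be non-empty")
  }
  structure(list(train = train, val = val, test = test), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d/%s/%d surgeries\n",
              length(x$train),
              if (length(x$val)) as.character(length(x$val)) else "-",
              length(x$test)))
  invisible(x)
}

#' Lookup vector surgery id -> set label
#' @param split a [split_assignment()].
#' @return named character vector; names are surgery ids, values set labels.
#' @export
split_lookup <- function(split) {
  stopifnot(inherits(split, "split_assignment"))
  stats::setNames(rep(names(split), lengths(split)), unlist(split, use.names = FALSE))
}

#' Names of the non-empty sets of a split
#' @param split a [split_assignment()].
#' @export
sets_present <- function(split) names(split)[lengths(split) > 0L]

#' Set cardinalities of a split
#' @param split a [split_assignment()].
#' @export
set_sizes <- function(split) lengths(split)

#' Dataset configuration
#'
#' Declares the phase vocabulary in its conceptual order (the order a textbook
#' procedure visits the phases; index 1..P), the instrument vocabulary, the
#' frame rates of the two annotation streams, an optional idle phase label to
#' exclude at load time (e.g. the CATARACTS "Idle" step), and the split.
#'
#' @param name dataset name.
#' @param phases ordered character vector of phase labels (may be empty for
#'   instrument-only datasets such as M2CAI-tool).
#' @param instruments character vector of instrument labels (may be empty for
#'   phase-only datasets such as M2CAI-workflow).
#' @param phase_fps,instrument_fps frames per second of the phase and
#'   instrument annotation files. `phase_fps` must be a multiple of
#'   `instrument_fps` so phase labels can be aligned by stride downsampling.
#' @param idle_phase_label optional label whose frames are dropped at load
#'   time, before any statistics.
#' @param split a [split_assignment()], or `NULL`.
#' @return object of class `dataset_config`.
#' @export
dataset_config <- function(name, phases = character(), instruments = character(),
                           phase_fps = 1L, instrument_fps = 1L,
                           idle_phase_label = NULL, split = NULL) {
  phases <- as.character(phases); instruments <- as.character(instruments)
  if (anyDuplicated(phases) > 0L) stop("duplicate phase labels")
  if (anyDuplicated(instruments) > 0L) stop("duplicate instrument labels")
  if (any(c(.START_SENTINEL, .END_SENTINEL) %in% phases)) {
    stop("phase labels 'START' and 'END' are reserved for sentinels")
  }
  phase_fps <- as.integer(phase_fps); instrument_fps <- as.integer(instrument_fps)
  if (is.na(phase_fps) || is.na(instrument_fps) || instrument_fps < 1L ||
      phase_fps < instrument_fps) {
    stop("need phase_fps >= instrument_fps >= 1")
  }
  if (phase_fps %% instrument_fps != 0L) {
    stop("phase_fps must be divisible by instrument_fps")
  }
  if (!is.null(idle_phase_label)) idle_phase_label <- as.character(idle_phase_label)
  if (!is.null(split)) stopifnot(inherits(split, "split_assignment"))
  structure(list(name = as.character(name), phases = phases,
                 instruments = instruments, phase_fps = phase_fps,
                 instrument_fps = instrument_fps,
                 idle_phase_label = idle_phase_label, split = split),
            class = "dataset_config")
}

#' @export
print.dataset_config <- function(x, ...) {
  cat(sprintf("<dataset_config> %s: %d phases, %d instruments, %d/%d fps\n",
              x$name, length(x$phases), length(x$instruments),
              x$phase_fps, x$instrument_fps))
  if (!is.null(x$split)) print(x$split)
  invisible(x)
}

#' Read a dataset configuration from JSON
#'
#' Expected keys: `name`, `phases` (ordered), `instruments`, `phase_fps`,
#' `instrument_fps`, optional `idle_phase_label`, and `split` with `train`,
#' `val`, `test` id arrays. Extra keys are ignored (files may carry
#' documentation fields such as proposed re-assignment moves).
#'
#' @param path path to a JSON file.
#' @return a [dataset_config()].
#' @export
read_dataset_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  split <- NULL
  if (!is.null(obj$split)) {
    split <- split_assignment(train = obj$split$train %||% character(),
                              val = obj$split$val %||% character(),
                              test = obj$split$test %||% character())
  }
  dataset_config(name = obj$name %||% "unnamed",
                 phases = obj$phases %||% character(),
                 instruments = obj$instruments %||% character(),
                 phase_fps = obj$phase_fps %||% 1L,
                 instrument_fps = obj$instrument_fps %||% 1L,
                 idle_phase_label = obj$idle_phase_label,
                 split = split)
}

#' Write a dataset configuration to JSON
#' @param config a [dataset_config()].
#' @param path output path.
#' @export
write_dataset_config <- function(config, path) {
  stopifnot(inherits(config, "dataset_config"))
  obj <- list(name = config$name, phases = config$phases,
              instruments = config$instruments,
              phase_fps = config$phase_fps,
              instrument_fps = config$instrument_fps,
              idle_phase_label = config$idle_phase_label,
              split = if (!is.null(config$split))
                list(train = config$split$train, val = config$split$val,
                     test = config$split$test))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
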