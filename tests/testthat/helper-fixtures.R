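# Small hand-built fixtures shared across test files.

toy_config <- function(P = 3L, I = 2L, split = NULL) {
  dataset_config(name = "toy",
                 phases = sprintf("P%d", seq_len(P)),
                 instruments = LETTERS[seq_len(I)],
                 phase_fps = 1L, instrument_fps = 1L,
                 split = split)
}

toy_surgery <- function(id, phases = NULL, inst = NULL, config = toy_config()) {
  mat <- NULL
  if (!is.null(inst)) {
    mat <- do.call(rbind, inst)
    colnames(mat) <- config$instruments[seq_len(ncol(mat))]
    storage.mode(mat) <- "integer"
  }
  surgery(id, phases = phases, instruments = mat)
}

# One-swap fixture: combination A+B occurs in surgeries c1 (train) and c2
# (test); t1/t2/t3 are plain single-instrument surgeries. With split
# train = {c1, c2}, test = {t1, t2}, the combination is absent from test and
# swapping c2 with any test surgery fixes the only flag.
one_swap_fixture <- function() {
  config <- toy_config(P = 2L, I = 2L)
  mk_combo <- function(id) toy_surgery(id, phases = c("P1", "P2"),
                                       inst = list(c(1L, 1L), c(1L, 0L)),
                                       config = config)
  mk_plain <- function(id) toy_surgery(id, phases = c("P1", "P2"),
                                       inst = list(c(1L, 0L), c(0L, 1L)),
                                       config = config)
  surgeries <- list(mk_combo("c1"), mk_combo("c2"), mk_plain("t1"),
                    mk_plain("t2"))
  names(surgeries) <- vapply(surgeries, `[[`, "", "surgery_id")
  split <- split_assignment(train = c("c1", "c2"), test = c("t1", "t2"))
  list(surgeries = surgeries, split = split, config = config)
}
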