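make_models <- function(seed = 9) {
  ds <- generate_dataset(generator_spec(n_surgeries = 8L), seed = seed)
  s <- ds$surgeries; sp <- ds$config$split; cfg <- ds$config
  list(ds = ds, cfg = cfg, sp = sp,
       pc = aggregate_phase_counts(s, sp, cfg),
       tc = aggregate_transition_counts(s, sp, cfg),
       ppi = per_phase_instrument_counts(s, sp, cfg),
       ic = aggregate_instrument_counts(s, sp, cfg),
       cc = aggregate_combination_counts(s, sp, cfg),
       dur = surgery_durations(s, sp))
}

test_that("arc widths are strictly monotone in occurrence counts", {
  m <- make_models()
  pv <- phase_view_model(m$pc, m$tc, m$ppi, m$cfg)
  a <- pv$arcs
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (a$total[i] > a$total[j]) expect_gt(a$width[i], a$width[j])
    if (a$total[i] == a$total[j]) expect_equal(a$width[i], a$width[j])
  }
  expect_true(all(a$width >= view_style()$min_arc_width))
  # model numbers are verbatim aggregates
  expect_equal(sum(pv$nodes$train + pv$nodes$val + pv$nodes$test),
               sum(m$pc$frames$frames))
  expect_equal(sum(a$train + a$val + a$test), sum(m$tc$count))
  # forward arcs up, backward arcs down, sentinels at the edges
  expect_true(all(a$side[a$direction == "forward"] == "upper"))
  expect_true(all(a$side[a$direction == "backward"] == "lower"))
  expect_true(all(a$x0[a$source == "START"] == 0))
  expect_true(all(a$x1[a$target == "END"] == length(m$cfg$phases) + 1))
})

test_that("a train-only transition carries an all-train (red) pie", {
  fx <- one_swap_fixture()
  s <- fx$surgeries
  # give c1 a transition no one else has: P2 -> P1 (backward), train-only
  s$c1 <- toy_surgery("c1", phases = c("P1", "P2", "P1"),
                      inst = list(c(1L, 1L), c(1L, 0L), c(0L, 1L)),
                      config = fx$config)
  pc <- aggregate_phase_counts(s, fx$split, fx$config)
  tc <- aggregate_transition_counts(s, fx$split, fx$config)
  pv <- phase_view_model(pc, tc, NULL, fx$config)
  back <- pv$arcs[pv$arcs$source == "P2" & pv$arcs$target == "P1", ]
  expect_equal(back$side, "lower")
  expect_gt(back$train, 0)
  expect_equal(back$val + back$test, 0)   # rendered pie is a single color
})

test_that("instrument view model normalizes bars and seeds the layout", {
  m <- make_models()
  iv_g <- instrument_view_model(m$ic, m$cc, m$cfg, normalize = "global")
  iv_p <- instrument_view_model(m$ic, m$cc, m$cfg, normalize = "per_instrument")
  expect_true(all(iv_g$bars$length <= 1))
  # per-instrument scaling: every instrument's largest bar reaches 1
  for (lab in unique(iv_p$bars$label)) {
    lens <- iv_p$bars$length[iv_p$bars$label == lab]
    if (any(lens > 0)) expect_equal(max(lens), 1)
  }
  expect_true("(idle)" %in% iv_g$bars$label)
  # combination node frames are verbatim aggregates
  expect_equal(sum(iv_g$combos$train + iv_g$combos$val + iv_g$combos$test),
               sum(m$cc$combinations$frames))
  # layout reproducibility under a fixed seed
  iv2 <- instrument_view_model(m$ic, m$cc, m$cfg, normalize = "global",
                               layout_seed = 42L)
  expect_identical(iv_g$combos[c("x", "y")], iv2$combos[c("x", "y")])
})

test_that("supplementary model carries the computed means", {
  m <- make_models()
  sm <- supplementary_model(per_set_totals(m$ds$surgeries, m$sp), m$dur, m$sp)
  for (st in sets_present(m$sp)) {
    per <- sm$per_surgery[sm$per_surgery$set == st, ]
    expect_equal(sm$means$mean_frames[sm$means$set == st],
                 mean(per$frames))
  }
})

test_that("all three views render non-empty image files", {
  m <- make_models()
  f1 <- withr::local_tempfile(fileext = ".svg")
  render_phase_view(phase_view_model(m$pc, m$tc, m$ppi, m$cfg), f1,
                    show_arc_pies = TRUE)
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_instrument_view(instrument_view_model(m$ic, m$cc, m$cfg), f2)
  f3 <- withr::local_tempfile(fileext = ".svg")
  render_supplementary(supplementary_model(
    per_set_totals(m$ds$surgeries, m$sp), m$dur, m$sp), f3)
  for (f in c(f1, f2, f3)) expect_gt(file.size(f), 1000)
  expect_error(render_phase_view(phase_view_model(m$pc, m$tc, NULL, m$cfg),
                                 withr::local_tempfile(fileext = ".bmp")),
               "unsupported")
})

test_that("JSON reports round-trip and Markdown carries the summary matrix", {
  m <- make_models()
  rep <- audit_splits(m$ds$surgeries, m$sp, m$cfg)
  fj <- withr::local_tempfile(fileext = ".json")
  write_report(rep, fj)
  back <- read_report(fj)
  expect_identical(rep$counts, back$counts)
  expect_identical(rep$unrepresented, back$unrepresented)
  expect_identical(rep$summary, back$summary)
  expect_equal(rep$totals, back$totals)
  expect_identical(summarize_unrepresented(back), rep$summary)

  fm <- withr::local_tempfile(fileext = ".md")
  write_report(rep, fm)
  md <- readLines(fm)
  for (k in rownames(rep$summary)) {
    row <- md[grepl(paste0("^\\| ", k, " \\|"), md)]
    expect_length(row, 1L)
    cells <- trimws(strsplit(row, "|", fixed = TRUE)[[1]])[-(1:2)]
    want <- ifelse(is.na(rep$summary[k, ]), "N/A",
                   as.character(rep$summary[k, ]))
    expect_equal(cells, unname(want))
  }

  fc <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, fc)
  csv <- read.csv(fc, stringsAsFactors = FALSE)
  expect_equal(nrow(csv), nrow(rep$unrepresented))
})

test_that("the CLI drives simulate -> audit -> plot end to end", {
  td <- withr::local_tempdir()
  expect_invisible(splitaudit_cli(c("simulate", "--out", td, "--seed", "4",
                                    "--surgeries", "6")))
  out <- file.path(td, "report.json")
  capture.output(splitaudit_cli(c("audit", "--config",
                                  file.path(td, "config.json"),
                                  "--data", td, "--out", out)))
  expect_true(file.exists(out))
  expect_s3_class(read_report(out), "audit_report")
  fig <- file.path(td, "fig.svg")
  capture.output(splitaudit_cli(c("plot", "--config",
                                  file.path(td, "config.json"),
                                  "--data", td, "--view", "summary",
                                  "--out", fig)))
  expect_gt(file.size(fig), 1000)
})
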