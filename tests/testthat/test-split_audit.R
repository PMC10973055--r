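test_that("unrepresented detection flags exactly the zero-count sets", {
  counts <- data.frame(
    kind = "combination",
    key = rep(c("A+B", "A+C"), each = 3),
    set = rep(c("train", "val", "test"), 2),
    count = c(5L, 2L, 1L,   4L, 0L, 1L))
  split <- split_assignment(train = "a", val = "b", test = "c")
  f <- find_unrepresented(counts, split)
  expect_equal(nrow(f), 1L)
  expect_equal(f$key, "A+C")
  expect_equal(f$absent_in, "val")

  # absence is judged against non-empty sets only (40/-/40 style)
  split2 <- split_assignment(train = "a", test = "c")
  f2 <- find_unrepresented(counts, split2)
  expect_equal(nrow(f2), 0L)

  # global count 0 is never flagged (vacuous absence)
  counts0 <- data.frame(kind = "phase", key = "P9",
                        set = c("train", "val", "test"), count = 0L)
  expect_equal(nrow(find_unrepresented(counts0, split)), 0L)
})

test_that("audit summary matrix matches the flag table cardinalities", {
  ds <- generate_dataset(generator_spec(n_surgeries = 10L), seed = 31)
  rep <- audit_splits(ds$surgeries, ds$config$split, ds$config)
  sm <- summarize_unrepresented(rep)
  for (k in rownames(sm)) for (st in .SETS) {
    fk <- rep$unrepresented[rep$unrepresented$kind == k, ]
    expected <- sum(vapply(strsplit(fk$absent_in, ", ", fixed = TRUE),
                           function(a) st %in% a, logical(1)))
    expect_equal(unname(sm[k, st]), expected,
                 label = sprintf("summary[%s, %s]", k, st))
  }
  # a flagged attribute always has positive global count
  tot <- rep$unrepresented$train + rep$unrepresented$val + rep$unrepresented$test
  expect_true(all(tot > 0))
})

test_that("kinds without data are reported as NA", {
  # instrument-only dataset: phase-family rows must be NA in the summary
  cfg <- toy_config(P = 0L, I = 2L)
  cfg$phases <- character()
  s <- list(a = toy_surgery("a", inst = list(c(1L, 0L)), config = cfg),
            b = toy_surgery("b", inst = list(c(0L, 1L)), config = cfg))
  split <- split_assignment(train = "a", test = "b")
  rep <- audit_splits(s, split, cfg)
  expect_true(all(is.na(rep$summary["phase", ])))
  expect_true(all(is.na(rep$summary["transition", ])))
  expect_false(anyNA(rep$summary["instrument", c("train", "test")]))
  # empty val column is NA even for kinds with data
  expect_true(is.na(rep$summary["instrument", "val"]))
})

test_that("per-set totals report empty validation sets as absent means", {
  cfg <- toy_config()
  s <- list(a = toy_surgery("a", phases = rep("P1", 10), config = cfg),
            b = toy_surgery("b", phases = rep("P2", 4), config = cfg))
  split <- split_assignment(train = "a", test = "b")
  t <- per_set_totals(s, split)
  expect_equal(t$surgeries, c(1L, 0L, 1L))
  expect_equal(t$frames, c(10L, 0L, 4L))
  expect_equal(t$mean_frames[t$set == "train"], 10)
  expect_true(is.na(t$mean_frames[t$set == "val"]))
})

test_that("reassign is pure, validates moves, and is an involution", {
  split <- split_assignment(train = c("a", "b"), val = "c", test = "d")
  r0 <- reassign(split, data.frame(surgery_id = character(),
                                   to = character()))
  expect_identical(r0$split, split)

  r1 <- reassign(split, c(a = "test"))
  expect_equal(split_lookup(r1$split)[["a"]], "test")
  expect_equal(split_lookup(split)[["a"]], "train")  # input untouched
  r2 <- reassign(r1$split, c(a = "train"))
  expect_identical(split_lookup(r2$split), split_lookup(split))

  expect_error(reassign(split, c(zz = "test")), "zz")
  expect_error(reassign(split, c(a = "holdout")), "invalid target")
  expect_warning(r3 <- reassign(split, c(a = "train")), "no-op")
  expect_identical(r3$split, split)
})

test_that("diff counts equal de-novo recomputation after random moves", {
  ds <- generate_dataset(generator_spec(n_surgeries = 10L), seed = 17)
  split <- ds$config$split
  set.seed(23)
  ids <- names(ds$surgeries)
  for (rep_i in 1:3) {
    n_mv <- sample(1:4, 1)
    mv_ids <- sample(ids, n_mv)
    lk <- split_lookup(split)
    targets <- vapply(mv_ids, function(id)
      sample(setdiff(.SETS, lk[[id]]), 1), "")
    res <- reassign(split, stats::setNames(targets, mv_ids),
                    ds$surgeries, ds$config)
    de_novo <- audit_splits(ds$surgeries, res$split, ds$config)
    expect_identical(res$diff$after$counts, de_novo$counts)
    expect_identical(res$diff$after$unrepresented, de_novo$unrepresented)
    expect_equal(res$diff$unrepresented_after,
                 length(splitaudit:::flag_pairs(de_novo)))
    # inverse moves restore the original report bit-exactly
    inv <- reassign(res$split, stats::setNames(unname(lk[mv_ids]), mv_ids),
                    ds$surgeries, ds$config)
    orig <- audit_splits(ds$surgeries, split, ds$config)
    expect_identical(inv$diff$after$counts, orig$counts)
    expect_identical(inv$diff$after$unrepresented, orig$unrepresented)
  }
})

test_that("greedy improvement fixes the one-swap fixture and keeps sizes", {
  fx <- one_swap_fixture()
  rep0 <- audit_splits(fx$surgeries, fx$split, fx$config)
  expect_equal(nrow(rep0$unrepresented), 1L)
  gi <- greedy_improve(fx$surgeries, fx$split, fx$config, max_iter = 5L)
  expect_equal(gi$objective, 0)
  expect_equal(nrow(gi$trace), 1L)          # found in one iteration
  expect_identical(set_sizes(gi$split), set_sizes(fx$split))
  expect_true(gi$converged)

  # zero objective returns the input split unchanged
  gi2 <- greedy_improve(fx$surgeries, gi$split, fx$config)
  expect_identical(gi2$split, gi$split)
  expect_equal(nrow(gi2$trace), 0L)
})

test_that("greedy objective never increases, sizes preserved, seeded runs deterministic", {
  for (seed in c(2, 12, 22)) {
    ds <- generate_dataset(generator_spec(n_surgeries = 8L), seed = seed)
    gi <- greedy_improve(ds$surgeries, ds$config$split, ds$config,
                         max_iter = 4L)
    expect_lte(gi$objective, gi$initial_objective)
    expect_identical(set_sizes(gi$split), set_sizes(ds$config$split))
    if (nrow(gi$trace) > 1L) {
      expect_true(all(diff(gi$trace$objective) < 0))
    }
    g1 <- greedy_improve(ds$surgeries, ds$config$split, ds$config,
                         max_iter = 2L, seed = 99L)
    g2 <- greedy_improve(ds$surgeries, ds$config$split, ds$config,
                         max_iter = 2L, seed = 99L)
    expect_identical(split_lookup(g1$split), split_lookup(g2$split))
  }
})

test_that("shipped Cholec80/M2CAI split metadata is internally consistent", {
  p <- system.file("extdata", "cholec80_40_40.json", package = "splitaudit")
  cfg <- read_dataset_config(p)
  expect_equal(set_sizes(cfg$split), c(train = 40L, val = 0L, test = 40L))
  moves <- as.data.frame(jsonlite::fromJSON(p)$proposed_moves)
  res <- reassign(cfg$split, moves)
  # the published re-assignment retains the 40/-/40 shape
  expect_equal(set_sizes(res$split), c(train = 40L, val = 0L, test = 40L))
  expect_true(all(c("video29", "video32", "video33", "video38") %in%
                    res$split$test))

  p2 <- system.file("extdata", "m2cai_tool_10_5.json", package = "splitaudit")
  cfg2 <- read_dataset_config(p2)
  expect_equal(set_sizes(cfg2$split), c(train = 10L, val = 0L, test = 5L))
  moves2 <- as.data.frame(jsonlite::fromJSON(p2)$proposed_moves)
  res2 <- reassign(cfg2$split, moves2)
  expect_equal(set_sizes(res2$split), c(train = 10L, val = 0L, test = 5L))
  # swapping back restores the original assignment
  inv <- reassign(res2$split, data.frame(
    surgery_id = moves2$surgery_id,
    to = unname(split_lookup(cfg2$split)[moves2$surgery_id])))
  expect_identical(split_lookup(inv$split), split_lookup(cfg2$split))
})
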