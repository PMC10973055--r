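test_that("frame classification uses exact-set semantics", {
  expect_equal(classify_frame(c(A = 0L, B = 0L))$kind, "idle")
  cl <- classify_frame(c(A = 1L, B = 0L))
  expect_equal(cl$kind, "singleton")
  expect_equal(cl$instruments, "A")
  cl2 <- classify_frame(c(A = 1L, B = 1L))
  expect_equal(cl2$kind, "combination")
  expect_equal(cl2$key, "A+B")
})

test_that("combination keys are canonical regardless of input order", {
  cfg <- toy_config(I = 2L)
  expect_equal(combo_key(c("B", "A")), "A+B")
  expect_equal(combo_key(c("B", "A"), cfg), "A+B")
})

test_that("the worked four-frame example tallies correctly", {
  # frames {}, {A}, {A,B}, {A,B}: idle 1, singleton A 1, combo A+B 2;
  # individual occurrence A = 3, B = 2; share of A+B in A's frames = 2/3
  cfg <- toy_config(P = 1L, I = 2L)
  s <- list(toy_surgery("a", phases = rep("P1", 4),
                        inst = list(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L)),
                        config = cfg))
  split <- split_assignment(train = "a", test = "a2")
  s$a2 <- toy_surgery("a2", phases = "P1", inst = list(c(1L, 0L)), config = cfg)
  names(s) <- c("a", "a2")

  ic <- aggregate_instrument_counts(s, split, cfg)
  expect_equal(ic$instruments$frames[ic$instruments$instrument == "A" &
                                       ic$instruments$set == "train"], 3L)
  expect_equal(ic$instruments$frames[ic$instruments$instrument == "B" &
                                       ic$instruments$set == "train"], 2L)
  expect_equal(ic$idle$frames[ic$idle$set == "train"], 1L)

  cc <- aggregate_combination_counts(s, split, cfg)
  expect_equal(cc$combinations$frames[cc$combinations$combination == "A+B" &
                                        cc$combinations$set == "train"], 2L)
  expect_equal(cc$singletons$frames[cc$singletons$instrument == "A" &
                                      cc$singletons$set == "train"], 1L)

  sh <- cooccurrence_share("A+B", ic, cc, set = "train")
  expect_equal(unname(sh["A"]), 2 / 3)
  expect_equal(unname(sh["B"]), 1)       # all of B's frames are in the combo
})

test_that("no multi-instrument frame yields an empty combination table", {
  cfg <- toy_config(P = 1L, I = 2L)
  s <- list(a = toy_surgery("a", phases = "P1", inst = list(c(1L, 0L)),
                            config = cfg),
            b = toy_surgery("b", phases = "P1", inst = list(c(0L, 1L)),
                            config = cfg))
  split <- split_assignment(train = "a", test = "b")
  cc <- aggregate_combination_counts(s, split, cfg)
  expect_equal(nrow(cc$combinations), 0L)
})

test_that("partition and consistency identities hold on synthetic data", {
  for (seed in c(3, 14)) {
    ds <- generate_dataset(generator_spec(n_surgeries = 9L, n_instruments = 4L),
                           seed = seed)
    split <- ds$config$split; cfg <- ds$config
    ic <- aggregate_instrument_counts(ds$surgeries, split, cfg)
    cc <- aggregate_combination_counts(ds$surgeries, split, cfg)
    for (st in .SETS) {
      idle <- cc$idle$frames[cc$idle$set == st]
      singles <- sum(cc$singletons$frames[cc$singletons$set == st])
      combos <- sum(cc$combinations$frames[cc$combinations$set == st])
      annotated <- ic$annotated$frames[ic$annotated$set == st]
      # idle + singletons + combinations = instrument-annotated frames
      expect_equal(idle + singles + combos, annotated)
      # frame_count(i) = singleton(i) + sum over combinations containing i
      for (i in cfg$instruments) {
        in_combo <- vapply(strsplit(cc$combinations$combination, "+",
                                    fixed = TRUE),
                           function(m) i %in% m, logical(1))
        expect_equal(
          ic$instruments$frames[ic$instruments$instrument == i &
                                  ic$instruments$set == st],
          cc$singletons$frames[cc$singletons$instrument == i &
                                 cc$singletons$set == st] +
            sum(cc$combinations$frames[in_combo & cc$combinations$set == st]))
      }
    }
    # all co-occurrence shares are in (0, 1]
    for (k in unique(cc$combinations$combination)) {
      sh <- cooccurrence_share(k, ic, cc)
      expect_true(all(sh > 0 & sh <= 1))
    }
  }
})

test_that("subset semantics dominates exact-set counts", {
  ds <- generate_dataset(generator_spec(n_surgeries = 6L, n_instruments = 4L),
                         seed = 5)
  cc_e <- aggregate_combination_counts(ds$surgeries, ds$config$split,
                                       ds$config, semantics = "exact")
  cc_s <- aggregate_combination_counts(ds$surgeries, ds$config$split,
                                       ds$config, semantics = "subset")
  # every exact combination also appears under subset semantics, with a
  # count at least as large (supersets contribute downward)
  for (i in seq_len(nrow(cc_e$combinations))) {
    r <- cc_e$combinations[i, ]
    m <- cc_s$combinations$frames[cc_s$combinations$combination == r$combination &
                                    cc_s$combinations$set == r$set]
    expect_gte(m, r$frames)
  }
  # a frame {A,B,C} must count toward {A,B} under subset semantics:
  cfg <- toy_config(P = 1L, I = 3L)
  cfg$instruments <- c("A", "B", "C")
  s <- list(a = toy_surgery("a", phases = "P1", inst = list(c(1L, 1L, 1L)),
                            config = cfg),
            b = toy_surgery("b", phases = "P1", inst = list(c(1L, 0L, 0L)),
                            config = cfg))
  split <- split_assignment(train = "a", test = "b")
  cc <- aggregate_combination_counts(s, split, cfg, semantics = "subset")
  got <- cc$combinations[cc$combinations$set == "train", ]
  expect_setequal(got$combination, c("A+B", "A+C", "B+C", "A+B+C"))
  expect_true(all(got$frames == 1L))
})

test_that("monotonicity: adding a surgery never decreases counts in its set", {
  ds <- generate_dataset(generator_spec(n_surgeries = 6L), seed = 8)
  cfg <- ds$config
  split <- cfg$split
  extra <- generate_dataset(generator_spec(n_surgeries = 4L,
                                           name = "extra"), seed = 9)$surgeries[1:2]
  extra <- stats::setNames(extra, c("x1", "x2"))
  extra <- lapply(names(extra), function(id) {
    e <- extra[[id]]; e$surgery_id <- id; e
  })
  names(extra) <- c("x1", "x2")
  split2 <- split_assignment(train = c(split$train, "x1", "x2"),
                             val = split$val, test = split$test)
  ic1 <- aggregate_instrument_counts(ds$surgeries, split, cfg)
  ic2 <- aggregate_instrument_counts(c(ds$surgeries, extra), split2, cfg)
  expect_true(all(ic2$instruments$frames >= ic1$instruments$frames))
})
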