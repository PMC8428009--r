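test_that("note-level confusion tabulates per note against the universe", {
  cc <- note_confusion(gold = c("A", "B"), predicted = c("A", "C"),
                       universe = c("A", "B", "C", "D"))
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  cc <- note_confusion(c("A", "B"), c("A", "B"), c("A", "B", "C"))
  expect_equal(cc$fp + cc$fn, 0L)
  cc <- note_confusion(character(), character(), paste0("n", 1:5))
  expect_equal(cc$tn, 5L)
  expect_error(note_confusion("A", "Z", c("A", "B")), "outside the declared")
})

test_that("sentence-level confusion is set algebra with no TN", {
  g <- data.frame(note_id = c("n1", "n1"), sentence_index = c(0L, 3L))
  p <- data.frame(note_id = "n1", sentence_index = 0L)
  cc <- sentence_confusion(g, p)
  expect_equal(unlist(cc[c("tp", "fp", "fn")]), c(tp = 1L, fp = 0L, fn = 1L))
  expect_true(is.na(cc$tn))

  g2 <- data.frame(note_id = c("a", "b"), sentence_index = c(1L, 1L))
  p2 <- data.frame(note_id = c("c", "d"), sentence_index = c(1L, 1L))
  cc <- sentence_confusion(g2, p2)
  expect_equal(unlist(cc[c("tp", "fp", "fn")]), c(tp = 0L, fp = 2L, fn = 2L))

  expect_warning(sentence_confusion(rbind(g, g[1, ]), p), "duplicate gold")
})

test_that("exact binomial intervals match the printed convention", {
  m <- metric_with_ci(29, 29, "sensitivity")
  expect_equal(m$estimate, 100)
  expect_equal(round(m$ci_low, 1), 88.1)
  expect_equal(m$ci_high, 100)

  m <- metric_with_ci(132, 132, "specificity")
  expect_equal(round(m$ci_low, 1), 97.2)

  m <- metric_with_ci(0, 10, "ppv")
  expect_equal(m$estimate, 0)
  expect_equal(m$ci_low, 0)

  expect_error(metric_with_ci(1, 0), "denominator")
  expect_error(metric_with_ci(5, 3), "numerator")
})

test_that("intervals agree with stats::binom.test across many cases", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:250, 1)
    x <- sample(0:n, 1)
    m <- metric_with_ci(x, n, "sensitivity")
    bt <- as.numeric(binom.test(x, n)$conf.int)
    expect_equal(c(m$ci_low, m$ci_high), 100 * bt, tolerance = 1e-10)
  }
})

test_that("Clopper-Pearson coverage is conservative", {
  set.seed(2026)
  for (case in list(c(p = 0.5, n = 20), c(p = 0.9, n = 50),
                    c(p = 0.99, n = 200))) {
    p <- case[["p"]]; n <- case[["n"]]
    xs <- 0:n
    lo <- ifelse(xs == 0, 0, qbeta(0.025, xs, n - xs + 1))
    hi <- ifelse(xs == n, 1, qbeta(0.975, xs + 1, n - xs))
    draws <- rbinom(1e4, n, p)
    covered <- lo[draws + 1] <= p & p <= hi[draws + 1]
    expect_gte(mean(covered), 0.95)
  }
})

test_that("corrections reclassify FP to TP and never lower sens or PPV", {
  cc <- structure(list(level = "sentence", tp = 8L, fp = 2L, fn = 1L,
                       tn = NA_integer_), class = "confusion_counts")
  expect_identical(corrected_counts(cc, 0L), cc)
  cc2 <- corrected_counts(cc, 2L)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(10L, 0L, 1L))
  expect_equal(metric_with_ci(cc2$tp, cc2$tp + cc2$fn)$estimate,
               100 * 10 / 11)
  expect_error(corrected_counts(cc, 3L), "inconsistent")

  nc <- structure(list(level = "note", tp = 5L, fp = 1L, fn = 0L, tn = 10L),
                  class = "confusion_counts")
  nc2 <- corrected_counts(nc, 1L)
  # corrected specificity: the corrected item leaves the negative pool
  expect_equal(metric_with_ci(nc2$tn, nc2$tn + nc2$fp,
                              "specificity")$estimate, 100)

  # exhaustive monotonicity over tp, fp, fn <= 50 and c <= fp
  g0 <- expand.grid(tp = 0:50, fp = 0:50, fn = 0:50)
  grid <- g0[rep(seq_len(nrow(g0)), g0$fp + 1L), ]
  grid$c <- unlist(lapply(g0$fp, function(f) 0:f))
  sens0 <- with(grid, ifelse(tp + fn > 0, tp / (tp + fn), NA))
  sens1 <- with(grid, ifelse(tp + c + fn > 0, (tp + c) / (tp + c + fn), NA))
  ppv0 <- with(grid, ifelse(tp + fp > 0, tp / (tp + fp), NA))
  ppv1 <- with(grid, ifelse(tp + fp > 0, (tp + c) / (tp + fp), NA))
  expect_true(all(sens1 >= sens0, na.rm = TRUE))
  expect_true(all(ppv1 >= ppv0, na.rm = TRUE))
})

test_that("Cohen's kappa matches hand computation and is symmetric", {
  expect_equal(cohens_kappa(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_equal(cohens_kappa(c(1, 0, 0, 0), c(1, 1, 0, 0)), 0.5)
  # invariant under swapping the two label values in both raters
  a <- c(1, 1, 0, 0, 1, 0); b <- c(1, 0, 0, 1, 1, 0)
  expect_equal(cohens_kappa(a, b), cohens_kappa(1 - a, 1 - b))
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "same note universe")

  # near zero for independently shuffled labels at large n
  set.seed(7)
  a <- rbinom(1e4, 1, 0.4)
  b <- sample(a)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (i in 1:20) {
    a <- rbinom(60, 1, 0.5); b <- rbinom(60, 1, 0.5)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
    expect_equal(cohens_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("per-concept kappa over a dual-adjudicator gold table", {
  gold <- rbind(
    data.frame(note_id = c("n1", "n2"), adjudicator_id = "a",
               concept = "hypertension", subcategory = "present",
               sentence_index = NA_integer_),
    data.frame(note_id = "n1", adjudicator_id = "b",
               concept = "hypertension", subcategory = "present",
               sentence_index = NA_integer_))
  tab <- kappa_by_concept(gold, universe = c("n1", "n2", "n3", "n4"))
  expect_equal(tab$kappa[tab$concept == "hypertension"], 0.5)
  expect_error(kappa_by_concept(gold[gold$adjudicator_id == "a", ],
                                c("n1", "n2")), "exactly two adjudicators")
})

test_that("evaluate_run produces the hand-computed table on a tiny corpus", {
  universe <- paste0("n", 1:4)
  gold <- data.frame(note_id = c("n1", "n2"), adjudicator_id = "g",
                     concept = "hypertension", subcategory = "present",
                     sentence_index = c(0L, 2L))
  pred <- list(
    sentences = data.frame(note_id = c("n1", "n3"), sentence_index = 0L,
                           category = "hypertension.present",
                           concept = "hypertension", subcategory = "present",
                           pattern_id = "p", output_id = 1L,
                           char_start = 0L, char_end = 5L),
    notes = data.frame(note_id = c("n1", "n3"),
                       category = "hypertension.present",
                       concept = "hypertension", subcategory = "present"),
    universe = universe)
  rep <- evaluate_run(gold, pred)
  m <- rep$metrics
  pick <- function(level, metric) {
    m[m$target == "hypertension" & m$level == level & m$metric == metric &
        !m$corrected, ]
  }
  expect_equal(pick("note", "sensitivity")$estimate, 50)
  expect_equal(pick("note", "specificity")$estimate, 50)
  expect_equal(pick("note", "ppv")$estimate, 50)
  expect_equal(pick("sentence", "sensitivity")$estimate, 50)
  expect_equal(pick("sentence", "ppv")$estimate, 50)
  expect_false(pick("sentence", "specificity")$estimable)

  # note-level conservation: tp+fp+fn+tn = universe size on every row
  cnt <- rep$counts[rep$counts$level == "note", ]
  expect_true(all(cnt$tp + cnt$fp + cnt$fn + cnt$tn == length(universe)))

  # concepts with no gold and no predictions are not estimable
  expect_false(any(m$estimable[m$target == "diabetes"]))
})

test_that("zero predictions: sensitivity 0, PPV not estimable, spec 100", {
  universe <- paste0("n", 1:5)
  gold <- data.frame(note_id = "n1", adjudicator_id = "g",
                     concept = "cad", subcategory = "mi",
                     sentence_index = 1L)
  pred <- list(sentences = data.frame(), notes = data.frame(),
               universe = universe)
  m <- evaluate_run(gold, pred)$metrics
  row <- function(metric, level = "note") {
    m[m$target == "cad" & m$level == level & m$metric == metric, ]
  }
  expect_equal(row("sensitivity")$estimate, 0)
  expect_equal(row("specificity")$estimate, 100)
  expect_false(row("ppv")$estimable)
})

test_that("corrections flow through evaluate_run and only upward", {
  universe <- paste0("n", 1:6)
  gold <- data.frame(note_id = c("n1", "n2"), adjudicator_id = "g",
                     concept = "diabetes", subcategory = "unspecified",
                     sentence_index = c(0L, 0L))
  pred <- list(
    sentences = data.frame(note_id = c("n1", "n2", "n3"),
                           sentence_index = 0L,
                           category = "diabetes.unspecified",
                           concept = "diabetes", subcategory = "unspecified",
                           pattern_id = "p", output_id = 1L,
                           char_start = 0L, char_end = 1L),
    notes = data.frame(note_id = c("n1", "n2", "n3"),
                       category = "diabetes.unspecified",
                       concept = "diabetes", subcategory = "unspecified"),
    universe = universe)
  corr <- data.frame(note_id = "n3", concept = "diabetes",
                     subcategory = "unspecified", sentence_index = 0L,
                     confirmed = TRUE)
  m <- evaluate_run(gold, pred, corrections = corr)$metrics
  g <- function(metric, corrected, level = "note") {
    m[m$target == "diabetes" & m$level == level & m$metric == metric &
        m$corrected == corrected, ]$estimate
  }
  expect_equal(g("ppv", FALSE), 100 * 2 / 3)
  expect_equal(g("ppv", TRUE), 100)
  expect_equal(g("sensitivity", TRUE), 100)
  expect_gte(g("specificity", TRUE), g("specificity", FALSE))

  bad <- data.frame(note_id = "n5", concept = "diabetes",
                    subcategory = "unspecified", sentence_index = 7L,
                    confirmed = TRUE)
  expect_error(evaluate_run(gold, pred, corrections = bad),
               "do not correspond")
})

test_that("dual-adjudicator gold merges by union and flags conflicts", {
  gold <- rbind(
    data.frame(note_id = c("n1", "n2"), adjudicator_id = "a",
               concept = "cad", subcategory = "mi", sentence_index = 0L),
    data.frame(note_id = "n1", adjudicator_id = "b",
               concept = "cad", subcategory = "mi", sentence_index = 0L))
  mg <- merge_gold(gold)
  expect_equal(nrow(mg$gold), 2L)
  expect_equal(mg$conflicts$note_id, "n2")
  single <- merge_gold(gold[gold$adjudicator_id == "a", ])
  expect_equal(nrow(single$conflicts), 0L)
})
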