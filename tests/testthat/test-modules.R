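test_that("shipped modules load, validate, and cover their taxonomies", {
  tax <- concept_taxonomy()
  for (name in shipped_modules()) {
    mod <- load_shipped_module(name)
    expect_s3_class(mod, "comorbidity_module")
    expect_equal(mod$name, name)
    cats <- unique(vapply(mod$patterns, `[[`, "", "category"))
    expect_setequal(cats, paste(mod$concept, tax[[mod$concept]], sep = "."))
    outs <- vapply(mod$patterns, `[[`, 1L, "output_id")
    expect_false(anyDuplicated(outs) > 0)
  }
  # the re-authored multi-level modules are structurally substantial
  for (name in c("diabetes", "cad", "stroke_tia")) {
    mod <- load_shipped_module(name)
    expect_gte(length(mod$wordclasses), 10L)
    expect_gte(length(mod$patterns), 25L)
  }
})

test_that("module validation collects and names rule errors", {
  base <- list(meta = list(name = "m", version = "1"), concept = "cad",
               wordclasses = list(CAD = list("cad"), MI = list("mi")),
               patterns = list(list(id = "p1", output = 1,
                                    category = "cad.mi", seq = "MI")))
  expect_s3_class(validate_module(base), "comorbidity_module")

  dup <- base; dup$wordclasses$MI <- list("mi", "cad")
  expect_error(validate_module(dup), "appears in multiple word classes")
  expect_error(validate_module(dup), "CAD, MI")

  dangling <- base
  dangling$patterns[[1]]$seq <- "FOO MI"
  expect_error(validate_module(dangling), "undeclared word class: FOO")

  dup_out <- base
  dup_out$patterns <- c(base$patterns, list(list(id = "p2", output = 1,
                                                 category = "cad.mi",
                                                 seq = "CAD")))
  expect_error(validate_module(dup_out), "duplicate output id")

  bad_cat <- base
  bad_cat$patterns[[1]]$category <- "diabetes.type1"
  expect_error(validate_module(bad_cat), "category not in module taxonomy")

  reserved <- base; reserved$wordclasses$UNKNOWN <- list("x")
  expect_error(validate_module(reserved), "reserved word-class name")

  # failures are collected, not reported one at a time
  multi <- dup
  multi$patterns[[1]]$seq <- "FOO MI"
  err <- tryCatch(validate_module(multi), error = conditionMessage)
  expect_match(err, "multiple word classes")
  expect_match(err, "undeclared word class")
})

test_that("module serialization round-trips", {
  mod <- load_shipped_module("cad")
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_module(mod, f1)
  re <- load_module(f1)
  write_module(re, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(re$wordclasses, mod$wordclasses)
  expect_identical(lapply(re$patterns, `[`, c("pattern_id", "output_id",
                                              "category", "seq")),
                   lapply(mod$patterns, `[`, c("pattern_id", "output_id",
                                               "category", "seq")))
})

test_that("sentence extraction reproduces the worked adjudication examples", {
  expect_setequal(
    extract_sentence(
      "Mr. Smith has a history of CAD s/p MI in 2018 requiring 2 stents to his LAD",
      shipped()$cad, ctx())$categories,
    c("cad.unspecified", "cad.mi", "cad.revascularization"))
  expect_equal(
    extract_sentence("Mrs. Smith has a history of elevated cholesterol",
                     shipped()$dyslipidemia, ctx())$categories,
    "dyslipidemia.present")
  expect_equal(
    extract_sentence("History: uncontrolled hemoglobin A1c",
                     shipped()$diabetes, ctx())$categories,
    "diabetes.unspecified")
  expect_length(
    extract_sentence("The patient has no personal history of CAD",
                     shipped()$cad, ctx())$categories, 0L)
  expect_length(
    extract_sentence("Family history of ischemic heart disease",
                     shipped()$cad, ctx())$categories, 0L)
})

test_that("numeric stenosis guard separates above from below 50%", {
  cadm <- shipped()$cad
  expect_true("cad.stenosis_gt50" %in% extract_sentence(
    "Catheterization revealed a 70% stenosis of the proximal LAD",
    cadm, ctx())$categories)
  expect_false("cad.stenosis_gt50" %in% extract_sentence(
    "Catheterization revealed a 30% stenosis of the proximal LAD",
    cadm, ctx())$categories)
  expect_false("cad.stenosis_gt50" %in% extract_sentence(
    "A stenosis was noted in 2018", cadm, ctx())$categories)
})

test_that("note-level flags are unions over sentences", {
  note <- list(note_id = "n1",
               text = paste("Known hypertension.",
                            "Blood pressure has been elevated.",
                            "No history of diabetes.", sep = "\n"))
  ann <- extract_note(note, shipped()$hypertension, ctx())
  expect_true(ann$concept_present)
  expect_length(ann$sentence_annotations, 2L)
  expect_true(ann$subcategory_present[["present"]])

  # a note whose only diagnostic sentence is negated: all flags false
  ann2 <- extract_note(list(note_id = "n2",
                            text = "No history of hypertension."),
                       shipped()$hypertension, ctx())
  expect_false(ann2$concept_present)
  expect_length(ann2$sentence_annotations, 0L)

  ann3 <- extract_note(list(note_id = "n3", text = ""),
                       shipped()$hypertension, ctx())
  expect_false(ann3$concept_present)
})

test_that("subcategory presence always implies concept presence", {
  corp <- generate_corpus(generator_config(n_notes = 40, seed = 11))
  pred <- extract_corpus(corp$notes)
  # every note with a subcategory row has >=1 sentence row of that concept
  for (i in seq_len(nrow(pred$notes))) {
    sel <- pred$sentences$note_id == pred$notes$note_id[i] &
      pred$sentences$concept == pred$notes$concept[i]
    expect_gt(sum(sel), 0L)
  }
})

test_that("modules are independent: any run order gives the same result", {
  corp <- generate_corpus(generator_config(n_notes = 15, seed = 21))
  fwd <- extract_corpus(corp$notes, shipped_modules())
  rev <- extract_corpus(corp$notes, rev(shipped_modules()))
  key <- function(df) {
    k <- do.call(paste, c(df[c("note_id", "sentence_index", "category",
                               "pattern_id")], sep = "|"))
    sort(k)
  }
  expect_identical(key(fwd$sentences), key(rev$sentences))
})

test_that("no module fires on a pure distractor corpus", {
  cfg <- generator_config(n_notes = 60, seed = 31,
                          prevalence = default_prevalence() * 0,
                          family_history_rate = 0.5)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$gold), 0L)
  pred <- extract_corpus(corp$notes)
  expect_equal(nrow(pred$sentences), 0L)
  expect_equal(nrow(pred$notes), 0L)
})

test_that("extraction is deterministic across repeated runs", {
  corp <- generate_corpus(generator_config(n_notes = 10, seed = 5))
  a <- extract_corpus(corp$notes)
  b <- extract_corpus(corp$notes)
  expect_identical(a$sentences, b$sentences)
  expect_identical(a$notes, b$notes)
})
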